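---
title: "Predicting predominant MMEJ deletion alleles: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting predominant MMEJ deletion alleles: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(premascan)
```

## The repair model

A programmable nuclease places a double-strand break (DSB) at a predictable
position. Two end-joining pathways then compete. Non-homologous end joining
(NHEJ) is versatile and produces a broad spectrum of small indels; its
outcome at a given locus is effectively unpredictable at base-pair
resolution. Microhomology-mediated end joining (MMEJ) instead resects the
ends, anneals a pair of identical direct repeats — *microhomology arms* —
located on opposite sides of the break, and ligates, deleting the
intervening sequence together with one arm copy. Because the arms are fixed
features of the locus, an MMEJ repair event is stereotyped: the same pair of
arms always yields the same deletion allele.

premascan treats every pair of identical repeats of at least `min_arm` bp
(default 3; 2 bp repeats are not considered productive MMEJ substrates and
are accepted only through a legacy comparison flag) with the left copy
entirely 5′ of the break and the right copy entirely 3′ of it, both within a
search window (default 40 bp per side), as one candidate deletion. Arms may
abut the break but may not straddle it — this matches the behaviour of the
published reference search this scoring scheme originates from, which the
package reproduces digit for digit.

### Pattern Score

Each pattern is scored as

$$S = 100 \cdot e^{-\Delta/20} \cdot (n_{AT} + 2\,n_{GC})$$

with $\Delta$ the deletion length (distance between the two arm copies,
which equals arm length + intervening length), and $n_{AT}$, $n_{GC}$ the
arm's base counts. GC pairs weigh double, reflecting annealing stability;
the exponential, with a fixed decay constant of 20 bp, halves the score
roughly every 14 bp of deletion. For bit-parity with the reference
implementation the length factor $e^{-\Delta/20}$ is rounded to 3 decimals
before multiplication (`replicate_reference_rounding`, on by default; a flag
disables it). The sum of all pattern scores at a locus is its *Microhomology
Score*, and the score-weighted share of patterns whose $\Delta$ is not a
multiple of 3 is the *out-of-frame score* (reported as missing, not zero,
for a locus with no pattern).

### Deduplication

A short arm nested inside a longer one often describes the same physical
deletion. A pattern is removed when its arm is a substring of a longer
pattern's arm **and** both deletions produce the identical resulting
sequence — indistinguishable outcomes must not compete against themselves.
Equality is decided on the windowed region, which is equivalent to
whole-sequence equality because the flanks outside the window are shared.
Patterns with the same arm at different offsets that produce *different*
alleles are kept: they are real alternative outcomes.

```{r}
p <- enumerate_patterns(target_locus("ACGTACGT", 4, window = 4))
p  # ACG / CGT collapse into ACGT
```

## Competition metrics and the four groups

Enumerated patterns are ranked by descending score. Ties are broken
deterministically — longer arm, then smaller deletion, then smaller left
coordinate — so that identical inputs always give identical reports; the
ordering beyond the score is a package convention, since "top" and "second"
are only meaningful given a total order.

Two criteria classify a locus:

* **Criterion 1 (proximity)**: the top pattern's arm copies are separated by
  at most 5 bp of intervening sequence. Note this measures the gap between
  the copies, not the deletion length.
* **Criterion 2 (dominance)**: the top-to-second score ratio is at least
  1.5. A locus with a single pattern has no competitor; we treat its ratio
  as infinite (zero competition is the limit of low competition) and the
  criterion as satisfied. An exact score tie gives ratio 1.0 and fails the
  criterion — a tied allele cannot be "predominant" — and the profile
  carries a tie flag.

Group 4 = both criteria, Group 3 = proximity only, Group 2 = dominance only,
Group 1 = neither; every locus with at least one pattern lands in exactly
one group. Group 4 sites are the PreMA candidates the scanner recommends
(Group 3 can be included on request).

### Slope Value

The earlier single-number competition summary is retained: the
ordinary-least-squares slope of score against 1-based rank over the top 10
ranked patterns (all, if fewer), in score units per rank, with the
historical low-competition cutoff at −40 behind the `classifier = "slope"`
flag. The source material names this quantity and its cutoff but does not
print its formula; the OLS-over-top-10 definition here is a
**reconstruction** that reproduces the cutoff's units and the flat-vs-steep
dichotomy, and `top_n` is configurable because the original choice of depth
is unknown. It should not be quoted as the original authors' exact formula.

## Scanning

`scan_sites()` places candidate protospacers at every IUPAC-PAM match on
both strands (`Biostrings::matchPattern`; a window containing an ambiguity
code in the subject never matches). The default scheme is SpCas9: 20 nt
guide, NGG PAM, blunt cut between protospacer positions 17 and 18
(`cut_offset = -3` from the PAM-proximal end) — configurable for other
nucleases. TALEN layouts are supported by placing the break at the spacer
midpoint (`talen_cut_index()`; the extra base of an odd spacer goes 5′).
TALEN pairs actually produce staggered 5′ overhangs; collapsing the overhang
to a single break index is a documented simplification, acceptable because
the scoring model is break-position based.

Sites without a full guide inside the supplied sequence are dropped; sites
whose search window overruns the sequence end are kept with a
`truncated_window` flag rather than silently discarded; sites with no
pattern are kept ungrouped and never recommended. For prevalence summaries,
forward- and reverse-strand PAMs implying the same break position share one
deletion landscape and are counted as one *unique cut site* (both guides are
still reported). A practical input convention for exon screens is the whole
exon plus ~40 bp of intronic flank on each side, so that every candidate cut
inside the exon has a full window; the package documents but does not
enforce this.

## Observed-outcome accounting

`classify_reads()` compares each observed allele of an analysis window
(typically ±25 bp around the cut, i.e. `target_locus(..., window = 25)`)
against the wildtype window and the deletion alleles of every enumerated
pattern. A read matches a deletion allele if it has at most 2 substitutions,
none of which fall on the retained microhomology arm; under the same
tolerance with no indel it is wildtype. Matching is attempted in rank order:
the top pattern yields `top_mh`, any other enumerated pattern `other_mmej`,
anything else alignable `other_mutant`. Insertions are never
MMEJ-consistent, including compound deletion+insertion alleles. Reads with
non-ACGT characters or with an indel too large to be contained in the
window (|length difference| > 2 × window) are `excluded` and leave all
denominators.

From the classified table, `compute_metrics()` reports:

* **mutagenic efficiency** = mutant / (wildtype + mutant) reads;
* **Microhomology Fraction** = (`top_mh` + `other_mmej`) / mutant reads;
* **Top MH Fraction** = `top_mh` / mutant reads;
* **PreMA** = the top predicted allele is the modal mutant allele (strictly
  more reads than any other single mutant allele), Top MH Fraction ≥ 0.5,
  and efficiency **strictly** > 20 %.

The efficiency comparisons are deliberately twofold: the PreMA definition
uses strict `> 0.2`, while the separate `low_activity` flag (`< 0.2`) marks
loci conventionally excluded from retrospective correlation analyses. The
Microhomology Fraction and Top MH Fraction formulas are **reconstructions**:
their source definitions exist only as supplementary-note titles, so the
package defines them as above (any enumerated ≥ 3 bp pattern's deletion
counts as MMEJ-consistent, with the same substitution tolerance) and says so
here rather than presenting them as the original formulas.
`tide_adjusted_prevalence()` applies the same idea to indel-size
decompositions from chromatogram tools: the predicted deletion size's share
of significant mutant signal.

## Synthetic ground-truth loci

`plant_locus()` builds test substrates whose entire microhomology landscape
is known. One main arm pair (length, GC content and intervening gap from the
spec) is planted around the break, optionally with decoy pairs (3 bp arms
drawn from a catalog disjoint from the main arm's 3-mer content) whose
scores are tuned toward `decoy_strength` × main score through deletion
length and arm composition; because deletion lengths are integers the
*achieved* strength is reported back, and the ground-truth group is derived
from achieved scores, never from the request. The i.i.d. background is then
audited by an independent brute-force scan: every maximal cross-break repeat
of ≥ 3 bp must be a planted pair. Strays are repaired by resampling a free
(non-planted) base; if repair stalls, a fresh background is drawn (up to 20
draws × 200 repairs) and otherwise generation fails loudly. This makes
ground truth a guarantee rather than a probability.

The audit is combinatorial: with a window of $w$ bp per side, roughly
$w^2/64$ stray 3-mer pairs are expected in random sequence, so the audited
window defaults to 20 bp per side (windows much beyond ~25 bp rarely
converge, and the generator then fails rather than degrade). What the
generator emulates is the *local competition structure* of real loci — one
strong pair, near-equal swarms, distant arms. What it does not emulate:
genomic base composition and repeat families, sequencing error beyond
uniform off-arm substitutions, NHEJ insertion spectra, or chromatin context.
Green tests on fixtures therefore validate the algorithmic contract
(enumeration, scoring, classification, accounting), not the biological
accuracy of the score itself on real genomes.

`simulate_allele_table()` draws multinomial reads over
wildtype / top-MH / other-MMEJ / other-mutant templates (the non-MMEJ mutant
is a 1 bp insertion at the break, which the classifier can never call
MMEJ-consistent), with optional uniform substitutions sprinkled off-arm, and
retains ground-truth labels.

## Numerical choices and conventions

* Coordinates are 0-based, half-open everywhere in code; `cut_index` counts
  bases 5′ of the break. CSV reports add 1-based twin columns for humans.
* Degenerate inputs: empty pattern lists give `NA` out-of-frame score and
  no competition profile (a site is then "ungrouped", never recommended);
  fewer than 2 patterns give `NA` Slope Value; zero mutant reads give
  missing fractions and a false PreMA call.
* Ambiguity codes: enumeration rejects non-ACGT inside the search window,
  naming the offending position, rather than guessing repeat identity;
  codes outside the window are tolerated.
* Determinism: every ranking tie-break is total; reports are byte-identical
  across runs on identical inputs; all stochastic helpers take explicit
  seeds and restore the caller's RNG state.

## Validation scale

The shipped suite validates enumeration against an independent brute-force
substring-pair oracle on 200 random loci (≤ 60 bp) plus 30 more in unit
tests, score parity against a transcription of the reference algorithm on
50 random 80-mers, group recovery on 400 planted loci (100 per group
archetype: lone proximal arm; proximal arm with near-equal decoys; lone
distant arm; distant arm with decoys), and the outcome pipeline on planted
allele tables including the published clone counts 21/24, 16/32 and 28/39.
These sizes keep the whole suite in a few tens of seconds while giving each
property hundreds of independent cases; `scripts/acceptance.R` re-runs the
same checks from scratch under a user seed and adds a whole-gene prevalence
screen on a **synthetic** 3 kb gene (random sequence at 42 % GC). On such
synthetic genes the recommended fraction of unique NGG cut sites comes out
near 10 %, with the majority of recommended sites predicted out-of-frame;
real genes carry repeat structure that random sequence does not, so those
numbers characterise the method's behaviour, not any particular genome.

## Known limitations

* The score is sequence-only: chromatin state, cell-cycle phase and pathway
  factor abundance all modulate MMEJ activation and are out of scope.
* Insertion and templated-insertion outcomes are not modelled; machine-
  learned repair predictors are deliberately out of scope.
* The Slope Value and the two outcome fractions are reconstructions (see
  above) and should be cited as this package's definitions.
* TALEN overhang geometry is collapsed to a single break position.
* Read classification assumes pre-aligned analysis windows; alignment and
  mapping are upstream of this package.
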