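# premascan

Predictable gene editing needs predictable DNA repair. Microhomology-mediated
end joining (MMEJ) repairs a double-strand break by annealing a pair of
identical direct repeats ("microhomology arms", here ≥ 3 bp) that flank the
break, deleting the intervening sequence plus one repeat copy — a stereotyped
outcome, unlike the diverse indel spectrum of non-homologous end joining.
**premascan** finds nuclease target sites where one MMEJ deletion is predicted
to dominate the mutant allele pool, so that a single injection or transfection
yields a predominantly single mutant allele (a *PreMA* outcome: Predominant
MMEJ Allele).

It is aimed at genome engineers designing CRISPR gRNAs or TALENs — for F0
phenotyping in zebrafish and other models, for knockout cell lines, and for
in-frame deletion work — and at anyone quantifying MMEJ activity from observed
allele tables.

## The model

Every pair of identical ≥ 3 bp repeats with one copy on each side of the
break defines a candidate deletion of length Δ (the distance between the two
copies). Each candidate gets a **Pattern Score**

    S = 100 × exp(−Δ / 20) × (n_AT + 2 n_GC)

where `n_AT`/`n_GC` count the arm's bases (GC pairs weigh double) and the
exponential penalises long deletions; the sum of all pattern scores at a
locus is its **Microhomology Score**. Local microhomology pairs compete, so a
high-scoring pattern is not enough — it must also *win*. Two criteria
classify every locus (Competition Hypothesis V2):

1. **Proximity** — the top pattern's arm copies are separated by ≤ 5 bp;
2. **Dominance** — the top-to-second Pattern Score ratio is ≥ 1.5.

Group 4 (both) is recommended as a PreMA candidate; Group 3 (proximity only)
is intermediate; Groups 1–2 (no proximity) favour NHEJ-type outcomes. From
observed alleles, the package computes mutagenic efficiency, the
*Microhomology Fraction* (MMEJ-consistent mutant reads / mutant reads), the
*Top MH Fraction* (top-predicted-allele reads / mutant reads) and the PreMA
call (modal top allele, Top MH Fraction ≥ 0.5, efficiency > 20 %).

## Worked example

```r
library(premascan)

# a 60 bp locus carrying one strong 6 bp microhomology pair (CTAAGG) with
# zero intervening bases, plus an SpCas9 NGG PAM placing the cut between them
locus <- paste0(strrep("A", 24), "CTAAGG", "CTAAGG", strrep("T", 24))

sites <- scan_sites(locus, targeting_scheme("NGG"), scan_config(window = 20))
sites[sites$recommended, c("cut_index", "guide_seq", "top_arm_seq",
                           "top_deletion_len", "ratio", "group")]
#> <candidate_sites> 1 candidate guide(s)
#>   cut_index            guide_seq top_arm_seq top_deletion_len ratio group
#> 2        30 AAAAAAAAAAACTAAGGCTA      CTAAGG                6   Inf     4

profile_cut_site(locus, 30, scan_config(window = 20))$profile
#> <competition_profile>
#>   patterns: 1  top: CTAAGG (6 bp deletion, score 666.9)
#>   ratio top/second: Inf   slope value: NA
#>   criterion 1 (spacing <= 5 bp): TRUE   criterion 2 (ratio >= 1.5): TRUE
#>   group: 4  ** PreMA candidate **
```

The one NGG site whose break falls between the two `CTAAGG` copies is
recommended: its only deletion pattern removes 6 bp (one arm copy plus
nothing in between), scores 100 × 0.741 × 9 = 666.9, and has no competitor
(ratio ∞), so both criteria hold and the site is Group 4. A second NGG site
on the same sequence has no cross-break repeat at all and is reported
ungrouped, never recommended.

Observed outcomes are scored the same way:

```r
loc <- target_locus(locus, 30, window = 20)
tab <- data.frame(allele_seq = c(locus, predicted_allele(loc,
                    enumerate_patterns(loc)[1, ])$resulting_sequence),
                  count = c(10, 30))
compute_metrics(classify_reads(tab, loc, scan_config(window = 20)))
#> <outcome_metrics>
#>   reads: 40 (30 mutant, 0 excluded)
#>   mutagenic efficiency: 0.750
#>   MH fraction: 1.000   top MH fraction: 1.000
#>   PreMA: TRUE
```

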