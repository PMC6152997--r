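#' Classify observed alleles against the predicted MMEJ deletion landscape
#'
#' Labels each observed allele of an analysis window (typically +/- 25 bp
#' around the cut) by comparison with the wildtype window and with the
#' deletion alleles implied by every enumerated microhomology pattern.
#' An allele counts as a pattern's deletion when it matches that pattern's
#' predicted sequence with at most `max_mismatch` substitutions, none of
#' which fall on the retained microhomology arm. The top-ranked pattern
#' yields `top_mh`; any other pattern yields `other_mmej`. Alleles matching
#' the wildtype window under the same substitution tolerance (no indel) are
#' `wildtype`; anything else alignable is `other_mutant`. Alleles with
#' non-ACGT characters or an indel too large to be contained in the window
#' are `excluded`.
#'
#' @param alleles data frame of observed alleles with a `count` column and
#'   either `allele_seq` (the full analysis-window sequence) or an indel
#'   descriptor (`del_start` 0-based, `del_len`, `ins_seq`; the allele is
#'   reconstructed from the wildtype window).
#' @param locus a [target_locus()] describing the analysis window (its
#'   `sequence` is the wildtype window, `cut_index` the break, `window`
#'   the tolerated indel reach, typically 25).
#' @param config a [scan_config()] used to enumerate patterns when
#'   `patterns` is not supplied.
#' @param patterns optional precomputed [enumerate_patterns()] output for
#'   `locus`.
#' @param max_mismatch substitution tolerance per read (default 2).
#' @return `alleles` with an added `class_label` column (factor over
#'   wildtype/top_mh/other_mmej/other_mutant/excluded).
#' @export
classify_reads <- function(alleles, locus, config = scan_config(window = 25L),
                           patterns = NULL, max_mismatch = 2L) {
  stopifnot(inherits(locus, "target_locus"), is.data.frame(alleles))
  wt <- locus$sequence
  if (is.null(alleles$allele_seq)) {
    if (is.null(alleles$del_start)) {
      stop("alleles must carry allele_seq or an indel descriptor ",
           "(del_start, del_len, ins_seq)")
    }
    ins <- if (is.null(alleles$ins_seq)) "" else ifelse(is.na(alleles$ins_seq), "", alleles$ins_seq)
    alleles$allele_seq <- toupper(paste0(
      substr(rep(wt, nrow(alleles)), 1L, alleles$del_start),
      ins,
      substring(wt, alleles$del_start + alleles$del_len + 1L)))
  } else {
    alleles$allele_seq <- toupper(alleles$allele_seq)
  }
  if (is.null(alleles$count)) stop("alleles must carry a count column")
  if (any(alleles$count < 1L)) stop("allele counts must be >= 1")

  if (is.null(patterns)) patterns <- enumerate_patterns(locus, config)
  ranked <- rank_patterns(patterns)
  cand <- lapply(seq_len(nrow(ranked)), function(i) {
    predicted_allele(locus, ranked[i, ])
  })
  cand_seq <- vapply(cand, `[[`, character(1), "resulting_sequence")
  cand_len <- nchar(cand_seq)

  wl <- nchar(wt)
  lab <- character(nrow(alleles))
  for (r in seq_len(nrow(alleles))) {
    a <- alleles$allele_seq[r]
    if (first_non_acgt(a) > 0L) { lab[r] <- "excluded"; next }
    al <- nchar(a)
    # an indel must be containable inside the analysis window (cut +/- window)
    if (abs(al - wl) > 2L * locus$window) { lab[r] <- "excluded"; next }
    if (al == wl) {
      lab[r] <- if (hamming(a, wt) <= max_mismatch) "wildtype" else "other_mutant"
      next
    }
    lab[r] <- "other_mutant"
    if (al < wl) {
      for (i in which(cand_len == al)) {
        mm <- mismatch_positions(a, cand_seq[i])
        if (length(mm) <= max_mismatch &&
            !any(mm > cand[[i]]$junction_pos &
                 mm <= cand[[i]]$junction_pos + nchar(cand[[i]]$junction_arm))) {
          lab[r] <- if (i == 1L) "top_mh" else "other_mmej"
          break
        }
      }
    }
  }
  alleles$class_label <- factor(lab, levels = c("wildtype", "top_mh",
                                                "other_mmej", "other_mutant",
                                                "excluded"))
  alleles
}

hamming <- function(a, b) {
  sum(utf8ToInt(a) != utf8ToInt(b))
}

# 1-based positions at which two equal-length strings differ
mismatch_positions <- function(a, b) {
  which(utf8ToInt(a) != utf8ToInt(b))
}

#' Repair-outcome metrics and the PreMA call
#'
#' Aggregates a classified allele table into the outcome metrics:
#' \describe{
#'   \item{mutagenic efficiency}{mutant reads / total (non-excluded) reads}
#'   \item{Microhomology Fraction}{MMEJ-consistent mutant reads (top or
#'     other enumerated deletion) / mutant reads}
#'   \item{Top MH Fraction}{top-predicted-allele reads / mutant reads}
#' }
#' A locus is called PreMA (Predominant MMEJ Allele) when the top predicted
#' allele is the modal mutant allele, comprises at least 50\% of the mutant
#' allele population, and mutagenic efficiency exceeds 20\% (strict).
#' Loci below 20\% efficiency are additionally flagged `low_activity`
#' (conventionally excluded from retrospective correlation analyses).
#'
#' @param classified output of [classify_reads()].
#' @return Object of class `outcome_metrics`: list with `total_reads`,
#'   `mutant_reads`, `excluded_reads`, `mutagenic_efficiency`,
#'   `mh_fraction`, `top_mh_fraction`, `modal_is_top`, `prema`,
#'   `low_activity`.
#' @examples
#' loc <- target_locus("ACGTACGT", 4, window = 4)
#' tab <- data.frame(allele_seq = c("ACGTACGT", "ACGT"), count = c(10, 30))
#' compute_metrics(classify_reads(tab, loc, scan_config(window = 4)))
#' @export
compute_metrics <- function(classified) {
  stopifnot(is.data.frame(classified), !is.null(classified$class_label))
  keep <- classified$class_label != "excluded"
  cl <- classified[keep, , drop = FALSE]
  total <- sum(cl$count)
  n_wt <- sum(cl$count[cl$class_label == "wildtype"])
  mutant <- total - n_wt
  n_top <- sum(cl$count[cl$class_label == "top_mh"])
  n_mmej <- n_top + sum(cl$count[cl$class_label == "other_mmej"])
  eff <- if (total > 0) mutant / total else NA_real_
  if (mutant > 0) {
    mh_fr <- n_mmej / mutant
    top_fr <- n_top / mutant
    mut <- cl[cl$class_label != "wildtype", , drop = FALSE]
    other <- mut[mut$class_label != "top_mh", , drop = FALSE]
    other_max <- if (nrow(other)) max(tapply(other$count, other$allele_seq, sum)) else 0
    modal_is_top <- n_top > other_max
  } else {
    mh_fr <- NA_real_
    top_fr <- NA_real_
    modal_is_top <- FALSE
  }
  prema <- isTRUE(modal_is_top) && !is.na(top_fr) && top_fr >= 0.5 &&
    !is.na(eff) && eff > 0.2
  structure(list(total_reads = total, mutant_reads = mutant,
                 excluded_reads = sum(classified$count[!keep]),
                 mutagenic_efficiency = eff, mh_fraction = mh_fr,
                 top_mh_fraction = top_fr, modal_is_top = modal_is_top,
                 prema = prema,
                 low_activity = !is.na(eff) && eff < 0.2),
            class = "outcome_metrics")
}

#' @export
print.outcome_metrics <- function(x, ...) {
  fr <- function(v) if (is.na(v)) "NA" else formatC(v, format = "f", digits = 3)
  cat("<outcome_metrics>\n",
      "  reads: ", x$total_reads, " (", x$mutant_reads, " mutant, ",
      x$excluded_reads, " excluded)\n",
      "  mutagenic efficiency: ", fr(x$mutagenic_efficiency),
      if (x$low_activity) "  [low activity]" else "", "\n",
      "  MH fraction: ", fr(x$mh_fraction),
      "   top MH fraction: ", fr(x$top_mh_fraction), "\n",
      "  PreMA: ", x$prema, "\n", sep = "")
  invisible(x)
}

#' @export
#' @method as.data.frame outcome_metrics
as.data.frame.outcome_metrics <- function(x, ...) {
  data.frame(total_reads = x$total_reads, mutant_reads = x$mutant_reads,
             excluded_reads = x$excluded_reads,
             mutagenic_efficiency = x$mutagenic_efficiency,
             mh_fraction = x$mh_fraction, top_mh_fraction = x$top_mh_fraction,
             modal_is_top = x$modal_is_top, prema = x$prema,
             low_activity = x$low_activity)
}

#' Adjusted prevalence of the predicted deletion in a TIDE decomposition
#'
#' Renormalises an indel-size decomposition (as produced by chromatogram
#' deconvolution tools) to the mutant signal only and reports the share of
#' the predicted deletion size — the decomposition analogue of the Top MH
#' Fraction.
#'
#' @param tide_table data frame with `indel_size` (signed; deletions
#'   negative, 0 = wildtype), `pct` (percent or proportion of total
#'   signal) and optionally `significant` (logical; non-significant rows
#'   are ignored).
#' @param predicted the predicted deletion: a [predicted_allele()] object
#'   or a signed indel size (a positive value is interpreted as a deletion
#'   length).
#' @return Fraction in `[0, 1]` of significant mutant signal attributed to
#'   the predicted deletion size; 0 with a warning when the predicted size
#'   is absent.
#' @export
tide_adjusted_prevalence <- function(tide_table, predicted) {
  stopifnot(is.data.frame(tide_table), !is.null(tide_table$indel_size),
            !is.null(tide_table$pct))
  size <- if (inherits(predicted, "deletion_allele")) {
    -predicted$deletion_len
  } else if (predicted > 0) -as.numeric(predicted) else as.numeric(predicted)
  tt <- tide_table
  if (!is.null(tt$significant)) tt <- tt[tt$significant %in% TRUE, , drop = FALSE]
  mut <- tt[tt$indel_size != 0, , drop = FALSE]
  if (nrow(mut) == 0L || sum(mut$pct) <= 0) {
    warning("no significant mutant signal in decomposition table")
    return(0)
  }
  hit <- mut$pct[mut$indel_size == size]
  if (length(hit) == 0L) {
    warning("predicted deletion size ", size, " absent from decomposition table")
    return(0)
  }
  sum(hit) / sum(mut$pct)
}
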