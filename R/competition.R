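#' Rank microhomology patterns by Pattern Score
#'
#' Sorts patterns by descending score with a deterministic tie-break:
#' longer arm first, then smaller deletion length, then smaller left start.
#'
#' @param patterns output of [enumerate_patterns()].
#' @return The same data frame, reordered; row names reset.
#' @export
rank_patterns <- function(patterns) {
  if (nrow(patterns) == 0L) return(patterns)
  o <- order(-patterns$score, -patterns$arm_len, patterns$deletion_len,
             patterns$left_start)
  out <- patterns[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Top-to-second Pattern Score ratio
#'
#' The competition ratio between the two strongest predicted MMEJ
#' deletions. A single-pattern locus has no competitor: the ratio is `Inf`
#' (zero competition is the limiting case of low competition). Exact ties
#' give 1.0 — a tied top allele cannot be predominant.
#'
#' @param ranked ranked patterns from [rank_patterns()] (non-empty).
#' @return `top_score / second_score` (`Inf` for a single pattern).
#' @export
top_ratio <- function(ranked) {
  n <- nrow(ranked)
  if (n == 0L) stop("no patterns: competition is undefined at this locus")
  if (n == 1L) return(Inf)
  ranked$score[1] / ranked$score[2]
}

#' Slope Value of the ranked score profile
#'
#' Ordinary-least-squares slope of Pattern Score against 1-based rank over
#' the strongest `top_n` patterns (all patterns when fewer). Units are
#' score per rank; the slope is never positive for a ranked profile. A
#' steeply negative slope marks a low-competition locus (one or two
#' dominant repeats); a flat slope marks many near-equal competitors.
#' The historical low-competition rule used a cutoff of -40.
#'
#' @param ranked ranked patterns (data frame with a `score` column) or a
#'   numeric vector of scores already in rank order.
#' @param top_n number of top-ranked patterns entering the fit (default 10).
#' @return The OLS slope, or `NA` when fewer than 2 patterns exist.
#' @examples
#' slope_value(c(100, 60, 20))  # -40
#' @export
slope_value <- function(ranked, top_n = 10L) {
  s <- if (is.data.frame(ranked)) ranked$score else as.numeric(ranked)
  m <- min(length(s), top_n)
  if (m < 2L) return(NA_real_)
  s <- s[seq_len(m)]
  r <- seq_len(m)
  sum((r - mean(r)) * (s - mean(s))) / sum((r - mean(r))^2)
}

#' Classify a locus under Competition Hypothesis V2
#'
#' Two criteria decide the group of a locus:
#' \describe{
#'   \item{Criterion 1 (proximity)}{the top-ranked pattern's arm copies are
#'     separated by at most 5 bp of intervening sequence.}
#'   \item{Criterion 2 (dominance)}{the top-to-second Pattern Score ratio
#'     is at least 1.5 (satisfied vacuously by a single-pattern locus;
#'     failed by an exact tie).}
#' }
#' Group 4 = both, Group 3 = proximity only, Group 2 = dominance only,
#' Group 1 = neither. Group 4 loci are predicted to yield a predominant
#' MMEJ allele (PreMA candidates).
#'
#' @param ranked ranked patterns from [rank_patterns()].
#' @param max_intervening Criterion 1 spacing threshold in bp (default 5).
#' @param min_ratio Criterion 2 ratio threshold (default 1.5).
#' @return A list with `criterion1`, `criterion2`, `tie`, `group` (integer
#'   1-4) and `prema_candidate` (`group == 4`).
#' @export
classify_group <- function(ranked, max_intervening = 5L, min_ratio = 1.5) {
  n <- nrow(ranked)
  if (n == 0L) stop("no patterns: locus cannot be grouped")
  ratio <- top_ratio(ranked)
  tie <- n >= 2L && ranked$score[1] == ranked$score[2]
  c1 <- ranked$intervening_len[1] <= max_intervening
  c2 <- !tie && ratio >= min_ratio
  group <- if (c1 && c2) 4L else if (c1) 3L else if (c2) 2L else 1L
  list(criterion1 = c1, criterion2 = c2, tie = tie, ratio = ratio,
       group = group, prema_candidate = group == 4L)
}

#' Competition profile of a locus
#'
#' Runs the full per-locus analysis: ranks the patterns, computes the
#' top-to-second ratio and Slope Value, applies the V2 criteria and, when
#' the legacy classifier is requested, the slope-based low-competition
#' call (slope below `slope_cutoff`).
#'
#' @param patterns output of [enumerate_patterns()].
#' @param top_n patterns entering the Slope Value fit.
#' @param classifier `"v2"` (default, the two-criterion group scheme) or
#'   `"slope"` (legacy: low competition when the Slope Value is below
#'   `slope_cutoff`).
#' @param slope_cutoff legacy low-competition cutoff (default -40,
#'   score units per rank).
#' @return An object of class `competition_profile`: list with
#'   `ranked_patterns`, `top_score`, `second_score`, `ratio`,
#'   `slope_value`, `criterion1`, `criterion2`, `tie`, `group`,
#'   `prema_candidate`, `classifier` and (legacy mode) `low_competition`.
#' @examples
#' p <- enumerate_patterns(target_locus("ACGTACGT", 4, window = 4))
#' competition_profile(p)
#' @export
competition_profile <- function(patterns, top_n = 10L,
                                classifier = c("v2", "slope"),
                                slope_cutoff = -40) {
  classifier <- match.arg(classifier)
  ranked <- rank_patterns(patterns)
  n <- nrow(ranked)
  if (n == 0L) stop("no patterns: locus has no competition profile")
  cls <- classify_group(ranked)
  sv <- slope_value(ranked, top_n = top_n)
  out <- list(ranked_patterns = ranked,
              top_score = ranked$score[1],
              second_score = if (n >= 2L) ranked$score[2] else NA_real_,
              ratio = cls$ratio,
              slope_value = sv,
              criterion1 = cls$criterion1,
              criterion2 = cls$criterion2,
              tie = cls$tie,
              group = cls$group,
              prema_candidate = cls$prema_candidate,
              classifier = classifier)
  if (classifier == "slope") {
    out$low_competition <- !is.na(sv) && sv < slope_cutoff
  }
  class(out) <- "competition_profile"
  out
}

#' @export
print.competition_profile <- function(x, ...) {
  top <- x$ranked_patterns[1, ]
  cat("<competition_profile>\n",
      "  patterns: ", nrow(x$ranked_patterns),
      "  top: ", top$arm_seq, " (", top$deletion_len, " bp deletion, score ",
      formatC(x$top_score, format = "f", digits = 1), ")\n",
      "  ratio top/second: ",
      if (is.finite(x$ratio)) formatC(x$ratio, format = "f", digits = 2) else "Inf",
      "   slope value: ",
      if (is.na(x$slope_value)) "NA" else formatC(x$slope_value, format = "f", digits = 1),
      "\n  criterion 1 (spacing <= 5 bp): ", x$criterion1,
      "   criterion 2 (ratio >= 1.5): ", x$criterion2,
      "\n  group: ", x$group,
      if (x$prema_candidate) "  ** PreMA candidate **" else "", "\n", sep = "")
  if (identical(x$classifier, "slope")) {
    cat("  legacy slope classifier: low competition = ", x$low_competition, "\n", sep = "")
  }
  invisible(x)
}

#' @export
#' @method summary competition_profile
summary.competition_profile <- function(object, ...) {
  data.frame(n_patterns = nrow(object$ranked_patterns),
             top_score = object$top_score,
             second_score = object$second_score,
             ratio = object$ratio,
             slope_value = object$slope_value,
             criterion1 = object$criterion1,
             criterion2 = object$criterion2,
             group = object$group,
             prema_candidate = object$prema_candidate)
}
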