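#' Enumerate microhomology deletion patterns around a break
#'
#' Finds every pair of identical direct repeats (microhomology arms) of at
#' least `config$min_arm` bp in which the left copy lies entirely 5' of the
#' break and the right copy entirely 3' of it, both within the search
#' window. Each pair defines one candidate MMEJ deletion: annealing the two
#' arms removes the intervening sequence together with one arm copy.
#'
#' Nested patterns that are experimentally indistinguishable are removed: a
#' pattern is dropped when its arm is a substring of a longer pattern's arm
#' and both deletions yield the same resulting sequence (the same physical
#' allele must not compete against itself).
#'
#' @param locus a [target_locus()].
#' @param config a [scan_config()].
#' @return A data frame of class `mh_patterns`, one row per pattern, with
#'   columns `left_start`, `right_start` (0-based arm starts), `arm_seq`,
#'   `arm_len`, `deletion_len`, `intervening_len`, `gc_count`, `at_count`
#'   and `score` (Pattern Score), in deterministic order (descending
#'   arm length, then position). The locus is attached as attribute
#'   `"locus"`.
#' @examples
#' enumerate_patterns(target_locus("ACGTACGT", 4, window = 4))
#' @export
enumerate_patterns <- function(locus, config = scan_config()) {
  stopifnot(inherits(locus, "target_locus"))
  seqc <- locus$sequence
  cut <- locus$cut_index
  n <- nchar(seqc)
  w <- locus$window                    # the locus defines its search window
  lo <- max(0L, cut - w)               # 0-based inclusive start of left flank
  hi <- min(n, cut + w)                # 0-based exclusive end of right flank

  region <- substr(seqc, lo + 1L, hi)
  bad <- first_non_acgt(region)
  if (bad > 0L) {
    stop("non-ACGT character '", substr(region, bad, bad),
         "' in the search window at position ", lo + bad,
         " (1-based); ambiguity codes are not enumerable")
  }

  max_k <- min(cut - lo, hi - cut)
  rows <- list()
  k <- max_k
  while (k >= config$min_arm) {
    left_starts <- lo:(cut - k)                  # left copy within [lo, cut)
    right_starts <- cut:(hi - k)                 # right copy within [cut, hi)
    left_subs <- substring(seqc, left_starts + 1L, left_starts + k)
    right_subs <- substring(seqc, right_starts + 1L, right_starts + k)
    right_map <- split(right_starts, right_subs)
    hit <- which(left_subs %in% names(right_map))
    for (ii in hit) {
      ls <- left_starts[ii]
      arm <- left_subs[ii]
      for (rs in right_map[[arm]]) {
        rows[[length(rows) + 1L]] <- list(left_start = ls, right_start = rs,
                                          arm_seq = arm, arm_len = k)
      }
    }
    k <- k - 1L
  }

  if (length(rows) == 0L) {
    out <- empty_patterns()
  } else {
    out <- data.frame(
      left_start = vapply(rows, `[[`, integer(1), "left_start"),
      right_start = vapply(rows, `[[`, integer(1), "right_start"),
      arm_seq = vapply(rows, `[[`, character(1), "arm_seq"),
      arm_len = vapply(rows, `[[`, integer(1), "arm_len"),
      stringsAsFactors = FALSE
    )
    out$deletion_len <- out$right_start - out$left_start
    out$intervening_len <- out$deletion_len - out$arm_len
    out$gc_count <- vapply(out$arm_seq, gc_count, integer(1), USE.NAMES = FALSE)
    out$at_count <- out$arm_len - out$gc_count
    out$score <- pattern_score(out, config)
    out <- dedup_patterns(out, seqc, lo, hi)
    out <- out[order(-out$arm_len, out$left_start, out$right_start), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("mh_patterns", "data.frame")
  attr(out, "locus") <- locus
  attr(out, "config") <- config
  out
}

empty_patterns <- function() {
  data.frame(left_start = integer(0), right_start = integer(0),
             arm_seq = character(0), arm_len = integer(0),
             deletion_len = integer(0), intervening_len = integer(0),
             gc_count = integer(0), at_count = integer(0),
             score = numeric(0), stringsAsFactors = FALSE)
}

# Remove patterns whose arm is a substring of a longer pattern's arm and
# whose deletion yields the same resulting sequence. Resulting-sequence
# equality is decided on the windowed region [lo, hi); flanks outside the
# window are shared by all patterns, so this equals full-sequence equality.
dedup_patterns <- function(p, seqc, lo, hi) {
  if (nrow(p) < 2L) return(p)
  key <- paste0(substr(rep(seqc, nrow(p)), lo + 1L, p$left_start),
                substring(seqc, p$right_start + 1L, hi))
  drop <- logical(nrow(p))
  for (grp in split(seq_len(nrow(p)), key)) {
    if (length(grp) < 2L) next
    for (i in grp) {
      for (j in grp) {
        if (p$arm_len[j] > p$arm_len[i] && !drop[j] &&
            grepl(p$arm_seq[i], p$arm_seq[j], fixed = TRUE)) {
          drop[i] <- TRUE
          break
        }
      }
    }
  }
  p[!drop, , drop = FALSE]
}

#' Bae-style Pattern Score
#'
#' Scores one candidate MMEJ deletion pattern:
#' `100 * length_factor * (at_count + 2 * gc_count)` where
#' `length_factor = exp(-deletion_len / decay_constant)` (decay constant 20).
#' Longer deletions are exponentially penalised; GC pairs in the arm count
#' double, reflecting annealing stability. With
#' `replicate_reference_rounding` on (the default) the length factor is
#' rounded to 3 decimals before multiplication, matching the reference
#' implementation digit for digit.
#'
#' @param p a data frame with columns `deletion_len` and either
#'   `gc_count`/`at_count` or `arm_seq`; typically a row subset of
#'   [enumerate_patterns()] output.
#' @param config a [scan_config()].
#' @return Numeric vector of Pattern Scores.
#' @examples
#' pattern_score(data.frame(arm_seq = "GCC", deletion_len = 10))  # 364.2
#' @export
pattern_score <- function(p, config = scan_config()) {
  if (is.null(p$gc_count)) {
    p$gc_count <- vapply(toupper(p$arm_seq), gc_count, integer(1), USE.NAMES = FALSE)
    p$at_count <- nchar(p$arm_seq) - p$gc_count
  }
  lf <- exp(-p$deletion_len / config$decay_constant)
  if (config$replicate_reference_rounding) lf <- round(lf, 3)
  100 * lf * (p$at_count + 2 * p$gc_count)
}

#' Microhomology Score of a locus
#'
#' The additive sum of the Pattern Scores of all (deduplicated) patterns at
#' one locus; a coarse measure of overall local MMEJ potential.
#'
#' @param patterns output of [enumerate_patterns()] (or any data frame with
#'   a `score` column).
#' @return A single number; 0 for an empty pattern list.
#' @export
microhomology_score <- function(patterns) {
  if (nrow(patterns) == 0L) return(0)
  sum(patterns$score)
}

#' Score-weighted out-of-frame percentage
#'
#' Percentage of the total Pattern Score mass carried by patterns whose
#' deletion length is not a multiple of 3, i.e. the predicted propensity of
#' the locus to yield frameshifting MMEJ deletions.
#'
#' @param patterns output of [enumerate_patterns()].
#' @return Percentage in `[0, 100]`, or `NA` when the locus has no pattern
#'   (an empty locus has no defined frame propensity, which is distinct
#'   from 0).
#' @export
out_of_frame_score <- function(patterns) {
  if (nrow(patterns) == 0L) return(NA_real_)
  total <- sum(patterns$score)
  if (total <= 0) return(NA_real_)
  100 * sum(patterns$score[patterns$deletion_len %% 3L != 0L]) / total
}

#' Predicted deletion allele of a pattern
#'
#' Applies one microhomology deletion to the locus: the half-open span
#' `[left_start, right_start)` is removed, so the intervening sequence and
#' one arm copy are lost and exactly one arm copy is retained at the
#' junction.
#'
#' @param locus a [target_locus()].
#' @param p a single-row pattern (one row of [enumerate_patterns()] output).
#' @return An object of class `deletion_allele`: list with
#'   `resulting_sequence`, `deletion_len`, `deleted_span` (0-based
#'   half-open), `junction_arm` and `junction_pos` (0-based position of the
#'   retained arm copy in the resulting sequence).
#' @examples
#' loc <- target_locus("ACGTACGT", 4, window = 4)
#' p <- enumerate_patterns(loc)
#' predicted_allele(loc, p[1, ])
#' @export
predicted_allele <- function(locus, p) {
  stopifnot(inherits(locus, "target_locus"), nrow(p) == 1L)
  seqc <- locus$sequence
  res <- paste0(substr(seqc, 1L, p$left_start),
                substr(seqc, p$right_start + 1L, nchar(seqc)))
  structure(list(resulting_sequence = res,
                 deletion_len = p$deletion_len,
                 deleted_span = c(p$left_start, p$right_start),
                 junction_arm = p$arm_seq,
                 junction_pos = p$left_start),
            class = "deletion_allele")
}

#' @export
print.deletion_allele <- function(x, ...) {
  cat("<deletion_allele> ", x$deletion_len, " bp deletion [",
      x$deleted_span[1], ", ", x$deleted_span[2], "), junction arm ",
      x$junction_arm, "\n", sep = "")
  invisible(x)
}

#' @export
print.mh_patterns <- function(x, n = 10L, ...) {
  loc <- attr(x, "locus")
  cat("<mh_patterns> ", nrow(x), " pattern(s)",
      if (!is.null(loc)) paste0(" at break ", loc$cut_index), "\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), n))
  if (nrow(x) > n) cat("... and", nrow(x) - n, "more\n")
  invisible(x)
}
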