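#' Construct a target locus
#'
#' A target locus is the substrate for microhomology enumeration: a DNA
#' sequence with a designated double-strand break position and a search
#' window on each side of the break.
#'
#' Coordinates are 0-based and half-open throughout the package; the break
#' lies between positions `cut_index - 1` and `cut_index`, i.e. `cut_index`
#' counts the bases 5' of the break. Human-facing CSV reports additionally
#' carry 1-based coordinates.
#'
#' @param sequence DNA string; normalised to upper case. Only A/C/G/T are
#'   accepted inside the searched window (IUPAC ambiguity codes are rejected
#'   at enumeration time rather than guessed at).
#' @param cut_index integer, number of bases 5' of the break (0-based; the
#'   break falls between `cut_index - 1` and `cut_index`). Must satisfy
#'   `0 < cut_index < nchar(sequence)`.
#' @param window integer, bp searched on each side of the break. Flanks are
#'   truncated to the available sequence when the window overruns an end.
#' @return An object of class `target_locus`: a list with elements
#'   `sequence`, `cut_index`, `window`.
#' @examples
#' target_locus("ACGTACGT", cut_index = 4, window = 4)
#' @export
target_locus <- function(sequence, cut_index, window = 40L) {
  stopifnot(is.character(sequence), length(sequence) == 1L, !is.na(sequence))
  sequence <- toupper(sequence)
  cut_index <- as.integer(cut_index)
  window <- as.integer(window)
  n <- nchar(sequence)
  if (is.na(cut_index) || cut_index <= 0L || cut_index >= n) {
    stop("cut_index must lie strictly inside the sequence (got ", cut_index,
         " for a sequence of length ", n, ")")
  }
  if (window < 2L) stop("window must be at least 2 bp")
  structure(list(sequence = sequence, cut_index = cut_index, window = window),
            class = "target_locus")
}

#' @export
print.target_locus <- function(x, ...) {
  n <- nchar(x$sequence)
  lo <- max(0L, x$cut_index - 10L)
  hi <- min(n, x$cut_index + 10L)
  ctx <- paste0(substr(x$sequence, lo + 1L, x$cut_index), "^",
                substr(x$sequence, x$cut_index + 1L, hi))
  cat("<target_locus> ", n, " bp, break at ", x$cut_index,
      " (", ctx, "), window ", x$window, " bp/side\n", sep = "")
  invisible(x)
}

#' Enumeration and scoring configuration
#'
#' Parameters controlling microhomology enumeration and Pattern Score
#' computation.
#'
#' @param min_arm minimum microhomology arm length in bp. Arms shorter than
#'   3 bp are not considered productive MMEJ substrates; the default of 3
#'   reflects that. A value of 2 is accepted only for the legacy comparison
#'   mode (see `include_2bp_arms`).
#' @param window search window in bp on each side of the break.
#' @param include_2bp_arms logical; when TRUE, lowers the effective minimum
#'   arm length to 2 bp. Provided only to reproduce the historical analysis
#'   that motivated excluding 2 bp arms; off by default.
#' @param decay_constant exponential length weight of the Pattern Score
#'   (score halves roughly every 14 bp of deletion). Fixed at 20 in the
#'   reference algorithm; exposed for completeness.
#' @param replicate_reference_rounding logical; round the exponential length
#'   factor to 3 decimals before multiplication, for bit-parity with the
#'   reference (RGEN) implementation. On by default.
#' @return An object of class `scan_config` (a list).
#' @export
scan_config <- function(min_arm = 3L, window = 40L, include_2bp_arms = FALSE,
                        decay_constant = 20, replicate_reference_rounding = TRUE) {
  min_arm <- as.integer(min_arm)
  window <- as.integer(window)
  if (isTRUE(include_2bp_arms)) min_arm <- min(min_arm, 2L)
  if (min_arm < 2L) stop("min_arm must be >= 2")
  if (window < min_arm) stop("window must be >= min_arm")
  structure(list(min_arm = min_arm, window = window,
                 include_2bp_arms = isTRUE(include_2bp_arms),
                 decay_constant = decay_constant,
                 replicate_reference_rounding = isTRUE(replicate_reference_rounding)),
            class = "scan_config")
}

## shared internal helpers ----------------------------------------------------

# run code with a temporary RNG state seeded by `seed`; restores the caller's
# .Random.seed so library calls never perturb user-level reproducibility
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# first offending position (1-based) of a non-ACGT character, or 0L
first_non_acgt <- function(x) {
  bad <- regexpr("[^ACGT]", x)
  if (bad < 0L) 0L else as.integer(bad)
}

gc_count <- function(arm) {
  nchar(gsub("[AT]", "", arm))
}
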