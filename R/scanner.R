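#' Targeting scheme for a programmable nuclease
#'
#' Describes how a nuclease picks its cut site. The default is SpCas9: a
#' 20-nt protospacer with a 3' NGG PAM and a blunt cut between protospacer
#' positions 17 and 18, i.e. 3 nt 5' of the PAM (`cut_offset = -3`,
#' measured from the PAM-proximal end of the PAM).
#'
#' @param pam PAM as an IUPAC string (e.g. `"NGG"`, `"NG"`, `"TTTV"`).
#' @param cut_offset signed offset of the break from the PAM-proximal end
#'   of the PAM, in nt (negative = 5' of the PAM on the protospacer).
#' @param guide_len protospacer length in nt.
#' @param mode `"CRISPR"` (PAM-anchored) or `"TALEN"` (spacer-anchored; see
#'   [talen_cut_index()]).
#' @param talen_spacer length range of the TALEN spacer (TALEN mode only).
#' @return An object of class `targeting_scheme`.
#' @export
targeting_scheme <- function(pam = "NGG", cut_offset = -3L, guide_len = 20L,
                             mode = c("CRISPR", "TALEN"),
                             talen_spacer = c(14L, 16L)) {
  mode <- match.arg(mode)
  pam <- toupper(pam)
  if (nchar(pam) == 0L) stop("pam must be non-empty")
  bad <- regexpr(sprintf("[^%s]", paste(names(Biostrings::IUPAC_CODE_MAP), collapse = "")), pam)
  if (bad > 0L) {
    stop("invalid IUPAC letter '", substr(pam, bad, bad), "' in PAM at position ", bad)
  }
  guide_len <- as.integer(guide_len)
  if (guide_len <= 0L) stop("guide_len must be positive")
  structure(list(pam = pam, cut_offset = as.integer(cut_offset),
                 guide_len = guide_len, mode = mode,
                 talen_spacer = as.integer(talen_spacer)),
            class = "targeting_scheme")
}

#' Find PAM occurrences on both strands
#'
#' Matches the scheme's IUPAC PAM against the forward strand and against
#' the reverse strand (reported in forward-strand coordinates). Ambiguity
#' codes in the subject sequence never match; only literal A/C/G/T bases
#' can satisfy the PAM.
#'
#' @param sequence DNA string.
#' @param scheme a [targeting_scheme()].
#' @return Data frame with `pam_start` (0-based forward-strand start of the
#'   PAM occurrence span) and `strand` (`"+"`/`"-"`), sorted by position
#'   then strand.
#' @examples
#' find_pam_sites("ACCGGT", targeting_scheme("NGG"))
#' @export
find_pam_sites <- function(sequence, scheme = targeting_scheme()) {
  sequence <- toupper(sequence)
  plen <- nchar(scheme$pam)
  if (nchar(sequence) < plen) {
    return(data.frame(pam_start = integer(0), strand = character(0),
                      stringsAsFactors = FALSE))
  }
  subj <- Biostrings::DNAString(sequence)
  # a window containing an ambiguity code in the subject must fail the
  # match (never silently satisfy the PAM)
  literal <- function(starts) {
    starts[vapply(starts, function(s0) {
      first_non_acgt(substr(sequence, s0 + 1L, s0 + plen)) == 0L
    }, logical(1))]
  }
  fwd_hits <- literal(Biostrings::start(Biostrings::matchPattern(
    scheme$pam, subj, fixed = "subject")) - 1L)
  rc_pam <- revcomp(scheme$pam)
  rev_hits <- literal(Biostrings::start(Biostrings::matchPattern(
    rc_pam, subj, fixed = "subject")) - 1L)
  out <- data.frame(
    pam_start = c(fwd_hits, rev_hits),
    strand = c(rep("+", length(fwd_hits)), rep("-", length(rev_hits))),
    stringsAsFactors = FALSE)
  out <- out[order(out$pam_start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# break position implied by a PAM hit, on forward-strand coordinates
pam_cut_index <- function(pam_start, strand, scheme) {
  plen <- nchar(scheme$pam)
  ifelse(strand == "+",
         pam_start + scheme$cut_offset,
         pam_start + plen - scheme$cut_offset)
}

#' Profile a single cut site
#'
#' Enumerates, scores and classifies the microhomology landscape of one
#' break position on a sequence. This is the per-site core shared by the
#' CRISPR scanner and TALEN layouts.
#'
#' @param sequence DNA string.
#' @param cut_index 0-based break position (bases 5' of the break).
#' @param config a [scan_config()].
#' @return A list with `locus`, `patterns`, `profile` (a
#'   [competition_profile()], or `NULL` when the site has no pattern),
#'   `predicted` (the top pattern's [predicted_allele()], or `NULL`) and
#'   `truncated_window` (TRUE when the window overran a sequence end).
#' @export
profile_cut_site <- function(sequence, cut_index, config = scan_config()) {
  locus <- target_locus(sequence, cut_index, window = config$window)
  pats <- enumerate_patterns(locus, config)
  n <- nchar(locus$sequence)
  trunc <- (cut_index - config$window < 0L) || (cut_index + config$window > n)
  if (nrow(pats) == 0L) {
    return(list(locus = locus, patterns = pats, profile = NULL,
                predicted = NULL, truncated_window = trunc))
  }
  prof <- competition_profile(pats)
  list(locus = locus, patterns = pats, profile = prof,
       predicted = predicted_allele(locus, prof$ranked_patterns[1, ]),
       truncated_window = trunc)
}

#' Scan a sequence for candidate MMEJ-predictable cut sites
#'
#' Finds every PAM placement with a full protospacer on either strand,
#' profiles the microhomology landscape at each implied break, and flags
#' the sites predicted to yield a predominant MMEJ allele (Group 4; Group
#' 3 optionally included). Sites whose break has no enumerable pattern are
#' retained ungrouped (`group = NA`) but never recommended.
#'
#' @param sequence DNA string (one record; scan multi-record FASTA input
#'   per record).
#' @param scheme a [targeting_scheme()] (CRISPR mode).
#' @param config a [scan_config()].
#' @param include_group3 logical; also recommend Group 3 sites.
#' @return Data frame of class `candidate_sites`, one row per candidate:
#'   identifiers and geometry (`site_id`, `strand`, `pam_start`,
#'   `cut_index`, `guide_seq`), the top pattern (`top_arm_seq`,
#'   `top_deletion_len`, `top_intervening_len`, `top_score`,
#'   `second_score`), competition metrics (`ratio`, `slope_value`,
#'   `criterion1`, `criterion2`, `group`), the frame consequence of the
#'   predicted allele (`frame_shift`), `recommended` and
#'   `truncated_window`.
#' @export
scan_sites <- function(sequence, scheme = targeting_scheme(),
                       config = scan_config(), include_group3 = FALSE) {
  sequence <- toupper(sequence)
  if (scheme$mode != "CRISPR") {
    stop("scan_sites() scans PAM-anchored (CRISPR) schemes; for TALEN ",
         "layouts place the break with talen_cut_index() and call ",
         "profile_cut_site()")
  }
  n <- nchar(sequence)
  plen <- nchar(scheme$pam)
  hits <- find_pam_sites(sequence, scheme)
  rows <- vector("list", nrow(hits))
  for (i in seq_len(nrow(hits))) {
    s <- hits$pam_start[i]
    strand <- hits$strand[i]
    if (strand == "+") {
      if (s < scheme$guide_len) next          # no room for a full guide
      guide <- substr(sequence, s - scheme$guide_len + 1L, s)
    } else {
      if (s + plen + scheme$guide_len > n) next
      guide <- revcomp(substr(sequence, s + plen + 1L, s + plen + scheme$guide_len))
    }
    cut <- pam_cut_index(s, strand, scheme)
    if (cut <= 0L || cut >= n) next
    site <- profile_cut_site(sequence, cut, config)
    prof <- site$profile
    if (is.null(prof)) {
      rows[[i]] <- data.frame(
        strand = strand, pam_start = s, cut_index = cut, guide_seq = guide,
        n_patterns = 0L, top_arm_seq = NA_character_,
        top_deletion_len = NA_integer_, top_intervening_len = NA_integer_,
        top_score = NA_real_, second_score = NA_real_, ratio = NA_real_,
        slope_value = NA_real_, criterion1 = NA, criterion2 = NA,
        group = NA_integer_, frame_shift = NA, recommended = FALSE,
        truncated_window = site$truncated_window, stringsAsFactors = FALSE)
    } else {
      top <- prof$ranked_patterns[1, ]
      rec <- prof$group == 4L || (include_group3 && prof$group == 3L)
      rows[[i]] <- data.frame(
        strand = strand, pam_start = s, cut_index = cut, guide_seq = guide,
        n_patterns = nrow(prof$ranked_patterns), top_arm_seq = top$arm_seq,
        top_deletion_len = top$deletion_len,
        top_intervening_len = top$intervening_len,
        top_score = prof$top_score, second_score = prof$second_score,
        ratio = prof$ratio, slope_value = prof$slope_value,
        criterion1 = prof$criterion1, criterion2 = prof$criterion2,
        group = prof$group, frame_shift = top$deletion_len %% 3L != 0L,
        recommended = rec, truncated_window = site$truncated_window,
        stringsAsFactors = FALSE)
    }
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    strand = character(0), pam_start = integer(0), cut_index = integer(0),
    guide_seq = character(0), n_patterns = integer(0),
    top_arm_seq = character(0), top_deletion_len = integer(0),
    top_intervening_len = integer(0), top_score = numeric(0),
    second_score = numeric(0), ratio = numeric(0), slope_value = numeric(0),
    criterion1 = logical(0), criterion2 = logical(0), group = integer(0),
    frame_shift = logical(0), recommended = logical(0),
    truncated_window = logical(0), stringsAsFactors = FALSE)
  out <- out[order(out$cut_index, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out)) out <- cbind(site_id = sprintf("site_%03d", seq_len(nrow(out))), out,
                              stringsAsFactors = FALSE)
  else out <- cbind(data.frame(site_id = character(0), stringsAsFactors = FALSE), out)
  class(out) <- c("candidate_sites", "data.frame")
  out
}

#' TALEN break placement
#'
#' Places the break at the midpoint of the TALEN spacer; for an odd spacer
#' length the extra base is assigned 5' of the break. TALEN pairs generate
#' staggered (5' overhang) cuts; the scoring model is break-position based,
#' so the overhang is collapsed to this single index.
#'
#' @param left_arm_end 0-based position where the left binding arm ends,
#'   i.e. where the spacer starts.
#' @param spacer_len spacer length in bp.
#' @return 0-based cut index.
#' @examples
#' talen_cut_index(100, 14)  # 107
#' talen_cut_index(100, 15)  # 108
#' @export
talen_cut_index <- function(left_arm_end, spacer_len) {
  as.integer(left_arm_end + ceiling(spacer_len / 2))
}

#' Frame consequence of a deletion
#'
#' A deletion shifts the reading frame when its length is not a multiple
#' of 3. When coding intervals are supplied and the deleted span removes a
#' coding/non-coding boundary (a splice edge), the frame consequence
#' cannot be inferred from length alone and is flagged indeterminate.
#'
#' @param deletion_len deletion length(s) in bp.
#' @param deleted_span optional 0-based half-open span `c(start, end)` of a
#'   single deletion on the supplied sequence.
#' @param coding_intervals optional data frame of 0-based half-open coding
#'   intervals (columns `start`, `end`).
#' @return Character vector over `"in-frame"`, `"out-of-frame"`,
#'   `"indeterminate"`.
#' @export
annotate_frame <- function(deletion_len, deleted_span = NULL,
                           coding_intervals = NULL) {
  out <- ifelse(deletion_len %% 3L != 0L, "out-of-frame", "in-frame")
  if (!is.null(deleted_span) && !is.null(coding_intervals) &&
      nrow(coding_intervals) > 0L) {
    stopifnot(length(deletion_len) == 1L)
    edges <- c(coding_intervals$start, coding_intervals$end)
    if (any(edges > deleted_span[1] & edges < deleted_span[2])) {
      out <- "indeterminate"
    }
  }
  out
}

#' Prevalence of PreMA-candidate cut sites on a sequence
#'
#' Scans the sequence and summarises how many unique cut sites exist and
#' what fraction of them are recommended (Group 4 by default). Forward and
#' reverse PAM hits implying the same break position share one deletion
#' landscape and are counted as a single cut site.
#'
#' @inheritParams scan_sites
#' @return A list with `total_sites` (all candidate guides),
#'   `unique_cut_sites`, `recommended_cut_sites`, `fraction_recommended`,
#'   and `fraction_recommended_out_of_frame` (share of recommended unique
#'   cuts whose predicted allele shifts frame; `NA` when none are
#'   recommended), plus the full `sites` table.
#' @export
prevalence_screen <- function(sequence, scheme = targeting_scheme(),
                              config = scan_config(), include_group3 = FALSE) {
  sites <- scan_sites(sequence, scheme, config, include_group3)
  uniq <- sites[!duplicated(sites$cut_index), , drop = FALSE]
  rec <- uniq[uniq$recommended %in% TRUE, , drop = FALSE]
  list(total_sites = nrow(sites),
       unique_cut_sites = nrow(uniq),
       recommended_cut_sites = nrow(rec),
       fraction_recommended = if (nrow(uniq)) nrow(rec) / nrow(uniq) else NA_real_,
       fraction_recommended_out_of_frame =
         if (nrow(rec)) mean(rec$frame_shift) else NA_real_,
       sites = sites)
}

#' @export
print.candidate_sites <- function(x, ...) {
  n_rec <- if (is.null(x$recommended)) NA_integer_ else sum(x$recommended)
  cat("<candidate_sites> ", nrow(x), " candidate guide(s)",
      if (!is.na(n_rec)) paste0(", ", n_rec, " recommended"), "\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat("... and", nrow(x) - 10L, "more\n")
  invisible(x)
}
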