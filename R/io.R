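#' Read a FASTA file of loci
#'
#' Reads single- or multi-record FASTA (wrapped or unwrapped), uppercases
#' sequences, and validates the records: duplicate ids are rejected, empty
#' records are rejected, and any character outside A/C/G/T/N and the IUPAC
#' ambiguity codes (e.g. RNA's `U`) is rejected with its record and
#' position named.
#'
#' @param path path to a FASTA file.
#' @param strict when TRUE (default), reject IUPAC ambiguity codes too, so
#'   every returned sequence is directly enumerable.
#' @return Named character vector of uppercase sequences, in file order.
#' @export
read_fasta <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0L) stop("no records in FASTA file: ", path)
  ids <- vapply(strsplit(names(recs), "[ \t]"), `[[`, character(1), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate record id(s) in ", path, ": ",
                        paste(unique(dup), collapse = ", "))
  seqs <- toupper(as.character(recs))
  names(seqs) <- ids
  allowed <- if (strict) "ACGT" else paste(names(Biostrings::IUPAC_CODE_MAP), collapse = "")
  for (i in seq_along(seqs)) {
    if (nchar(seqs[i]) == 0L) stop("empty record '", ids[i], "' in ", path)
    bad <- regexpr(sprintf("[^%s]", allowed), seqs[i])
    if (bad > 0L) {
      stop("invalid character '", substr(seqs[i], bad, bad), "' at position ",
           as.integer(bad), " of record '", ids[i], "' in ", path)
    }
  }
  seqs
}

#' Write a deterministic CSV report
#'
#' Writes a results table as RFC-4180 CSV preceded by a comment line
#' carrying the tool version and a hash of the run configuration, so that
#' identical inputs yield byte-identical files. Internal 0-based half-open
#' coordinate columns are accompanied by 1-based inclusive twins (suffix
#' `_1based`) for human consumption; floating-point columns are printed
#' with 4 significant digits except Pattern Scores, which keep 1 decimal.
#'
#' @param x a data frame ([scan_sites()] output, pattern tables, or an
#'   `outcome_metrics` object).
#' @param path output path.
#' @param config optional configuration object(s) folded into the header
#'   hash.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, config = NULL) {
  if (inherits(x, "outcome_metrics")) x <- as.data.frame(x)
  stopifnot(is.data.frame(x))
  x <- as.data.frame(x)
  for (col in intersect(c("left_start", "right_start", "pam_start", "cut_index"),
                        names(x))) {
    x[[paste0(col, "_1based")]] <- x[[col]] + 1L
  }
  for (col in names(x)) {
    if (is.double(x[[col]])) {
      digits <- if (grepl("score", col)) 1L else NA
      x[[col]] <- if (is.na(digits)) signif(x[[col]], 4) else round(x[[col]], digits)
    }
  }
  cfg_hash <- sum(utf8ToInt(paste(deparse(config), collapse = ""))) %% 100000L
  header <- sprintf("# premascan %s config=%05d",
                    as.character(utils::packageVersion("premascan")), cfg_hash)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(x, con, sep = ",", qmethod = "double", row.names = FALSE,
                     col.names = TRUE, quote = which(vapply(x, is.character, logical(1))))
  invisible(path)
}

#' Read a premascan CSV report back into a data frame
#'
#' @param path path written by [write_report()].
#' @return The data frame (header comment stripped).
#' @export
read_report <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read BED-style intervals
#'
#' Reads minimal 3+-column BED (0-based, half-open) for coding-interval
#' frame annotation.
#'
#' @param path path to a BED file.
#' @return Data frame with `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(bed) < 3L) stop("BED file needs at least 3 columns: ", path)
  data.frame(chrom = bed[[1]], start = as.integer(bed[[2]]),
             end = as.integer(bed[[3]]), stringsAsFactors = FALSE)
}
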