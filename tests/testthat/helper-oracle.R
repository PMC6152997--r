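# Independent oracles and sequence builders used across the suite.
# Nothing here calls the package's enumeration/dedup path.

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# brute-force microhomology enumeration: every (left substring, right
# substring) identity pair, deduplicated straight from the definition
# (arm contained in a longer arm + identical full resulting sequence)
oracle_enumerate <- function(seqc, cut, window, min_arm = 3L) {
  n <- nchar(seqc)
  lo <- max(0L, cut - window)
  hi <- min(n, cut + window)
  rows <- list()
  if (cut - min_arm >= lo && hi - min_arm >= cut) {
    for (i in lo:(cut - min_arm)) {
      for (j in cut:(hi - min_arm)) {
        kmax <- min(cut - i, hi - j)
        if (kmax < min_arm) next
        for (k in min_arm:kmax) {
          a <- substr(seqc, i + 1L, i + k)
          if (a == substr(seqc, j + 1L, j + k)) {
            rows[[length(rows) + 1L]] <-
              data.frame(left_start = i, right_start = j, arm_seq = a,
                         arm_len = k, stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(left_start = integer(0), right_start = integer(0),
                      arm_seq = character(0), arm_len = integer(0),
                      deletion_len = integer(0), score = numeric(0),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, rows)
  df$deletion_len <- df$right_start - df$left_start
  res <- paste0(substr(rep(seqc, nrow(df)), 1L, df$left_start),
                substring(seqc, df$right_start + 1L))
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    for (j in seq_len(nrow(df))) {
      if (df$arm_len[j] > df$arm_len[i] && res[j] == res[i] &&
          grepl(df$arm_seq[i], df$arm_seq[j], fixed = TRUE)) {
        keep[i] <- FALSE
        break
      }
    }
  }
  df <- df[keep, , drop = FALSE]
  gc <- nchar(gsub("[AT]", "", df$arm_seq))
  df$score <- 100 * round(1 / exp(df$deletion_len / 20), 3) *
    ((df$arm_len - gc) + 2 * gc)
  df[order(df$left_start, df$right_start, df$arm_len), , drop = FALSE]
}

# transcription of the published reference microhomology-scoring search:
# arms swept longest-first over the two flanks of the break, duplicated
# deletion outcomes skipped, scores summed into the Microhomology Score
# and the score-weighted out-of-frame percentage
bae_reference <- function(seqc, cut, window, length_weight = 20) {
  lo <- max(0L, cut - window)
  hi <- min(nchar(seqc), cut + window)
  s <- substr(seqc, lo + 1L, hi)
  brk <- cut - lo                        # bases left of the break within s
  sn <- nchar(s)
  found <- list()
  for (k in rev(seq_len(min(brk, sn - brk)))) {
    if (k < 3L) break
    for (j in (brk + 1L):(sn - k + 1L)) {
      for (i in 1L:(brk - k + 1L)) {
        arm <- substr(s, i, i + k - 1L)
        if (arm != substr(s, j, j + k - 1L)) next
        after <- paste0(substr(s, 1L, i - 1L), substr(s, j, sn))
        dup <- FALSE
        for (f in found) {
          if (nchar(f$arm) > k && f$after == after &&
              grepl(arm, f$arm, fixed = TRUE)) { dup <- TRUE; break }
        }
        if (!dup) {
          d <- (j - 1L) - (i - 1L)
          gc <- nchar(gsub("[AT]", "", arm))
          found[[length(found) + 1L]] <- list(
            arm = arm, after = after, d = d,
            score = 100 * round(1 / exp(d / length_weight), 3) *
              ((k - gc) + 2 * gc))
        }
      }
    }
  }
  scores <- vapply(found, `[[`, numeric(1), "score")
  dels <- vapply(found, `[[`, numeric(1), "d")
  list(scores = scores, deletions = dels,
       mh_score = sum(scores),
       oof_score = if (length(scores)) 100 * sum(scores[dels %% 3 != 0]) / sum(scores) else NA_real_)
}

# 66-mer in which every 3-mer occurs at most once: no microhomology of
# >= 3 bp exists across any break (uniqueness asserted where it is used)
unique_kmer_seq <-
  "TAGTGGTCCTGTATTTGAATGCACTTCAAAGGGAGATCTCGACCATAACGGCCCGCGTTACAGCTA"

# sum over mutant classes of a classified table, convenience for tests
class_counts <- function(tab) {
  tapply(tab$count, tab$class_label, sum, default = 0L)
}
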