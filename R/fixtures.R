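#' Specification for a planted synthetic locus
#'
#' Describes a synthetic locus archetype: one "main" microhomology arm pair
#' planted around the break, optionally accompanied by decoy pairs of
#' tunable relative strength. The generator guarantees the planted
#' landscape is the whole landscape (no stray cross-break repeats survive
#' inside the window), so every downstream answer — top pattern, group,
#' predicted allele — is known by construction.
#'
#' @param arm_len main arm length in bp (>= 3).
#' @param arm_gc G+C bases in the main arm (default: half, rounded up).
#' @param intervening_len bp between the two main arm copies; at most 5
#'   satisfies the proximity criterion.
#' @param n_decoys number of additional planted repeat pairs (3 bp arms).
#' @param decoy_strength target ratio of the strongest decoy's Pattern
#'   Score to the main score, in (0, 1); near 1 defeats the dominance
#'   criterion, near 0 leaves the main pattern unchallenged. The achieved
#'   strength (reported back) may differ slightly because deletion lengths
#'   are integers.
#' @param seed RNG seed; generation is deterministic per seed.
#' @param locus_len total locus length (default hosts the window plus
#'   10 bp margins).
#' @param background_gc GC fraction of the i.i.d. background.
#' @param window audited search window per side (default 20 bp; the
#'   stray-repeat guarantee is combinatorial and tightens with window
#'   size).
#' @return An object of class `plant_spec`.
#' @export
plant_spec <- function(arm_len = 6L, arm_gc = NULL, intervening_len = 0L,
                       n_decoys = 0L, decoy_strength = 0.5, seed = 1L,
                       locus_len = NULL, background_gc = 0.5, window = 20L) {
  arm_len <- as.integer(arm_len)
  if (arm_len < 3L) stop("arm_len must be >= 3")
  if (is.null(arm_gc)) arm_gc <- ceiling(arm_len / 2)
  arm_gc <- as.integer(arm_gc)
  if (arm_gc < 0L || arm_gc > arm_len) stop("arm_gc must be in [0, arm_len]")
  intervening_len <- as.integer(intervening_len)
  if (intervening_len < 0L) stop("intervening_len must be >= 0")
  window <- as.integer(window)
  if (is.null(locus_len)) locus_len <- 2L * window + 20L
  locus_len <- as.integer(locus_len)
  if (locus_len < 2L * window) stop("locus_len too small to host the window")
  if (intervening_len + arm_len > window) {
    stop("main arm pair does not fit in the window")
  }
  structure(list(arm_len = arm_len, arm_gc = arm_gc,
                 intervening_len = intervening_len,
                 n_decoys = as.integer(n_decoys),
                 decoy_strength = decoy_strength, seed = as.integer(seed),
                 locus_len = locus_len, background_gc = background_gc,
                 window = window),
            class = "plant_spec")
}

# arm with the requested composition and no repeated internal 3-mer
# (internal repeats would spawn unplanted cross-diagonal matches)
make_arm <- function(len, gc) {
  for (try in 1:200) {
    is_gc <- rep(FALSE, len)
    if (gc > 0) is_gc[sample.int(len, gc)] <- TRUE
    letters <- ifelse(is_gc, sample(c("G", "C"), len, replace = TRUE),
                      sample(c("A", "T"), len, replace = TRUE))
    arm <- paste(letters, collapse = "")
    if (len < 4L) return(arm)
    kmers <- substring(arm, 1:(len - 2L), 3:len)
    if (!anyDuplicated(kmers)) return(arm)
  }
  stop("could not build an arm of length ", len, " with GC count ", gc,
       " free of internal 3-mer repeats")
}

internal_kmers <- function(arm, k = 3L) {
  n <- nchar(arm)
  if (n < k) character(0) else substring(arm, 1:(n - k + 1L), k:n)
}

# reference-rounded pattern score from raw components
planted_score <- function(d, w, config) {
  lf <- exp(-d / config$decay_constant)
  if (config$replicate_reference_rounding) lf <- round(lf, 3)
  100 * lf * w
}

#' Generate a synthetic locus with a known microhomology landscape
#'
#' Draws an i.i.d. background, writes the planted arm pairs into it, then
#' audits the window by brute force: every maximal cross-break repeat of
#' at least 3 bp must be one of the planted pairs. Stray repeats are
#' repaired by resampling a free (non-planted) base of one of their
#' copies; generation fails with a diagnostic if the audit cannot be
#' satisfied within the retry budget.
#'
#' @param spec a [plant_spec()].
#' @param max_repairs repair-iteration budget for the stray-repeat audit.
#' @return A list with `locus` (a [target_locus()]), `expected` (the
#'   ground-truth answers: `patterns` data frame, `top` row, `group`,
#'   `criterion1`, `criterion2`, `ratio`, `predicted` allele) and
#'   `achieved_strength` (realised decoy-to-main score ratio, `NA`
#'   without decoys).
#' @export
plant_locus <- function(spec, max_repairs = 200L) {
  stopifnot(inherits(spec, "plant_spec"))
  with_seed(spec$seed, plant_locus_impl(spec, max_repairs))
}

plant_locus_impl <- function(spec, max_repairs) {
  config <- scan_config(min_arm = 3L, window = spec$window)
  cut <- spec$locus_len %/% 2L
  lo <- cut - spec$window
  hi <- cut + spec$window

  main_arm <- make_arm(spec$arm_len, spec$arm_gc)
  w_main <- (spec$arm_len - spec$arm_gc) + 2L * spec$arm_gc
  d_main <- spec$arm_len + spec$intervening_len
  score_main <- planted_score(d_main, w_main, config)

  # planted copies: main left arm abuts the break; intervening lies 3' of it
  plants <- list(list(left = cut - spec$arm_len,
                      right = cut + spec$intervening_len,
                      arm = main_arm, len = spec$arm_len))

  # decoy pairs: 3 bp arms drawn from a catalog disjoint from the main
  # arm's 3-mer content, scores tuned through deletion length + composition
  used_kmers <- internal_kmers(main_arm)
  decoy_scores <- numeric(0)
  if (spec$n_decoys > 0L) {
    target <- spec$decoy_strength * score_main
    b_floor <- spec$intervening_len + spec$arm_len + 1L   # clear main right arm
    b_used <- integer(0)
    for (j in seq_len(spec$n_decoys)) {
      a_j <- spec$arm_len + 1L + (j - 1L) * 4L            # left-side gap
      if (a_j + 3L > spec$window) {
        stop("infeasible plant_spec: decoy ", j,
             " left arm falls outside the window (", spec$window, " bp)")
      }
      # choose composition + deletion length closest to the target score
      best <- NULL
      for (gcd in 0:3) {
        w_d <- 3L + gcd
        d_ideal <- -config$decay_constant * log(target / (100 * w_d))
        for (d_try in as.integer(unique(pmax(round(d_ideal) + (-1:1),
                                             a_j + b_floor + 3L)))) {
          b_j <- d_try - 3L - a_j
          if (b_j < b_floor || b_j + 3L > spec$window) next
          while (any(abs(b_j - b_used) < 4L)) b_j <- b_j + 1L   # keep right copies apart
          if (b_j + 3L > spec$window) next
          d_real <- a_j + b_j + 3L
          s <- planted_score(d_real, w_d, config)
          if (s >= score_main) next                        # main must stay top
          if (is.null(best) || abs(s - target) < abs(best$s - target)) {
            best <- list(gcd = gcd, b = b_j, d = d_real, s = s)
          }
        }
      }
      if (is.null(best)) {
        stop("infeasible plant_spec: no placement for decoy ", j,
             " with strength ", spec$decoy_strength, " inside a ",
             spec$window, " bp window")
      }
      arm_j <- NULL
      for (try in 1:200) {
        cand <- make_arm(3L, best$gcd)
        if (!(cand %in% used_kmers)) { arm_j <- cand; break }
      }
      if (is.null(arm_j)) stop("infeasible plant_spec: decoy arm catalog exhausted")
      used_kmers <- c(used_kmers, arm_j)
      b_used <- c(b_used, best$b)
      decoy_scores <- c(decoy_scores, best$s)
      plants[[length(plants) + 1L]] <- list(left = cut - a_j - 3L,
                                            right = cut + best$b,
                                            arm = arm_j, len = 3L)
    }
  }

  # overlap sanity among planted spans (left side and right side separately)
  spans <- do.call(rbind, lapply(plants, function(p) {
    rbind(c(p$left, p$left + p$len), c(p$right, p$right + p$len))
  }))
  o <- order(spans[, 1])
  if (any(spans[o, 1][-1] < spans[o, 2][-nrow(spans)])) {
    stop("infeasible plant_spec: planted arm copies overlap")
  }

  planted_pos <- unlist(lapply(plants, function(p) {
    c(p$left + seq_len(p$len), p$right + seq_len(p$len)) - 1L  # 0-based
  }))

  # i.i.d. background, then write the planted copies; repair strays by
  # resampling free bases, with a fresh background draw if repair stalls
  gc <- spec$background_gc
  expected_runs <- lapply(plants, function(p) as.integer(c(p$left, p$right, p$len)))
  clean <- FALSE
  for (attempt in 1:20) {
    base <- sample(c("A", "C", "G", "T"), spec$locus_len, replace = TRUE,
                   prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
    for (p in plants) {
      base[p$left + seq_len(p$len)] <- strsplit(p$arm, "")[[1]]
      base[p$right + seq_len(p$len)] <- strsplit(p$arm, "")[[1]]
    }
    repairs <- 0L
    repeat {
      runs <- maximal_cross_runs(base, cut, lo, hi)
      stray <- Filter(function(r) !any(vapply(expected_runs, identical,
                                              logical(1), y = r)), runs)
      if (length(stray) == 0L) { clean <- TRUE; break }
      if (repairs >= max_repairs) break
      r <- stray[[1]]
      pos <- c(r[1] + seq_len(r[3]), r[2] + seq_len(r[3])) - 1L   # 0-based
      free <- setdiff(pos, planted_pos)
      if (length(free) == 0L) {
        stop("stray repeat fully inside planted arms; choose different arms")
      }
      pick <- free[sample.int(length(free), 1L)] + 1L
      base[pick] <- sample(setdiff(c("A", "C", "G", "T"), base[pick]), 1L)
      repairs <- repairs + 1L
    }
    if (clean) break
  }
  if (!clean) {
    stop("stray-repeat audit not satisfied after ", max_repairs,
         " repairs in each of 20 background draws; spec is likely ",
         "infeasible (window too large?)")
  }

  sequence <- paste(base, collapse = "")
  locus <- target_locus(sequence, cut, window = spec$window)

  exp_pat <- data.frame(
    left_start = as.integer(vapply(plants, `[[`, numeric(1), "left")),
    right_start = as.integer(vapply(plants, `[[`, numeric(1), "right")),
    arm_seq = vapply(plants, `[[`, character(1), "arm"),
    arm_len = as.integer(vapply(plants, `[[`, numeric(1), "len")),
    stringsAsFactors = FALSE)
  exp_pat$deletion_len <- exp_pat$right_start - exp_pat$left_start
  exp_pat$intervening_len <- exp_pat$deletion_len - exp_pat$arm_len
  exp_pat$gc_count <- vapply(exp_pat$arm_seq, gc_count, integer(1), USE.NAMES = FALSE)
  exp_pat$at_count <- exp_pat$arm_len - exp_pat$gc_count
  exp_pat$score <- pattern_score(exp_pat, config)
  exp_pat <- rank_patterns(exp_pat)

  ratio <- if (nrow(exp_pat) == 1L) Inf else exp_pat$score[1] / exp_pat$score[2]
  c1 <- spec$intervening_len <= 5L
  c2 <- ratio >= 1.5
  group <- if (c1 && c2) 4L else if (c1) 3L else if (c2) 2L else 1L

  list(locus = locus,
       config = config,
       expected = list(patterns = exp_pat,
                       top = exp_pat[1, ],
                       criterion1 = c1, criterion2 = c2, ratio = ratio,
                       group = group,
                       predicted = predicted_allele(locus, exp_pat[1, ])),
       achieved_strength = if (length(decoy_scores)) max(decoy_scores) / score_main else NA_real_)
}

# every maximal identical cross-break run of >= 3 bp within [lo, hi);
# deliberately a plain nested scan, independent of enumerate_patterns()
maximal_cross_runs <- function(base, cut, lo, hi) {
  runs <- list()
  for (i0 in (lo + 1L):(cut - 2L)) {          # 1-based left run start
    for (j0 in (cut + 1L):(hi - 2L)) {        # 1-based right run start
      if (base[i0] != base[j0]) next
      if (i0 > lo + 1L && j0 > cut + 1L && base[i0 - 1L] == base[j0 - 1L]) next
      k <- 1L
      while (i0 + k <= cut && j0 + k <= hi && base[i0 + k] == base[j0 + k]) {
        k <- k + 1L
      }
      if (k >= 3L) runs[[length(runs) + 1L]] <- c(i0 - 1L, j0 - 1L, k)  # 0-based
    }
  }
  runs
}

#' Simulate an observed allele table with known ground truth
#'
#' Draws a multinomial sample of reads over the outcome classes of a locus
#' whose microhomology landscape is known: wildtype windows, the top
#' predicted deletion allele, other enumerated MMEJ deletion alleles, and
#' a non-MMEJ mutant (a 1 bp insertion at the break, which is never
#' MMEJ-consistent). Optional uniform substitutions are sprinkled on
#' off-arm positions to emulate sequencing noise within the tolerated
#' polymorphism budget.
#'
#' @param locus a [target_locus()] (the analysis window).
#' @param fractions named numeric over
#'   `c("wildtype", "top_mh", "other_mmej", "other_mutant")` summing to 1
#'   (tolerance 1e-9).
#' @param depth total reads.
#' @param substitution_rate per-base substitution probability applied to
#'   off-arm positions (default 0).
#' @param seed RNG seed.
#' @param config a [scan_config()].
#' @return Data frame with `allele_seq`, `count`, `true_class`.
#' @export
simulate_allele_table <- function(locus, fractions, depth,
                                  substitution_rate = 0, seed = 1L,
                                  config = scan_config(window = locus$window)) {
  stopifnot(inherits(locus, "target_locus"))
  want <- c("wildtype", "top_mh", "other_mmej", "other_mutant")
  if (!all(want %in% names(fractions)) ||
      abs(sum(fractions[want]) - 1) > 1e-9) {
    stop("fractions must cover ", paste(want, collapse = "/"),
         " and sum to 1 (tolerance 1e-9)")
  }
  with_seed(seed, {
    ranked <- rank_patterns(enumerate_patterns(locus, config))
    if ((fractions[["top_mh"]] > 0 && nrow(ranked) < 1L) ||
        (fractions[["other_mmej"]] > 0 && nrow(ranked) < 2L)) {
      stop("locus has too few microhomology patterns for the requested fractions")
    }
    wt <- locus$sequence
    counts <- as.vector(stats::rmultinom(1L, depth, fractions[want]))
    names(counts) <- want

    templates <- list(wildtype = list(seq = wt, arm = NULL))
    if (nrow(ranked) >= 1L) {
      al <- predicted_allele(locus, ranked[1, ])
      templates$top_mh <- list(seq = al$resulting_sequence,
                               arm = c(al$junction_pos, al$junction_pos + nchar(al$junction_arm)))
    }
    ins_base <- sample(c("A", "C", "G", "T"), 1L)
    templates$other_mutant <- list(
      seq = paste0(substr(wt, 1L, locus$cut_index), ins_base,
                   substring(wt, locus$cut_index + 1L)),
      arm = NULL)

    out <- list()
    emit <- function(class, seqs) {
      tab <- table(seqs)
      data.frame(allele_seq = names(tab), count = as.integer(tab),
                 true_class = class, stringsAsFactors = FALSE)
    }
    sprinkle <- function(seq, n_reads, arm) {
      if (n_reads == 0L) return(character(0))
      if (substitution_rate <= 0) return(rep(seq, n_reads))
      chars <- strsplit(seq, "")[[1]]
      free <- seq_along(chars)
      if (!is.null(arm)) free <- setdiff(free, (arm[1] + 1L):arm[2])
      vapply(seq_len(n_reads), function(i) {
        mut <- chars
        hit <- free[stats::runif(length(free)) < substitution_rate]
        for (p in hit) mut[p] <- sample(setdiff(c("A", "C", "G", "T"), mut[p]), 1L)
        paste(mut, collapse = "")
      }, character(1))
    }

    for (cls in c("wildtype", "top_mh", "other_mutant")) {
      if (counts[[cls]] == 0L) next
      tpl <- templates[[cls]]
      out[[cls]] <- emit(cls, sprinkle(tpl$seq, counts[[cls]], tpl$arm))
    }
    if (counts[["other_mmej"]] > 0L) {
      idx <- if (nrow(ranked) == 2L) rep(2L, counts[["other_mmej"]]) else
        sample(2:nrow(ranked), counts[["other_mmej"]], replace = TRUE)
      seqs <- vapply(idx, function(i) {
        al <- predicted_allele(locus, ranked[i, ])
        sprinkle(al$resulting_sequence, 1L,
                 c(al$junction_pos, al$junction_pos + nchar(al$junction_arm)))
      }, character(1))
      out$other_mmej <- emit("other_mmej", seqs)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}
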