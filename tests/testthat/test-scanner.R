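# deterministic locus with exactly one strong microhomology pair: poly-A
# flank, CTAAGG arm duplicated across the break at 30, poly-T flank; the
# arm carries the only GG dinucleotides, so the PAM landscape is known
g4_seq <- paste0(strrep("A", 24), "CTAAGG", "CTAAGG", strrep("T", 24))

test_that("PAM matching is IUPAC-aware, both-stranded and deterministic", {
  hits <- find_pam_sites("ACCGGT", targeting_scheme("NGG"))
  expect_equal(hits$pam_start, c(1L, 2L))
  expect_equal(hits$strand, c("-", "+"))
  # universal PAM: L - 2 windows per strand
  hits <- find_pam_sites("ACGTACGTAC", targeting_scheme("NNN"))
  expect_equal(sum(hits$strand == "+"), 8L)
  expect_equal(sum(hits$strand == "-"), 8L)
  expect_equal(nrow(find_pam_sites("", targeting_scheme("NGG"))), 0L)
  expect_equal(nrow(find_pam_sites("AC", targeting_scheme("NGG"))), 0L)
  expect_error(targeting_scheme("NGQ"), "IUPAC")
  # ambiguity in the subject never matches, even against pattern N
  expect_equal(nrow(find_pam_sites("AANGG", targeting_scheme("NGG"))), 0L)
  expect_equal(nrow(find_pam_sites("AATGG", targeting_scheme("NGG"))), 1L)
})

test_that("scanning recommends exactly the planted Group 4 site", {
  sites <- scan_sites(g4_seq, config = scan_config(window = 20))
  expect_equal(nrow(sites), 2L)          # PAMs at 27 and 33, both forward
  expect_equal(sites$cut_index, c(24L, 30L))
  rec <- sites[sites$recommended, ]
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$cut_index, 30L)
  expect_equal(rec$group, 4L)
  expect_equal(rec$top_arm_seq, "CTAAGG")
  expect_equal(rec$top_deletion_len, 6L)
  expect_false(rec$frame_shift)          # 6 bp deletion keeps frame
  expect_equal(nchar(rec$guide_seq), 20L)
  # the patternless site is retained, ungrouped, never recommended
  expect_true(is.na(sites$group[sites$cut_index == 24L]))
  # recommended implies Group 4 implies both criteria
  expect_true(all(rec$group == 4L & rec$criterion1 & rec$criterion2))
})

test_that("scanning a reverse complement mirrors cut positions and groups", {
  set.seed(21)
  cfg <- scan_config(window = 15)
  for (i in 1:3) {
    s <- random_dna(100)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    fwd <- scan_sites(s, config = cfg)
    rev <- scan_sites(rc, config = cfg)
    a <- fwd[order(fwd$cut_index, fwd$strand), c("cut_index", "group")]
    b <- rev
    b$cut_index <- 100L - b$cut_index
    b <- b[order(b$cut_index, b$strand), c("cut_index", "group")]
    rownames(a) <- rownames(b) <- NULL
    expect_equal(a, b)
  }
})

test_that("TALEN breaks land at the spacer midpoint, extra base 5'", {
  expect_equal(talen_cut_index(100, 14), 107L)
  expect_equal(talen_cut_index(100, 15), 108L)
  # the group depends only on the break position, not on the nuclease
  fx <- plant_locus(plant_spec(arm_len = 6L, intervening_len = 0L, seed = 9))
  cut <- fx$locus$cut_index
  # a 14 bp spacer centred on the break
  expect_equal(talen_cut_index(cut - 7L, 14L), cut)
  site <- profile_cut_site(fx$locus$sequence, talen_cut_index(cut - 7L, 14L),
                           fx$config)
  expect_equal(site$profile$group, fx$expected$group)
})

test_that("frame annotation flags shifts and splice-spanning deletions", {
  expect_equal(annotate_frame(4L), "out-of-frame")
  expect_equal(annotate_frame(12L), "in-frame")
  expect_equal(annotate_frame(3L), "in-frame")
  cds <- data.frame(start = 50L, end = 120L)
  expect_equal(annotate_frame(6L, deleted_span = c(46L, 52L),
                              coding_intervals = cds), "indeterminate")
  expect_equal(annotate_frame(6L, deleted_span = c(60L, 66L),
                              coding_intervals = cds), "in-frame")
})

test_that("prevalence counts unique cut sites and recommended fractions", {
  # no repeats anywhere: nothing can be recommended
  res <- prevalence_screen(unique_kmer_seq, config = scan_config(window = 10))
  expect_gt(res$unique_cut_sites, 0L)
  expect_equal(res$recommended_cut_sites, 0L)
  expect_equal(res$fraction_recommended, 0)

  # one planted Group 4 site among two unique cuts
  res <- prevalence_screen(g4_seq, config = scan_config(window = 20))
  expect_equal(res$unique_cut_sites, 2L)
  expect_equal(res$recommended_cut_sites, 1L)
  expect_equal(res$fraction_recommended, 0.5)
  expect_equal(res$fraction_recommended_out_of_frame, 0)

  # forward and reverse PAMs implying the same break collapse to one cut
  base <- strsplit(strrep("AT", 23), "")[[1]][1:45]
  base[c(15, 16)] <- "C"   # CC -> reverse-strand PAM, cut 14+3+3 = 20
  base[c(25, 26)] <- "G"   # GG -> forward PAM at 23, cut 20
  s <- paste(base, collapse = "")
  res <- prevalence_screen(s, config = scan_config(window = 10))
  expect_equal(res$total_sites, 2L)
  expect_equal(res$unique_cut_sites, 1L)
})

test_that("every recommended site satisfies both V2 criteria", {
  set.seed(33)
  for (i in 1:3) {
    s <- random_dna(150, gc = 0.6)
    sites <- scan_sites(s, config = scan_config(window = 15))
    rec <- sites[sites$recommended, ]
    if (nrow(rec)) {
      expect_true(all(rec$group == 4L))
      expect_true(all(rec$criterion1 & rec$criterion2))
    }
    # include_group3 widens recommendations to groups 3 and 4 only
    sites3 <- scan_sites(s, config = scan_config(window = 15),
                         include_group3 = TRUE)
    rec3 <- sites3[sites3$recommended, ]
    if (nrow(rec3)) expect_true(all(rec3$group %in% c(3L, 4L)))
  }
})
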