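# shared analysis-window fixture: planted dominant arm plus decoys gives a
# locus with a known top allele and several competing MMEJ alleles
fx <- plant_locus(plant_spec(arm_len = 4L, arm_gc = 2L, intervening_len = 2L,
                             n_decoys = 3L, decoy_strength = 0.6, seed = 101L))
loc <- fx$locus
cfg <- fx$config
pats <- enumerate_patterns(loc, cfg)
ranked <- rank_patterns(pats)
wt <- loc$sequence
top_allele <- predicted_allele(loc, ranked[1, ])$resulting_sequence
second_allele <- predicted_allele(loc, ranked[2, ])$resulting_sequence
third_allele <- predicted_allele(loc, ranked[3, ])$resulting_sequence
ins_allele <- paste0(substr(wt, 1, loc$cut_index), "A",
                     substring(wt, loc$cut_index + 1))

# substitute positions (1-based) of a sequence
sub_at <- function(s, pos) {
  for (p in pos) substr(s, p, p) <- setdiff(c("A", "C", "G", "T"),
                                            substr(s, p, p))[1]
  s
}

test_that("read classification applies the 2-polymorphism off-arm rule", {
  arm_start <- ranked$left_start[1]           # retained arm, 0-based
  arm_len <- ranked$arm_len[1]
  off_arm <- c(2L, nchar(top_allele) - 1L)    # far from the junction arm
  on_arm <- arm_start + 1L                    # inside the retained arm
  tab <- data.frame(
    allele_seq = c(wt,                         # clean wildtype
                   sub_at(wt, off_arm),        # 2 subs, no indel
                   sub_at(wt, c(2L, 5L, 9L)),  # 3 subs: not wildtype
                   top_allele,
                   sub_at(top_allele, off_arm[1]),       # 1 off-arm sub
                   sub_at(top_allele, c(off_arm, 5L)),   # 3 subs: too many
                   sub_at(top_allele, on_arm),           # sub on the arm
                   second_allele,              # another enumerated deletion
                   ins_allele,                 # insertion: never MMEJ
                   paste0(wt, "NN"),           # non-ACGT: excluded
                   substr(wt, 1, nchar(wt) - 45L)),  # indel beyond window
    count = 1:11)
  got <- classify_reads(tab, loc, cfg, patterns = pats)$class_label
  expect_equal(as.character(got),
               c("wildtype", "wildtype", "other_mutant",
                 "top_mh", "top_mh", "other_mutant", "other_mutant",
                 "other_mmej", "other_mutant", "excluded", "excluded"))
})

test_that("indel descriptors reconstruct the same alleles as raw sequences", {
  tab <- data.frame(del_start = ranked$left_start[1],
                    del_len = ranked$deletion_len[1],
                    ins_seq = NA_character_, count = 5L)
  got <- classify_reads(tab, loc, cfg, patterns = pats)
  expect_equal(got$allele_seq, top_allele)
  expect_equal(as.character(got$class_label), "top_mh")
  # compound deletion+insertion is never MMEJ-consistent
  tab <- data.frame(del_start = ranked$left_start[1],
                    del_len = ranked$deletion_len[1],
                    ins_seq = "T", count = 2L)
  expect_equal(as.character(classify_reads(tab, loc, cfg,
                                           patterns = pats)$class_label),
               "other_mutant")
})

test_that("outcome metrics reproduce the printed subcloning fractions", {
  # 21 of 24 mutant clones carry the top allele ("88%")
  mk_tab <- function(n_top, n_other1, n_other2, n_wt) {
    df <- data.frame(allele_seq = c(top_allele, second_allele, ins_allele, wt),
                     count = c(n_top, n_other1, n_other2, n_wt))
    df[df$count > 0, ]
  }
  m <- compute_metrics(classify_reads(mk_tab(21, 2, 1, 6), loc, cfg,
                                      patterns = pats))
  expect_equal(m$mutant_reads, 24)
  expect_equal(m$top_mh_fraction, 21 / 24)
  expect_equal(round(m$top_mh_fraction, 3), 0.875)
  expect_true(m$prema)

  # 16 of 32 mutant reads ("50%"), still modal and PreMA
  m <- compute_metrics(classify_reads(mk_tab(16, 9, 7, 8), loc, cfg,
                                      patterns = pats))
  expect_equal(m$top_mh_fraction, 0.5)
  expect_true(m$modal_is_top)
  expect_true(m$prema)

  # 28 of 39 clones ("72%")
  m <- compute_metrics(classify_reads(mk_tab(28, 6, 5, 9), loc, cfg,
                                      patterns = pats))
  expect_equal(round(m$top_mh_fraction, 3), 0.718)
  expect_true(m$prema)
})

test_that("the PreMA call honours its strict boundary conditions", {
  mk_tab <- function(n_top, n_other1, n_other2, n_wt) {
    df <- data.frame(allele_seq = c(top_allele, second_allele, ins_allele, wt),
                     count = c(n_top, n_other1, n_other2, n_wt))
    df[df$count > 0, ]
  }
  # top fraction exactly 0.50 with efficiency 20/95 = 0.2105 -> PreMA
  m <- compute_metrics(classify_reads(mk_tab(10, 6, 4, 75), loc, cfg,
                                      patterns = pats))
  expect_equal(m$top_mh_fraction, 0.5)
  expect_equal(m$mutagenic_efficiency, 20 / 95)
  expect_true(m$prema)
  # efficiency exactly 0.20 fails the strict > 20% requirement
  m <- compute_metrics(classify_reads(mk_tab(10, 6, 4, 80), loc, cfg,
                                      patterns = pats))
  expect_equal(m$mutagenic_efficiency, 0.2)
  expect_false(m$prema)
  expect_false(m$low_activity)     # the < 20% analysis filter is separate
  # a tied modal allele cannot be "predominant"
  m <- compute_metrics(classify_reads(mk_tab(10, 10, 0, 5), loc, cfg,
                                      patterns = pats))
  expect_false(m$modal_is_top)
  expect_false(m$prema)
  # no mutant reads: fractions missing, prema false
  m <- compute_metrics(classify_reads(data.frame(allele_seq = wt, count = 50),
                                      loc, cfg, patterns = pats))
  expect_true(is.na(m$top_mh_fraction))
  expect_false(m$prema)
  expect_equal(m$mutagenic_efficiency, 0)
})

test_that("classes partition reads, counts are conserved, fractions nest", {
  set.seed(77)
  for (i in 1:5) {
    tab <- simulate_allele_table(
      loc, fractions = c(wildtype = 0.2, top_mh = 0.4, other_mmej = 0.25,
                         other_mutant = 0.15),
      depth = 500, substitution_rate = 0.002, seed = i, config = cfg)
    got <- classify_reads(tab, loc, cfg, patterns = pats)
    expect_equal(sum(got$count), 500)
    expect_false(any(is.na(got$class_label)))
    m <- compute_metrics(got)
    expect_lte(m$top_mh_fraction, m$mh_fraction)
    expect_lte(m$mh_fraction, 1)
    expect_gte(m$top_mh_fraction, 0)
  }
})

test_that("decomposition tables renormalise to the predicted deletion size", {
  tt <- data.frame(indel_size = c(0, -4, -1, -2),
                   pct = c(40, 27, 18, 15),
                   significant = TRUE)
  expect_equal(tide_adjusted_prevalence(tt, -4), 27 / 60)
  expect_equal(tide_adjusted_prevalence(tt, 4), 27 / 60)  # length alias
  only <- data.frame(indel_size = c(0, -7), pct = c(55, 45))
  expect_equal(tide_adjusted_prevalence(only, -7), 1)
  expect_warning(v <- tide_adjusted_prevalence(tt, -9), "absent")
  expect_equal(v, 0)
  # non-significant rows are ignored
  tt$significant <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(tide_adjusted_prevalence(tt, -4), 1)
})
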