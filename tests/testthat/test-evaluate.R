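# FDR, delta-m grouping, color classification and LIPR.

tab1 <- data.table::fread(system.file("extdata",
  "strategy1_score_distribution.tsv", package = "specshift"))
tab2 <- data.table::fread(system.file("extdata",
  "strategy2_score_distribution.tsv", package = "specshift"))

test_that("the FDR is the decoy share of all retained best PSMs", {
  # printed count rows: D / (T + D), not D / T
  expect_equal(round(100 * 70 / (17160 + 70), 2), 0.41)
  expect_equal(round(100 * 186815 / (268589 + 186815), 2), 41.02)
  expect_equal(round(100 * 534 / (57784 + 534), 2), 0.92)
  fdr <- tab1$total_decoy / (tab1$total_target + tab1$total_decoy)
  # one printed row differs by 0.01 from the recomputed value (rounding in
  # the source table); everything else matches exactly
  expect_true(all(abs(round(100 * fdr, 2) - tab1$fdr_pct) <= 0.01 + 1e-9))
  best <- data.table::data.table(
    score = c(9L, 8L, 8L, 7L), hit_origin = c("target", "target", "decoy",
                                              "target"),
    delta_m = c(0, 1, -1, 0))
  row <- compute_fdr(best, 8L)
  expect_equal(row$fdr, 1 / 3)
  expect_equal(row$g1_target + row$g2_target + row$g3_target,
               row$total_target)
  expect_equal(compute_fdr(best[best$hit_origin == "target"], 0L)$fdr, 0)
  expect_true(is.na(compute_fdr(best, 99L)$fdr))
})

test_that("the 1% FDR score thresholds match the printed distributions", {
  expect_equal(threshold_from_curve(tab1$min_score, tab1$total_target,
                                    tab1$total_decoy), 17L)
  expect_equal(threshold_from_curve(tab2$min_score, tab2$total_target,
                                    tab2$total_decoy), 21L)
  # PSM-table route: all-target input validates at the smallest score
  best <- data.table::data.table(score = c(7L, 9L, 12L),
                                 hit_origin = "target", delta_m = 0)
  expect_equal(threshold_at_fdr(best), 7L)
  all_decoy <- data.table::data.table(score = 7L, hit_origin = "decoy",
                                      delta_m = 0)
  expect_true(is.na(threshold_at_fdr(all_decoy)))
})

test_that("delta-m grouping uses the sign with an exact zero test", {
  rm_ <- residue_masses()
  expect_equal(delta_m_group(c(0, rm_[["D"]], -rm_[["G"]])),
               c("G1", "G2", "G3"))
  # transposed sequences have delta_m exactly 0
  expect_equal(delta_m_group(peptide_mass("LESGAEEK") -
                               peptide_mass("LEGSAEEK")), "G1")
})

test_that("the four reference classification scenarios reproduce", {
  rm_ <- residue_masses()
  hit <- "LEGAEEVLK"
  # single-residue insertion of S: Green
  bait_ins <- paste0(substr(hit, 1, 3), "S", substr(hit, 4, 9))
  expect_equal(classify_color(bait_ins, hit, rm_[["S"]]), "Green")
  # deletion of a six-residue block: Green (content read from the hit)
  hit_del <- paste0(substr(hit, 1, 3), "EPPNPE", substr(hit, 4, 9))
  expect_equal(classify_color(hit, hit_del, -peptide_mass("EPPNPE") +
                                mass_constants()[["water"]]), "Green")
  # two-residue insertion VH: Orange (VH vs HV is ambiguous)
  bait_vh <- paste0(substr(hit, 1, 3), "VH", substr(hit, 4, 9))
  expect_equal(classify_color(bait_vh, hit, rm_[["V"]] + rm_[["H"]]),
               "Orange")
  # same mass, different sequences: Red
  expect_equal(classify_color("LESGAEEK", "LEGSAEEK", 0), "Red")
})

test_that("classification handles ambiguity, substitutions and multi-site edits", {
  rm_ <- residue_masses()
  hit <- "PGTEDFNAK"
  # I/L insertion is mass-ambiguous: Orange
  bait_i <- paste0(substr(hit, 1, 4), "I", substr(hit, 5, 9))
  expect_equal(classify_color(bait_i, hit, rm_[["I"]]), "Orange")
  # substitution with a unique replacement mass: Green
  bait_s <- sub("F", "W", hit)
  expect_equal(classify_color(bait_s, hit, rm_[["W"]] - rm_[["F"]]), "Green")
  # substitution to I or L: Orange
  bait_sl <- sub("F", "L", hit)
  expect_equal(classify_color(bait_sl, hit, rm_[["L"]] - rm_[["F"]]),
               "Orange")
  # substitutions at two separated sites: Red
  bait_2 <- hit
  substr(bait_2, 2, 2) <- "W"
  substr(bait_2, 6, 6) <- "Y"
  dm2 <- peptide_mass(bait_2) - peptide_mass(hit)
  expect_equal(classify_color(bait_2, hit, dm2), "Red")
  # a deduced edit that cannot carry delta_m is Red
  expect_equal(classify_color("AAAWK", "AAAGK", 1.2345), "Red")
})

test_that("classification verdicts agree with planted-edit ground truth", {
  sources <- as_peptide_table(random_peptides(60, seed = 3))
  planted <- plant_edits(sources, 60,
                         kinds = c("insert1", "insertK", "delete",
                                   "substitute", "twoSite"),
                         seed = 17, confound_rate = 0)
  got <- mapply(classify_color, planted$truth$bait, planted$truth$source,
                planted$truth$delta_m)
  expect_equal(unname(got), planted$truth$expected_color)
})

test_that("LIPR matches hand-traced and oracle values", {
  # every shared mass concordant
  expect_equal(lipr("PEPTIDEK", "PEPTIDER"), 0)
  # the transposed pair: 8 of 14 shared masses are discordant
  expect_equal(lipr("LESGAEEK", "LEGSAEEK"), 8 / 14)
  expect_equal(oracle_lipr_raw("LESGAEEK", "LEGSAEEK"), 8 / 14)
  # against the brute-force oracle on random same-mass-ish pairs
  seqs <- random_peptides(30, seed = 8)
  set.seed(31)
  for (i in 1:15) {
    a <- sample(seqs, 1)
    b <- sample(setdiff(seqs, a), 1)
    if (length(intersect(specshift::spectrum_keys(a)[[1]],
                         specshift::spectrum_keys(b)[[1]])) == 0) next
    expect_equal(lipr(a, b), oracle_lipr_raw(a, b))
    expect_gte(lipr(a, b), 0)
    expect_lte(lipr(a, b), 1)
    expect_equal(lipr(a, b), lipr(b, a)) # delta_m = 0 raw alignments
  }
  expect_error(lipr("AAAAAAK", "GGGGGGR"), "no shared masses")
})

test_that("a correctly realigned single-edit PSM has LIPR 0", {
  f <- fig2_fixture()
  expect_equal(lipr(f$bait, f$hit, f$delta_m, location = 3L), 0)
  dm <- peptide_mass("PEPTIDEGK") - peptide_mass("PEPTIDEK")
  bs <- best_shift("PEPTIDEGK", "PEPTIDEK", dm)
  expect_equal(lipr("PEPTIDEGK", "PEPTIDEK", dm, bs$location), 0)
})

test_that("decoy best PSMs carry higher LIPR than target best PSMs", {
  rec <- recovery_experiment(n_proteins = 20, n_edits = 40, seed = 19)
  ev <- evaluate_psms(rec$best2)
  # recovered true sources are sequence-consistent; decoy hits are random
  tgt <- ev$lipr[ev$hit_origin == "target"]
  dec <- ev$lipr[ev$hit_origin == "decoy"]
  if (length(dec) >= 1) expect_gt(mean(dec), mean(tgt))
  expect_true(all(ev$lipr >= 0 & ev$lipr <= 1))
  expect_true(all(ev$group %in% c("G1", "G2", "G3")))
})

test_that("summaries conserve counts and specific sets are size-matched", {
  rec <- recovery_experiment(n_proteins = 15, n_edits = 30, seed = 23)
  ev <- evaluate_psms(rec$best2)
  sm <- summarize_colors(ev, "planted")
  expect_equal(sm$n_green + sm$n_orange + sm$n_red, nrow(ev))
  curves <- color_fraction_by_score(ev)
  expect_true(all(abs(curves$frac_green + curves$frac_orange +
                        curves$frac_red - 1) < 1e-12))
  ss <- strategy_specific_sets(rec$best1, rec$best2)
  expect_equal(nrow(ss$ss1), nrow(ss$ss2))
  expect_true(all(ss$ss1$bait_id == ss$ss2$bait_id))
})
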