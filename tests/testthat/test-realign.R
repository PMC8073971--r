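# Shift realignment: apply_shift, best_shift and Strategy2 selection.

test_that("apply_shift moves exactly the fragments spanning the boundary", {
  f <- fig2_fixture()
  sp <- generate_spectrum(f$hit)
  sh <- apply_shift(sp, f$delta_m, 3)
  moved <- sh[sh$shifted]
  # b4..b7 and y4..y7 move; everything else stays
  expect_equal(nrow(moved), 8L)
  expect_setequal(paste0(moved$ion, moved$index),
                  c(paste0("b", 4:7), paste0("y", 4:7)))
  expect_equal(sh$mass[sh$shifted] - sp$mass[sh$shifted],
               rep(f$delta_m, 8))
  expect_equal(sh$mass[!sh$shifted], sp$mass[!sh$shifted])
  # boundary case: at l = n_hit no b-ion moves, every y-ion does
  sh_c <- apply_shift(sp, f$delta_m, nchar(f$hit))
  expect_true(all(sh_c$shifted[sh_c$ion == "y"]))
  expect_false(any(sh_c$shifted[sh_c$ion == "b"]))
  expect_error(apply_shift(sp, 0, 3), "non-zero")
  expect_error(apply_shift(sp, f$delta_m, 8), "location")
})

test_that("the worked example realigns at location 3 with shift SPC 14", {
  f <- fig2_fixture()
  bs <- best_shift(f$bait, f$hit, f$delta_m)
  expect_equal(bs$location, 3L)
  expect_equal(bs$shift_spc, 14L)
  expect_equal(bs$raw_spc, 7L)
  d <- shift_match_delta(f$bait, f$hit, f$delta_m, 3)
  expect_equal(d$new, 8L)
  expect_equal(d$removed, 1L)
  expect_equal(d$shift_spc, d$raw_spc + d$new - d$removed)
})

test_that("a planted single insertion realigns to the full 2n match", {
  dm <- peptide_mass("PEPTIDEGK") - peptide_mass("PEPTIDEK")
  bs <- best_shift("PEPTIDEGK", "PEPTIDEK", dm)
  expect_equal(bs$shift_spc, 16L) # 2 * length(hit)
  # the identity alignment is kept exactly when no location strictly
  # improves on the raw SPC
  for (pair in list(c("WWWWGHMK", "AAAAAAK"), c("PFNDWGER", "TTTVSEK"),
                    c("EAEDISEK", "EAEISEK"))) {
    dm2 <- peptide_mass(pair[1]) - peptide_mass(pair[2])
    bs2 <- best_shift(pair[1], pair[2], dm2)
    loc_scores <- vapply(0:nchar(pair[2]), function(l)
      oracle_mult_intersect(oracle_keys(pair[1]),
                            oracle_shifted_keys(pair[2], dm2, l)), 0)
    if (max(loc_scores) <= bs2$raw_spc) {
      expect_true(is.na(bs2$location))
      expect_equal(bs2$shift_spc, bs2$raw_spc)
    } else {
      expect_equal(bs2$shift_spc, as.integer(max(loc_scores)))
    }
  }
})

test_that("best_shift equals the rebuild-from-scratch oracle", {
  seqs <- random_peptides(40, seed = 9)
  set.seed(21)
  for (i in seq_len(30)) {
    hit <- sample(seqs, 1)
    # half related pairs (planted insertion), half unrelated pairs
    bait <- if (i %% 2 == 0) {
      pos <- sample(0:nchar(hit), 1)
      paste0(substr(hit, 1, pos), sample(c("D", "W", "G"), 1),
             substr(hit, pos + 1, nchar(hit)))
    } else {
      sample(setdiff(seqs, hit), 1)
    }
    dm <- peptide_mass(bait) - peptide_mass(hit)
    if (abs(dm) < 1e-6) next
    bs <- best_shift(bait, hit, dm)
    orc <- oracle_best_shift(bait, hit, dm)
    expect_equal(bs$shift_spc, as.integer(orc[["spc"]]))
    expect_equal(bs$location, as.integer(orc[["location"]]))
    expect_gte(bs$shift_spc, bs$raw_spc)
  }
})

test_that("Strategy2 lets a realigned candidate overtake a raw-SPC leader", {
  # the bait is a single substitution away from hit3; hit2 is a same-mass
  # transposition of the bait, so its raw SPC (2n - 2) leads, but it cannot
  # be realigned (delta_m = 0) and the true relative overtakes it at 2n
  hit3 <- "LESGAEEWK"
  bait <- sub("A", "D", hit3)
  hit2 <- paste0(substr(bait, 1, 1), substr(bait, 3, 3), substr(bait, 2, 2),
                 substr(bait, 4, 9))
  db <- as_peptide_table(c(hit2, hit3, "WWWWGHMK"))
  cand <- enumerate_candidates(as_peptide_table(bait), db, threshold = 7)
  expect_setequal(cand$hit_seq, c(hit2, hit3))
  b1 <- select_best_strategy1(cand)
  b2 <- select_best_strategy2(cand)
  expect_equal(b1$hit_seq, hit2)              # raw SPC 16 beats 8
  expect_equal(b1$score, 2L * nchar(bait) - 2L)
  expect_equal(b2$hit_seq, hit3)              # shift SPC 18 wins after realign
  expect_equal(b2$score, 2L * nchar(hit3))
  expect_equal(nrow(b1), nrow(b2))            # same best-PSM count per strategy
})

test_that("shift SPC dominates raw SPC and is even for realigned best PSMs", {
  rec <- recovery_experiment(n_proteins = 10, n_edits = 25, seed = 13)
  cand <- enumerate_candidates(
    as_peptide_table(rec$truth$bait), rec$sets$database, threshold = 7)
  idx <- which(cand$delta_m != 0)
  for (i in idx[seq_len(min(60, length(idx)))]) {
    bs <- best_shift(cand$bait_seq[i], cand$hit_seq[i], cand$delta_m[i])
    expect_gte(bs$shift_spc, cand$raw_spc[i])
  }
  best2 <- rec$best2
  aligned <- best2[!is.na(best2$location)]
  tr <- rec$truth[match(aligned$bait_id, rec$truth$bait_id)]
  even_ok <- aligned$score %% 2L == 0L | tr$coincidence
  expect_true(all(even_ok))
})
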