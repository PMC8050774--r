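test_that("localization filtering is strictly greater than the threshold", {
  s <- random_sites(3)
  s$localization_prob <- c(0.74, 0.75, 0.76)
  out <- filter_sites(s)
  expect_equal(nrow(out), 1)
  expect_equal(out$localization_prob, 0.76)
  expect_equal(attr(out, "removed"), 2)

  empty <- filter_sites(s[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("occupancy change subtracts the protein component", {
  expect_equal(occupancy_change(1, -1), 2)
  expect_equal(occupancy_change(0.7, 0.7), 0)   # pure abundance change
  expect_equal(occupancy_change(c(1, NA), c(0, 1)), c(1, NA))
})

test_that("site occupancy matches sites to protein replicates and averages tech reps", {
  per_rep <- data.frame(
    protein_group_id = rep("P1", 4),
    replicate_bio = c(1L, 1L, 2L, 2L),
    replicate_tech = c(1L, 2L, 1L, 2L),
    log2_ratio = c(0, 0, 1, 1)
  )
  pq <- data.frame(protein_group_id = "P1", mean_log2fc = 0.5)
  attr(pq, "per_replicate") <- per_rep

  s <- data.frame(protein_group_id = c("P1", "P9"), position = c(10L, 5L),
                  residue = c("S", "T"), localization_prob = c(0.9, 0.9),
                  stringsAsFactors = FALSE)
  s$`ratio_hl.b1t1` <- c(2, 2)     # site log2 = 1, protein 0 -> occ 1
  s$`ratio_hl.b1t2` <- c(8, 2)     # site log2 = 3 -> occ 3; tech mean = 2
  s$`ratio_hl.b2t1` <- c(4, 2)     # site log2 = 2, protein 1 -> occ 1
  s$`ratio_hl.b2t2` <- c(NA, 2)    # missing tech rep ignored
  attr(s, "ratio_labels") <- c("b1t1", "b1t2", "b2t1", "b2t2")

  sq <- site_occupancy(s, pq)
  expect_equal(sq$occ_b1[1], 2)
  expect_equal(sq$occ_b2[1], 1)
  expect_equal(sq$mean_log2_occupancy_change[1], 1.5)
  expect_equal(sq$site_id[1], "P1_S10")
  # unmatched protein: kept, flagged, no occupancy values
  expect_false(sq$matched[2])
  expect_true(is.na(sq$mean_log2_occupancy_change[2]))
})

test_that("noise-free occupancy doubling is recovered exactly end to end", {
  gt <- make_ground_truth(n_proteins = 80, sigma = 0, missingness = FALSE,
                          seed = 29, category_sizes = c(OXPHOS = 10),
                          frac_phospho = 0.8, frac_occ_shift = 0.5,
                          occ_shift_log2 = 1)
  sim <- simulate_experiment(gt)
  res <- run_pipeline(sim$evidence, sim$protein_groups, sim$sites)
  key <- sprintf("%s_%s%d", gt$phosphosites$protein_id,
                 gt$phosphosites$residue, gt$phosphosites$position)
  m <- match(res$site_quant$site_id, key)
  ok <- !is.na(m) & !is.na(res$site_quant$mean_log2_occupancy_change)
  expect_gt(sum(ok), 10)
  err <- res$site_quant$mean_log2_occupancy_change[ok] -
    gt$phosphosites$true_log2_occ_ratio[m[ok]]
  expect_lt(max(abs(err)), 1e-9)
  # doubled sites on unchanged proteins recover exactly log2(2) = 1
  doubled <- ok & abs(gt$phosphosites$true_log2_occ_ratio[m] - 1) < 1e-12 &
    abs(res$site_quant$protein_log2fc) < 1e-9
  if (any(doubled, na.rm = TRUE))
    expect_equal(res$site_quant$mean_log2_occupancy_change[which(doubled)],
                 rep(1, sum(doubled, na.rm = TRUE)), tolerance = 1e-9)
})

test_that("protein-level confounding is flagged, never dropped", {
  sq <- data.frame(site_id = c("A_S1", "B_S2", "C_S3"),
                   protein_group_id = c("A", "B", "C"),
                   stringsAsFactors = FALSE)
  pq <- data.frame(protein_group_id = c("A", "B", "C"),
                   mean_log2fc = c(-4.3, 0, -1.0))
  out <- flag_protein_confound(sq, pq, threshold = 2)
  expect_equal(out$confounded, c(TRUE, FALSE, FALSE))
  out2 <- flag_protein_confound(sq, pq, threshold = 1)
  expect_equal(out2$confounded, c(TRUE, FALSE, FALSE))  # strict inequality at 1.0
  expect_equal(nrow(out2), 3)
})

test_that("sites failing localization never reach downstream statistics", {
  gt <- make_ground_truth(n_proteins = 150, seed = 37,
                          category_sizes = c(OXPHOS = 20))
  sim <- simulate_experiment(gt)
  res <- run_pipeline(sim$evidence, sim$protein_groups, sim$sites)
  low_ids <- sprintf("%s_%s%d",
                     sim$sites$protein_group_id,
                     sim$sites$residue,
                     sim$sites$position)[sim$sites$localization_prob <= 0.75]
  expect_gt(length(low_ids), 0)
  expect_false(any(low_ids %in% res$site_quant$site_id))
  expect_false(any(low_ids %in% res$site_tests$feature_id))
})
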