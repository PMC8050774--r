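test_that("flagged protein groups are excluded exactly, clean rows kept", {
  pg <- data.frame(
    protein_group_id = sprintf("G%d", 1:5),
    flag_reverse = c(TRUE, FALSE, FALSE, FALSE, FALSE),
    flag_contaminant = c(FALSE, FALSE, FALSE, FALSE, FALSE),
    flag_only_by_site = c(FALSE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
  out <- filter_protein_groups(pg)
  expect_equal(out$protein_group_id, sprintf("G%d", 2:5))
  expect_equal(attr(out, "removed")[["total"]], 1)

  # doubly flagged rows are removed once but counted under both flags
  pg$flag_contaminant[1] <- TRUE
  out2 <- filter_protein_groups(pg)
  expect_equal(nrow(out2), 4)
  expect_equal(attr(out2, "removed")[["reverse"]], 1)
  expect_equal(attr(out2, "removed")[["contaminant"]], 1)
  expect_equal(attr(out2, "removed")[["total"]], 1)

  # all-clean input is the identity
  pg$flag_reverse <- pg$flag_contaminant <- FALSE
  out3 <- filter_protein_groups(pg)
  expect_equal(out3$protein_group_id, pg$protein_group_id)
})

test_that("incorporation rate is H/(H+L) with missing reported as NA", {
  expect_equal(incorporation_rate(50, 50), 0.5)
  expect_equal(incorporation_rate(1, 0), 1)
  expect_equal(incorporation_rate(3, 1), 0.75)
  expect_true(is.na(incorporation_rate(0, 0)))
  expect_true(is.na(incorporation_rate(NA, NA)))
  expect_equal(incorporation_rate(NA, 10), 0)     # absent heavy = no heavy signal
  expect_equal(incorporation_rate(c(50, 3), c(50, 1)), c(0.5, 0.75))
  expect_error(incorporation_rate(-1, 5), "domain")
})

test_that("ratio normalization median-centers per run and is idempotent", {
  # ratios {2,2,2} -> {1,1,1}: median log2 shifted to 0
  expect_equal(as.numeric(normalize_ratios(log2(c(2, 2, 2)))), c(0, 0, 0))
  # symmetric ratios {0.5, 1, 2} unchanged
  expect_equal(as.numeric(normalize_ratios(log2(c(0.5, 1, 2)))),
               log2(c(0.5, 1, 2)))
  # single ratio {8} -> {1}
  expect_equal(as.numeric(normalize_ratios(log2(8))), 0)

  set.seed(1)
  x <- rnorm(50)
  run <- sample(c("r1", "r2"), 50, replace = TRUE)
  n1 <- normalize_ratios(x, run)
  n2 <- normalize_ratios(as.numeric(n1), run)
  expect_equal(as.numeric(n2), as.numeric(n1))     # idempotence
  expect_equal(unname(attr(n2, "shifts")), c(0, 0))

  expect_error(normalize_ratios(c(NA_real_, Inf), c("rx", "rx")), "rx")
})

test_that("scaling one channel leaves normalized ratios unchanged", {
  set.seed(2)
  ev <- random_evidence(40)
  ev$intensity_heavy[is.na(ev$intensity_heavy)] <- 1e5
  ev$intensity_light[is.na(ev$intensity_light)] <- 1e5
  a <- add_normalized_ratios(ev)
  ev2 <- ev
  ev2$intensity_heavy <- ev2$intensity_heavy * 7.3
  b <- add_normalized_ratios(ev2)
  expect_equal(b$log2_ratio_norm, a$log2_ratio_norm)
})

test_that("protein aggregation is the median over peptides, tech reps averaged", {
  ev <- data.frame(
    peptide_sequence = c("AAK", "CCK", "DDK"),
    protein_group_id = "P1",
    replicate_bio = 1L, replicate_tech = 1L,
    log2_ratio_norm = c(1, 1, 3),
    stringsAsFactors = FALSE
  )
  pq <- protein_log2fc(ev)
  expect_equal(pq$mean_log2fc, 1)                 # median of {1,1,3}
  expect_equal(pq$n_peptide_ratios, 3L)

  # single peptide: that value
  pq1 <- protein_log2fc(ev[3, ])
  expect_equal(pq1$mean_log2fc, 3)

  # technical replicates averaged on log2 before biological means
  ev2 <- rbind(
    data.frame(peptide_sequence = "AAK", protein_group_id = "P1",
               replicate_bio = 1L, replicate_tech = 1L, log2_ratio_norm = 1),
    data.frame(peptide_sequence = "AAK", protein_group_id = "P1",
               replicate_bio = 1L, replicate_tech = 2L, log2_ratio_norm = 3),
    data.frame(peptide_sequence = "AAK", protein_group_id = "P1",
               replicate_bio = 2L, replicate_tech = 1L, log2_ratio_norm = 0)
  )
  pq2 <- protein_log2fc(ev2)
  expect_equal(pq2$log2fc_b1, 2)                  # mean(1, 3)
  expect_equal(pq2$log2fc_b2, 0)
  expect_equal(pq2$mean_log2fc, 1)                # mean over biological reps
})

test_that("noise-free synthetic fold changes are recovered exactly", {
  gt <- noise_free_gt(60)
  sim <- simulate_experiment(gt)
  pgf <- filter_protein_groups(sim$protein_groups)
  ev <- sim$evidence[sim$evidence$protein_group_id %in% pgf$protein_group_id, ]
  pq <- protein_log2fc(add_normalized_ratios(ev))
  truth <- gt$proteins$true_log2fc[match(pq$protein_group_id,
                                         gt$proteins$protein_id)]
  expect_equal(nrow(pq), 60)
  expect_lt(max(abs(pq$mean_log2fc - truth)), 1e-9)
})

test_that("incorporation time course pools intensity sums before the ratio", {
  ev <- data.frame(
    peptide_sequence = c("AAK", "CCK", "DDK"),
    protein_group_id = c("P1", "P1", "P2"),
    intensity_heavy = c(60, 40, 50),
    intensity_light = c(0, 0, 50),
    timepoint_days = 2,
    stringsAsFactors = FALSE
  )
  tc <- incorporation_timecourse(ev)
  expect_equal(tc$per_protein$fraction[tc$per_protein$protein_group_id == "P1"], 1)
  expect_equal(tc$per_protein$fraction[tc$per_protein$protein_group_id == "P2"], 0.5)
})

test_that("noise-free time course matches the closed form, pooled median included", {
  gt <- make_ground_truth(n_proteins = 50, sigma = 0, missingness = FALSE,
                          seed = 21, category_sizes = c(OXPHOS = 10),
                          category_k_multiplier = c(OXPHOS = 1),
                          timepoints = c(0, 3, 6),
                          contam_rate = 0, decoy_rate = 0,
                          only_by_site_rate = 0)
  gt$proteins$turnover_rate_k <- 0.75
  sim <- simulate_experiment(gt, mode = "timecourse")
  tc <- incorporation_timecourse(sim$evidence)
  # pooled median fraction at t = 6 with k = 0.75: 1 - exp(-4.5)
  med6 <- tc$per_timepoint$median[tc$per_timepoint$timepoint_days == 6]
  expect_equal(med6, 1 - exp(-4.5), tolerance = 1e-9)
  expect_equal(med6, 0.98889, tolerance = 1e-5)
  # per-protein fractions are non-decreasing in t
  for (d in split(tc$per_protein, tc$per_protein$protein_group_id))
    expect_true(all(diff(d$fraction[order(d$timepoint_days)]) >= -1e-12))
})

test_that("null simulation shows high heavy/light intensity correlation", {
  gt <- make_ground_truth(n_proteins = 300, seed = 17,
                          category_sizes = c(OXPHOS = 30),
                          category_log2fc = c(OXPHOS = 0))
  sim <- simulate_experiment(gt)
  ev <- sim$evidence[sim$evidence$replicate_bio == 1 &
                       sim$evidence$replicate_tech == 1 &
                       sim$evidence$protein_group_id %in% gt$proteins$protein_id, ]
  h <- tapply(ev$intensity_heavy, ev$protein_group_id, sum, na.rm = TRUE)
  l <- tapply(ev$intensity_light, ev$protein_group_id, sum, na.rm = TRUE)
  ok <- h > 0 & l > 0
  expect_gt(cor(log2(h[ok]), log2(l[ok])), 0.95)
})
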