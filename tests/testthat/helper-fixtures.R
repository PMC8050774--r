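# Shared fixture builders. All fixtures are generated in code; tests that
# need files write them to tempdir().

write_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

aa20 <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_peptide <- function(n = 1, len = c(7, 20)) {
  vapply(sample(len[1]:len[2], n, replace = TRUE), function(L)
    paste(sample(aa20, L, replace = TRUE), collapse = ""), "")
}

# random internal-representation evidence table; some single-channel rows,
# never both channels absent
random_evidence <- function(n = 20) {
  h <- round(2^rnorm(n, 20, 2), 4)
  l <- round(2^rnorm(n, 20, 2), 4)
  drop_h <- runif(n) < 0.15
  drop_l <- !drop_h & runif(n) < 0.15
  h[drop_h] <- NA
  l[drop_l] <- NA
  data.frame(
    peptide_sequence = random_peptide(n),
    charge = sample(2:4, n, replace = TRUE),
    intensity_heavy = h,
    intensity_light = l,
    protein_group_id = sample(sprintf("P%03d", 1:8), n, replace = TRUE),
    raw_file = sample(c("run_b1t1", "run_b2t1"), n, replace = TRUE),
    fraction = sample(0:3, n, replace = TRUE),
    replicate_bio = sample(1:2, n, replace = TRUE),
    replicate_tech = 1L,
    timepoint_days = NA_real_,
    modifications = "Unmodified",
    stringsAsFactors = FALSE
  )
}

random_protein_groups <- function(n = 10) {
  pg <- data.frame(
    protein_group_id = sprintf("G%03d", seq_len(n)),
    ratio_hl_normalized = round(2^rnorm(n, 0, 1), 6),
    intensity_heavy = round(2^rnorm(n, 20, 2), 4),
    intensity_light = round(2^rnorm(n, 20, 2), 4),
    flag_reverse = runif(n) < 0.1,
    flag_contaminant = runif(n) < 0.1,
    flag_only_by_site = runif(n) < 0.1,
    stringsAsFactors = FALSE
  )
  pg$member_protein_ids <- lapply(seq_len(n), function(i)
    sprintf("Q%03d_%d", i, seq_len(sample(1:3, 1))))
  pg
}

random_sites <- function(n = 10, labels = c("b1t1", "b1t2", "b2t1")) {
  s <- data.frame(
    protein_group_id = sample(sprintf("P%03d", 1:8), n, replace = TRUE),
    position = sample(1:300, n),
    residue = sample(c("S", "T", "Y"), n, replace = TRUE, prob = c(.7, .2, .1)),
    localization_prob = round(runif(n), 6),
    intensity_heavy = round(2^rnorm(n, 18, 2), 4),
    intensity_light = round(2^rnorm(n, 18, 2), 4),
    stringsAsFactors = FALSE
  )
  for (lab in labels) {
    r <- round(2^rnorm(n, 0, 1), 6)
    r[runif(n) < 0.1] <- NA
    s[[paste0("ratio_hl.", lab)]] <- r
  }
  attr(s, "ratio_labels") <- labels
  s
}

# small noise-free comparison ground truth used across tests
noise_free_gt <- function(n = 60, seed = 42) {
  make_ground_truth(
    n_proteins = n, sigma = 0, missingness = FALSE, seed = seed,
    category_sizes = c(OXPHOS = max(5, round(n / 10)),
                       Ribosome = max(5, round(n / 10)))
  )
}
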