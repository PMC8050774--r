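## Synthetic two-channel (heavy/light) labeling experiment with known ground
## truth. The generator emulates the downstream-visible structure of a
## MaxQuant-style SILAF experiment: an in-silico Lys-C digested proteome,
## log-normal peptide intensities, first-order heavy-lysine incorporation
## kinetics in time-course mode, condition fold changes concentrated in a
## down-regulated OXPHOS-like category in comparison mode, phosphosites with
## localization probabilities, MNAR missingness, and injected contaminant /
## decoy rows.

# rough proteome-wide amino-acid frequencies; lysine ~7% so random proteins
# digest into many observable peptides
.AA_FREQ <- c(A = 7.4, R = 4.2, N = 4.4, D = 5.9, C = 3.3, E = 5.8, Q = 3.7,
              G = 7.4, H = 2.9, I = 3.8, L = 7.6, K = 7.2, M = 1.8, F = 4.0,
              P = 5.0, S = 8.1, T = 6.2, W = 1.3, Y = 3.3, V = 6.8)

#' First-order label incorporation
#'
#' Fraction of a protein pool carrying the heavy label after `t` days of
#' pulse labeling under a single-pool first-order synthesis/degradation
#' model with rate constant `k`: `1 - exp(-k t)`.
#'
#' @param k turnover rate constant, per day (> 0).
#' @param t labeling time in days (>= 0); vectorized over both arguments.
#' @return incorporation fraction in `[0, 1]`.
#' @export
incorporation_fraction <- function(k, t) {
  if (any(k <= 0)) stop("domain error: k must be > 0")
  if (any(t < 0)) stop("domain error: t must be >= 0")
  1 - exp(-k * t)
}

.random_sequences <- function(n, length_range) {
  lens <- sample(length_range[1]:length_range[2], n, replace = TRUE)
  vapply(lens, function(L) {
    s <- sample(names(.AA_FREQ), L, replace = TRUE, prob = .AA_FREQ)
    if (!any(s == "K")) s[sample.int(L, 1)] <- "K"  # at least one cleavage site
    paste(s, collapse = "")
  }, "")
}

#' Define a synthetic SILAF experiment (ground truth)
#'
#' Draws per-protein parameters (sequence, abundance, turnover rate,
#' functional category, condition log2 fold change, phosphosite
#' occupancies) and records every generator setting, so that
#' [simulate_experiment()] is fully determined by this object. Default
#' condition effects place a log2 fold change of -1 on a 50-protein
#' OXPHOS-like category while all other proteins are unchanged; turnover
#' rates are log-normal with ribosome-like proteins labeling faster and
#' OXPHOS-like proteins slower.
#'
#' @param n_proteins number of (non-contaminant) proteins.
#' @param n_bio,n_tech biological and technical replicates per condition in
#'   comparison mode.
#' @param sigma multiplicative intensity noise, standard deviation of the
#'   per-observation log2 heavy/light ratio. 0 gives a noise-free dataset.
#' @param seed RNG seed stored with the truth; the same object always
#'   regenerates byte-identical tables.
#' @param mean_log2_abundance,sd_log2_abundance log2-normal protein
#'   abundance model (arbitrary MS intensity units).
#' @param k_meanlog,k_sdlog log-normal turnover-rate model (per day); the
#'   default median of 0.05/day reproduces slow adult-fly labeling
#'   (about 50\% by two weeks).
#' @param category_sizes named integer vector of functional-category sizes;
#'   remaining proteins fall in category "Other" and stay unannotated.
#' @param category_log2fc named vector of true condition log2 fold changes
#'   per category (heavy = knockdown-like condition, light = control).
#' @param category_k_multiplier named vector of turnover-rate multipliers
#'   per category.
#' @param frac_phospho fraction of proteins carrying 1-2 phosphosites.
#' @param frac_occ_shift fraction of phosphosites with a true occupancy
#'   change of `occ_shift_log2` (random sign).
#' @param occ_shift_log2 magnitude of the true log2 occupancy ratio at
#'   shifted sites (default twofold).
#' @param loc_conf_frac fraction of site rows drawn from the confidently
#'   localized component (> 0.75 localization probability).
#' @param contam_rate,decoy_rate,only_by_site_rate injection rates for
#'   contaminant, reversed-decoy and only-identified-by-site rows, as a
#'   fraction of real evidence rows.
#' @param missingness logical; apply missing-not-at-random channel dropout.
#' @param missing_max,missing_mid_offset,missing_scale MNAR model: a
#'   channel intensity is dropped with probability
#'   `missing_max * plogis(-(log2 I - mid) / missing_scale)` where
#'   `mid = mean_log2_abundance + missing_mid_offset`.
#' @param peptide_length_range detectable peptide length window (residues).
#' @param max_missed maximum missed cleavages in the in-silico digestion.
#' @param max_peptides_per_protein detectability cap: at most this many
#'   peptides are observed per protein.
#' @param timepoints labeling time course (days) for time-course mode.
#' @param n_bio_timecourse biological replicates per timepoint.
#' @param seq_length_range protein sequence length range (residues).
#' @return object of class `silaf_ground_truth`: list with `proteins`,
#'   `phosphosites` and `params`.
#' @export
make_ground_truth <- function(n_proteins = 1000,
                              n_bio = 4, n_tech = 2,
                              sigma = 0.25,
                              seed = 1,
                              mean_log2_abundance = 20, sd_log2_abundance = 2,
                              k_meanlog = log(0.05), k_sdlog = 0.5,
                              category_sizes = c(OXPHOS = 50, Ribosome = 50,
                                                 Proteasome = 40,
                                                 Glycolysis = 40, TCA = 40),
                              category_log2fc = c(OXPHOS = -1),
                              category_k_multiplier = c(Ribosome = 3, OXPHOS = 0.3),
                              frac_phospho = 0.3,
                              frac_occ_shift = 0.25,
                              occ_shift_log2 = 1,
                              loc_conf_frac = 0.8,
                              contam_rate = 0.02, decoy_rate = 0.01,
                              only_by_site_rate = 0.005,
                              missingness = TRUE,
                              missing_max = 0.2, missing_mid_offset = -4,
                              missing_scale = 1.5,
                              peptide_length_range = c(7, 40),
                              max_missed = 2, max_peptides_per_protein = 8,
                              timepoints = seq(0, 14, by = 2),
                              n_bio_timecourse = 2,
                              seq_length_range = c(150, 500)) {
  if (sum(category_sizes) > n_proteins)
    stop("category sizes exceed n_proteins")
  set.seed(seed)
  protein_id <- sprintf("P%04d", seq_len(n_proteins))
  category <- rep("Other", n_proteins)
  idx <- sample.int(n_proteins)  # random category placement
  pos <- 1L
  for (cn in names(category_sizes)) {
    category[idx[pos:(pos + category_sizes[[cn]] - 1L)]] <- cn
    pos <- pos + category_sizes[[cn]]
  }
  sequence <- .random_sequences(n_proteins, seq_length_range)
  abundance_log2 <- stats::rnorm(n_proteins, mean_log2_abundance, sd_log2_abundance)
  k <- exp(stats::rnorm(n_proteins, k_meanlog, k_sdlog))
  mult <- category_k_multiplier[category]
  k <- k * ifelse(is.na(mult), 1, mult)
  k <- pmin(pmax(k, 1e-4), 9)
  lfc <- category_log2fc[category]
  true_log2fc <- ifelse(is.na(lfc), 0, lfc)
  proteins <- data.frame(
    protein_id = protein_id, sequence = sequence,
    abundance_log2 = abundance_log2, turnover_rate_k = k,
    functional_category = category,
    is_mitochondrial = category %in% c("OXPHOS", "TCA"),
    true_log2fc = as.numeric(true_log2fc),
    stringsAsFactors = FALSE
  )

  # phosphosites on existing S/T/Y residues
  ph <- list()
  cand <- sample(protein_id, round(frac_phospho * n_proteins))
  for (pid in cand) {
    s <- strsplit(sequence[match(pid, protein_id)], "", fixed = TRUE)[[1]]
    sty <- which(s %in% c("S", "T", "Y"))
    if (!length(sty)) next
    npos <- min(sample(1:2, 1), length(sty))
    at <- sort(sample(sty, npos))
    shifted <- stats::runif(npos) < frac_occ_shift
    sign <- sample(c(-1, 1), npos, replace = TRUE)
    occ_c <- ifelse(shifted, stats::runif(npos, 0.1, 0.45),
                    stats::runif(npos, 0.1, 0.9))
    occ_k <- ifelse(shifted, occ_c * 2^(sign * occ_shift_log2), occ_c)
    ph[[pid]] <- data.frame(
      protein_id = pid, position = at, residue = s[at],
      occ_control = occ_c, occ_kd = occ_k,
      true_log2_occ_ratio = log2(occ_k / occ_c),
      stringsAsFactors = FALSE
    )
  }
  phosphosites <- if (length(ph)) do.call(rbind, ph) else
    data.frame(protein_id = character(), position = integer(),
               residue = character(), occ_control = numeric(),
               occ_kd = numeric(), true_log2_occ_ratio = numeric())
  rownames(phosphosites) <- NULL

  params <- list(
    n_proteins = n_proteins, n_bio = n_bio, n_tech = n_tech, sigma = sigma,
    seed = seed, mean_log2_abundance = mean_log2_abundance,
    sd_log2_abundance = sd_log2_abundance,
    loc_conf_frac = loc_conf_frac, contam_rate = contam_rate,
    decoy_rate = decoy_rate, only_by_site_rate = only_by_site_rate,
    missingness = missingness, missing_max = missing_max,
    missing_mid = mean_log2_abundance + missing_mid_offset,
    missing_scale = missing_scale,
    peptide_length_range = peptide_length_range, max_missed = max_missed,
    max_peptides_per_protein = max_peptides_per_protein,
    timepoints = timepoints, n_bio_timecourse = n_bio_timecourse
  )
  structure(list(proteins = proteins, phosphosites = phosphosites,
                 params = params),
            class = "silaf_ground_truth")
}

#' @export
print.silaf_ground_truth <- function(x, ...) {
  cat(sprintf("silaf_ground_truth: %d proteins, %d phosphosites, n = %d x %d, sigma = %g, seed = %d\n",
              nrow(x$proteins), nrow(x$phosphosites), x$params$n_bio,
              x$params$n_tech, x$params$sigma, x$params$seed))
  invisible(x)
}

#' Derive annotation and gene sets from a ground truth
#'
#' Proteins in category "Other" are left unannotated so downstream code is
#' exercised on partially annotated data.
#'
#' @param ground_truth a `silaf_ground_truth` object.
#' @return `annotation_from_ground_truth()`: annotation data.frame as from
#'   [read_annotation()]; `gene_sets_from_ground_truth()`: gene-set list as
#'   from [read_gmt()].
#' @export
annotation_from_ground_truth <- function(ground_truth) {
  p <- ground_truth$proteins
  p <- p[p$functional_category != "Other", ]
  data.frame(protein_id = p$protein_id,
             functional_category = p$functional_category,
             is_mitochondrial = p$is_mitochondrial,
             stringsAsFactors = FALSE)
}

#' @rdname annotation_from_ground_truth
#' @export
gene_sets_from_ground_truth <- function(ground_truth) {
  p <- ground_truth$proteins
  cats <- setdiff(unique(p$functional_category), "Other")
  sets <- lapply(cats, function(cn)
    list(set_id = cn, description = paste("synthetic category", cn),
         members = p$protein_id[p$functional_category == cn]))
  names(sets) <- cats
  sets
}

# deterministic per-experiment peptide library: digest, detectability window,
# per-protein cap, per-peptide ionization yield
.peptide_library <- function(gt) {
  p <- gt$proteins
  win <- gt$params$peptide_length_range
  digs <- lapply(seq_len(nrow(p)), function(i) {
    d <- lysc_digest(p$sequence[i], gt$params$max_missed)
    d <- d[nchar(d$peptide) >= win[1] & nchar(d$peptide) <= win[2], , drop = FALSE]
    if (nrow(d) > gt$params$max_peptides_per_protein)
      d <- d[sort(sample.int(nrow(d), gt$params$max_peptides_per_protein)), ,
             drop = FALSE]
    if (nrow(d)) d$protein_id <- p$protein_id[i]
    d
  })
  lib <- do.call(rbind, digs[vapply(digs, nrow, 1L) > 0])
  rownames(lib) <- NULL
  lib$yield_log2 <- stats::rnorm(nrow(lib), 0, 1)
  lib$base_log2 <- p$abundance_log2[match(lib$protein_id, p$protein_id)] +
    lib$yield_log2
  lib$charge <- sample(2:4, nrow(lib), replace = TRUE, prob = c(0.6, 0.3, 0.1))
  lib
}

.mnar_mask <- function(log2_int, gt) {
  pm <- gt$params
  if (!pm$missingness) return(rep(FALSE, length(log2_int)))
  p <- pm$missing_max * stats::plogis(-(log2_int - pm$missing_mid) / pm$missing_scale)
  stats::runif(length(log2_int)) < p
}

.junk_rows <- function(prefix, ids, n_rows, gt, n_bio, n_tech) {
  if (n_rows == 0)
    return(NULL)
  pep <- vapply(sample(10:25, n_rows, replace = TRUE), function(L)
    paste(c(sample(setdiff(.AA20, "K"), L - 1, replace = TRUE), "K"),
          collapse = ""), "")
  b <- sample.int(n_bio, n_rows, replace = TRUE)
  tt <- sample.int(n_tech, n_rows, replace = TRUE)
  data.frame(
    peptide_sequence = pep,
    charge = sample(2:3, n_rows, replace = TRUE),
    intensity_heavy = 2^stats::rnorm(n_rows, 18, 2),
    intensity_light = 2^stats::rnorm(n_rows, 18, 2),
    protein_group_id = sample(ids, n_rows, replace = TRUE),
    raw_file = sprintf("run_b%dt%d", b, tt),
    fraction = 0L, replicate_bio = b, replicate_tech = tt,
    timepoint_days = NA_real_, modifications = "Unmodified",
    stringsAsFactors = FALSE
  )
}

#' Simulate a full synthetic SILAF experiment
#'
#' Generates evidence, protein-groups and (in comparison mode) phosphosite
#' tables exactly in the dialect the readers consume. In comparison mode the
#' per-peptide heavy/light ratio encodes the protein's true condition fold
#' change (`H/L = 2^true_log2fc` times noise) and phosphopeptide ratios are
#' additionally multiplied by the site's true occupancy ratio. In
#' time-course mode the heavy share of each peptide's intensity equals the
#' protein's first-order incorporation fraction at that timepoint.
#' Identical ground truth implies byte-identical output.
#'
#' @param ground_truth a `silaf_ground_truth` object.
#' @param mode `"comparison"` (two conditions mixed heavy/light) or
#'   `"timecourse"` (pulse labeling).
#' @param out_dir optional directory; when given, all tables plus the
#'   ground truth (JSON) are written there.
#' @return list of class `silaf_simulation` with elements `evidence`,
#'   `protein_groups`, `sites` (`NULL` in time-course mode),
#'   `ground_truth`, `mode`.
#' @export
simulate_experiment <- function(ground_truth,
                                mode = c("comparison", "timecourse"),
                                out_dir = NULL) {
  gt <- ground_truth
  stopifnot(inherits(gt, "silaf_ground_truth"))
  mode <- match.arg(mode)
  .validate_ground_truth(gt)
  set.seed(gt$params$seed)
  lib <- .peptide_library(gt)
  p <- gt$proteins
  sigma <- gt$params$sigma
  sd_ch <- sigma / sqrt(2)  # per-channel noise; ratio noise sd = sigma

  if (mode == "comparison") {
    n_bio <- gt$params$n_bio; n_tech <- gt$params$n_tech
    lfc <- p$true_log2fc[match(lib$protein_id, p$protein_id)]
    blocks <- list()
    for (b in seq_len(n_bio)) for (tt in seq_len(n_tech)) {
      epsH <- if (sigma > 0) stats::rnorm(nrow(lib), 0, sd_ch) else 0
      epsL <- if (sigma > 0) stats::rnorm(nrow(lib), 0, sd_ch) else 0
      log2H <- lib$base_log2 + lfc + epsH
      log2L <- lib$base_log2 + epsL
      H <- 2^log2H; L <- 2^log2L
      H[.mnar_mask(log2H, gt)] <- NA_real_
      L[.mnar_mask(log2L, gt)] <- NA_real_
      keep <- !(is.na(H) & is.na(L))
      blocks[[length(blocks) + 1L]] <- data.frame(
        peptide_sequence = lib$peptide[keep], charge = lib$charge[keep],
        intensity_heavy = H[keep], intensity_light = L[keep],
        protein_group_id = lib$protein_id[keep],
        raw_file = sprintf("run_b%dt%d", b, tt),
        fraction = 0L, replicate_bio = b, replicate_tech = tt,
        timepoint_days = NA_real_, modifications = "Unmodified",
        stringsAsFactors = FALSE
      )
    }
    evidence <- do.call(rbind, blocks)
  } else {
    n_bio <- gt$params$n_bio_timecourse; n_tech <- 1L
    kk <- p$turnover_rate_k[match(lib$protein_id, p$protein_id)]
    blocks <- list()
    for (tp in gt$params$timepoints) for (b in seq_len(n_bio)) {
      f <- incorporation_fraction(kk, tp)
      epsT <- if (sigma > 0) stats::rnorm(nrow(lib), 0, sigma) else 0
      epsH <- if (sigma > 0) stats::rnorm(nrow(lib), 0, sd_ch) else 0
      epsL <- if (sigma > 0) stats::rnorm(nrow(lib), 0, sd_ch) else 0
      total <- 2^(lib$base_log2 + epsT)
      H <- total * f * 2^epsH
      L <- total * (1 - f) * 2^epsL
      blocks[[length(blocks) + 1L]] <- data.frame(
        peptide_sequence = lib$peptide, charge = lib$charge,
        intensity_heavy = H, intensity_light = L,
        protein_group_id = lib$protein_id,
        raw_file = sprintf("run_t%02d_b%d", tp, b),
        fraction = 0L, replicate_bio = b, replicate_tech = 1L,
        timepoint_days = tp, modifications = "Unmodified",
        stringsAsFactors = FALSE
      )
    }
    evidence <- do.call(rbind, blocks)
  }
  rownames(evidence) <- NULL

  # contaminant / decoy / only-by-site injection
  n_real <- nrow(evidence)
  con_ids <- sprintf("CON__%d", 1:5)
  rev_ids <- sprintf("REV__%d", 1:3)
  ois_ids <- sprintf("OIS__%d", 1:2)
  junk <- rbind(
    .junk_rows("CON", con_ids, round(gt$params$contam_rate * n_real), gt, n_bio, n_tech),
    .junk_rows("REV", rev_ids, round(gt$params$decoy_rate * n_real), gt, n_bio, n_tech),
    .junk_rows("OIS", ois_ids, round(gt$params$only_by_site_rate * n_real), gt, n_bio, n_tech)
  )
  if (!is.null(junk) && mode == "timecourse") {
    junk$raw_file <- sprintf("run_t%02d_b%d", sample(gt$params$timepoints,
                                                     nrow(junk), replace = TRUE),
                             junk$replicate_bio)
    junk$timepoint_days <- as.numeric(sub("^run_t([0-9]+)_b.*$", "\\1", junk$raw_file))
  }
  evidence <- rbind(evidence, junk)
  rownames(evidence) <- NULL

  # protein-groups table
  sumH <- tapply(evidence$intensity_heavy, evidence$protein_group_id, sum, na.rm = TRUE)
  sumL <- tapply(evidence$intensity_light, evidence$protein_group_id, sum, na.rm = TRUE)
  all_ids <- c(p$protein_id, con_ids, rev_ids, ois_ids)
  protein_groups <- data.frame(
    protein_group_id = all_ids,
    ratio_hl_normalized = c(2^p$true_log2fc, rep(1, length(all_ids) - nrow(p))),
    intensity_heavy = as.numeric(sumH[all_ids]),
    intensity_light = as.numeric(sumL[all_ids]),
    flag_reverse = all_ids %in% rev_ids,
    flag_contaminant = all_ids %in% con_ids,
    flag_only_by_site = all_ids %in% ois_ids,
    stringsAsFactors = FALSE
  )
  protein_groups$member_protein_ids <- as.list(all_ids)
  rownames(protein_groups) <- NULL

  sites <- NULL
  if (mode == "comparison" && nrow(gt$phosphosites)) {
    ph <- gt$phosphosites
    ns <- nrow(ph)
    lfc_s <- p$true_log2fc[match(ph$protein_id, p$protein_id)]
    conf <- stats::runif(ns) < gt$params$loc_conf_frac
    loc <- ifelse(conf, 0.75 + 0.25 * stats::rbeta(ns, 2, 1),
                  0.75 * stats::rbeta(ns, 2, 2))
    site_int_log2 <- p$abundance_log2[match(ph$protein_id, p$protein_id)] - 2 +
      stats::rnorm(ns, 0, 1)
    sites <- data.frame(
      protein_group_id = ph$protein_id, position = ph$position,
      residue = ph$residue, localization_prob = loc,
      intensity_heavy = 2^(site_int_log2 + lfc_s + ph$true_log2_occ_ratio),
      intensity_light = 2^site_int_log2,
      stringsAsFactors = FALSE
    )
    for (b in seq_len(gt$params$n_bio)) for (tt in seq_len(gt$params$n_tech)) {
      eps <- if (sigma > 0) stats::rnorm(ns, 0, sigma) else 0
      r <- 2^(lfc_s + ph$true_log2_occ_ratio + eps)
      if (gt$params$missingness)
        r[.mnar_mask(site_int_log2, gt)] <- NA_real_
      sites[[paste0("ratio_hl.", replicate_label(b, tt))]] <- r
    }
    attr(sites, "ratio_labels") <-
      as.vector(t(outer(seq_len(gt$params$n_bio), seq_len(gt$params$n_tech),
                        replicate_label)))
  }

  sim <- structure(list(evidence = evidence, protein_groups = protein_groups,
                        sites = sites, ground_truth = gt, mode = mode),
                   class = "silaf_simulation")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_evidence(evidence, file.path(out_dir, "evidence.txt"))
    write_protein_groups(protein_groups, file.path(out_dir, "proteinGroups.txt"))
    if (!is.null(sites)) write_sites(sites, file.path(out_dir, "sites.txt"))
    write_ground_truth(gt, file.path(out_dir, "ground_truth.json"))
  }
  sim
}

.validate_ground_truth <- function(gt) {
  p <- gt$proteins
  if (!all(grepl("K", p$sequence, fixed = TRUE)))
    stop("validation error: protein sequence without lysine")
  if (nrow(gt$phosphosites)) {
    ph <- gt$phosphosites
    seqs <- p$sequence[match(ph$protein_id, p$protein_id)]
    at <- substring(seqs, ph$position, ph$position)
    if (!all(at == ph$residue & ph$residue %in% c("S", "T", "Y")))
      stop("validation error: phosphosite residue does not match sequence")
    if (!all(ph$occ_control > 0 & ph$occ_control < 1 &
               ph$occ_kd > 0 & ph$occ_kd < 1))
      stop("validation error: occupancies must lie in (0,1)")
  }
  invisible(TRUE)
}

#' Persist / load a ground truth as JSON
#'
#' @param ground_truth a `silaf_ground_truth` object.
#' @param path JSON file path.
#' @export
write_ground_truth <- function(ground_truth, path) {
  # 17 significant digits: doubles survive the text round-trip bit-exactly
  jsonlite::write_json(unclass(ground_truth), path, digits = I(17),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  x$params <- lapply(x$params, function(v) if (is.list(v)) unlist(v) else v)
  structure(x, class = "silaf_ground_truth")
}

#' Simulate a replicate matrix for differential testing
#'
#' Direct feature-level simulation used to study the calibration of the
#' moderated t-test: per-feature true variances are drawn from a scaled
#' inverse chi-squared distribution (the moderated model's own prior) and a
#' fraction of features receive a true log2 fold change of `+/- lfc`.
#'
#' @param n_features,n_reps matrix dimensions.
#' @param prop_de fraction of features with a true effect (half up, half
#'   down).
#' @param lfc magnitude of the true log2 fold change of affected features.
#' @param sigma prior scale: `s0_sq = sigma^2`.
#' @param d0_true prior degrees of freedom of the variance distribution.
#' @return list with `x` (matrix, features x replicates) and `true_log2fc`.
#' @export
simulate_feature_matrix <- function(n_features, n_reps, prop_de = 0, lfc = 1,
                                    sigma = 0.25, d0_true = 4) {
  s2 <- d0_true * sigma^2 / stats::rchisq(n_features, d0_true)
  true <- rep(0, n_features)
  n_de <- round(prop_de * n_features)
  if (n_de > 0) {
    de <- sample.int(n_features, n_de)
    true[de] <- lfc * rep_len(c(1, -1), n_de)
  }
  x <- matrix(stats::rnorm(n_features * n_reps, mean = true,
                           sd = sqrt(s2)), nrow = n_features)
  rownames(x) <- sprintf("F%05d", seq_len(n_features))
  list(x = x, true_log2fc = true)
}
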