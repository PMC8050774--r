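#' Exclude flagged protein groups
#'
#' Removes protein groups marked as reversed decoys, potential contaminants
#' or only identified by site. Counts of removed rows per flag (a doubly
#' flagged row counts under each of its flags) are attached as
#' `attr(, "removed")`.
#'
#' @param protein_groups data.frame as from [read_protein_groups()].
#' @return the clean subset, same columns.
#' @export
filter_protein_groups <- function(protein_groups) {
  pg <- protein_groups
  flagged <- pg$flag_reverse | pg$flag_contaminant | pg$flag_only_by_site
  out <- pg[!flagged, , drop = FALSE]
  attr(out, "removed") <- c(
    reverse = sum(pg$flag_reverse),
    contaminant = sum(pg$flag_contaminant),
    only_by_site = sum(pg$flag_only_by_site),
    total = sum(flagged)
  )
  out
}

#' Heavy-label incorporation rate
#'
#' `H / (H + L)` from not-normalized channel intensities. An absent channel
#' contributes 0 signal; if both channels are absent or zero the rate is
#' undefined and reported as `NA`, never as 0.
#'
#' @param intensity_heavy,intensity_light non-negative intensities
#'   (vectorized; `NA` = absent).
#' @return incorporation fraction in `[0, 1]`, or `NA`.
#' @export
incorporation_rate <- function(intensity_heavy, intensity_light) {
  if (any(intensity_heavy < 0, na.rm = TRUE) ||
        any(intensity_light < 0, na.rm = TRUE))
    stop("domain error: intensities must be non-negative")
  h <- ifelse(is.na(intensity_heavy), 0, intensity_heavy)
  l <- ifelse(is.na(intensity_light), 0, intensity_light)
  out <- ifelse(h + l > 0, h / (h + l), NA_real_)
  as.numeric(out)
}

#' Median-center log2 heavy/light ratios per run
#'
#' Shifts log2 ratios so that the within-run median is 0, reproducing the
#' default behaviour of upstream ratio normalization. The applied shift per
#' run is attached as `attr(, "shifts")`.
#'
#' @param log2_ratios numeric vector of log2 H/L ratios (`NA`/non-finite
#'   entries are passed through unchanged and ignored for the median).
#' @param run optional run identifier per element; `NULL` treats the whole
#'   vector as one run.
#' @return normalized log2 ratios, same length and order.
#' @export
normalize_ratios <- function(log2_ratios, run = NULL) {
  if (is.null(run)) run <- rep("all", length(log2_ratios))
  stopifnot(length(run) == length(log2_ratios))
  out <- log2_ratios
  shifts <- c()
  for (r in unique(run)) {
    i <- run == r
    v <- log2_ratios[i]
    fin <- v[is.finite(v)]
    if (!length(fin))
      stop("normalization error: no finite ratios in run '", r, "'")
    shift <- stats::median(fin)
    out[i] <- v - shift
    shifts[r] <- shift
  }
  attr(out, "shifts") <- shifts
  out
}

#' Compute and normalize peptide ratios on an evidence table
#'
#' Adds `log2_ratio` (log2 H/L, finite only where both channels are
#' positive; one-channel-only peptides get `NA` and are excluded from ratio
#' statistics but retained for incorporation and presence counts) and
#' `log2_ratio_norm` (median-centered per raw file).
#'
#' @param evidence evidence data.frame.
#' @return evidence with the two ratio columns; per-run shifts in
#'   `attr(, "shifts")`.
#' @export
add_normalized_ratios <- function(evidence) {
  h <- evidence$intensity_heavy
  l <- evidence$intensity_light
  r <- ifelse(!is.na(h) & !is.na(l) & h > 0 & l > 0, log2(h / l), NA_real_)
  evidence$log2_ratio <- r
  norm <- normalize_ratios(r, evidence$raw_file)
  evidence$log2_ratio_norm <- as.numeric(norm)
  attr(evidence, "shifts") <- attr(norm, "shifts")
  evidence
}

#' Protein-level log2 fold changes from peptide ratios
#'
#' Per protein and replicate, the protein log2 ratio is the median of its
#' peptides' normalized log2 ratios; technical replicates are then averaged
#' on the log2 scale and `mean_log2fc` is the mean over biological
#' replicates. Proteins without any usable ratio are dropped (ids in
#' `attr(, "dropped")`).
#'
#' @param evidence evidence table; `log2_ratio_norm` is computed via
#'   [add_normalized_ratios()] if absent.
#' @param min_peptides minimum number of distinct peptides with a finite
#'   ratio for a protein to be reported.
#' @return data.frame (`protein_quant`): `protein_group_id`,
#'   `mean_log2fc`, `n_peptide_ratios`, `n_bio_used` and one `log2fc_b<i>`
#'   column per biological replicate. The pre-averaging per-(bio, tech)
#'   protein ratios are attached as `attr(, "per_replicate")` for
#'   site-to-protein matching.
#' @export
protein_log2fc <- function(evidence, min_peptides = 1) {
  ev <- evidence
  if (is.null(ev$log2_ratio_norm)) ev <- add_normalized_ratios(ev)
  ok <- is.finite(ev$log2_ratio_norm)
  ev <- ev[ok, , drop = FALSE]
  if (!nrow(ev)) stop("no finite peptide ratios in evidence")

  key <- interaction(ev$protein_group_id, ev$replicate_bio, ev$replicate_tech,
                     drop = TRUE, sep = "\r")
  med <- tapply(ev$log2_ratio_norm, key, stats::median)
  parts <- do.call(rbind, strsplit(names(med), "\r", fixed = TRUE))
  per_rep <- data.frame(
    protein_group_id = parts[, 1],
    replicate_bio = as.integer(parts[, 2]),
    replicate_tech = as.integer(parts[, 3]),
    log2_ratio = as.numeric(med),
    stringsAsFactors = FALSE
  )

  # technical replicates averaged on log2 scale before biological statistics
  key_b <- interaction(per_rep$protein_group_id, per_rep$replicate_bio,
                       drop = TRUE, sep = "\r")
  bio <- tapply(per_rep$log2_ratio, key_b, mean)
  parts_b <- do.call(rbind, strsplit(names(bio), "\r", fixed = TRUE))
  bio_df <- data.frame(
    protein_group_id = parts_b[, 1],
    replicate_bio = as.integer(parts_b[, 2]),
    log2fc = as.numeric(bio),
    stringsAsFactors = FALSE
  )

  n_pep <- tapply(ev$peptide_sequence, ev$protein_group_id,
                  function(x) length(unique(x)))
  ids <- sort(unique(bio_df$protein_group_id))
  bios <- sort(unique(bio_df$replicate_bio))
  mat <- matrix(NA_real_, length(ids), length(bios),
                dimnames = list(ids, paste0("log2fc_b", bios)))
  mat[cbind(match(bio_df$protein_group_id, ids),
            match(bio_df$replicate_bio, bios))] <- bio_df$log2fc

  out <- data.frame(
    protein_group_id = ids,
    mean_log2fc = rowMeans(mat, na.rm = TRUE),
    n_peptide_ratios = as.integer(n_pep[ids]),
    n_bio_used = as.integer(rowSums(!is.na(mat))),
    stringsAsFactors = FALSE
  )
  out <- cbind(out, as.data.frame(mat))
  rownames(out) <- NULL

  keep <- out$n_peptide_ratios >= min_peptides
  dropped <- out$protein_group_id[!keep]
  out <- out[keep, , drop = FALSE]
  attr(out, "per_replicate") <- per_rep[per_rep$protein_group_id %in%
                                          out$protein_group_id, ]
  attr(out, "dropped") <- dropped
  out
}

#' Incorporation time course
#'
#' Per protein and timepoint, the incorporation fraction is
#' [incorporation_rate()] applied to the protein's summed (not normalized)
#' heavy and light peptide intensities. The per-protein values are the
#' pooled distribution used for density summaries; per-category medians are
#' computed when an annotation is supplied.
#'
#' @param evidence evidence table with `timepoint_days`.
#' @param annotation optional annotation data.frame
#'   ([read_annotation()]); proteins it does not cover are grouped as
#'   `"unannotated"`.
#' @return list of class `silaf_timecourse`: `per_protein` (protein x
#'   timepoint fractions), `per_timepoint` (n, median, quartiles),
#'   `per_category` (category medians/quartiles per timepoint, or `NULL`).
#' @export
incorporation_timecourse <- function(evidence, annotation = NULL) {
  ev <- evidence[!is.na(evidence$timepoint_days), , drop = FALSE]
  if (!nrow(ev)) {
    warning("no evidence with timepoints; empty time course")
    return(structure(list(per_protein = NULL, per_timepoint = NULL,
                          per_category = NULL), class = "silaf_timecourse"))
  }
  key <- interaction(ev$protein_group_id, ev$timepoint_days,
                     drop = TRUE, sep = "\r")
  sh <- tapply(ev$intensity_heavy, key, sum, na.rm = TRUE)
  sl <- tapply(ev$intensity_light, key, sum, na.rm = TRUE)
  parts <- do.call(rbind, strsplit(names(sh), "\r", fixed = TRUE))
  per_protein <- data.frame(
    protein_group_id = parts[, 1],
    timepoint_days = as.numeric(parts[, 2]),
    intensity_heavy = as.numeric(sh),
    intensity_light = as.numeric(sl),
    fraction = incorporation_rate(as.numeric(sh), as.numeric(sl)),
    stringsAsFactors = FALSE
  )
  per_protein <- per_protein[order(per_protein$protein_group_id,
                                   per_protein$timepoint_days), ]
  rownames(per_protein) <- NULL

  qs <- function(v) c(n = sum(is.finite(v)),
                      median = stats::median(v, na.rm = TRUE),
                      q25 = unname(stats::quantile(v, 0.25, na.rm = TRUE)),
                      q75 = unname(stats::quantile(v, 0.75, na.rm = TRUE)))
  tp_sum <- do.call(rbind, tapply(per_protein$fraction,
                                  per_protein$timepoint_days, qs))
  per_timepoint <- data.frame(timepoint_days = as.numeric(rownames(tp_sum)),
                              tp_sum, row.names = NULL)

  per_category <- NULL
  if (!is.null(annotation)) {
    cat <- annotation$functional_category[
      match(per_protein$protein_group_id, annotation$protein_id)]
    cat[is.na(cat)] <- "unannotated"
    keyc <- interaction(cat, per_protein$timepoint_days, drop = TRUE, sep = "\r")
    cs <- do.call(rbind, tapply(per_protein$fraction, keyc, qs))
    pc <- do.call(rbind, strsplit(rownames(cs), "\r", fixed = TRUE))
    per_category <- data.frame(functional_category = pc[, 1],
                               timepoint_days = as.numeric(pc[, 2]),
                               cs, row.names = NULL)
  }
  structure(list(per_protein = per_protein, per_timepoint = per_timepoint,
                 per_category = per_category), class = "silaf_timecourse")
}
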