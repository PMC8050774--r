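#' Filter phosphosites on localization probability
#'
#' Retains sites with localization probability strictly greater than the
#' threshold (default 0.75; a site at exactly 0.75 is removed). The number
#' of removed sites and the residue composition of the retained ones are
#' attached as attributes `removed` and `residue_counts`.
#'
#' @param sites site data.frame as from [read_sites()].
#' @param min_loc_prob strict lower threshold.
#' @return the filtered subset.
#' @export
filter_sites <- function(sites, min_loc_prob = 0.75) {
  keep <- sites$localization_prob > min_loc_prob
  out <- sites[keep, , drop = FALSE]
  attr(out, "ratio_labels") <- attr(sites, "ratio_labels")
  attr(out, "removed") <- sum(!keep)
  attr(out, "residue_counts") <- table(factor(out$residue, c("S", "T", "Y")))
  out
}

#' Protein-normalized occupancy change
#'
#' The log2 phosphosite occupancy change between conditions, after removing
#' the protein-abundance component: the difference between the site's log2
#' heavy/light ratio and its protein's log2 heavy/light ratio in the same
#' replicate. A site whose ratio equals its protein's ratio has occupancy
#' change 0 (pure abundance change).
#'
#' @param site_log2_ratio,protein_log2_ratio log2 H/L ratios (vectorized);
#'   `NA` in either yields `NA`.
#' @return log2 occupancy change.
#' @export
occupancy_change <- function(site_log2_ratio, protein_log2_ratio) {
  site_log2_ratio - protein_log2_ratio
}

#' Site-level occupancy quantification
#'
#' Matches each localization-filtered site to its protein's per-replicate
#' log2 ratio (by exact `protein_group_id`), computes the occupancy change
#' within each (biological, technical) replicate, averages technical
#' replicates on the log2 scale, and reports per-biological-replicate and
#' mean occupancy changes. Sites on proteins absent from the protein
#' quantification are kept in the output with `matched = FALSE` and no
#' occupancy values.
#'
#' @param sites filtered site data.frame ([filter_sites()]) with
#'   `ratio_hl.<label>` columns.
#' @param protein_quant protein quantification from [protein_log2fc()]
#'   (its `per_replicate` attribute provides the matching ratios).
#' @return data.frame with one row per site: `site_id`
#'   (`<protein>_<residue><position>`), identification fields,
#'   `occ_b<i>` per biological replicate, `mean_log2_occupancy_change`,
#'   `n_bio_used`, `matched`.
#' @export
site_occupancy <- function(sites, protein_quant) {
  labels <- attr(sites, "ratio_labels")
  if (is.null(labels))
    labels <- sub("^ratio_hl\\.", "",
                  grep("^ratio_hl\\.", names(sites), value = TRUE))
  if (!length(labels)) stop("sites table carries no per-replicate ratios")
  rep_info <- parse_replicate_label(labels)
  per_rep <- attr(protein_quant, "per_replicate")
  if (is.null(per_rep))
    stop("protein_quant lacks per-replicate ratios; use protein_log2fc()")

  ns <- nrow(sites)
  bios <- sort(unique(rep_info$replicate_bio))
  occ_bio <- matrix(NA_real_, ns, length(bios),
                    dimnames = list(NULL, paste0("occ_b", bios)))
  for (b in bios) {
    labs <- rep_info$label[rep_info$replicate_bio == b]
    occ_tech <- matrix(NA_real_, ns, length(labs))
    for (j in seq_along(labs)) {
      li <- rep_info[rep_info$label == labs[j], ]
      pr <- per_rep[per_rep$replicate_bio == li$replicate_bio &
                      per_rep$replicate_tech == li$replicate_tech, ]
      prot_log2 <- pr$log2_ratio[match(sites$protein_group_id,
                                       pr$protein_group_id)]
      occ_tech[, j] <- occupancy_change(
        log2(sites[[paste0("ratio_hl.", labs[j])]]), prot_log2)
    }
    occ_bio[, match(b, bios)] <- rowMeans(occ_tech, na.rm = TRUE)
  }
  occ_bio[is.nan(occ_bio)] <- NA_real_

  matched <- sites$protein_group_id %in% per_rep$protein_group_id
  out <- data.frame(
    site_id = sprintf("%s_%s%d", sites$protein_group_id, sites$residue,
                      sites$position),
    protein_group_id = sites$protein_group_id,
    position = sites$position,
    residue = sites$residue,
    localization_prob = sites$localization_prob,
    stringsAsFactors = FALSE
  )
  out <- cbind(out, as.data.frame(occ_bio))
  out$mean_log2_occupancy_change <- rowMeans(occ_bio, na.rm = TRUE)
  out$mean_log2_occupancy_change[!is.finite(out$mean_log2_occupancy_change)] <- NA_real_
  out$n_bio_used <- as.integer(rowSums(!is.na(occ_bio)))
  out$matched <- matched
  rownames(out) <- NULL
  out
}

#' Flag occupancy changes confounded by protein-level change
#'
#' A large protein fold change (e.g. a 20-fold knockdown) can skew the
#' apparent occupancy change of its sites; such sites are flagged — never
#' silently dropped — when the absolute protein log2 fold change strictly
#' exceeds the threshold.
#'
#' @param site_quant output of [site_occupancy()].
#' @param protein_quant output of [protein_log2fc()].
#' @param threshold absolute protein log2 fold change above which a site is
#'   flagged (strict inequality; default 2 = fourfold).
#' @return `site_quant` with columns `protein_log2fc` and `confounded`.
#' @export
flag_protein_confound <- function(site_quant, protein_quant, threshold = 2) {
  pl <- protein_quant$mean_log2fc[match(site_quant$protein_group_id,
                                        protein_quant$protein_group_id)]
  site_quant$protein_log2fc <- pl
  site_quant$confounded <- !is.na(pl) & abs(pl) > threshold
  site_quant
}
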