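## Overrepresentation analysis (one-sided hypergeometric) and rank-based
## gene-set enrichment over log2 fold changes. These substitute standard
## published statistics for the web service typically used for such
## analyses; identifiers must already be in the same ID space as the
## results (no ortholog or accession mapping is performed).

.as_gene_sets <- function(sets) {
  if (!length(sets)) stop("empty gene-set collection")
  if (is.list(sets[[1]]) && !is.null(sets[[1]]$members)) return(sets)
  # plain named list of member vectors
  out <- lapply(names(sets), function(nm)
    list(set_id = nm, description = "", members = unique(sets[[nm]])))
  names(out) <- names(sets)
  out
}

#' Overrepresentation analysis (hypergeometric)
#'
#' One-sided upper-tail hypergeometric test of each gene set's overlap with
#' a foreground list against a background universe. Sets are intersected
#' with the background before testing; sets with fewer than `min_overlap`
#' foreground hits are reported untested. Adjustment across sets is
#' Benjamini-Hochberg via [bh_adjust()].
#'
#' @param foreground character vector of hit identifiers (subset of
#'   `background`).
#' @param background character vector, the tested universe.
#' @param sets gene sets as from [read_gmt()] (or a named list of member
#'   vectors).
#' @param min_overlap minimum number of foreground hits for a set to be
#'   tested (default 3).
#' @return data.frame: `set_id`, `n_set` (set size within background),
#'   `n_hits`, `fold_enrichment`, `p`, `p_adj`, `tested`.
#' @export
ora <- function(foreground, background, sets, min_overlap = 3) {
  foreground <- unique(foreground); background <- unique(background)
  if (!length(foreground)) stop("empty foreground")
  if (!length(background)) stop("empty background")
  if (!all(foreground %in% background))
    stop("foreground must be a subset of background")
  sets <- .as_gene_sets(sets)
  N <- length(background); nf <- length(foreground)
  rows <- lapply(sets, function(s) {
    mem <- intersect(s$members, background)
    hits <- length(intersect(mem, foreground))
    m <- length(mem)
    tested <- hits >= min_overlap && m > 0
    p <- if (tested)
      stats::phyper(hits - 1, m, N - m, nf, lower.tail = FALSE) else NA_real_
    data.frame(set_id = s$set_id, n_set = m, n_hits = hits,
               fold_enrichment = if (m > 0) (hits / nf) / (m / N) else NA_real_,
               p = p, tested = tested, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_adj <- bh_adjust(out$p)
  out[, c("set_id", "n_set", "n_hits", "fold_enrichment", "p", "p_adj",
          "tested")]
}

# Weighted running-sum enrichment score. Hit increments are proportional to
# |score|^weight, miss decrements to 1/(N - k); the extrema can only occur
# at hit positions (just before or at a hit), so only those are evaluated.
.gsea_es <- function(hit_pos, weights_at_hits, N) {
  k <- length(hit_pos)
  if (k == 0 || k >= N) return(NA_real_)
  o <- order(hit_pos)
  pos <- hit_pos[o]
  w <- weights_at_hits[o]
  W <- sum(w)
  w <- if (W > 0) w / W else rep(1 / k, k)  # all-zero weights: unweighted
  cw <- cumsum(w)
  i <- seq_len(k)
  at <- cw - (pos - i) / (N - k)
  before <- c(0, cw[-k]) - (pos - i) / (N - k)
  cand <- c(at, before, 0)
  es <- cand[which.max(abs(cand))]
  es
}

#' Gene-set enrichment analysis (permutation GSEA)
#'
#' Weighted Kolmogorov-Smirnov-like running-sum statistic over a ranked
#' list of log2 fold changes (hit weight `|score|^weight`, default weight
#' 1; weight 0 recovers the classic unweighted statistic). Significance is
#' assessed by gene-label permutation: for each set, `n_perm` random
#' same-size gene sets are drawn and the p-value is the fraction of
#' same-signed permutation scores at least as extreme (floor
#' `1/(n_perm + 1)`). The normalized score divides by the mean magnitude of
#' same-signed permutation scores. BH adjustment across tested sets.
#'
#' @param ids character vector of unique feature identifiers.
#' @param scores numeric ranking metric (mean log2 fold changes), parallel
#'   to `ids`.
#' @param sets gene sets ([read_gmt()] or named list of member vectors).
#' @param n_perm number of permutations (>= 100).
#' @param weight exponent on `|score|` for hit increments.
#' @param min_size minimum set size after intersection with `ids`; smaller
#'   sets are reported untested.
#' @param seed optional RNG seed for the permutations.
#' @return data.frame: `set_id`, `n_set`, `es`, `nes`, `p`, `p_adj`,
#'   `direction` (`up`/`down` by ES sign), `leading_edge`
#'   (";"-collapsed members), `tested`.
#' @export
gsea <- function(ids, scores, sets, n_perm = 1000, weight = 1, min_size = 5,
                 seed = NULL) {
  if (anyDuplicated(ids))
    stop("duplicate ids in ranking: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  stopifnot(length(ids) == length(scores))
  if (n_perm < 100) stop("n_perm must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  o <- order(scores, decreasing = TRUE)
  ids_sorted <- ids[o]
  w_all <- abs(scores[o])^weight
  N <- length(ids_sorted)
  sets <- .as_gene_sets(sets)

  rows <- lapply(sets, function(s) {
    pos <- which(ids_sorted %in% s$members)
    k <- length(pos)
    if (k < min_size || k >= N)
      return(data.frame(set_id = s$set_id, n_set = k, es = NA_real_,
                        nes = NA_real_, p = NA_real_, direction = NA_character_,
                        leading_edge = NA_character_, tested = FALSE,
                        stringsAsFactors = FALSE))
    es <- .gsea_es(pos, w_all[pos], N)
    perm <- vapply(seq_len(n_perm), function(b) {
      idx <- sample.int(N, k)
      .gsea_es(idx, w_all[idx], N)
    }, 0)
    # p conditional on the ES sign, against same-signed permutations
    same <- if (es >= 0) perm[perm >= 0] else perm[perm < 0]
    p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
    nes <- if (length(same)) es / mean(abs(same)) else NA_real_
    # leading edge: members up to the running-sum extremum
    cw <- cumsum(w_all[pos] / max(sum(w_all[pos]), .Machine$double.eps))
    i <- seq_len(k)
    dev_at <- cw - (pos - i) / (N - k)
    le <- if (es >= 0) ids_sorted[pos[seq_len(which.max(dev_at))]] else
      ids_sorted[pos[which.min(dev_at):k]]
    data.frame(set_id = s$set_id, n_set = k, es = es, nes = nes, p = p,
               direction = if (es >= 0) "up" else "down",
               leading_edge = paste(le, collapse = ";"), tested = TRUE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_adj <- bh_adjust(out$p)
  out[, c("set_id", "n_set", "es", "nes", "p", "p_adj", "direction",
          "leading_edge", "tested")]
}

#' Per-category distribution summary with median-shift tests
#'
#' Boxplot-style summary (median, quartile box, +/- 1.5 IQR whiskers
#' clipped to the data) of a per-protein quantity by functional category,
#' with a Wilcoxon rank-sum test of each category against all other
#' proteins and BH adjustment across categories.
#'
#' @param values data.frame with `protein_id` (or `protein_group_id`) and
#'   `value`, or a named numeric vector.
#' @param annotation annotation data.frame ([read_annotation()]);
#'   unannotated proteins contribute only to the comparison background.
#' @param min_size categories with fewer members are summarised but not
#'   tested.
#' @return data.frame: `functional_category`, `n`, `median`, `q25`, `q75`,
#'   `whisker_low`, `whisker_high`, `p`, `p_adj`, `significant` (at
#'   adjusted p < 0.05).
#' @export
category_boxplot_summary <- function(values, annotation, min_size = 3) {
  if (is.numeric(values))
    values <- data.frame(protein_id = names(values), value = unname(values),
                         stringsAsFactors = FALSE)
  id_col <- if ("protein_id" %in% names(values)) "protein_id" else
    "protein_group_id"
  cat <- annotation$functional_category[match(values[[id_col]],
                                              annotation$protein_id)]
  v <- values$value
  cats <- sort(unique(cat[!is.na(cat)]))
  rows <- lapply(cats, function(cn) {
    vc <- v[!is.na(cat) & cat == cn]
    vo <- v[is.na(cat) | cat != cn]
    q <- stats::quantile(vc, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE)
    iqr <- q[3] - q[1]
    wl <- min(vc[vc >= q[1] - 1.5 * iqr], na.rm = TRUE)
    wh <- max(vc[vc <= q[3] + 1.5 * iqr], na.rm = TRUE)
    p <- if (length(vc) >= min_size && length(vo))
      suppressWarnings(stats::wilcox.test(vc, vo)$p.value) else NA_real_
    data.frame(functional_category = cn, n = length(vc), median = q[2],
               q25 = q[1], q75 = q[3], whisker_low = wl, whisker_high = wh,
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_adj <- bh_adjust(out$p)
  out$significant <- !is.na(out$p_adj) & out$p_adj < 0.05
  out
}
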