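#' Fit first-order incorporation kinetics
#'
#' Least-squares fit of `f(t) = 1 - exp(-k t)` to a protein's incorporation
#' time course by bounded scalar optimization over
#' `k in (k_range[1], k_range[2]]`. The fit is flagged non-converged when
#' the estimate hits a bound or the residual sum of squares exceeds
#' `rss_threshold`.
#'
#' @param t_days timepoints in days (>= 3 distinct values required).
#' @param fraction incorporation fractions in `[0, 1]` (`NA` dropped).
#' @param k_range search interval for `k` (per day).
#' @param rss_threshold residual sum of squares above which the fit is
#'   declared non-converged.
#' @return one-row data.frame: `k_hat`, `half_life` (`log(2)/k_hat`),
#'   `rss`, `n_timepoints`, `converged`.
#' @export
fit_turnover <- function(t_days, fraction, k_range = c(1e-6, 10),
                         rss_threshold = Inf) {
  ok <- !is.na(t_days) & !is.na(fraction)
  t_days <- t_days[ok]; fraction <- fraction[ok]
  if (length(unique(t_days)) < 3)
    stop("fit_turnover requires >= 3 distinct timepoints")
  if (any(fraction < 0 | fraction > 1))
    stop("fractions must lie in [0, 1]")
  rss_fun <- function(k) sum((fraction - (1 - exp(-k * t_days)))^2)
  opt <- stats::optimize(rss_fun, interval = k_range, tol = 1e-10)
  k_hat <- opt$minimum
  rss <- opt$objective
  at_bound <- k_hat <= k_range[1] * 1.01 || k_hat >= k_range[2] * 0.999
  converged <- !at_bound && rss <= rss_threshold
  data.frame(k_hat = k_hat, half_life = log(2) / k_hat, rss = rss,
             n_timepoints = length(unique(t_days)), converged = converged)
}

#' Fit turnover rates for all proteins of a time course
#'
#' @param timecourse a `silaf_timecourse` object
#'   ([incorporation_timecourse()]) or its `per_protein` data.frame.
#' @inheritParams fit_turnover
#' @return data.frame with one row per protein (`protein_id`, `k_hat`,
#'   `half_life`, `rss`, `n_timepoints`, `converged`); proteins with fewer
#'   than 3 usable timepoints are omitted.
#' @export
fit_turnover_table <- function(timecourse, k_range = c(1e-6, 10),
                               rss_threshold = Inf) {
  pp <- if (inherits(timecourse, "silaf_timecourse"))
    timecourse$per_protein else timecourse
  fits <- lapply(split(pp, pp$protein_group_id), function(d) {
    d <- d[is.finite(d$fraction), , drop = FALSE]
    if (length(unique(d$timepoint_days)) < 3) return(NULL)
    cbind(protein_id = d$protein_group_id[1],
          fit_turnover(d$timepoint_days, d$fraction, k_range, rss_threshold),
          stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, fits[!vapply(fits, is.null, TRUE)])
  rownames(out) <- NULL
  out
}

#' Labeling quartile bins
#'
#' Partitions proteins into the four fixed labeling-percentage bins
#' `[0-25]`, `(25-50]`, `(50-75]`, `(75-100]` of their incorporation
#' fraction (used to select foregrounds for overrepresentation analysis).
#'
#' @param fraction incorporation fractions in `[0, 1]`.
#' @return factor with the four bin labels.
#' @export
labeling_quartile <- function(fraction) {
  if (any(fraction < 0 | fraction > 1, na.rm = TRUE))
    stop("fractions must lie in [0, 1]")
  cut(100 * fraction, breaks = c(0, 25, 50, 75, 100),
      labels = c("[0-25]", "(25-50]", "(50-75]", "(75-100]"),
      include.lowest = TRUE, right = TRUE)
}

#' Per-category labeling summary
#'
#' Median and quartiles of incorporation fractions per functional category,
#' plus the labeling-quartile bin of every protein (for quartile-wise
#' overrepresentation analysis at the final timepoint). Proteins without
#' annotation are grouped as `"unannotated"`.
#'
#' @param fractions data.frame with `protein_group_id` (or `protein_id`)
#'   and `fraction`, e.g. the final-timepoint slice of
#'   [incorporation_timecourse()]'s `per_protein`.
#' @param annotation annotation data.frame ([read_annotation()]).
#' @return list: `summary` (per-category n/median/q25/q75) and `proteins`
#'   (per-protein category and quartile bin).
#' @export
category_labeling_summary <- function(fractions, annotation) {
  id_col <- if ("protein_group_id" %in% names(fractions))
    "protein_group_id" else "protein_id"
  cat <- annotation$functional_category[
    match(fractions[[id_col]], annotation$protein_id)]
  cat[is.na(cat)] <- "unannotated"
  proteins <- data.frame(
    protein_id = fractions[[id_col]],
    fraction = fractions$fraction,
    functional_category = cat,
    labeling_quartile = labeling_quartile(fractions$fraction),
    stringsAsFactors = FALSE
  )
  s <- lapply(split(proteins$fraction, proteins$functional_category),
              function(v) data.frame(
                n = sum(is.finite(v)),
                median = stats::median(v, na.rm = TRUE),
                q25 = unname(stats::quantile(v, 0.25, na.rm = TRUE)),
                q75 = unname(stats::quantile(v, 0.75, na.rm = TRUE))))
  summary <- cbind(functional_category = names(s), do.call(rbind, s))
  rownames(summary) <- NULL
  list(summary = summary, proteins = proteins)
}
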