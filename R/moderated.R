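## Empirical-Bayes moderated one-sample t-test and Benjamini-Hochberg FDR,
## implemented here (not delegated) so the pipeline is self-contained. The
## variance prior is a scaled inverse chi-squared with hyperparameters
## (d0, s0_sq) estimated by method of moments on log sample variances,
## using closed-form digamma/trigamma inversion.

# Newton inversion of the trigamma function: solve trigamma(y) = x, x > 0.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (abs(dif) / y < 1e-10) break
  }
  y
}

#' Estimate the variance prior across features
#'
#' Method-of-moments fit of the scaled inverse chi-squared prior
#' `s2 ~ s0_sq * d0 / chisq(d0)` to per-feature sample variances with known
#' residual degrees of freedom, on the log scale: the excess dispersion of
#' `log(s2)` beyond `trigamma(d/2)` determines `d0` through trigamma
#' inversion, and the location determines `s0_sq`. When the observed
#' dispersion does not exceed the sampling dispersion the prior is
#' degenerate and `d0 = Inf` is returned with a warning (all posterior
#' variances shrink completely to `s0_sq`).
#'
#' @param s2 per-feature sample variances (> 0; zeros are excluded from
#'   estimation).
#' @param df residual degrees of freedom per feature (recycled).
#' @return list with `d0` and `s0_sq`.
#' @export
estimate_variance_prior <- function(s2, df) {
  df <- rep_len(df, length(s2))
  ok <- is.finite(s2) & s2 > 0 & df > 0
  if (sum(ok) < 2)
    stop("cannot estimate variance prior: fewer than two features with positive variance; add a measurement noise floor")
  s2 <- s2[ok]; df <- df[ok]
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- sum((e - emean)^2) / (n - 1)
  target <- evar - mean(trigamma(df / 2))
  if (target > 0) {
    d0 <- 2 * trigamma_inverse(target)
    s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    warning("log-variance moment equation has no finite root; using complete shrinkage (d0 = Inf)")
    d0 <- Inf
    s0_sq <- exp(emean)
  }
  list(d0 = d0, s0_sq = s0_sq)
}

#' Empirical-Bayes moderated one-sample t-test
#'
#' Tests, per feature, whether the mean log2 ratio differs from 0 (the
#' two-channel mixing design makes each replicate self-paired). Per-feature
#' variances are shrunk toward the prior `s0_sq` estimated across features:
#' `s2_post = (d0 * s0_sq + d * s2) / (d0 + d)` with `d = n - 1`, the
#' moderated statistic is `mean / sqrt(s2_post / n)` and two-sided p-values
#' use `d0 + d` degrees of freedom. `d0 = 0` reproduces the ordinary
#' one-sample t-test; `d0 = Inf` gives complete shrinkage to `s0_sq` and a
#' z-test.
#'
#' @param x numeric matrix, features x replicates (`NA` allowed); row names
#'   are feature ids.
#' @param d0,s0_sq optional fixed hyperparameters; by default both are
#'   estimated from the data via [estimate_variance_prior()].
#' @param min_reps minimum number of finite replicate values for a feature
#'   to be tested; features below it are reported untested (`NA`
#'   statistics).
#' @return data.frame (`ModeratedResult`): `feature_id`, `n`,
#'   `mean_log2fc`, `s2`, `s2_post`, `t_mod`, `p`, `p_adj`, `tested`;
#'   hyperparameters in `attr(, "d0")` / `attr(, "s0_sq")`.
#' @export
moderated_t_test <- function(x, d0 = NULL, s0_sq = NULL, min_reps = 2) {
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- sprintf("feature_%d", seq_len(nrow(x)))
  n <- rowSums(is.finite(x))
  means <- rowMeans(x, na.rm = TRUE)
  s2 <- apply(x, 1, function(v) stats::var(v[is.finite(v)]))
  tested <- n >= max(2, min_reps)
  if (!any(tested)) stop("no feature has enough replicates to test")
  if (all(s2[tested] == 0, na.rm = TRUE))
    stop("all features have zero variance; add a measurement noise floor")
  d <- n - 1

  if (is.null(d0) || is.null(s0_sq)) {
    prior <- estimate_variance_prior(s2[tested], d[tested])
    if (is.null(d0)) d0 <- prior$d0
    if (is.null(s0_sq)) s0_sq <- prior$s0_sq
  }
  if (d0 < 0) stop("d0 must be >= 0")

  s2_post <- if (is.infinite(d0)) rep(s0_sq, length(s2)) else
    (d0 * s0_sq + d * s2) / (d0 + d)
  t_mod <- means / sqrt(s2_post / n)
  df_tot <- d0 + d
  p <- 2 * stats::pt(-abs(t_mod), df = df_tot)

  out <- data.frame(
    feature_id = rownames(x), n = as.integer(n), mean_log2fc = means,
    s2 = s2, s2_post = s2_post, t_mod = t_mod, p = p,
    stringsAsFactors = FALSE
  )
  out[!tested, c("mean_log2fc", "s2", "s2_post", "t_mod", "p")] <- NA_real_
  out$p_adj <- NA_real_
  out$p_adj[tested] <- bh_adjust(out$p[tested])
  out$tested <- tested
  rownames(out) <- NULL
  attr(out, "d0") <- d0
  attr(out, "s0_sq") <- s0_sq
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up procedure controlling the false discovery rate: order the m
#' p-values increasingly, multiply `p_(i)` by `m / i`, and enforce
#' monotonicity by a cumulative minimum from the largest down; results are
#' returned in the input order and capped at 1.
#'
#' @param p p-values in `(0, 1]` (`NA` allowed; `NA`s are returned as such
#'   and do not count toward m).
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  bad <- which(!is.na(p) & (p <= 0 | p > 1))
  if (length(bad))
    stop("domain error: p-value outside (0, 1] at index ", bad[1])
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (m == 0) return(out)
  pv <- p[ok]
  o <- order(pv, decreasing = TRUE)
  ro <- order(o)
  out[ok] <- pmin(1, cummin(m / (m:1) * pv[o]))[ro]
  out
}

#' Significance calls at an adjusted-p threshold
#'
#' Adds a significance call and direction (by sign of the mean log2 fold
#' change) to a moderated-test result, and attaches the up/down counts as
#' `attr(, "counts")` (volcano-plot annotation numbers).
#'
#' @param results data.frame with `p_adj` and `mean_log2fc` (e.g. from
#'   [moderated_t_test()]).
#' @param p_adj_threshold adjusted-p cutoff (default 0.01, the proteome
#'   convention; phosphosite occupancies conventionally use 0.05).
#' @return `results` with columns `significant` and `direction`.
#' @export
significance_tables <- function(results, p_adj_threshold = 0.01) {
  sig <- !is.na(results$p_adj) & results$p_adj < p_adj_threshold
  dir <- ifelse(is.na(results$mean_log2fc) | results$mean_log2fc == 0, "none",
                ifelse(results$mean_log2fc > 0, "up", "down"))
  results$significant <- sig
  results$direction <- dir
  attr(results, "counts") <- c(up = sum(sig & dir == "up"),
                               down = sum(sig & dir == "down"),
                               not_significant = sum(!sig))
  attr(results, "p_adj_threshold") <- p_adj_threshold
  results
}
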