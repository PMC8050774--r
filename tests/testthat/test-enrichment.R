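# direct hypergeometric tail by enumeration, independent of the implementation
ora_oracle <- function(hits, m, N, nf) {
  j <- hits:min(m, nf)
  sum(choose(m, j) * choose(N - m, nf - j)) / choose(N, nf)
}

test_that("ORA p-values equal exact tail enumeration", {
  # background 20, set 4, foreground 5 with 3 hits:
  # [C(4,3)C(16,2) + C(4,4)C(16,1)] / C(20,5) = 496/15504
  bg <- sprintf("g%02d", 1:20)
  fg <- c("g01", "g02", "g03", "g10", "g11")
  sets <- list(S = list(set_id = "S", description = "",
                        members = c("g01", "g02", "g03", "g04")))
  res <- ora(fg, bg, sets)
  expect_equal(res$n_hits, 3)
  expect_equal(res$p, 496 / 15504, tolerance = 1e-12)
  expect_equal(res$p, 0.031992, tolerance = 1e-4)

  # randomized instances vs the enumeration oracle
  set.seed(51)
  for (i in 1:40) {
    N <- sample(8:25, 1)
    bg <- sprintf("x%02d", 1:N)
    fg <- sample(bg, sample(2:(N - 2), 1))
    mem <- sample(bg, sample(2:N, 1))
    res <- ora(fg, bg, list(A = mem), min_overlap = 0)
    expect_equal(res$p,
                 ora_oracle(res$n_hits, res$n_set, N, length(fg)),
                 tolerance = 1e-12)
  }
})

test_that("ORA degenerate cases follow the contracts", {
  bg <- sprintf("g%d", 1:12)
  # set disjoint from foreground at min_overlap = 0: p = P(X >= 0) = 1
  res <- ora(bg[1:3], bg, list(D = bg[10:12]), min_overlap = 0)
  expect_equal(res$p, 1)
  # foreground = background: every tested set has p = 1
  res2 <- ora(bg, bg, list(A = bg[1:5], B = bg[3:11]), min_overlap = 0)
  expect_true(all(res2$p == 1))
  # too-small overlap is untested, not dropped
  res3 <- ora(bg[1:3], bg, list(D = bg[10:12]), min_overlap = 3)
  expect_false(res3$tested)
  expect_true(is.na(res3$p))
  expect_error(ora(character(), bg, list(A = bg[1:3])), "empty")
  expect_error(ora(c("zz"), bg, list(A = bg[1:3])), "subset")
})

# unweighted running-sum statistic computed the long way (full N-vector walk)
ks_oracle <- function(in_set_sorted) {
  k <- sum(in_set_sorted); N <- length(in_set_sorted)
  step <- ifelse(in_set_sorted, 1 / k, -1 / (N - k))
  rs <- cumsum(step)
  rs[which.max(abs(rs))]
}

test_that("GSEA enrichment score matches a direct unweighted computation at w = 0", {
  set.seed(52)
  for (i in 1:10) {
    N <- 60
    ids <- sprintf("g%02d", 1:N)
    scores <- sort(rnorm(N), decreasing = TRUE)
    mem <- sample(ids, 12)
    res <- gsea(ids, scores, list(A = mem), n_perm = 100, weight = 0, seed = 1)
    expect_equal(res$es, ks_oracle(ids %in% mem), tolerance = 1e-12)
  }
})

test_that("GSEA ES is invariant to monotone rescaling when w = 0", {
  set.seed(53)
  ids <- sprintf("g%02d", 1:50)
  scores <- rnorm(50)
  mem <- sample(ids, 10)
  a <- gsea(ids, scores, list(A = mem), n_perm = 100, weight = 0, seed = 7)
  b <- gsea(ids, scores * 3 + sign(scores) * 0.1, list(A = mem),
            n_perm = 100, weight = 0, seed = 7)
  expect_equal(a$es, b$es)
})

test_that("a set of exactly the top-ranked genes is maximally enriched", {
  set.seed(54)
  N <- 40
  ids <- sprintf("g%02d", 1:N)
  scores <- sort(abs(rnorm(N)) + 0.1, decreasing = TRUE)
  top <- ids[1:5]
  res_top <- gsea(ids, scores, list(TOP = top), n_perm = 100, seed = 2)
  expect_gt(res_top$es, 0)
  for (i in 1:30) {
    mem <- sample(ids, 5)
    res <- gsea(ids, scores, list(R = mem), n_perm = 100, seed = 2)
    expect_lte(res$es, res_top$es + 1e-12)
  }
})

test_that("GSEA agrees with the reference implementation on enrichment scores", {
  set.seed(55)
  N <- 120
  ids <- sprintf("g%03d", 1:N)
  scores <- rnorm(N)
  sets <- list(A = sample(ids, 15), B = sample(ids, 25), C = ids[order(scores)][1:20])
  mine <- gsea(ids, scores, sets, n_perm = 200, weight = 1, seed = 3)
  sorted <- sort(scores, decreasing = TRUE)
  names(sorted) <- ids[order(scores, decreasing = TRUE)]
  for (nm in names(sets)) {
    ref <- fgsea::calcGseaStat(sorted,
                               selectedStats = which(names(sorted) %in% sets[[nm]]),
                               gseaParam = 1)
    expect_equal(mine$es[mine$set_id == nm], ref, tolerance = 1e-10)
  }
})

test_that("GSEA contracts: duplicates rejected, permutation p floored", {
  ids <- sprintf("g%d", 1:30)
  expect_error(gsea(c(ids, "g1"), rnorm(31), list(A = ids[1:6]), n_perm = 100),
               "duplicate")
  expect_error(gsea(ids, rnorm(30), list(A = ids[1:6]), n_perm = 10), "100")
  res <- gsea(ids, sort(rnorm(30), decreasing = TRUE), list(A = ids[1:8]),
              n_perm = 100, seed = 4)
  expect_gte(res$p, 1 / 101)
  expect_lte(res$p, 1)
  # small sets untested
  res2 <- gsea(ids, rnorm(30), list(A = ids[1:2]), n_perm = 100, min_size = 5)
  expect_false(res2$tested)
})

test_that("category summaries compute boxplot statistics definitionally", {
  vals <- data.frame(protein_id = sprintf("P%d", 1:10),
                     value = c(1, 2, 3, 4, 5, 0.1, 0.2, 0.15, 0.05, 0.12))
  an <- data.frame(protein_id = sprintf("P%d", 1:5),
                   functional_category = "A", is_mitochondrial = FALSE)
  out <- category_boxplot_summary(vals, an)
  expect_equal(out$median, 3)
  expect_equal(out$q25, 2)
  expect_equal(out$q75, 4)
  expect_equal(out$whisker_low, 1)    # clipped to data within 1.5 IQR
  expect_equal(out$whisker_high, 5)
  expect_equal(out$n, 5)
  expect_true(!is.na(out$p))
})
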