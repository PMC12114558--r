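test_that("Spearman correlations are rank-invariant with t-approximation p-values", {
  X <- cbind(a = c(1, 2, 3, 4, 5), b = c(5, 4, 3, 2, 1))
  res <- correlation_matrix(X)
  expect_equal(res$r, -1)
  expect_equal(res$p, 0)
  # monotone nonlinear transform leaves rho at 1
  X2 <- cbind(x = 1:8, y = exp(1:8))
  expect_equal(correlation_matrix(X2)$r, 1)
  # tie-containing fixture matches the rank-then-Pearson oracle to 1e-12
  set.seed(15)
  x <- c(1, 2, 2, 3, 4, 5, 6, 7, 8, 9)
  y <- rnorm(10)
  res3 <- correlation_matrix(cbind(x = x, y = y))
  orc <- oracle_spearman(x, y)
  expect_equal(res3$r, orc$r, tolerance = 1e-12)
  expect_equal(res3$p, orc$p, tolerance = 1e-12)
})

test_that("correlation matrices are symmetric, unit-diagonal, and flag constants", {
  set.seed(16)
  X <- matrix(rnorm(50), 10, 5, dimnames = list(NULL, letters[1:5]))
  res <- correlation_matrix(X)
  r <- attr(res, "r_matrix")
  expect_equal(r, t(r))
  expect_equal(unname(diag(r)), rep(1, 5))
  expect_true(all(abs(res$r) <= 1))
  expect_true(all(res$p >= 0 & res$p <= 1))
  Xc <- cbind(X, konst = 1)
  expect_warning(resc <- correlation_matrix(Xc), "konst")
  expect_true(all(is.na(resc$r[resc$var2 == "konst"])))
  # BH adjustment never lowers a p-value
  res_bh <- suppressWarnings(correlation_matrix(X, adjust_bh = TRUE))
  expect_true(all(res_bh$p >= res$p - 1e-15))
})

test_that("Mantel statistic is exact under affine identity and enumerable at n = 5", {
  set.seed(17)
  pts <- matrix(rnorm(10), 5, 2)
  d1 <- dist(pts)
  m <- mantel_test(d1, 2 * d1, n_perm = 99, seed = 1)
  expect_equal(m$r, 1)
  expect_equal(m$p, 1 / 100)
  # exhaustive enumeration equals the independent full-permutation oracle
  d2 <- dist(matrix(rnorm(10), 5, 2))
  me <- mantel_test(d1, d2, exhaustive = TRUE)
  orc <- oracle_mantel_exhaustive(as.matrix(d1), as.matrix(d2))
  expect_equal(me$r, orc$r, tolerance = 1e-12)
  expect_equal(me$p, orc$p, tolerance = 1e-12)
  expect_equal(me$n_perm, factorial(5) - 1)
  # agreement with the reference implementation on the statistic
  mv <- vegan::mantel(d1, d2, method = "spearman", permutations = 99)
  expect_equal(mantel_test(d1, d2, n_perm = 99)$r, mv$statistic,
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("Mantel matches labels and rejects disjoint sample sets", {
  m1 <- as.matrix(dist(matrix(rnorm(8), 4, 2)))
  dimnames(m1) <- list(letters[1:4], letters[1:4])
  perm <- c("b", "a", "d", "c")
  m2 <- m1[perm, perm] * 2
  # same samples in different order: labels are realigned, so r = 1
  expect_equal(mantel_test(m1, m2, n_perm = 9, seed = 1)$r, 1)
  m3 <- m1
  dimnames(m3) <- list(letters[5:8], letters[5:8])
  expect_error(mantel_test(m1, m3), "only in d1")
})

test_that("Mantel null p-values are uniform (KS over 500 independent runs)", {
  set.seed(18)
  ps <- vapply(1:500, function(i) {
    d1 <- dist(matrix(rnorm(16), 8, 2))
    d2 <- dist(matrix(rnorm(16), 8, 2))
    mantel_test(d1, d2, n_perm = 99, seed = i)$p
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("marginal RDA explained fractions match the projection-trace oracle", {
  set.seed(19)
  # Y exactly linear in a single variable -> it explains 100%
  x <- rnorm(12)
  Y1 <- cbind(2 * x, -x, 0.5 * x) + 0  # rank-1 response
  colnames(Y1) <- c("r1", "r2", "r3")
  res1 <- rda_explained(Y1, data.frame(x = x), standardize = FALSE)
  expect_equal(res1$table$explained_pct, 100, tolerance = 1e-8)
  # independent noise explains next to nothing at large n
  n <- 400
  Y0 <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  res0 <- rda_explained(Y0, data.frame(z = rnorm(n)), standardize = FALSE)
  expect_lt(res0$table$explained_pct, 3)
  # 8-sample fixture vs the explicit hat-matrix oracle to 1e-10
  Y <- matrix(rnorm(8 * 4), 8, 4, dimnames = list(NULL, paste0("f", 1:4)))
  X <- data.frame(u = rnorm(8), v = rnorm(8))
  res <- rda_explained(Y, X, standardize = FALSE)
  for (v in c("u", "v")) {
    expect_equal(res$table$explained_pct[res$table$variable == v],
                 oracle_rda_marginal(Y, X[[v]]), tolerance = 1e-10)
  }
  # ranking is descending
  expect_true(all(diff(res$table$explained_pct) <= 0))
})

test_that("RDA explained fractions are invariant to rescaling X and drop collinear terms", {
  set.seed(20)
  Y <- matrix(rnorm(40), 10, 4)
  X <- data.frame(a = rnorm(10), b = rnorm(10))
  base <- rda_explained(Y, X, standardize = FALSE)
  Xs <- data.frame(a = 1000 * X$a - 3, b = X$b / 50)
  scaled <- rda_explained(Y, Xs, standardize = FALSE)
  expect_equal(base$table$explained_pct, scaled$table$explained_pct,
               tolerance = 1e-10)
  Xc <- data.frame(a = X$a, b = X$b, twice_a = 2 * X$a)
  expect_warning(resc <- rda_explained(Y, Xc, standardize = FALSE),
                 "twice_a")
  expect_setequal(resc$table$variable, c("a", "b"))
})

test_that("Tukey letter displays separate groups exactly when pairwise tests do", {
  set.seed(21)
  # three statistically identical groups share one letter
  v0 <- rnorm(15, 10, 1)
  g0 <- rep(c("x", "y", "z"), each = 5)
  res0 <- anova_tukey_letters(v0, g0)
  expect_equal(unique(res0$letters), "a")
  # two wildly separated groups get distinct letters
  v1 <- c(rnorm(5, 0, 1), rnorm(5, 100, 1))
  res1 <- anova_tukey_letters(v1, rep(c("lo", "hi"), each = 5))
  expect_setequal(res1$letters, c("a", "b"))
  # intermediate group bridges the extremes: pattern a / ab / b
  v2 <- c(rnorm(6, 0, 1), rnorm(6, 2.2, 1), rnorm(6, 4.4, 1))
  g2 <- rep(c("low", "mid", "high"), each = 6)
  res2 <- anova_tukey_letters(v2, g2)
  tuk <- attr(res2, "tukey")
  # oracle: letters must share iff the pairwise Tukey test is not significant
  lookup <- setNames(res2$letters, res2$group)
  prs <- strsplit(rownames(tuk), "-", fixed = TRUE)
  for (k in seq_along(prs)) {
    shared <- length(intersect(strsplit(lookup[[prs[[k]][1]]], "")[[1]],
                               strsplit(lookup[[prs[[k]][2]]], "")[[1]])) > 0
    expect_equal(shared, tuk[k, "p adj"] >= 0.05)
  }
  expect_error(anova_tukey_letters(c(1, 2, 3), c("a", "a", "b")),
               "replicates")
})

test_that("letter displays agree with the reference multiple-comparison letters", {
  skip_if_not_installed("multcomp")
  set.seed(22)
  v <- c(rnorm(8, 0), rnorm(8, 1.5), rnorm(8, 3.5), rnorm(8, 3.6))
  g <- factor(rep(c("a1", "a2", "a3", "a4"), each = 8))
  ours <- anova_tukey_letters(v, g)
  fit <- stats::aov(v ~ g)
  ref <- multcomp::cld(multcomp::glht(fit, linfct = multcomp::mcp(g = "Tukey")))
  ref_letters <- ref$mcletters$Letters
  # same partition structure: pairs share a letter in ours iff they do in ref
  lookup <- setNames(ours$letters, ours$group)
  for (i in 1:3) for (j in (i + 1):4) {
    gi <- levels(g)[i]; gj <- levels(g)[j]
    ours_share <- length(intersect(strsplit(lookup[[gi]], "")[[1]],
                                   strsplit(lookup[[gj]], "")[[1]])) > 0
    ref_share <- length(intersect(strsplit(ref_letters[[gi]], "")[[1]],
                                  strsplit(ref_letters[[gj]], "")[[1]])) > 0
    expect_equal(ours_share, ref_share)
  }
})
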