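test_that("matrix Pearson correlation works over strict upper triangles", {
  set.seed(1)
  a <- rsym(4)
  expect_equal(matrix_pearson(a, a), 1)
  expect_equal(matrix_pearson(a, -a), -1)
  # hand evaluation on the 6 dyads of two fixed 4x4 matrices
  ids <- letters[1:4]
  m1 <- matrix(0, 4, 4, dimnames = list(ids, ids))
  m2 <- m1
  m1[upper.tri(m1)] <- c(1, 2, 3, 4, 5, 6)
  m2[upper.tri(m2)] <- c(2, 1, 4, 3, 6, 5)
  m1 <- m1 + t(m1); m2 <- m2 + t(m2)
  expect_equal(matrix_pearson(m1, m2),
               stats::cor(c(1, 2, 3, 4, 5, 6), c(2, 1, 4, 3, 6, 5)))
  con <- matrix(1, 4, 4, dimnames = list(ids, ids))
  expect_error(matrix_pearson(con, m1), class = "kinclique_degenerate")
})

test_that("first-order partial correlation follows the recursion formula", {
  expect_equal(partial_r(0.6, 0, 0), 0.6)
  expect_equal(partial_r(0.6, 0.5, 0.5), 0.35 / 0.75)
  expect_equal(partial_r(0.35, 0.7, 0.5), 0)
  expect_error(partial_r(0.2, 1, 0.5), class = "kinclique_degenerate")
})

test_that("order-0 HPMT is exactly the simple Mantel test", {
  set.seed(2)
  x <- rsym(9); y <- rsym(9)
  h <- hpmt_test(x, y, z = NULL, n_perm = 199, seed = 5)
  m <- mantel_test(x, y, n_perm = 199, seed = 5)
  expect_identical(h$statistic, m$statistic)
  expect_identical(h$p_value, m$p_value)
  expect_equal(h$order, 0)
  skip_if_not_installed("vegan")
  # independent implementation agrees on the statistic
  v <- vegan::mantel(as.dist(x), as.dist(y), permutations = 99)
  expect_equal(h$statistic, unname(v$statistic), tolerance = 1e-12)
})

test_that("recursive partial r equals least-squares residual correlation up to k = 3", {
  set.seed(3)
  for (k in 0:3) {
    for (rep in 1:5) {
      n <- sample(6:10, 1)
      x <- rsym(n); y <- rsym(n)
      zs <- replicate(k, rsym(n), simplify = FALSE)
      h <- hpmt_test(x, y, z = zs, n_perm = 5, seed = 1)
      expect_equal(h$statistic, oracle_partial_resid(x, y, zs),
                   tolerance = 1e-9)
    }
  }
})

test_that("permutation p follows the unbiased (n1+1)/(n2+1) rule", {
  set.seed(4)
  # y = x + tiny noise: no permutation should beat the observed r
  x <- rsym(10)
  y <- x + rsym(10) * 1e-6
  h <- hpmt_test(x, y, n_perm = 999, seed = 6)
  expect_equal(h$n_exceed, 0)
  expect_equal(h$p_value, 1 / 1000)
})

test_that("statistics are invariant under consistent relabelling", {
  set.seed(5)
  n <- 8
  x <- rsym(n); y <- rsym(n); z <- rsym(n)
  h1 <- hpmt_test(x, y, z = list(z), n_perm = 29, seed = 9)
  p <- sample(n)
  relab <- function(m) m[p, p]
  h2 <- hpmt_test(relab(x), relab(y), z = list(relab(z)),
                  n_perm = 29, seed = 9)
  expect_equal(h1$statistic, h2$statistic, tolerance = 1e-12)
  r2a <- multiple_determination(y, list(x, z))
  r2b <- multiple_determination(relab(y), list(relab(x), relab(z)))
  expect_equal(r2a, r2b, tolerance = 1e-12)
})

test_that("coefficient of multiple determination matches hand evaluation", {
  set.seed(6)
  x <- rsym(8)
  # single factor: R2 = r^2
  y <- rsym(8)
  expect_equal(multiple_determination(y, list(x)),
               matrix_pearson(y, x)^2, tolerance = 1e-12)
  # order invariance within floating tolerance
  z <- rsym(8); w <- rsym(8)
  expect_equal(multiple_determination(y, list(x, z, w)),
               multiple_determination(y, list(w, x, z)), tolerance = 1e-9)
  # duplicated factor adds nothing
  expect_equal(multiple_determination(y, list(x, x + 0e0)),
               multiple_determination(y, list(x)), tolerance = 1e-9)
})

test_that("contribution rates decompose R2 for orthogonal predictors", {
  # two exactly uncorrelated predictors each correlated 0.5 with y:
  # R2 = 0.5, CR = 0.25 each (hand evaluation of the recursion)
  n <- 40
  ids <- sprintf("i%02d", 1:n)
  nd <- n * (n - 1) / 2
  set.seed(7)
  # orthonormal, mean-centred columns (first column of the QR is the
  # intercept, so the rest are exactly uncorrelated)
  base <- qr.Q(qr(cbind(1, matrix(rnorm(nd * 3), nd, 3))))[, 2:4]
  u1 <- base[, 1]; u2 <- base[, 2]; e <- base[, 3]
  yv <- 0.5 * u1 + 0.5 * u2 + sqrt(0.5) * e
  tosym <- function(v) {
    m <- matrix(0, n, n, dimnames = list(ids, ids))
    m[upper.tri(m)] <- v
    m + t(m)
  }
  y <- tosym(yv); x1 <- tosym(u1); x2 <- tosym(u2)
  cr <- contribution_rates(y, list(a = x1, b = x2))
  expect_equal(attr(cr, "r.squared"), 0.5, tolerance = 1e-9)
  expect_equal(cr$cr, c(0.25, 0.25), tolerance = 1e-9)
  # single factor: CR = R2 = r^2
  cr1 <- contribution_rates(y, list(a = x1))
  expect_equal(cr1$cr, attr(cr1, "r.squared"), tolerance = 1e-12)
  expect_equal(cr1$cr, matrix_pearson(y, x1)^2, tolerance = 1e-12)
})

test_that("a factor unrelated to y and to other factors contributes ~0", {
  set.seed(8)
  x <- rsym(12)
  y <- x + rsym(12) * 0.5
  junk <- rsym(12)
  cr <- contribution_rates(y, list(signal = x, noise = junk))
  expect_gt(cr$cr[cr$factor == "signal"], cr$cr[cr$factor == "noise"])
  expect_lt(cr$cr[cr$factor == "noise"], 0.1)
})

test_that("CR values and their sum respect the published bounds", {
  set.seed(9)
  for (rep in 1:20) {
    n <- sample(6:12, 1)
    y <- rsym(n)
    k <- sample(1:3, 1)
    facs <- replicate(k, rsym(n), simplify = FALSE)
    names(facs) <- paste0("f", seq_len(k))
    cr <- contribution_rates(y, facs)
    r2 <- attr(cr, "r.squared")
    expect_lte(sum(cr$cr), 1)
    expect_lte(r2, 1)
    expect_true(all(cr$cr >= 0 & cr$cr <= 1))
  }
})

test_that("label permutation test separates planted group structure", {
  ids <- letters[1:8]
  groups <- setNames(rep(c("g1", "g2"), each = 4), ids)
  m <- matrix(0, 8, 8, dimnames = list(ids, ids))
  same <- outer(groups, groups, "==")
  m[same] <- 1
  diag(m) <- 0
  res <- label_permutation_test(m, groups, n_perm = 199, seed = 3)
  expect_equal(res$statistic, 1)
  expect_equal(res$p_value, 1 / 200)
  expect_error(label_permutation_test(m, setNames(rep("g", 8), ids)),
               class = "kinclique_no_test")
})

test_that("label permutation p is calibrated on i.i.d. matrices", {
  set.seed(10)
  ps <- vapply(1:120, function(i) {
    m <- rsym(10)
    groups <- setNames(sample(rep(c("a", "b"), 5)), rownames(m))
    label_permutation_test(m, groups, n_perm = 99)$p_value
  }, numeric(1))
  expect_gt(mean(ps), 0.40)
  expect_lt(mean(ps), 0.60)
  expect_lt(mean(ps <= 0.05), 0.12)
})
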