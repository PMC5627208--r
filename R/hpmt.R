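#' Matrix Pearson correlation over dyads
#'
#' Pearson correlation between the strict upper triangles of two symmetric
#' dyadic matrices on the same individuals — the elementary statistic the
#' Mantel test and its partial extensions permute. Diagonals are excluded.
#'
#' @param a,b symmetric numeric matrices with identical id labels (order
#'   matters; see [dyad_matrix()]).
#' @return Pearson r, a length-1 numeric.
#' @examples
#' m1 <- matrix(runif(16), 4, 4); m1 <- m1 + t(m1); diag(m1) <- 0
#' dimnames(m1) <- list(letters[1:4], letters[1:4])
#' matrix_pearson(m1, m1)  # 1
#' @export
matrix_pearson <- function(a, b) {
  check_same_labels(a, b)
  if (nrow(a) < 4) {
    rlang::abort("need at least 4 individuals for a dyadic correlation",
                 class = "kinclique_invalid")
  }
  va <- upper_vec(a)
  vb <- upper_vec(b)
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    rlang::abort("zero variance across dyads; correlation undefined",
                 class = "kinclique_degenerate")
  }
  stats::cor(va, vb)
}

#' First-order partial correlation
#'
#' The classical recursion step: correlation of x and y after removing the
#' linear effect of a single control z, from the three pairwise
#' correlations. Higher-order partials are obtained by applying this step
#' recursively, peeling one control at a time.
#'
#' @param r_xy,r_xz,r_yz pairwise Pearson correlations.
#' @return partial correlation r_xy.z.
#' @examples
#' partial_r(0.6, 0.5, 0.5)  # 0.35 / 0.75
#' @export
partial_r <- function(r_xy, r_xz, r_yz) {
  stopifnot(abs(r_xy) <= 1 + 1e-12, abs(r_xz) <= 1 + 1e-12,
            abs(r_yz) <= 1 + 1e-12)
  denom2 <- (1 - r_xz^2) * (1 - r_yz^2)
  if (denom2 <= .Machine$double.eps) {
    rlang::abort("a control correlation is +/-1; partial correlation degenerate",
                 class = "kinclique_degenerate")
  }
  (r_xy - r_xz * r_yz) / sqrt(denom2)
}

# kth-order partial correlation between variables u and v given controls
# (indices into a correlation matrix R), by recursive peeling. The peel
# order is the input order; exact arithmetic is order-invariant.
partial_r_recursive <- function(R, u, v, controls) {
  if (length(controls) == 0) return(R[u, v])
  z <- controls[length(controls)]
  rest <- controls[-length(controls)]
  partial_r(
    partial_r_recursive(R, u, v, rest),
    partial_r_recursive(R, u, z, rest),
    partial_r_recursive(R, v, z, rest)
  )
}

# Correlation matrix among a list of dyad matrices (upper triangles).
triangle_cor_matrix <- function(mats) {
  V <- vapply(mats, upper_vec, numeric(sum(upper.tri(mats[[1]]))))
  sds <- apply(V, 2, stats::sd)
  if (any(sds == 0)) {
    rlang::abort(
      paste0("zero dyadic variance in matrix: ",
             paste(names(mats)[sds == 0], collapse = ", ")),
      class = "kinclique_degenerate")
  }
  stats::cor(V)
}

#' Higher-order partial Mantel test (HPMT)
#'
#' Tests whether a dyadic matrix `x` correlates with a dependent matrix `y`
#' while controlling any number of further dyadic matrices `z`. The
#' kth-order partial correlation is built from three (k-1)th-order partials
#' by the classical recursion; significance comes from a Monte-Carlo null in
#' which the rows and columns of `x` alone are jointly permuted (`y` and all
#' controls stay fixed), with the unbiased estimate p = (n1 + 1) / (n2 + 1)
#' where n1 of n2 permutations strictly exceed the observed statistic.
#'
#' With no controls this is exactly the simple Mantel test ([mantel_test()]
#' is a convenience wrapper).
#'
#' @param x matrix under test (its rows/columns are permuted).
#' @param y dependent matrix.
#' @param z a single control matrix or a (possibly named) list of them;
#'   `NULL` for a plain Mantel test.
#' @param n_perm number of permutations (default 999).
#' @param alternative `"one.sided"` (default; in the direction of the
#'   observed statistic — note this adaptive choice roughly doubles the
#'   type-I rate of a fixed-direction test), `"greater"`, `"less"` (fixed
#'   direction), or `"two.sided"` (on absolute value).
#' @param seed optional integer seed for the permutation stream.
#' @return an object of class `hpmt_result`: a list with `statistic` (the
#'   partial r), `p_value`, `order` (number of controls), `n_perm`,
#'   `n_exceed`, `alternative` and `permutations` (the null statistics).
#' @examples
#' set.seed(1)
#' ids <- letters[1:8]
#' rmat <- function() {
#'   m <- matrix(rnorm(64), 8, 8); m <- m + t(m); diag(m) <- 0
#'   dimnames(m) <- list(ids, ids); m
#' }
#' hpmt_test(rmat(), rmat(), z = list(rmat()), n_perm = 99, seed = 7)
#' @export
hpmt_test <- function(x, y, z = NULL, n_perm = 999,
                      alternative = c("one.sided", "greater", "less",
                                      "two.sided"),
                      seed = NULL) {
  alternative <- match.arg(alternative)
  if (n_perm < 1) rlang::abort("n_perm must be >= 1", class = "kinclique_invalid")
  if (is.matrix(z)) z <- list(z)
  z <- z %||% list()
  if (length(z) > 0 && is.null(names(z))) names(z) <- paste0("z", seq_along(z))
  mats <- c(list(x = x, y = y), z)
  do.call(check_same_labels, unname(mats))
  n <- nrow(x)
  if (n < 4) rlang::abort("need at least 4 individuals", class = "kinclique_invalid")

  k <- length(z)
  ctrl_idx <- if (k > 0) 2 + seq_len(k) else integer(0)
  R <- triangle_cor_matrix(mats)
  r_obs <- partial_r_recursive(R, 1, 2, ctrl_idx)

  # Precompute fixed triangles; per permutation only the triangle of the
  # permuted x changes, so each null statistic needs k + 1 correlations.
  ut <- which(upper.tri(x), arr.ind = TRUE)
  fixed <- lapply(mats[-1], upper_vec)
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_seed(old), add = TRUE)
    set.seed(seed)
  }
  xm <- unclass_dyad(x)
  r_perm <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    p <- sample.int(n)
    xv <- xm[cbind(p[ut[, 1]], p[ut[, 2]])]
    Rp <- R
    cors <- vapply(fixed, function(v) stats::cor(xv, v), numeric(1))
    Rp[1, -1] <- Rp[-1, 1] <- cors
    r_perm[b] <- tryCatch(partial_r_recursive(Rp, 1, 2, ctrl_idx),
                          error = function(e) NA_real_)
  }
  ok <- !is.na(r_perm)
  n2 <- sum(ok)
  # n1 counts permutations strictly beating the observed statistic
  n1 <- switch(alternative,
    two.sided = sum(abs(r_perm[ok]) > abs(r_obs)),
    greater = sum(r_perm[ok] > r_obs),
    less = sum(r_perm[ok] < r_obs),
    one.sided = if (r_obs >= 0) sum(r_perm[ok] > r_obs) else
      sum(r_perm[ok] < r_obs))
  structure(
    list(statistic = r_obs, p_value = (n1 + 1) / (n2 + 1), order = k,
         n_perm = n2, n_exceed = n1, alternative = alternative,
         n_ids = n, permutations = r_perm[ok]),
    class = "hpmt_result")
}

restore_seed <- function(old) {
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' @rdname hpmt_test
#' @param ... passed to [hpmt_test()].
#' @export
mantel_test <- function(x, y, n_perm = 999, ...) {
  hpmt_test(x, y, z = NULL, n_perm = n_perm, ...)
}

#' @export
print.hpmt_result <- function(x, ...) {
  lab <- if (x$order == 0) "Mantel test" else
    sprintf("higher-order partial Mantel test (order %d)", x$order)
  cat(sprintf("%s: r = %.4f, p = %.4g (%d of %d permutations, %s)\n",
              lab, x$statistic, x$p_value, x$n_exceed, x$n_perm,
              x$alternative))
  invisible(x)
}

#' @rdname hpmt_test
#' @export
tidy.hpmt_result <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p.value = x$p_value,
                 order = x$order, n.perm = x$n_perm, n.exceed = x$n_exceed)
}

#' @rdname hpmt_test
#' @param object an `hpmt_result`.
#' @export
glance.hpmt_result <- function(x, ...) tidy.hpmt_result(x, ...)

#' Coefficient of multiple determination over dyadic factors
#'
#' Share of dyadic variance in `y` jointly explained by a set of factor
#' matrices: R2 = 1 - prod_i (1 - r^2_i) where r_i is the partial
#' correlation of factor i with `y` given factors 1..i-1 (sequential
#' partials via the same recursion as [hpmt_test()]). The value is
#' order-invariant up to floating-point drift.
#'
#' @param y dependent dyadic matrix.
#' @param factors list of factor matrices on the same ids.
#' @return R-squared in \[0, 1\].
#' @export
multiple_determination <- function(y, factors) {
  if (is.matrix(factors)) factors <- list(factors)
  if (length(factors) < 1) {
    rlang::abort("need at least one factor", class = "kinclique_invalid")
  }
  do.call(check_same_labels, c(list(y), unname(factors)))
  R <- triangle_cor_matrix(c(list(y = y), factors))
  r2 <- 1
  for (i in seq_along(factors)) {
    # a factor perfectly collinear with earlier ones adds nothing: its
    # sequential partial is taken as 0 rather than propagating the 0/0
    ri <- tryCatch(
      partial_r_recursive(R, 1, i + 1,
                          if (i > 1) 1 + seq_len(i - 1) else integer(0)),
      kinclique_degenerate = function(e) 0)
    r2 <- r2 * (1 - ri^2)
  }
  1 - r2
}

#' Contribution rate of each dyadic factor
#'
#' The contribution rate (CR) of a factor is the drop in the coefficient of
#' multiple determination when that factor is removed: CR_f = R2(all) -
#' R2(all except f). Each CR lies in \[0, 1\] and the CRs sum to at most the
#' full R2. Tiny negative values arising from floating-point drift are
#' clipped to zero with a warning.
#'
#' @inheritParams multiple_determination
#' @param factors named list of factor matrices.
#' @return a tibble of class `hpmt_cr` with columns `factor`, `cr`, plus the
#'   full-model `r.squared` as an attribute (also a column of `glance()`).
#' @examples
#' # see vignette("bachelor-band-analysis") for a full worked example
#' @export
contribution_rates <- function(y, factors) {
  if (is.matrix(factors)) factors <- list(factor = factors)
  if (is.null(names(factors)) || any(!nzchar(names(factors)))) {
    names(factors) <- paste0("factor", seq_along(factors))
  }
  r2_full <- multiple_determination(y, factors)
  cr <- vapply(seq_along(factors), function(f) {
    rest <- factors[-f]
    r2_rest <- if (length(rest) == 0) 0 else multiple_determination(y, rest)
    r2_full - r2_rest
  }, numeric(1))
  if (any(cr < -1e-8)) {
    rlang::warn("negative contribution rate beyond tolerance; clipped to 0")
  }
  cr <- pmax(cr, 0)
  out <- tibble::tibble(factor = names(factors), cr = cr)
  structure(out, r.squared = r2_full,
            class = c("hpmt_cr", class(out)))
}

#' @rdname contribution_rates
#' @param x an `hpmt_cr` object.
#' @param ... unused.
#' @export
glance.hpmt_cr <- function(x, ...) {
  tibble::tibble(r.squared = attr(x, "r.squared"),
                 cr.total = sum(x$cr), n.factors = nrow(x))
}

#' Matrix permutation test for within- vs between-group dyad means
#'
#' Tests whether dyads inside the same group (e.g. the same all-male unit)
#' carry systematically higher values (relatedness, HWI) than dyads spanning
#' groups. The statistic is mean(within) - mean(between); the null permutes
#' group labels across individuals; p = (n1 + 1)/(n2 + 1).
#'
#' @param values symmetric dyadic matrix.
#' @param groups named vector of group labels covering the matrix ids.
#' @param n_perm number of label permutations.
#' @param seed optional integer seed.
#' @param alternative `"greater"` (default: within > between) or `"two.sided"`.
#' @return list with `statistic`, `p_value`, `n_perm`, `mean_within`,
#'   `mean_between`.
#' @export
label_permutation_test <- function(values, groups, n_perm = 999, seed = NULL,
                                   alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  ids <- rownames(values)
  g <- groups[ids]
  if (any(is.na(g))) rlang::abort("groups must cover all matrix ids",
                                  class = "kinclique_invalid")
  if (length(unique(g)) < 2) {
    rlang::abort("need at least two groups with between-group dyads",
                 class = "kinclique_no_test")
  }
  same <- outer(g, g, "==")[upper.tri(values)]
  if (!any(same)) {
    rlang::abort("no within-group dyads; test undefined",
                 class = "kinclique_no_test")
  }
  v <- upper_vec(values)
  stat_fn <- function(s) mean(v[s]) - mean(v[!s])
  obs <- stat_fn(same)
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_seed(old), add = TRUE)
    set.seed(seed)
  }
  ut <- which(upper.tri(values), arr.ind = TRUE)
  null <- vapply(seq_len(n_perm), function(b) {
    gp <- sample(g)
    stat_fn(gp[ut[, 1]] == gp[ut[, 2]])
  }, numeric(1))
  n1 <- if (alternative == "two.sided") sum(abs(null) > abs(obs))
        else sum(null > obs)
  list(statistic = obs, p_value = (n1 + 1) / (n_perm + 1), n_perm = n_perm,
       mean_within = mean(v[same]), mean_between = mean(v[!same]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
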