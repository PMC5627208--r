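#' Estimate allele frequencies with null-allele EM
#'
#' Microsatellite null alleles fail to amplify, so a heterozygote carrying
#' one is scored as a visible-allele homozygote and a null homozygote as
#' missing. Per locus this EM treats the true genotype as latent: the
#' E-step splits each observed visible homozygote between true homozygote
#' and heterozygote-with-null in proportion to their Hardy-Weinberg
#' probabilities under the current frequencies, and books missing calls as
#' null/null; the M-step re-estimates all frequencies (visible plus null)
#' by allele counting. The observed-data likelihood is non-decreasing
#' across iterations.
#'
#' Loci with a single visible allele carry no homozygote-excess signal; the
#' null frequency is fixed at 0 with a warning.
#'
#' @param genotypes a [genotype_table()].
#' @param tol L-infinity convergence tolerance on the frequency vector
#'   (default 1e-8).
#' @param max_iter iteration cap (default 1000).
#' @return an object of class `allele_frequencies`: a named list per locus
#'   with `visible` (named frequency vector), `null` (null frequency),
#'   `n_iter` and `log_lik` (likelihood trace).
#' @export
estimate_allele_freqs_em <- function(genotypes, tol = 1e-8, max_iter = 1000) {
  out <- lapply(seq_along(genotypes$loci), function(j) {
    em_one_locus(genotypes$a1[, j], genotypes$a2[, j],
                 locus = genotypes$loci[j], tol = tol, max_iter = max_iter)
  })
  names(out) <- genotypes$loci
  structure(out, class = "allele_frequencies")
}

em_one_locus <- function(a1, a2, locus, tol, max_iter) {
  typed <- !is.na(a1)
  alleles <- sort(unique(c(a1[typed], a2[typed])))
  n_ind <- length(a1)
  if (length(alleles) == 0) {
    rlang::abort(sprintf("locus %s has no typed individuals", locus),
                 class = "kinclique_invalid")
  }
  het <- typed & a1 != a2
  hom <- typed & a1 == a2
  n_miss <- sum(!typed)
  hom_allele <- factor(a1[hom], levels = alleles)
  hom_counts <- as.vector(table(hom_allele))
  het_counts <- as.vector(table(factor(a1[het], levels = alleles))) +
    as.vector(table(factor(a2[het], levels = alleles)))

  if (length(alleles) == 1 && n_miss == 0) {
    rlang::warn(sprintf("locus %s is monomorphic; null frequency fixed at 0",
                        locus))
    return(list(visible = stats::setNames(1, alleles), null = 0,
                n_iter = 0L, log_lik = NA_real_))
  }

  p0 <- if (n_miss > 0 || sum(hom_counts) > 0) 0.05 else 0
  p <- (het_counts + 2 * hom_counts)
  p <- p / sum(p) * (1 - p0)
  ll_trace <- numeric(0)
  loglik <- function(p, p0) {
    sum(het * log(pmax(2 * p[match(a1, alleles)] * p[match(a2, alleles)],
                       1e-300)), na.rm = TRUE) +
      sum(hom_counts * log(pmax(p^2 + 2 * p * p0, 1e-300))) +
      n_miss * log(pmax(p0^2, 1e-300))
  }
  it <- 0L
  repeat {
    it <- it + 1L
    ll_trace <- c(ll_trace, loglik(p, p0))
    # E-step: expected allele counts
    w_true_hom <- ifelse(p + 2 * p0 > 0, p / (p + 2 * p0), 1)
    vis_counts <- het_counts + hom_counts * (2 * w_true_hom + (1 - w_true_hom))
    null_count <- sum(hom_counts * (1 - w_true_hom)) + 2 * n_miss
    # M-step: allele counting over 2 * n_ind gene copies
    total <- sum(vis_counts) + null_count
    p_new <- vis_counts / total
    p0_new <- null_count / total
    delta <- max(abs(c(p_new - p, p0_new - p0)))
    p <- p_new; p0 <- p0_new
    if (delta < tol || it >= max_iter) break
  }
  ll_trace <- c(ll_trace, loglik(p, p0))
  list(visible = stats::setNames(p, alleles), null = p0, n_iter = it,
       log_lik = ll_trace)
}

#' @export
print.allele_frequencies <- function(x, ...) {
  cat(sprintf("<allele_frequencies: %d loci, mean null freq %.3f>\n",
              length(x), mean(vapply(x, `[[`, numeric(1), "null"))))
  invisible(x)
}

#' @rdname estimate_allele_freqs_em
#' @param x an `allele_frequencies` object.
#' @param ... unused.
#' @export
tidy.allele_frequencies <- function(x, ...) {
  purrr::imap_dfr(x, function(f, locus) {
    tibble::tibble(locus = locus,
                   allele = c(names(f$visible), "null"),
                   frequency = c(unname(f$visible), f$null))
  })
}

# Lynch & Ritland (1999) single-locus regression estimator with x = (a, b)
# as reference and y = (c, d) as proband. Returns c(numerator, denominator);
# the denominator doubles as the locus information weight.
lr_terms <- function(a, b, c_, d, pa, pb) {
  sac <- as.numeric(a == c_); sad <- as.numeric(a == d)
  sbc <- as.numeric(b == c_); sbd <- as.numeric(b == d)
  sab <- as.numeric(a == b)
  num <- pa * (sbc + sbd) + pb * (sac + sad) - 4 * pa * pb
  den <- (1 + sab) * (pa + pb) - 4 * pa * pb
  c(num, den)
}

# Posterior over true genotypes given an observed call under the
# null-allele model: an observed homozygote (i, i) is truly (i, i) with
# probability p_i/(p_i + 2 p0), else (i, null).
genotype_posterior <- function(a1, a2, p_vis, p0) {
  if (a1 != a2 || p0 <= 0) {
    return(list(g = list(c(a1, a2)), w = 1))
  }
  pi_ <- p_vis[[a1]]
  w_hom <- pi_ / (pi_ + 2 * p0)
  list(g = list(c(a1, a1), c(a1, ".null")), w = c(w_hom, 1 - w_hom))
}

#' Pairwise Lynch-Ritland relatedness
#'
#' Regression-based pairwise relatedness from codominant genotypes and
#' reference allele frequencies. Per locus each individual serves in turn
#' as the reference; multi-locus estimates combine loci as a ratio of
#' summed numerators to summed denominators (the denominator is the locus
#' information weight), and the dyad value is the mean of the two
#' reciprocal estimates. With `null_correction`, allele-identity indicators
#' are replaced by their posterior expectations given the observed
#' phenotypes and the EM-estimated null frequency, the null allele entering
#' the formula as an allele of frequency p0.
#'
#' @param genotypes a [genotype_table()].
#' @param freqs an `allele_frequencies` object covering all observed
#'   alleles (see [estimate_allele_freqs_em()]); typically estimated on a
#'   larger reference population.
#' @param null_correction logical; correct for null alleles (default TRUE).
#' @param pairs optional tibble with columns `id_a`, `id_b`: estimate only
#'   these dyads and return a tibble instead of the full matrix.
#' @return symmetric [dyad_matrix()] of relatedness estimates (`NA` for
#'   dyads with no informative locus), or a tibble when `pairs` is given.
#' @export
lr_relatedness <- function(genotypes, freqs, null_correction = TRUE,
                           pairs = NULL) {
  g <- genotypes
  n <- length(g$ids)
  if (n < 2) rlang::abort("need at least 2 individuals",
                          class = "kinclique_invalid")
  # per-locus visible frequencies; uncorrected mode renormalizes over the
  # visible alleles so they form a proper simplex
  locus_freqs <- lapply(g$loci, function(l) {
    f <- freqs[[l]]
    if (is.null(f)) rlang::abort(sprintf("no frequencies for locus %s", l),
                                 class = "kinclique_invalid")
    if (null_correction) {
      list(p = c(f$visible, .null = f$null), p0 = f$null)
    } else {
      list(p = f$visible / sum(f$visible), p0 = 0)
    }
  })
  names(locus_freqs) <- g$loci
  if (!is.null(pairs)) {
    est <- vapply(seq_len(nrow(pairs)), function(r) {
      lr_pair(g, match(pairs$id_a[r], g$ids), match(pairs$id_b[r], g$ids),
              locus_freqs, null_correction)
    }, numeric(1))
    return(tibble::tibble(id_a = pairs$id_a, id_b = pairs$id_b,
                          relatedness = est))
  }
  m <- matrix(NA_real_, n, n, dimnames = list(g$ids, g$ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      est <- lr_pair(g, i, j, locus_freqs, null_correction)
      m[i, j] <- m[j, i] <- est
    }
  }
  diag(m) <- 1
  dyad_matrix(m, directed = FALSE, type = "relatedness")
}

#' Build an allele-frequency object from known frequency vectors
#'
#' Wraps per-locus named frequency vectors (as produced by
#' [simulate_allele_freqs()], with the null share named `".null"`) in the
#' same structure [estimate_allele_freqs_em()] returns, for use with
#' [lr_relatedness()] when the frequencies are known rather than
#' estimated.
#'
#' @param freqs named list of per-locus frequency vectors summing to 1.
#' @return an `allele_frequencies` object.
#' @export
as_allele_frequencies <- function(freqs) {
  structure(lapply(freqs, function(f) {
    null <- if (".null" %in% names(f)) unname(f[[".null"]]) else 0
    vis <- f[setdiff(names(f), ".null")]
    list(visible = vis, null = null, n_iter = 0L, log_lik = NA_real_)
  }), class = "allele_frequencies")
}

lr_pair <- function(g, i, j, locus_freqs, null_correction) {
  num_ij <- den_ij <- num_ji <- den_ji <- 0
  used <- 0L
  for (l in seq_along(g$loci)) {
    if (is.na(g$a1[i, l]) || is.na(g$a1[j, l])) next
    lf <- locus_freqs[[l]]
    gi <- genotype_posterior(g$a1[i, l], g$a2[i, l], lf$p, lf$p0)
    gj <- genotype_posterior(g$a1[j, l], g$a2[j, l], lf$p, lf$p0)
    if (!null_correction) {
      gi <- list(g = list(c(g$a1[i, l], g$a2[i, l])), w = 1)
      gj <- list(g = list(c(g$a1[j, l], g$a2[j, l])), w = 1)
    }
    for (u in seq_along(gi$g)) {
      for (v in seq_along(gj$g)) {
        w <- gi$w[u] * gj$w[v]
        ga <- gi$g[[u]]; gb <- gj$g[[v]]
        pa <- lf$p[[ga[1]]]; pb <- lf$p[[ga[2]]]
        t1 <- lr_terms(ga[1], ga[2], gb[1], gb[2], pa, pb)
        pc <- lf$p[[gb[1]]]; pd <- lf$p[[gb[2]]]
        t2 <- lr_terms(gb[1], gb[2], ga[1], ga[2], pc, pd)
        num_ij <- num_ij + w * t1[1]; den_ij <- den_ij + w * t1[2]
        num_ji <- num_ji + w * t2[1]; den_ji <- den_ji + w * t2[2]
      }
    }
    used <- used + 1L
  }
  if (used == 0L) return(NA_real_)
  # reciprocal estimates averaged; a direction whose summed information
  # weight is zero (e.g. reference heterozygous at two equifrequent
  # alleles everywhere) is dropped rather than invalidating the dyad
  ests <- c(if (den_ij > 1e-12) num_ij / den_ij,
            if (den_ji > 1e-12) num_ji / den_ji)
  if (length(ests) == 0) return(NA_real_)
  mean(ests)
}

#' UPGMA clustering on a relatedness matrix
#'
#' Agglomerative mean-linkage clustering that repeatedly merges the two
#' clusters with the highest average cross-cluster relatedness
#' (sum of r over all cross pairs divided by n_a * n_b), until one cluster
#' remains. Merge heights are the relatedness at merge (so heights
#' decrease). Ties break lexicographically on the smallest member label,
#' making the tree invariant to input order.
#'
#' @param relatedness symmetric relatedness [dyad_matrix()]; `NA` entries
#'   are handled by pairwise-complete means.
#' @return an object of class `relatedness_upgma` with `merges` (tibble of
#'   cluster pairs and heights) and `newick` (tree string with branch
#'   lengths on a 1 - r depth scale).
#' @export
upgma_relatedness <- function(relatedness) {
  m <- unclass_dyad(relatedness)
  ids <- rownames(m)
  n <- length(ids)
  if (n < 2) rlang::abort("need at least 2 individuals",
                          class = "kinclique_invalid")
  diag(m) <- NA
  members <- as.list(ids)
  labels <- ids                      # smallest label per cluster (tie-break)
  newick <- ids
  active <- rep(TRUE, n)
  merges <- list()
  cluster_r <- function(a, b) {
    vals <- m[members[[a]], members[[b]], drop = FALSE]
    if (all(is.na(vals))) return(-Inf)
    mean(vals, na.rm = TRUE)
  }
  depth <- stats::setNames(rep(0, n), NULL)
  while (sum(active) > 1) {
    idx <- which(active)
    best <- c(NA, NA); best_r <- -Inf
    for (ai in seq_along(idx)) {
      for (bi in seq_along(idx)[-seq_len(ai)]) {
        a <- idx[ai]; b <- idx[bi]
        r <- cluster_r(a, b)
        better <- r > best_r ||
          (r == best_r && (is.na(best[1]) ||
             paste(sort(c(labels[a], labels[b])), collapse = "\r") <
             paste(sort(c(labels[best[1]], labels[best[2]])), collapse = "\r")))
        if (better) { best <- c(a, b); best_r <- r }
      }
    }
    a <- best[1]; b <- best[2]
    h <- (1 - best_r) / 2            # ultrametric depth on a distance scale
    merges[[length(merges) + 1]] <- tibble::tibble(
      cluster_a = labels[a], cluster_b = labels[b], height = best_r)
    newick[a] <- sprintf("(%s:%g,%s:%g)", newick[a], max(h - depth[a], 0),
                         newick[b], max(h - depth[b], 0))
    depth[a] <- h
    members[[a]] <- c(members[[a]], members[[b]])
    labels[a] <- min(labels[a], labels[b])
    active[b] <- FALSE
  }
  root <- which(active)
  structure(list(merges = dplyr::bind_rows(merges),
                 newick = paste0(newick[root], ";"),
                 ids = ids),
            class = "relatedness_upgma")
}

#' @export
print.relatedness_upgma <- function(x, ...) {
  cat(sprintf("<relatedness_upgma: %d tips, first merge at r = %.3f>\n",
              length(x$ids), x$merges$height[1]))
  invisible(x)
}

#' @rdname upgma_relatedness
#' @param x a `relatedness_upgma` object.
#' @param ... unused.
#' @export
tidy.relatedness_upgma <- function(x, ...) x$merges

#' Per-locus genetic diversity statistics
#'
#' Number of visible alleles (Na), observed heterozygosity (Ho), unbiased
#' expected heterozygosity He = 2n/(2n-1) * (1 - sum p^2) with p the sample
#' allele frequencies, and Wright's inbreeding coefficient F = 1 - Ho/He.
#' F is undefined (NA) at loci with He = 0 and excluded from the mean.
#'
#' @param genotypes a [genotype_table()].
#' @return tibble with one row per locus plus a `summarise`-ready shape;
#'   use `dplyr::summarise` or [glance_diversity()] for across-locus means.
#' @export
diversity_stats <- function(genotypes) {
  g <- genotypes
  purrr::map_dfr(seq_along(g$loci), function(j) {
    a1 <- g$a1[, j]; a2 <- g$a2[, j]
    typed <- !is.na(a1)
    n <- sum(typed)
    obs <- c(a1[typed], a2[typed])
    p <- as.vector(table(obs)) / length(obs)
    ho <- mean(a1[typed] != a2[typed])
    he <- if (n > 0) 2 * n / (2 * n - 1) * (1 - sum(p^2)) else NA_real_
    tibble::tibble(
      locus = g$loci[j], n_typed = n, na = length(unique(obs)),
      ho = ho, he = he,
      f = ifelse(!is.na(he) && he > 0, 1 - ho / he, NA_real_)
    )
  })
}

#' @rdname diversity_stats
#' @param stats_tbl output of [diversity_stats()].
#' @export
glance_diversity <- function(stats_tbl) {
  tibble::tibble(
    n_loci = nrow(stats_tbl),
    na_mean = mean(stats_tbl$na), na_sd = stats::sd(stats_tbl$na),
    ho_mean = mean(stats_tbl$ho), ho_sd = stats::sd(stats_tbl$ho),
    he_mean = mean(stats_tbl$he), he_sd = stats::sd(stats_tbl$he),
    f_mean = mean(stats_tbl$f, na.rm = TRUE),
    f_sd = stats::sd(stats_tbl$f, na.rm = TRUE)
  )
}

#' Hardy-Weinberg chi-squared test at one locus
#'
#' Pearson chi-squared of observed genotype counts against Hardy-Weinberg
#' expectations from the sample allele frequencies, on g - a degrees of
#' freedom (genotype classes minus alleles). A warning is attached when any
#' expected class count falls below 5.
#'
#' @param genotypes a [genotype_table()].
#' @param locus locus name.
#' @return list with `statistic`, `df`, `p_value`, `small_counts` (logical)
#'   or a `no_test` result for monomorphic loci.
#' @export
hwe_chisq <- function(genotypes, locus) {
  j <- match(locus, genotypes$loci)
  if (is.na(j)) rlang::abort(sprintf("unknown locus %s", locus),
                             class = "kinclique_invalid")
  a1 <- genotypes$a1[, j]; a2 <- genotypes$a2[, j]
  typed <- !is.na(a1)
  a1 <- a1[typed]; a2 <- a2[typed]
  alleles <- sort(unique(c(a1, a2)))
  k <- length(alleles)
  if (k < 2) {
    return(list(no_test = TRUE, reason = "monomorphic locus"))
  }
  n <- length(a1)
  p <- (as.vector(table(factor(a1, alleles))) +
          as.vector(table(factor(a2, alleles)))) / (2 * n)
  # observed genotype counts over unordered pairs
  gkey <- paste(pmin(a1, a2), pmax(a1, a2), sep = "/")
  pairs <- t(utils::combn(alleles, 2))
  classes <- c(paste(alleles, alleles, sep = "/"),
               paste(pairs[, 1], pairs[, 2], sep = "/"))
  obs <- as.vector(table(factor(gkey, classes)))
  exp_p <- c(p^2, 2 * p[match(pairs[, 1], alleles)] * p[match(pairs[, 2], alleles)])
  e <- exp_p * n
  keep <- e > 0
  stat <- sum((obs[keep] - e[keep])^2 / e[keep])
  df <- length(classes) - k
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       small_counts = any(e[keep] < 5), no_test = FALSE)
}
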