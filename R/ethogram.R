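#' Tally behavioural categories
#'
#' Counts events per ethogram category and expresses them as percentages of
#' the categorised total (2 decimal places in the printed tibble; exact
#' values retained).
#'
#' @param events tibble with a `behaviour` column.
#' @param categories character vector of ethogram categories; events with
#'   other labels are rejected and counted.
#' @return a tibble of class `ethogram_tally` with `behaviour`, `count`,
#'   `percent`, and attribute `n_rejected`.
#' @examples
#' ev <- tibble::tibble(behaviour = c("chasing", "biting", "chasing"))
#' tally_ethogram(ev, c("biting", "chasing"))
#' @export
tally_ethogram <- function(events, categories) {
  if (length(categories) == 0) {
    rlang::abort("categories must be non-empty", class = "kinclique_invalid")
  }
  known <- events$behaviour %in% categories
  counts <- table(factor(events$behaviour[known], levels = categories))
  total <- sum(counts)
  out <- tibble::tibble(
    behaviour = categories,
    count = as.integer(counts),
    percent = if (total > 0) 100 * as.integer(counts) / total else 0
  )
  structure(out, n_rejected = sum(!known),
            class = c("ethogram_tally", class(out)))
}

#' Reconstruct integer counts from printed percentages
#'
#' Published tallies often print only category percentages and a total.
#' This inverts that rounding: counts = round(percent/100 * total), with any
#' residual (at most a few counts) assigned by largest remainder so the
#' counts sum exactly to the total.
#'
#' @param percents numeric percentages (should sum to ~100).
#' @param total integer grand total.
#' @return integer vector of counts summing to `total`.
#' @examples
#' counts_from_percent(c(1.00, 1.39, 97.61), 2092)
#' @export
counts_from_percent <- function(percents, total) {
  raw <- percents / 100 * total
  counts <- round(raw)
  residual <- total - sum(counts)
  if (residual != 0) {
    frac <- raw - floor(raw)
    ord <- if (residual > 0) order(-frac) else order(frac)
    take <- ord[seq_len(abs(residual))]
    counts[take] <- counts[take] + sign(residual)
  }
  as.integer(counts)
}

#' Chi-squared goodness-of-fit test
#'
#' Pearson goodness-of-fit of observed category counts against expected
#' proportions (uniform by default): X2 = sum (O - E)^2 / E on c - 1
#' degrees of freedom.
#'
#' @param counts non-negative integer counts.
#' @param expected optional expected proportions (default uniform).
#' @return list with `statistic`, `df`, `p_value`, `expected`.
#' @examples
#' chisq_gof(c(30, 40, 30))  # vs uniform thirds
#' @export
chisq_gof <- function(counts, expected = NULL) {
  if (any(counts < 0) || sum(counts) <= 0) {
    rlang::abort("counts must be non-negative with positive total",
                 class = "kinclique_invalid")
  }
  k <- length(counts)
  expected <- expected %||% rep(1 / k, k)
  if (any(expected <= 0)) {
    rlang::abort("expected proportions must be positive",
                 class = "kinclique_invalid")
  }
  expected <- expected / sum(expected)
  e <- expected * sum(counts)
  stat <- sum((counts - e)^2 / e)
  list(statistic = stat, df = k - 1,
       p_value = stats::pchisq(stat, k - 1, lower.tail = FALSE),
       expected = e)
}

#' Sequential Bonferroni (Holm) correction
#'
#' Holm's step-down procedure: order the p values ascending and reject
#' while p_(i) < alpha / (m - i + 1), stopping at the first failure.
#'
#' @param p_values numeric vector of p values in \[0, 1\].
#' @param alpha family-wise error level (default 0.05).
#' @return tibble with original order preserved: `p.value`, `threshold`
#'   (the step-down cut-off applied to that p value) and `reject`.
#' @examples
#' sequential_bonferroni(c(0.001, 0.02, 0.03))
#' @export
sequential_bonferroni <- function(p_values, alpha = 0.05) {
  m <- length(p_values)
  if (m == 0) {
    return(tibble::tibble(p.value = numeric(), threshold = numeric(),
                          reject = logical()))
  }
  stopifnot(all(p_values >= 0 & p_values <= 1))
  ord <- order(p_values)
  thresholds <- alpha / (m - seq_len(m) + 1)
  reject_sorted <- logical(m)
  for (i in seq_len(m)) {
    if (p_values[ord[i]] < thresholds[i]) reject_sorted[i] <- TRUE else break
  }
  out <- tibble::tibble(p.value = p_values, threshold = NA_real_,
                        reject = FALSE)
  out$threshold[ord] <- thresholds
  out$reject[ord] <- reject_sorted
  out
}

#' Mann-Whitney rank comparison of two samples
#'
#' Wilcoxon rank-sum (Mann-Whitney U) comparison: exact enumeration for
#' small untied samples, normal approximation with tie correction
#' otherwise (delegated to [stats::wilcox.test()]; the reported U is the
#' number of (a, b) pairs with a > b, plus half the ties).
#'
#' @param sample_a,sample_b numeric vectors.
#' @param alternative passed to [stats::wilcox.test()].
#' @return list with `u`, `p_value`, `n_a`, `n_b`.
#' @examples
#' rank_compare(c(1, 3, 5), c(2, 4, 6))
#' @export
rank_compare <- function(sample_a, sample_b, alternative = "two.sided") {
  if (length(sample_a) == 0 || length(sample_b) == 0) {
    rlang::abort("both samples must be non-empty", class = "kinclique_invalid")
  }
  wt <- suppressWarnings(
    stats::wilcox.test(sample_a, sample_b, alternative = alternative,
                       exact = length(sample_a) < 20 && length(sample_b) < 20)
  )
  list(u = unname(wt$statistic), p_value = wt$p.value,
       n_a = length(sample_a), n_b = length(sample_b))
}
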