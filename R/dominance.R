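#' Build a win/loss matrix from agonistic bouts
#'
#' Converts a stream of agonistic bouts into a directed count matrix:
#' `wins[i, j]` is the number of bouts in which `i` directed agonism at `j`
#' and `j` responded submissively (a decided bout). Bouts with no decided
#' outcome are excluded and counted. Records whose behaviour label is not in
#' the ethogram are rejected and counted separately.
#'
#' @param agonistic tibble/data.frame with columns `actor`, `recipient`,
#'   `behaviour` and `outcome` (`"decided"` or `"undecided"`).
#' @param agonistic_behaviours character vector of the agonistic ethogram;
#'   defaults to the biting/fighting/chasing/lunging/supplanting/vocal
#'   threat repertoire of bachelor-male conflict.
#' @param ids optional character vector fixing the matrix label set/order.
#' @return a directed [dyad_matrix()] of win counts with attributes
#'   `n_excluded` (undecided bouts) and `n_rejected` (unknown labels).
#' @examples
#' bouts <- tibble::tibble(actor = c("a", "a", "b"), recipient = c("b", "b", "c"),
#'                         behaviour = "chasing", outcome = "decided")
#' build_conflict_matrix(bouts)
#' @export
build_conflict_matrix <- function(agonistic,
                                  agonistic_behaviours = agonistic_ethogram(),
                                  ids = NULL) {
  stopifnot(all(c("actor", "recipient", "behaviour", "outcome") %in%
                  names(agonistic)))
  if (any(agonistic$actor == agonistic$recipient)) {
    rlang::abort("self-directed agonistic records are invalid",
                 class = "kinclique_invalid_record")
  }
  known <- agonistic$behaviour %in% agonistic_behaviours
  n_rejected <- sum(!known)
  agonistic <- agonistic[known, , drop = FALSE]
  decided <- agonistic$outcome == "decided"
  n_excluded <- sum(!decided)
  agonistic <- agonistic[decided, , drop = FALSE]
  ids <- ids %||% sort(unique(c(agonistic$actor, agonistic$recipient)))
  m <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  if (nrow(agonistic) > 0) {
    tab <- table(factor(agonistic$actor, ids), factor(agonistic$recipient, ids))
    m <- m + unclass(tab)
  }
  out <- dyad_matrix(m, directed = TRUE, type = "wins")
  attr(out, "n_excluded") <- n_excluded
  attr(out, "n_rejected") <- n_rejected
  out
}

#' Agonistic and submissive ethograms
#'
#' The behaviour repertoires used to classify bachelor-male conflict bouts.
#' @return character vector of behaviour labels.
#' @export
agonistic_ethogram <- function() {
  c("biting", "fighting", "chasing", "lunging", "supplanting",
    "vocal threatening")
}

#' @rdname agonistic_ethogram
#' @export
submissive_ethogram <- function() c("avoidance", "fleeing", "crouching")

# Dyadic win-proportion matrix. Pij mode: wins_ij / n_ij, 0 where a dyad
# never interacted. Dij mode applies the sample-size correction
# Dij = Pij - (Pij - 0.5)/(n_ij + 1), which shrinks sparse dyads to 0.5.
dyadic_proportions <- function(wins, dyadic = c("Pij", "Dij")) {
  dyadic <- match.arg(dyadic)
  n <- wins + t(wins)
  p <- ifelse(n > 0, wins / ifelse(n > 0, n, 1), 0)
  if (dyadic == "Dij") {
    p <- ifelse(n > 0, p - (p - 0.5) / (n + 1), 0)
  }
  diag(p) <- 0
  p
}

#' David's scores and normalized David's scores
#'
#' Ranks individuals from dyadic win proportions. For individual i,
#' DS_i = w_i + w2_i - l_i - l2_i, where w_i is the sum of i's win
#' proportions, w2_i weights each by the opponent's own w, and l, l2 are the
#' mirrored loss terms. NDS rescales DS to \[0, N-1\]:
#' NDS_i = (DS_i + N(N-1)/2) / N. Rank order is descending NDS with ties
#' broken by id label.
#'
#' @param wins directed win-count matrix from [build_conflict_matrix()].
#' @param dyadic `"Pij"` (raw win proportions, the default) or `"Dij"`
#'   (de Vries' sample-size-corrected proportions). Under `"Pij"` a dyad
#'   that never interacted contributes 0.
#' @return an object of class `dominance_result` with per-individual `ds`,
#'   `nds`, `rank` and the proportion matrix used.
#' @examples
#' wins <- matrix(c(0, 3, 0, 0), 2, 2, dimnames = list(c("a","b"), c("a","b")))
#' david_scores(wins)
#' @export
david_scores <- function(wins, dyadic = c("Pij", "Dij")) {
  dyadic <- match.arg(dyadic)
  n_id <- nrow(wins)
  if (n_id < 2) rlang::abort("need at least 2 individuals",
                             class = "kinclique_invalid")
  p <- dyadic_proportions(unclass_dyad(wins), dyadic)
  w <- rowSums(p)
  l <- colSums(p)
  w2 <- as.vector(p %*% w)
  l2 <- as.vector(t(p) %*% l)
  ds <- unname(w + w2 - l - l2)
  nds <- (ds + n_id * (n_id - 1) / 2) / n_id
  ids <- rownames(wins)
  ord <- order(-nds, ids)
  scores <- tibble::tibble(
    id = ids, ds = ds, nds = nds,
    rank = match(seq_along(ids), ord)
  )
  structure(list(scores = scores, proportions = p, dyadic = dyadic,
                 n = n_id, wins = unclass_dyad(wins)),
            class = "dominance_result")
}

#' @export
print.dominance_result <- function(x, ...) {
  cat(sprintf("<dominance_result: %d individuals, %s dyadic proportions>\n",
              x$n, x$dyadic))
  print(dplyr::arrange(x$scores, .data$rank), ...)
  invisible(x)
}

#' @rdname david_scores
#' @param x a `dominance_result`.
#' @param ... unused.
#' @export
tidy.dominance_result <- function(x, ...) dplyr::arrange(x$scores, .data$rank)

#' @rdname david_scores
#' @export
glance.dominance_result <- function(x, ...) {
  tibble::tibble(n = x$n, ds.sum = sum(x$scores$ds),
                 nds.max = max(x$scores$nds), dyadic = x$dyadic)
}

#' Hierarchy steepness
#'
#' Absolute slope of the ordinary least-squares regression of NDS on rank
#' position 1..N: 1 for a despotic (fully decided, transitive) hierarchy, 0
#' for an egalitarian one. The permutation p value randomizes the win
#' counts within dyads (binomial with the observed dyad totals, the default)
#' or shuffles scores across ranks.
#'
#' @param result a `dominance_result` from [david_scores()].
#' @param n_perm number of randomizations (default 1000).
#' @param seed optional integer seed.
#' @param method `"matrix"` (randomize dyad outcomes keeping totals) or
#'   `"shuffle"` (permute NDS across rank positions).
#' @return list with `steepness`, `r_squared`, `p_value`, `n_perm`.
#' @export
hierarchy_steepness <- function(result, n_perm = 1000, seed = NULL,
                                method = c("matrix", "shuffle")) {
  method <- match.arg(method)
  if (n_perm < 1) rlang::abort("n_perm must be >= 1", class = "kinclique_invalid")
  if (result$n < 3) rlang::abort("need at least 3 individuals",
                                 class = "kinclique_invalid")
  slope_fit <- function(nds) {
    rank_pos <- seq_along(nds)
    y <- sort(nds, decreasing = TRUE)
    fit <- stats::lm.fit(cbind(1, rank_pos), y)
    slope <- fit$coefficients[2]
    ssr <- sum(fit$residuals^2)
    sst <- sum((y - mean(y))^2)
    c(abs(slope), if (sst > 0) 1 - ssr / sst else 1)
  }
  obs <- slope_fit(result$scores$nds)
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_seed(old), add = TRUE)
    set.seed(seed)
  }
  wins <- result$wins
  ut <- which(upper.tri(wins), arr.ind = TRUE)
  totals <- (wins + t(wins))[upper.tri(wins)]
  null <- vapply(seq_len(n_perm), function(b) {
    if (method == "matrix") {
      wij <- stats::rbinom(length(totals), totals, 0.5)
      wp <- matrix(0, nrow(wins), ncol(wins), dimnames = dimnames(wins))
      wp[ut] <- wij
      wp[ut[, c(2, 1), drop = FALSE]] <- totals - wij
      slope_fit(david_scores(wp, dyadic = result$dyadic)$scores$nds)[1]
    } else {
      slope_fit(sample(result$scores$nds))[1]
    }
  }, numeric(1))
  list(steepness = unname(obs[1]), r_squared = unname(obs[2]),
       p_value = (sum(null >= obs[1]) + 1) / (n_perm + 1), n_perm = n_perm,
       method = method)
}

# Landau linearity with the correction for unknown/tied dyads: ties and
# never-interacting dyads give each individual half a "win" in V_i, and the
# expected inflation 6u/(N^3 - N) from randomly directing the u unknown
# dyads is added back.
linearity_h_prime <- function(wins) {
  n <- nrow(wins)
  tot <- wins + t(wins)
  dom <- (wins > t(wins)) + 0.5 * (tot == 0 | wins == t(wins))
  diag(dom) <- 0
  v <- rowSums(dom)
  h <- 12 / (n^3 - n) * sum((v - (n - 1) / 2)^2)
  u <- sum((tot == 0 | wins == t(wins))[upper.tri(tot)])
  h + 6 * u / (n^3 - n)
}

#' Hierarchy linearity
#'
#' Landau's h with the unknown/tied-relationship correction: unresolved
#' dyads contribute half a dominance each and the expected contribution of
#' randomly directing them, 6u/(N^3 - N), is added. p comes from
#' randomizing the direction of every dyad.
#'
#' @inheritParams hierarchy_steepness
#' @param wins directed win-count matrix.
#' @return list with `h_prime`, `p_value`, `n_unknown`, `n_perm`.
#' @export
hierarchy_linearity <- function(wins, n_perm = 1000, seed = NULL) {
  if (n_perm < 1) rlang::abort("n_perm must be >= 1", class = "kinclique_invalid")
  n <- nrow(wins)
  if (n < 3) rlang::abort("need at least 3 individuals",
                          class = "kinclique_invalid")
  wins <- unclass_dyad(wins)
  obs <- linearity_h_prime(wins)
  tot <- wins + t(wins)
  unknown <- (tot == 0 | wins == t(wins))[upper.tri(tot)]
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(restore_seed(old), add = TRUE)
    set.seed(seed)
  }
  ut <- which(upper.tri(wins), arr.ind = TRUE)
  null <- vapply(seq_len(n_perm), function(b) {
    dir_up <- stats::runif(nrow(ut)) < 0.5
    wp <- matrix(0, n, n, dimnames = dimnames(wins))
    wp[ut[!unknown & dir_up, , drop = FALSE]] <- 1
    wp[ut[!unknown & !dir_up, c(2, 1), drop = FALSE]] <- 1
    linearity_h_prime(wp)
  }, numeric(1))
  list(h_prime = obs, p_value = (sum(null >= obs) + 1) / (n_perm + 1),
       n_unknown = sum(unknown), n_perm = n_perm)
}
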