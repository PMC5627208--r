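#' Half-weight index association matrix
#'
#' Dyadic association from scan samples, corrected for unequal sighting
#' effort (Cairns & Schwager half-weight form). For a dyad,
#' HWI = x / (x + y_ab + (y_a + y_b)/2), where over all sampling periods
#' (scans) x counts periods with the pair together, y_ab periods with both
#' seen but apart, and y_a / y_b periods with only one seen. Dyads never
#' co-observed score 0; an individual never observed at all is dropped
#' with a warning.
#'
#' @param scans tibble with columns `scan_id`, `id_a`, `id_b`, `together`
#'   (0/1). A pair listed with `together = 0` was seen apart in that scan;
#'   an individual is "seen" in a scan if it appears in any of its rows.
#' @return symmetric [dyad_matrix()] of HWI values in \[0, 1\].
#' @export
compute_hwi <- function(scans) {
  stopifnot(all(c("scan_id", "id_a", "id_b", "together") %in% names(scans)))
  if (nrow(scans) == 0) rlang::abort("need at least one scan",
                                     class = "kinclique_invalid")
  long <- dplyr::bind_rows(
    dplyr::select(scans, scan = "scan_id", id = "id_a"),
    dplyr::select(scans, scan = "scan_id", id = "id_b")
  ) |> dplyr::distinct()
  ids <- sort(unique(long$id))
  scan_ids <- unique(scans$scan_id)
  seen <- matrix(FALSE, length(scan_ids), length(ids),
                 dimnames = list(as.character(scan_ids), ids))
  seen[cbind(match(long$scan, scan_ids), match(long$id, ids))] <- TRUE
  tg <- scans[scans$together == 1, , drop = FALSE]
  x <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  if (nrow(tg) > 0) {
    ij <- cbind(match(tg$id_a, ids), match(tg$id_b, ids))
    key <- paste(tg$scan_id, pmin(ij[, 1], ij[, 2]), pmax(ij[, 1], ij[, 2]))
    ij <- ij[!duplicated(key), , drop = FALSE]
    for (r in seq_len(nrow(ij))) {
      x[ij[r, 1], ij[r, 2]] <- x[ij[r, 1], ij[r, 2]] + 1
    }
    x <- x + t(x)
  }
  n_seen <- colSums(seen)
  both_seen <- crossprod(seen)          # scans with both individuals seen
  y_ab <- both_seen - x                 # both seen but apart
  only <- outer(n_seen, n_seen, "+") - 2 * both_seen  # y_a + y_b
  denom <- x + y_ab + only / 2
  hwi <- ifelse(denom > 0, x / denom, 0)
  diag(hwi) <- 0
  never <- n_seen == 0
  if (any(never)) {
    rlang::warn(paste("individuals never observed dropped:",
                      paste(ids[never], collapse = ", ")))
    hwi <- hwi[!never, !never, drop = FALSE]
  }
  dyad_matrix(hwi, directed = FALSE, type = "hwi")
}

#' Directional affiliation index from grooming bouts
#'
#' Directed grooming index DAI_ij built from bout counts G_ij (bouts i
#' initiated toward j). The default normalization is the initiator share
#' G_ij / sum_k G_ik; alternatives: `"dyadic"` divides by the dyad total
#' G_ij + G_ji, `"rate"` divides by the number of distinct observation
#' sessions (days). Individuals who never initiated get an all-zero row.
#'
#' @param grooming tibble with columns `initiator`, `recipient` (and
#'   `datetime` for `"rate"` normalization).
#' @param denominator `"initiator"`, `"dyadic"` or `"rate"`.
#' @param ids optional label set/order.
#' @return directed [dyad_matrix()]; raw counts in attribute `counts`.
#' @export
compute_dai <- function(grooming, denominator = c("initiator", "dyadic", "rate"),
                        ids = NULL) {
  denominator <- match.arg(denominator)
  stopifnot(all(c("initiator", "recipient") %in% names(grooming)))
  if (nrow(grooming) == 0) rlang::abort("need at least one bout",
                                        class = "kinclique_invalid")
  if (any(grooming$initiator == grooming$recipient)) {
    rlang::abort("self-grooming records are invalid",
                 class = "kinclique_invalid_record")
  }
  ids <- ids %||% sort(unique(c(grooming$initiator, grooming$recipient)))
  g_counts <- unclass(table(factor(grooming$initiator, ids),
                            factor(grooming$recipient, ids)))
  dai <- switch(denominator,
    initiator = {
      tot <- rowSums(g_counts)
      sweep(g_counts, 1, ifelse(tot > 0, tot, 1), "/")
    },
    dyadic = {
      tot <- g_counts + t(g_counts)
      ifelse(tot > 0, g_counts / ifelse(tot > 0, tot, 1), 0)
    },
    rate = {
      if (!"datetime" %in% names(grooming)) {
        rlang::abort("rate normalization needs a datetime column",
                     class = "kinclique_invalid")
      }
      n_days <- length(unique(as.Date(grooming$datetime)))
      g_counts / n_days
    })
  out <- dyad_matrix(dai, directed = TRUE, type = "dai")
  attr(out, "counts") <- g_counts
  out
}

#' Cluster bachelor males into subgroups (all-male units)
#'
#' Average-linkage hierarchical clustering on association distance
#' (1 - HWI). When `n_groups` is not given, the dendrogram is cut at the
#' number of clusters that maximizes Newman modularity Q of the partition
#' on the weighted HWI graph; Q of the chosen cut is reported as the
#' cliquishness coefficient.
#'
#' @param hwi symmetric association [dyad_matrix()].
#' @param n_groups optional fixed number of subgroups.
#' @param linkage linkage method for [stats::hclust()] (default
#'   `"average"`).
#' @return object of class `subgroup_partition`: `assignment` tibble (id,
#'   subgroup), `hclust` tree, `cliquishness` (modularity Q) and the per-id
#'   eigenvector centrality of the HWI graph.
#' @export
cluster_subgroups <- function(hwi, n_groups = NULL, linkage = "average") {
  m <- unclass_dyad(hwi)
  n <- nrow(m)
  if (n < 2) rlang::abort("need at least 2 individuals",
                          class = "kinclique_invalid")
  all_zero <- all(m[upper.tri(m)] == 0)
  if (all_zero) {
    rlang::warn("all-zero association matrix: single cluster, cliquishness 0")
    assignment <- tibble::tibble(id = rownames(m), subgroup = "S1")
    return(structure(list(assignment = assignment, hclust = NULL,
                          cliquishness = 0,
                          centrality = stats::setNames(rep(0, n), rownames(m))),
                     class = "subgroup_partition"))
  }
  d <- stats::as.dist(1 - m)
  hc <- stats::hclust(d, method = linkage)
  graph <- igraph::graph_from_adjacency_matrix(m, mode = "undirected",
                                               weighted = TRUE, diag = FALSE)
  q_of <- function(member) newman_modularity(m, member)
  if (is.null(n_groups)) {
    cuts <- seq_len(n)
    qs <- vapply(cuts, function(k) q_of(stats::cutree(hc, k)), numeric(1))
    n_groups <- cuts[which.max(qs)]
  }
  member <- stats::cutree(hc, n_groups)
  q <- q_of(member)
  ec <- eigenvector_centrality(m)
  assignment <- tibble::tibble(id = rownames(m),
                               subgroup = paste0("S", member))
  structure(list(assignment = assignment, hclust = hc, cliquishness = q,
                 n_groups = n_groups, centrality = ec, graph = graph),
            class = "subgroup_partition")
}

# Newman modularity of a hard partition on a weighted undirected graph:
# Q = sum_g (w_in_g / W - (k_g / 2W)^2), with W the total edge weight.
newman_modularity <- function(w, member) {
  diag(w) <- 0
  total <- sum(w) / 2
  if (total == 0) return(0)
  q <- 0
  for (g in unique(member)) {
    sel <- member == g
    w_in <- sum(w[sel, sel]) / 2
    k_g <- sum(w[sel, ])
    q <- q + w_in / total - (k_g / (2 * total))^2
  }
  q
}

# Principal eigenvector of the association matrix, non-negative and
# normalized to unit maximum.
eigenvector_centrality <- function(m) {
  diag(m) <- 0
  ev <- eigen(m, symmetric = TRUE)
  v <- ev$vectors[, which.max(ev$values)]
  if (sum(v) < 0) v <- -v
  v <- pmax(v, 0)
  if (max(v) > 0) v <- v / max(v)
  stats::setNames(v, rownames(m))
}

#' @export
print.subgroup_partition <- function(x, ...) {
  cat(sprintf("<subgroup_partition: %d subgroups, cliquishness Q = %.3f>\n",
              length(unique(x$assignment$subgroup)), x$cliquishness))
  print(dplyr::count(x$assignment, .data$subgroup), ...)
  invisible(x)
}

#' @rdname cluster_subgroups
#' @param x a `subgroup_partition`.
#' @param ... unused.
#' @export
tidy.subgroup_partition <- function(x, ...) {
  dplyr::mutate(x$assignment, centrality = unname(x$centrality[.data$id]))
}

#' @rdname cluster_subgroups
#' @export
glance.subgroup_partition <- function(x, ...) {
  tibble::tibble(n_groups = length(unique(x$assignment$subgroup)),
                 cliquishness = x$cliquishness,
                 n = nrow(x$assignment))
}

#' Threshold a sociogram for display/export
#'
#' Keeps edges at or above a weight threshold (the convention used for
#' sociogram figures: weak HWI/DAI relationships are hidden) and attaches
#' optional node attributes for export.
#'
#' @param matrix_ a [dyad_matrix()] (HWI or DAI).
#' @param threshold minimum retained weight (closed bound: `>=`).
#' @param node_attrs optional tibble keyed by `id` with columns to attach.
#' @return tibble edge list (`from`, `to`, `weight`); node attributes in
#'   attribute `nodes`.
#' @export
filter_sociogram <- function(matrix_, threshold, node_attrs = NULL) {
  stopifnot(threshold >= 0)
  edges <- tidy(matrix_) |>
    dplyr::filter(.data$value >= threshold) |>
    dplyr::rename(from = "id_a", to = "id_b", weight = "value")
  nodes <- tibble::tibble(id = rownames(matrix_))
  if (!is.null(node_attrs)) nodes <- dplyr::left_join(nodes, node_attrs, by = "id")
  structure(edges, nodes = nodes)
}

#' Write a thresholded sociogram as GraphML
#'
#' @param edges output of [filter_sociogram()].
#' @param path output file.
#' @export
write_sociogram_graphml <- function(edges, path) {
  nodes <- attr(edges, "nodes")
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname cluster_subgroups
#' @param object a `subgroup_partition`.
#' @export
autoplot.subgroup_partition <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$subgroup, .data$centrality)) +
    ggplot2::geom_jitter(width = 0.1, height = 0,
                         ggplot2::aes(colour = .data$subgroup)) +
    ggplot2::labs(x = "subgroup (all-male unit)",
                  y = "eigenvector centrality") +
    ggplot2::theme_minimal() +
    ggplot2::guides(colour = "none")
}
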