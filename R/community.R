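#' Time-decayed daily affiliation graph
#'
#' Builds the weighted graph of affiliation on a given day from dated
#' dyadic events (proximity co-occurrences or grooming bouts), with an
#' exponential memory: each event on day s contributes
#' 2^-((day - s)/half_life) to its dyad's weight on `day`. With an
#' infinite half-life the weight is the cumulative count.
#'
#' @param events tibble with columns `day` (integer), `id_a`, `id_b` and
#'   optionally `count` (default 1 per row).
#' @param day the day index to evaluate at.
#' @param half_life_days decay half-life in days (> 0; `Inf` allowed).
#' @return tibble edge list (`id_a`, `id_b`, `weight`) of class
#'   `daily_graph` with attribute `day`.
#' @export
edge_weights <- function(events, day, half_life_days = 14) {
  if (!is.infinite(half_life_days) && half_life_days <= 0) {
    rlang::abort("half_life_days must be positive", class = "kinclique_invalid")
  }
  stopifnot(all(c("day", "id_a", "id_b") %in% names(events)))
  ev <- dplyr::filter(events, .data$day <= !!day)
  if (!"count" %in% names(ev)) ev$count <- 1
  if (nrow(ev) == 0) {
    out <- tibble::tibble(id_a = character(), id_b = character(),
                          weight = numeric())
    return(structure(out, day = day, class = c("daily_graph", class(out))))
  }
  ev <- dplyr::mutate(ev,
    a = pmin(.data$id_a, .data$id_b), b = pmax(.data$id_a, .data$id_b),
    w = .data$count * if (is.infinite(half_life_days)) 1 else
      2^(-(!!day - .data$day) / half_life_days))
  out <- ev |>
    dplyr::group_by(id_a = .data$a, id_b = .data$b) |>
    dplyr::summarise(weight = sum(.data$w), .groups = "drop")
  structure(out, day = day, class = c("daily_graph", class(out)))
}

#' k-clique percolation communities
#'
#' Overlapping community detection: keep edges with weight at or above
#' `w_star`, enumerate all cliques of exactly `k` nodes, declare two
#' k-cliques adjacent when they share k - 1 nodes, and return the node
#' sets of the connected components of that clique adjacency graph.
#' Individuals can belong to several communities.
#'
#' @param graph a `daily_graph` edge list (or any tibble with `id_a`,
#'   `id_b`, `weight`).
#' @param k clique size (>= 3).
#' @param w_star edge weight threshold (default 1).
#' @return list of character vectors (sorted member ids), ordered by first
#'   member.
#' @export
cpm_communities <- function(graph, k = 3, w_star = 1) {
  if (k < 3) rlang::abort("k must be >= 3", class = "kinclique_invalid")
  edges <- graph[graph$weight >= w_star, , drop = FALSE]
  if (nrow(edges) == 0) return(list())
  g <- igraph::graph_from_data_frame(edges[, c("id_a", "id_b")],
                                     directed = FALSE)
  cliques <- igraph::cliques(g, min = k, max = k)
  if (length(cliques) == 0) return(list())
  names_g <- igraph::V(g)$name
  cl_nodes <- lapply(cliques, function(cl) sort(names_g[cl]))
  nc <- length(cl_nodes)
  # clique-by-node incidence; overlap counts via one matrix product
  inc <- matrix(0L, nc, length(names_g), dimnames = list(NULL, names_g))
  for (i in seq_len(nc)) inc[i, cl_nodes[[i]]] <- 1L
  overlap <- tcrossprod(inc)
  adj <- overlap == k - 1
  diag(adj) <- FALSE
  cg <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(cg)$membership
  comms <- lapply(split(seq_len(nc), comp), function(ix) {
    sort(unique(unlist(cl_nodes[ix])))
  })
  comms <- unname(comms)
  comms[order(vapply(comms, paste, character(1), collapse = "|"))]
}

#' Track communities across days
#'
#' Matches each day's communities to the previous day's by maximal Jaccard
#' overlap (ties broken by larger community, then lexicographic first
#' member) and assigns per-individual turnover flags: EB (existing member,
#' present in the matched community on both days), NFB (newly joined that
#' day), and LND (absent from the next day's matched community). Days with
#' no community simply have no members.
#'
#' @param daily list of community sets, one element per consecutive day
#'   (each a list of character vectors as returned by [cpm_communities()]).
#' @return object of class `community_timeline`: tibble `members` (day,
#'   community, id, eb, nfb, lnd) and tibble `sizes` (day, community,
#'   size).
#' @export
track_communities <- function(daily) {
  if (length(daily) < 2) rlang::abort("need at least 2 days",
                                      class = "kinclique_invalid")
  n_days <- length(daily)
  jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  match_prev <- function(comm, prev_comms) {
    if (length(prev_comms) == 0) return(NULL)
    js <- vapply(prev_comms, jaccard, numeric(1), a = comm)
    if (max(js) == 0) return(NULL)
    best <- which(js == max(js))
    if (length(best) > 1) {
      sizes <- lengths(prev_comms[best])
      best <- best[sizes == max(sizes)]
      if (length(best) > 1) {
        firsts <- vapply(prev_comms[best], `[[`, character(1), 1)
        best <- best[order(firsts)]
      }
    }
    prev_comms[[best[1]]]
  }
  rows <- list()
  for (d in seq_len(n_days)) {
    comms <- daily[[d]]
    for (ci in seq_along(comms)) {
      comm <- comms[[ci]]
      prev <- if (d > 1) match_prev(comm, daily[[d - 1]]) else NULL
      nxt <- if (d < n_days) match_prev(comm, daily[[d + 1]]) else NULL
      rows[[length(rows) + 1]] <- tibble::tibble(
        day = d, community = ci, id = comm,
        eb = !is.null(prev) & comm %in% (prev %||% character(0)),
        nfb = d > 1 & !(comm %in% (prev %||% character(0))),
        lnd = d < n_days & !(comm %in% (nxt %||% character(0)))
      )
    }
  }
  members <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(day = integer(), community = integer(), id = character(),
                   eb = logical(), nfb = logical(), lnd = logical())
  sizes <- members |>
    dplyr::count(.data$day, .data$community, name = "size")
  structure(list(members = members, sizes = sizes, n_days = n_days),
            class = "community_timeline")
}

#' @export
print.community_timeline <- function(x, ...) {
  cat(sprintf("<community_timeline: %d days, %d community-days>\n",
              x$n_days, nrow(x$sizes)))
  invisible(x)
}

#' @rdname track_communities
#' @param x a `community_timeline`.
#' @param ... unused.
#' @export
tidy.community_timeline <- function(x, ...) x$members

#' @rdname track_communities
#' @export
glance.community_timeline <- function(x, ...) {
  tibble::tibble(
    n_days = x$n_days,
    mean_size = mean(x$sizes$size),
    n_lnd = sum(x$members$lnd), n_nfb = sum(x$members$nfb),
    n_eb = sum(x$members$eb)
  )
}

# Daily total COMMUNITY size (members across communities, distinct ids).
community_size_series <- function(timeline) {
  tibble::tibble(day = seq_len(timeline$n_days)) |>
    dplyr::left_join(
      timeline$members |>
        dplyr::distinct(.data$day, .data$id) |>
        dplyr::count(.data$day, name = "size"),
      by = "day") |>
    dplyr::mutate(size = dplyr::coalesce(.data$size, 0L))
}

#' @rdname track_communities
#' @param object a `community_timeline`.
#' @export
autoplot.community_timeline <- function(object, ...) {
  df <- community_size_series(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$day, .data$size)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "day", y = "COMMUNITY size (individuals)") +
    ggplot2::theme_minimal()
}

#' Daily distance between two band centroids
#'
#' Median daily centroid per band from GPS fixes, then the haversine
#' great-circle distance (WGS84 lon/lat, sphere radius 6,371,000 m)
#' between centroids. Days missing fixes for either band get `NA`.
#'
#' @param gps_a,gps_b tibbles with columns `day`, `lon`, `lat`.
#' @return tibble (`day`, `distance_m`) covering the union of days.
#' @export
band_distance <- function(gps_a, gps_b) {
  centroid <- function(gps) {
    gps |>
      dplyr::group_by(.data$day) |>
      dplyr::summarise(lon = stats::median(.data$lon),
                       lat = stats::median(.data$lat), .groups = "drop")
  }
  ca <- centroid(gps_a); cb <- centroid(gps_b)
  days <- sort(union(ca$day, cb$day))
  joined <- tibble::tibble(day = days) |>
    dplyr::left_join(ca, by = "day") |>
    dplyr::left_join(cb, by = "day", suffix = c("_a", "_b"))
  ok <- stats::complete.cases(joined)
  dist <- rep(NA_real_, nrow(joined))
  if (any(ok)) {
    dist[ok] <- geosphere::distHaversine(
      as.matrix(joined[ok, c("lon_a", "lat_a")]),
      as.matrix(joined[ok, c("lon_b", "lat_b")]),
      r = 6371000)
  }
  tibble::tibble(day = joined$day, distance_m = dist)
}

#' Community size vs inter-band distance
#'
#' Correlates daily COMMUNITY size with the AMB-BB distance and reports
#' mean size within distance bins. Default breakpoints (200, 300, 900 m)
#' bracket the distances at which bachelor cohesion peaks and collapses.
#'
#' @param timeline a `community_timeline`.
#' @param distances tibble (`day`, `distance_m`) from [band_distance()].
#' @param breaks bin edges in metres.
#' @return list with `pearson`, `spearman` (correlations with p values),
#'   `bins` tibble (bin, n_days, mean_size) and the joined daily tibble.
#' @export
community_distance_model <- function(timeline, distances,
                                     breaks = c(200, 300, 900)) {
  daily <- community_size_series(timeline) |>
    dplyr::inner_join(distances, by = "day") |>
    dplyr::filter(!is.na(.data$distance_m))
  if (nrow(daily) < 10) {
    rlang::abort("need at least 10 paired days", class = "kinclique_invalid")
  }
  safe_cor <- function(method) {
    if (stats::sd(daily$size) == 0 || stats::sd(daily$distance_m) == 0) {
      return(list(estimate = 0, p.value = NA_real_))
    }
    ct <- suppressWarnings(
      stats::cor.test(daily$size, daily$distance_m, method = method))
    list(estimate = unname(ct$estimate), p.value = ct$p.value)
  }
  all_breaks <- c(-Inf, breaks, Inf)
  labels <- c(paste0("<", breaks[1]),
              paste0(breaks[-length(breaks)], "-", breaks[-1]),
              paste0(">", breaks[length(breaks)]))
  bins <- daily |>
    dplyr::mutate(bin = cut(.data$distance_m, all_breaks, labels = labels)) |>
    dplyr::group_by(.data$bin, .drop = FALSE) |>
    dplyr::summarise(n_days = dplyr::n(), mean_size = mean(.data$size),
                     .groups = "drop")
  list(pearson = safe_cor("pearson"), spearman = safe_cor("spearman"),
       bins = bins, daily = daily)
}

#' Probability of leaving the COMMUNITY by outside-contact rate
#'
#' Bins member-days by each individual's rate of contact with individuals
#' outside its community that day and reports P(leave next day | bin) =
#' LND member-days / member-days in the bin.
#'
#' @param timeline a `community_timeline`.
#' @param outside_contact tibble (`day`, `id`, `rate`) of per-member-day
#'   outside-contact rates.
#' @param breaks bin edges for the contact rate.
#' @return tibble (bin, n, n_leave, p_leave); empty bins have `NA`
#'   probability.
#' @export
leave_probability <- function(timeline, outside_contact,
                              breaks = c(0.25, 0.5, 0.75)) {
  md <- timeline$members |>
    dplyr::filter(.data$day < timeline$n_days) |>
    dplyr::distinct(.data$day, .data$id, .keep_all = TRUE) |>
    dplyr::inner_join(outside_contact, by = c("day", "id"))
  if (nrow(md) == 0) {
    rlang::abort("no member-days with contact rates", class = "kinclique_invalid")
  }
  all_breaks <- unique(c(-Inf, breaks, Inf))
  md |>
    dplyr::mutate(bin = cut(.data$rate, all_breaks)) |>
    dplyr::group_by(.data$bin, .drop = FALSE) |>
    dplyr::summarise(n = dplyr::n(), n_leave = sum(.data$lnd),
                     .groups = "drop") |>
    dplyr::mutate(p_leave = ifelse(.data$n > 0, .data$n_leave / .data$n,
                                   NA_real_))
}
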