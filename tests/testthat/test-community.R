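test_that("edge weights decay with the stated half-life", {
  ev <- tibble::tibble(day = 5, id_a = "a", id_b = "b")
  expect_equal(edge_weights(ev, 5, 14)$weight, 1)
  expect_equal(edge_weights(ev, 5 + 14, 14)$weight, 0.5)
  expect_equal(edge_weights(ev, 5 + 28, 14)$weight, 0.25)
  # infinite half-life: cumulative count
  ev2 <- tibble::tibble(day = c(1, 2, 3), id_a = "a", id_b = "b")
  expect_equal(edge_weights(ev2, 3, Inf)$weight, 3)
  # day before any observation: empty graph
  expect_equal(nrow(edge_weights(ev, 4, 14)), 0)
  expect_error(edge_weights(ev, 5, 0), class = "kinclique_invalid")
})

test_that("clique percolation merges cliques sharing k-1 nodes", {
  tri <- function(...) {
    v <- c(...)
    p <- t(utils::combn(v, 2))
    tibble::tibble(id_a = p[, 1], id_b = p[, 2], weight = 1)
  }
  # triangles sharing an edge percolate into one community
  g1 <- dplyr::distinct(dplyr::bind_rows(tri("1", "2", "3"), tri("2", "3", "4")))
  c1 <- cpm_communities(g1, k = 3)
  expect_equal(c1, list(c("1", "2", "3", "4")))
  # triangles sharing a single node stay separate; the node is in both
  g2 <- dplyr::bind_rows(tri("1", "2", "3"), tri("3", "4", "5"))
  c2 <- cpm_communities(g2, k = 3)
  expect_equal(c2, list(c("1", "2", "3"), c("3", "4", "5")))
  # edgeless graph
  empty <- tibble::tibble(id_a = character(), id_b = character(),
                          weight = numeric())
  expect_equal(cpm_communities(empty, k = 3), list())
  expect_error(cpm_communities(g1, k = 2), class = "kinclique_invalid")
})

test_that("clique percolation matches brute force on random small graphs", {
  set.seed(11)
  for (rep in 1:40) {
    n <- sample(4:8, 1)
    ids <- as.character(seq_len(n))
    p <- t(utils::combn(ids, 2))
    keep <- stats::runif(nrow(p)) < 0.55
    edges <- tibble::tibble(id_a = p[keep, 1], id_b = p[keep, 2], weight = 1)
    for (k in 3:4) {
      expect_equal(cpm_communities(edges, k = k), oracle_cpm(edges, k),
                   info = sprintf("rep %d k %d", rep, k))
    }
  }
})

test_that("raising the percolation threshold never grows a community", {
  set.seed(12)
  ids <- as.character(1:7)
  p <- t(utils::combn(ids, 2))
  edges <- tibble::tibble(id_a = p[, 1], id_b = p[, 2],
                          weight = stats::runif(nrow(p), 0, 2))
  sizes <- vapply(c(0.2, 0.8, 1.4), function(w) {
    cs <- cpm_communities(edges, k = 3, w_star = w)
    if (length(cs) == 0) 0L else max(lengths(cs))
  }, integer(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("community tracking assigns EB/NFB/LND per the matching rules", {
  daily <- list(list(c("1", "2", "3")), list(c("1", "2", "4")))
  tl <- track_communities(daily)
  d1 <- dplyr::filter(tl$members, day == 1)
  d2 <- dplyr::filter(tl$members, day == 2)
  expect_equal(d1$lnd, d1$id == "3")
  expect_equal(d2$eb, d2$id %in% c("1", "2"))
  expect_equal(d2$nfb, d2$id == "4")
  # identical communities: all EB, nobody leaves or joins
  same <- list(list(c("a", "b", "c")), list(c("a", "b", "c")))
  tls <- track_communities(same)
  expect_true(all(dplyr::filter(tls$members, day == 2)$eb))
  expect_false(any(tls$members$nfb))
  expect_false(any(tls$members$lnd))
  # community vanishes: everyone LND
  gone <- list(list(c("a", "b", "c")), list())
  tlg <- track_communities(gone)
  expect_true(all(dplyr::filter(tlg$members, day == 1)$lnd))
})

test_that("band distance matches the haversine closed form", {
  gps_a <- tibble::tibble(day = 1, lon = 0, lat = 0)
  gps_b <- tibble::tibble(day = 1, lon = 0, lat = 0.01)
  d <- band_distance(gps_a, gps_b)
  expect_equal(d$distance_m, oracle_haversine(0, 0, 0, 0.01),
               tolerance = 1e-9)
  expect_equal(d$distance_m, 1111.95, tolerance = 1e-3)
  # identical centroids
  expect_equal(band_distance(gps_a, gps_a)$distance_m, 0)
  # a day missing one band is NA
  gps_c <- tibble::tibble(day = c(1, 2), lon = 0, lat = 0)
  expect_true(is.na(band_distance(gps_c, gps_b)$distance_m[2]))
})

test_that("simulated GPS tracks honour the distance profile", {
  gps <- simulate_gps(90, function(d) 600, jitter = 0, seed = 4)
  d <- band_distance(gps$amb, gps$bb)
  expect_equal(nrow(d), 90)
  expect_equal(d$distance_m, rep(600, 90), tolerance = 1e-6)
  gps0 <- simulate_gps(5, function(d) 0, jitter = 0, seed = 4)
  expect_equal(band_distance(gps0$amb, gps0$bb)$distance_m, rep(0, 5))
  expect_error(simulate_gps(5, function(d) 100, jitter = -1),
               class = "kinclique_invalid")
  expect_error(simulate_gps(5, function(d) -5), class = "kinclique_invalid")
})

test_that("community size couples to inter-band distance as an inverted U", {
  # deterministic toy: size peaks in the 300-900 m band, collapses < 200 m
  n_days <- 40
  dist <- rep(c(100, 250, 600, 1200), each = 10)
  size <- rep(c(3, 5, 9, 4), each = 10)
  members <- purrr::map_dfr(seq_len(n_days), function(d) {
    tibble::tibble(day = d, community = 1L,
                   id = as.character(seq_len(size[d])),
                   eb = TRUE, nfb = FALSE, lnd = FALSE)
  })
  tl <- structure(list(members = members,
                       sizes = dplyr::count(members, day, community,
                                            name = "size"),
                       n_days = n_days),
                  class = "community_timeline")
  dm <- community_distance_model(tl, tibble::tibble(day = seq_len(n_days),
                                                    distance_m = dist))
  means <- setNames(dm$bins$mean_size, as.character(dm$bins$bin))
  expect_gt(means[["300-900"]], means[[">900"]])
  expect_gt(means[["300-900"]], means[["<200"]])
  # constant size: zero correlation
  tl2 <- tl
  tl2$members <- dplyr::filter(members, id %in% c("1", "2", "3"))
  tl2$sizes <- dplyr::count(tl2$members, day, community, name = "size")
  dm2 <- community_distance_model(tl2, tibble::tibble(day = seq_len(n_days),
                                                      distance_m = dist))
  expect_equal(dm2$pearson$estimate, 0)
  expect_error(community_distance_model(tl, tibble::tibble(day = 1:5,
                                                           distance_m = 1:5)),
               class = "kinclique_invalid")
})

test_that("leave probability equals hand-counted ratios on a toy timeline", {
  # 5 individuals, 4 days; by construction:
  # high-contact members (rate 0.9) always leave, low (0.1) never do
  members <- dplyr::bind_rows(
    purrr::map_dfr(1:3, function(d) tibble::tibble(
      day = d, community = 1L, id = c("a", "b", "c", "d", "e"),
      eb = TRUE, nfb = FALSE,
      lnd = c(TRUE, FALSE, FALSE, TRUE, FALSE))),
    tibble::tibble(day = 4, community = 1L, id = c("b", "c", "e"),
                   eb = TRUE, nfb = FALSE, lnd = FALSE))
  tl <- structure(list(members = members,
                       sizes = dplyr::count(members, day, community,
                                            name = "size"),
                       n_days = 4L),
                  class = "community_timeline")
  contact <- tidyr::crossing(day = 1:3, id = c("a", "b", "c", "d", "e")) |>
    dplyr::mutate(rate = ifelse(id %in% c("a", "d"), 0.9, 0.1))
  lp <- leave_probability(tl, contact, breaks = 0.5)
  low <- dplyr::filter(lp, grepl("-Inf", bin))
  high <- dplyr::filter(lp, grepl("Inf]", bin))
  expect_equal(low$p_leave, 0)      # 9 low-contact member-days, 0 leavers
  expect_equal(low$n, 9)
  expect_equal(high$p_leave, 1)     # 6 high-contact member-days, all leave
  expect_equal(high$n, 6)
})
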