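# Independent oracles used to validate the package's implementations.
# Each one recomputes a quantity by a different route (enumeration,
# closed form, textbook recursion) than the code under test.

# random symmetric dyadic matrix with zero diagonal
rsym <- function(n, ids = sprintf("i%02d", seq_len(n))) {
  m <- matrix(stats::rnorm(n * n), n)
  m <- m + t(m)
  diag(m) <- 0
  dimnames(m) <- list(ids, ids)
  m
}

# pedigree numerator relationship by the recursive kinship-coefficient
# method (phi recursion), independent of the tabular method in the package
oracle_pedigree_relatedness <- function(ped) {
  sire <- stats::setNames(ped$sire, ped$id)
  dam <- stats::setNames(ped$dam, ped$id)
  depth <- function(i) {
    if (is.na(sire[[i]]) && is.na(dam[[i]])) return(0)
    1 + max(if (is.na(sire[[i]])) 0 else depth(sire[[i]]),
            if (is.na(dam[[i]])) 0 else depth(dam[[i]]))
  }
  memo <- new.env()
  phi <- function(a, b) {
    key <- paste(sort(c(a, b)), collapse = "|")
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (a == b) {
      if (is.na(sire[[a]]) || is.na(dam[[a]])) 0.5
      else 0.5 * (1 + phi(sire[[a]], dam[[a]]))
    } else {
      if (depth(a) < depth(b)) { tmp <- a; a <- b; b <- tmp }
      if (is.na(sire[[a]]) && is.na(dam[[a]])) 0
      else 0.5 * ((if (is.na(sire[[a]])) 0 else phi(sire[[a]], b)) +
                    (if (is.na(dam[[a]])) 0 else phi(dam[[a]], b)))
    }
    memo[[key]] <- val
    val
  }
  ids <- ped$id
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in seq_along(ids)) {
    for (j in seq_len(i)) m[i, j] <- m[j, i] <- 2 * phi(ids[i], ids[j])
  }
  m
}

# all set partitions of a character vector (for brute-force modularity)
set_partitions <- function(x) {
  if (length(x) == 1) return(list(list(x)))
  rest <- set_partitions(x[-1])
  out <- list()
  for (p in rest) {
    for (i in seq_along(p)) {
      q <- p
      q[[i]] <- c(x[1], q[[i]])
      out <- c(out, list(q))
    }
    out <- c(out, list(c(list(x[1]), p)))
  }
  out
}

# modularity by the elementwise definition Q = (1/2W) sum_ij
# (w_ij - k_i k_j / 2W) delta(c_i, c_j)
oracle_modularity <- function(w, member) {
  diag(w) <- 0
  w2 <- sum(w)
  kdeg <- rowSums(w)
  delta <- outer(member, member, "==")
  sum((w - outer(kdeg, kdeg) / w2) * delta) / w2
}

# brute-force clique percolation: enumerate k-subsets, test completeness,
# BFS over (k-1)-overlap adjacency
oracle_cpm <- function(edges, k) {
  nodes <- sort(unique(c(edges$id_a, edges$id_b)))
  if (length(nodes) < k) return(list())
  has_edge <- function(a, b) {
    any((edges$id_a == a & edges$id_b == b) |
          (edges$id_a == b & edges$id_b == a))
  }
  combs <- utils::combn(nodes, k, simplify = FALSE)
  cliques <- Filter(function(s) {
    all(utils::combn(s, 2, function(p) has_edge(p[1], p[2])))
  }, combs)
  if (length(cliques) == 0) return(list())
  nc <- length(cliques)
  adj <- matrix(FALSE, nc, nc)
  for (i in seq_len(nc)) {
    for (j in seq_len(nc)) {
      if (i != j) {
        adj[i, j] <- length(intersect(cliques[[i]], cliques[[j]])) == k - 1
      }
    }
  }
  comp <- rep(NA_integer_, nc)
  cid <- 0
  for (s in seq_len(nc)) {
    if (!is.na(comp[s])) next
    cid <- cid + 1
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cid
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comms <- unname(lapply(split(seq_len(nc), comp),
                         function(ix) sort(unique(unlist(cliques[ix])))))
  comms[order(vapply(comms, paste, "", collapse = "|"))]
}

# haversine closed form
oracle_haversine <- function(lon1, lat1, lon2, lat2, R = 6371000) {
  torad <- pi / 180
  dlat <- (lat2 - lat1) * torad
  dlon <- (lon2 - lon1) * torad
  a <- sin(dlat / 2)^2 + cos(lat1 * torad) * cos(lat2 * torad) * sin(dlon / 2)^2
  2 * R * asin(sqrt(pmin(a, 1)))
}

# partial correlation by least-squares residualization of the dyad vectors
oracle_partial_resid <- function(x, y, zs) {
  ut <- upper.tri(x)
  xv <- x[ut]; yv <- y[ut]
  if (length(zs) == 0) return(stats::cor(xv, yv))
  Z <- vapply(zs, function(m) m[ut], numeric(sum(ut)))
  rx <- stats::lm.fit(cbind(1, Z), xv)$residuals
  ry <- stats::lm.fit(cbind(1, Z), yv)$residuals
  stats::cor(rx, ry)
}

# exact Mann-Whitney U and two-sided p by full enumeration of group
# assignments
oracle_mann_whitney <- function(a, b) {
  u_stat <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  obs <- u_stat(a, b)
  pooled <- c(a, b)
  n <- length(a)
  combs <- utils::combn(length(pooled), n, simplify = FALSE)
  us <- vapply(combs, function(ix) u_stat(pooled[ix], pooled[-ix]),
               numeric(1))
  mu <- length(a) * length(b) / 2
  list(u = obs, p = mean(abs(us - mu) >= abs(obs - mu) - 1e-12))
}

# small deterministic scan fixture builder: rows are (scan, id_a, id_b,
# together)
make_scans <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(scan_id = r[[1]], id_a = r[[2]], id_b = r[[3]],
                   together = as.integer(r[[4]]))
  }))
}
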