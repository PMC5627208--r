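#' Dyadic matrices
#'
#' Most statistics in this package operate on individual-by-individual
#' matrices: HWI association, DAI grooming shares, pairwise relatedness,
#' win counts, and absolute age/rank differences. These are stored as plain
#' base matrices with individual identifiers as dimnames and a light
#' `dyad_matrix` class so that [generics::tidy()] and [ggplot2::autoplot()]
#' have something to dispatch on. Diagonals are never part of any statistic.
#'
#' @param x numeric matrix with identical row and column names.
#' @param directed logical; `FALSE` for symmetric association-type matrices.
#' @param type short label describing the quantity (e.g. `"hwi"`).
#' @return `dyad_matrix()` returns `x` with class `dyad_matrix` and the
#'   `directed`/`type` attributes set.
#' @examples
#' m <- matrix(c(0, .4, .4, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
#' dm <- dyad_matrix(m, directed = FALSE, type = "hwi")
#' tidy(dm)
#' @export
dyad_matrix <- function(x, directed = FALSE, type = "dyad") {
  x <- as.matrix(x)
  if (nrow(x) != ncol(x)) {
    rlang::abort("dyadic matrix must be square", class = "kinclique_invalid")
  }
  if (is.null(rownames(x)) && is.null(colnames(x))) {
    rownames(x) <- colnames(x) <- paste0("id", seq_len(nrow(x)))
  }
  if (is.null(rownames(x))) rownames(x) <- colnames(x)
  if (is.null(colnames(x))) colnames(x) <- rownames(x)
  if (!identical(rownames(x), colnames(x))) {
    rlang::abort("row and column labels must match", class = "kinclique_invalid")
  }
  structure(x, class = c("dyad_matrix", class(x)),
            directed = directed, type = type)
}

#' @export
print.dyad_matrix <- function(x, ...) {
  cat(sprintf("<dyad_matrix [%d x %d], type = %s, %s>\n",
              nrow(x), ncol(x), attr(x, "type"),
              if (isTRUE(attr(x, "directed"))) "directed" else "symmetric"))
  print(unclass_dyad(x), ...)
  invisible(x)
}

unclass_dyad <- function(x) {
  attr(x, "directed") <- NULL
  attr(x, "type") <- NULL
  class(x) <- "matrix"
  x
}

#' @rdname dyad_matrix
#' @param ... unused.
#' @export
tidy.dyad_matrix <- function(x, ...) {
  ids <- rownames(x)
  directed <- isTRUE(attr(x, "directed"))
  idx <- if (directed) which(row(x) != col(x)) else which(upper.tri(x))
  tibble::tibble(
    id_a = ids[row(x)[idx]],
    id_b = ids[col(x)[idx]],
    value = as.vector(x)[idx]
  )
}

#' @rdname dyad_matrix
#' @param object a `dyad_matrix`.
#' @export
autoplot.dyad_matrix <- function(object, ...) {
  df <- tidy(object)
  if (!isTRUE(attr(object, "directed"))) {
    df <- dplyr::bind_rows(df, dplyr::rename(df, id_a = "id_b", id_b = "id_a"))
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$id_a, .data$id_b, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = attr(object, "type")) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

# Strict upper-triangle vector, NA-free check left to callers.
upper_vec <- function(m) m[upper.tri(m)]

# Check two or more dyad matrices share an identical label ordering.
check_same_labels <- function(...) {
  mats <- list(...)
  ids <- rownames(mats[[1]])
  for (m in mats[-1]) {
    if (!identical(rownames(m), ids)) {
      rlang::abort("matrices must share an identical id ordering",
                   class = "kinclique_label_mismatch")
    }
  }
  invisible(ids)
}

# Absolute pairwise difference matrix from a named numeric vector; the
# standard way age and rank enter Mantel-type comparisons.
#' Absolute pairwise-difference matrix
#'
#' Turns a per-individual covariate (age in years, rank position, NDS) into
#' the symmetric dyadic distance matrix used by Mantel-type tests.
#'
#' @param values named numeric vector, one value per individual.
#' @param type label stored on the result.
#' @return symmetric [dyad_matrix()] of `|value_i - value_j|`.
#' @examples
#' pairwise_difference(c(a = 1, b = 3, c = 6), type = "age_diff")
#' @export
pairwise_difference <- function(values, type = "difference") {
  stopifnot(is.numeric(values), !is.null(names(values)))
  m <- abs(outer(values, values, "-"))
  dimnames(m) <- list(names(values), names(values))
  dyad_matrix(m, directed = FALSE, type = type)
}
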