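#' Genotype tables
#'
#' Diploid microsatellite calls for a set of individuals at a set of loci.
#' Internally two character matrices (one per allele copy, individuals by
#' loci); missing calls are `NA` in both copies. Allele order within a call
#' is not meaningful.
#'
#' @param calls long tibble with columns `id`, `locus`, `allele1`,
#'   `allele2` (character; both `NA` for missing).
#' @return an object of class `genotype_table`.
#' @examples
#' gt <- genotype_table(tibble::tibble(
#'   id = c("x", "y"), locus = "L1",
#'   allele1 = c("1", "2"), allele2 = c("2", "2")))
#' tidy(gt)
#' @export
genotype_table <- function(calls) {
  stopifnot(all(c("id", "locus", "allele1", "allele2") %in% names(calls)))
  ids <- unique(calls$id)
  loci <- unique(calls$locus)
  a1 <- a2 <- matrix(NA_character_, length(ids), length(loci),
                     dimnames = list(ids, loci))
  ri <- match(calls$id, ids)
  ci <- match(calls$locus, loci)
  a1[cbind(ri, ci)] <- as.character(calls$allele1)
  a2[cbind(ri, ci)] <- as.character(calls$allele2)
  one_missing <- xor(is.na(a1), is.na(a2))
  if (any(one_missing)) {
    rlang::abort("half-missing genotype calls are invalid",
                 class = "kinclique_invalid")
  }
  structure(list(a1 = a1, a2 = a2, ids = ids, loci = loci),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("<genotype_table: %d individuals x %d loci, %.1f%% missing>\n",
              length(x$ids), length(x$loci),
              100 * mean(is.na(x$a1))))
  invisible(x)
}

#' @rdname genotype_table
#' @param x a `genotype_table`.
#' @param ... unused.
#' @export
tidy.genotype_table <- function(x, ...) {
  tibble::tibble(
    id = rep(x$ids, times = length(x$loci)),
    locus = rep(x$loci, each = length(x$ids)),
    allele1 = as.vector(x$a1),
    allele2 = as.vector(x$a2)
  )
}

#' Read and write GenePop files
#'
#' Minimal GenePop (two- or three-digit allele codes) support: a title
#' line, one locus name per line (or comma-separated), `Pop` markers, then
#' `id ,  aaabbb ...` genotype rows. `000`/`00` codes mean missing.
#'
#' @param path file path.
#' @return `read_genepop()` returns a [genotype_table()]; allele labels are
#'   the integer codes with leading zeros stripped.
#' @export
read_genepop <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  header <- lines[-1]
  pop_at <- grep("^\\s*pop\\s*$", header, ignore.case = TRUE)
  if (length(pop_at) == 0) rlang::abort("no 'Pop' line found",
                                        class = "kinclique_invalid")
  locus_lines <- header[seq_len(pop_at[1] - 1)]
  loci <- trimws(unlist(strsplit(locus_lines, ",")))
  body <- header[-seq_len(pop_at[1])]
  body <- body[!grepl("^\\s*pop\\s*$", body, ignore.case = TRUE)]
  parts <- strsplit(body, ",")
  ids <- trimws(vapply(parts, `[[`, character(1), 1))
  geno <- lapply(parts, function(p) {
    codes <- strsplit(trimws(p[[2]]), "\\s+")[[1]]
    codes
  })
  width <- nchar(geno[[1]][1]) / 2
  calls <- purrr::map2_dfr(ids, geno, function(id, codes) {
    if (length(codes) != length(loci)) {
      rlang::abort(sprintf("individual %s: %d genotypes for %d loci",
                           id, length(codes), length(loci)),
                   class = "kinclique_invalid")
    }
    c1 <- substr(codes, 1, width)
    c2 <- substr(codes, width + 1, 2 * width)
    decode <- function(c_) {
      v <- as.integer(c_)
      ifelse(is.na(v) | v == 0, NA_character_, as.character(v))
    }
    tibble::tibble(id = id, locus = loci, allele1 = decode(c1),
                   allele2 = decode(c2))
  })
  genotype_table(calls)
}

#' @rdname read_genepop
#' @param genotypes a [genotype_table()].
#' @param title title line written as the first line.
#' @export
write_genepop <- function(genotypes, path, title = "kinclique genotypes") {
  g <- genotypes
  # per-locus integer codes: numeric labels kept, others coded by sort order
  code_col <- function(j) {
    obs <- c(g$a1[, j], g$a2[, j])
    v <- suppressWarnings(as.integer(obs))
    if (any(!is.na(obs) & is.na(v))) {
      v <- match(obs, sort(unique(obs[!is.na(obs)])))
    }
    if (any(v >= 1000, na.rm = TRUE)) {
      rlang::abort("allele codes above 999 cannot be written as GenePop",
                   class = "kinclique_invalid")
    }
    m <- sprintf("%03d", ifelse(is.na(v), 0L, v))
    n <- length(g$ids)
    paste0(m[seq_len(n)], m[n + seq_len(n)])
  }
  codes <- vapply(seq_along(g$loci), code_col, character(length(g$ids)))
  codes <- matrix(codes, nrow = length(g$ids))
  rows <- vapply(seq_along(g$ids), function(i) {
    paste0(g$ids[i], " ,  ", paste0(codes[i, ], collapse = " "))
  }, character(1))
  writeLines(c(title, g$loci, "Pop", rows), path)
  invisible(path)
}
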