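founder_ped <- function(n, prefix = "i") {
  tibble::tibble(id = paste0(prefix, seq_len(n)), sire = NA_character_,
                 dam = NA_character_)
}

test_that("EM leaves null frequency at zero when genotypes sit at Hardy-Weinberg", {
  # 100 individuals exactly at HWE for p = q = 0.5: 25 AA, 50 AB, 25 BB
  calls <- tibble::tibble(
    id = paste0("i", 1:100), locus = "L1",
    allele1 = c(rep("1", 25), rep("1", 50), rep("2", 25)),
    allele2 = c(rep("1", 25), rep("2", 50), rep("2", 25)))
  em <- estimate_allele_freqs_em(genotype_table(calls))
  expect_lt(em$L1$null, 5e-3)
  expect_equal(unname(em$L1$visible), c(0.5, 0.5), tolerance = 1e-2)
  expect_true(all(diff(em$L1$log_lik) >= -1e-8))
})

test_that("EM recovers a simulated null-allele frequency and keeps the simplex", {
  ped <- founder_ped(500)
  fr <- list(L1 = c("1" = 0.4, "2" = 0.4, ".null" = 0.2))
  g <- simulate_genotypes(ped, fr, seed = 9)
  em <- estimate_allele_freqs_em(g)
  expect_lt(abs(em$L1$null - 0.2), 0.05)
  expect_equal(sum(em$L1$visible) + em$L1$null, 1, tolerance = 1e-9)
  expect_true(all(diff(em$L1$log_lik) >= -1e-8))
})

test_that("null masking produces the closed-form observed-phenotype distribution", {
  # locus {A: 0.4, B: 0.4, null: 0.2}: P(obs AA) = pA^2 + 2 pA p0 = 0.32,
  # P(obs AB) = 2 pA pB = 0.32, P(missing) = p0^2 = 0.04
  ped <- founder_ped(4000)
  fr <- list(L1 = c("1" = 0.4, "2" = 0.4, ".null" = 0.2))
  g <- simulate_genotypes(ped, fr, seed = 5)
  aa <- mean(!is.na(g$a1) & g$a1 == "1" & g$a2 == "1")
  ab <- mean(!is.na(g$a1) & g$a1 != g$a2)
  miss <- mean(is.na(g$a1))
  expect_lt(abs(aa - 0.32), 0.025)
  expect_lt(abs(ab - 0.32), 0.025)
  expect_lt(abs(miss - 0.04), 0.012)
  # a het carrying the null is always recorded as a visible homozygote
  truth <- attr(g, "truth")
  carried <- xor(truth$a1 == ".null", truth$a2 == ".null")
  expect_true(all(g$a1[carried] == g$a2[carried]))
})

test_that("relatedness with zero null rate is identical with and without correction", {
  freqs <- simulate_allele_freqs(6, null_rates = 0, n_alleles = 5, seed = 2)
  ped <- dplyr::bind_rows(
    founder_ped(6),
    tibble::tibble(id = "kid", sire = "i1", dam = "i2"))
  g <- simulate_genotypes(ped, freqs, seed = 3)
  fr <- as_allele_frequencies(freqs)   # true frequencies, null share 0
  r1 <- lr_relatedness(g, fr, null_correction = TRUE)
  r0 <- lr_relatedness(g, fr, null_correction = FALSE)
  expect_equal(unclass(r1), unclass(r0), tolerance = 1e-9)
})

test_that("a dyad untyped at every locus is masked as NA", {
  calls <- tibble::tibble(
    id = rep(c("u", "v", "w"), each = 2),
    locus = rep(c("L1", "L2"), 3),
    allele1 = c("1", NA, NA, "1", "1", "2"),
    allele2 = c("2", NA, NA, "2", "1", "2"))
  g <- genotype_table(calls)
  em <- suppressWarnings(estimate_allele_freqs_em(g))
  r <- lr_relatedness(g, em, null_correction = FALSE)
  expect_true(is.na(r["u", "v"]))   # u typed only at L1, v only at L2
  expect_false(is.na(r["u", "w"]))
})

test_that("UPGMA merges by maximal mean relatedness with hand-checked heights", {
  m <- matrix(c(1, 0.5, 0.1,
                0.5, 1, 0.0,
                0.1, 0.0, 1), 3, 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  up <- upgma_relatedness(dyad_matrix(m, type = "relatedness"))
  expect_equal(up$merges$height, c(0.5, 0.05))
  expect_setequal(c(up$merges$cluster_a[1], up$merges$cluster_b[1]),
                  c("x", "y"))
  # two individuals: single merge at their relatedness
  m2 <- matrix(c(1, .3, .3, 1), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(upgma_relatedness(dyad_matrix(m2))$merges$height, 0.3)
})

test_that("UPGMA tree is invariant to input ordering and parses as newick", {
  set.seed(4)
  m <- rsym(6) / 5
  diag(m) <- 1
  up1 <- upgma_relatedness(dyad_matrix(m))
  perm <- sample(6)
  up2 <- upgma_relatedness(dyad_matrix(m[perm, perm]))
  expect_equal(up1$merges$height, up2$merges$height)
  skip_if_not_installed("ape")
  tr <- ape::read.tree(text = up1$newick)
  expect_setequal(tr$tip.label, rownames(m))
})

test_that("diversity statistics match closed forms", {
  # all heterozygous A/B, n = 50: Ho = 1, He = (2n/(2n-1)) * 0.5, F < 0
  calls <- tibble::tibble(id = paste0("i", 1:50), locus = "L1",
                          allele1 = "1", allele2 = "2")
  d <- diversity_stats(genotype_table(calls))
  expect_equal(d$ho, 1)
  expect_equal(d$he, 100 / 99 * 0.5)
  expect_equal(d$f, 1 - 1 / (100 / 99 * 0.5))
  # two individuals AA and BB
  calls2 <- tibble::tibble(id = c("a", "b"), locus = "L1",
                           allele1 = c("1", "2"), allele2 = c("1", "2"))
  d2 <- diversity_stats(genotype_table(calls2))
  expect_equal(d2$ho, 0)
  expect_equal(d2$na, 2)
  # monomorphic locus: F undefined
  calls3 <- tibble::tibble(id = c("a", "b"), locus = "L1",
                           allele1 = "1", allele2 = "1")
  d3 <- diversity_stats(genotype_table(calls3))
  expect_equal(d3$ho, 0)
  expect_equal(d3$he, 0)
  expect_true(is.na(d3$f))
})

test_that("HWE chi-squared equals hand arithmetic", {
  # AA = 30, AB = 40, BB = 30 with p = q = 0.5: expected (25, 50, 25),
  # X2 = 25/25 + 100/50 + 25/25 = 4
  calls <- tibble::tibble(
    id = paste0("i", 1:100), locus = "L1",
    allele1 = c(rep("1", 30), rep("1", 40), rep("2", 30)),
    allele2 = c(rep("1", 30), rep("2", 40), rep("2", 30)))
  h <- hwe_chisq(genotype_table(calls), "L1")
  expect_equal(h$statistic, 4)
  expect_equal(h$df, 1)
  # exact HWE proportions give statistic 0
  calls0 <- tibble::tibble(
    id = paste0("i", 1:100), locus = "L1",
    allele1 = c(rep("1", 25), rep("1", 50), rep("2", 25)),
    allele2 = c(rep("1", 25), rep("2", 50), rep("2", 25)))
  expect_equal(hwe_chisq(genotype_table(calls0), "L1")$statistic, 0)
  # all homozygotes, p = q = 0.5, n = 100: X2 = n (closed form)
  callsh <- tibble::tibble(
    id = paste0("i", 1:100), locus = "L1",
    allele1 = c(rep("1", 50), rep("2", 50)),
    allele2 = c(rep("1", 50), rep("2", 50)))
  # observed (50, 0, 50) vs expected (25, 50, 25): 25 + 50 + 25 = 100
  hh <- hwe_chisq(genotype_table(callsh), "L1")
  expect_equal(hh$statistic, 100)
  # monomorphic: no test
  mono <- tibble::tibble(id = c("a", "b"), locus = "L1",
                         allele1 = "1", allele2 = "1")
  expect_true(hwe_chisq(genotype_table(mono), "L1")$no_test)
})

test_that("GenePop files round-trip through write and read", {
  freqs <- simulate_allele_freqs(3, null_rates = 0, n_alleles = 4, seed = 8)
  g <- simulate_genotypes(founder_ped(8), freqs, missing_rate = 0.1, seed = 8)
  path <- withr::local_tempfile(fileext = ".gen")
  write_genepop(g, path)
  g2 <- read_genepop(path)
  expect_equal(g2$ids, g$ids)
  expect_equal(g2$loci, g$loci)
  expect_equal(is.na(g2$a1), is.na(g$a1))
  expect_equal(unname(g2$a1), unname(g$a1))
  expect_equal(unname(g2$a2), unname(g$a2))
})

test_that("within-family relatedness exceeds between-family on kin scenarios", {
  out <- recovery_run(31, n_scans = 300, n_groom_bouts = 100,
                      n_agonistic = 120)
  expect_gt(out$rel_within, out$rel_between)
})
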