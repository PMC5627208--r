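test_that("pedigree simulation honours family structure", {
  # one family of two: both founders, unrelated
  p2 <- simulate_pedigree(1, 2, seed = 1)
  expect_equal(nrow(p2$individuals), 2)
  expect_true(all(p2$individuals$founder))
  r2 <- pedigree_relatedness(p2$pedigree, p2$individuals$id)
  expect_equal(r2["F1_A", "F1_B"], 0)
  # three families of seven: 21 males, labels follow families
  p21 <- simulate_pedigree(3, c(7, 7, 7), seed = 2)
  expect_equal(nrow(p21$individuals), 21)
  expect_equal(unname(table(p21$individuals$family)), rep(7L, 3),
               ignore_attr = TRUE)
  # every family of >= 3 has at least one dyad with relatedness >= 0.25
  r21 <- pedigree_relatedness(p21$pedigree, p21$individuals$id)
  for (f in unique(p21$individuals$family)) {
    ids <- p21$individuals$id[p21$individuals$family == f]
    sub <- unclass(r21)[ids, ids]
    expect_gte(max(sub[upper.tri(sub)]), 0.25)
  }
  expect_error(simulate_pedigree(2, c(3, 0)), class = "kinclique_invalid")
})

test_that("pedigree relatedness agrees with the recursive kinship oracle", {
  # hand-built pedigree with full sibs, half sibs and grandparents
  ped <- tibble::tibble(
    id = c("gpa", "gma", "dad", "mom", "mom2", "kid1", "kid2", "kid3", "gkid"),
    sire = c(NA, NA, "gpa", NA, NA, "dad", "dad", "dad", "kid1"),
    dam = c(NA, NA, "gma", NA, NA, "mom", "mom", "mom2", "mom2"))
  a <- unclass(pedigree_relatedness(ped))
  o <- oracle_pedigree_relatedness(ped)
  expect_equal(a[rownames(o), colnames(o)], o, tolerance = 1e-12)
  expect_equal(a["kid1", "kid2"], 0.5)    # full sibs
  expect_equal(a["kid1", "kid3"], 0.25)   # paternal half sibs
  expect_equal(a["dad", "kid1"], 0.5)     # parent-offspring
  expect_equal(a["gpa", "kid1"], 0.25)    # grandparent
  # seeded family pedigrees agree with the oracle too (aligned order)
  p <- simulate_pedigree(2, c(5, 6), seed = 7)
  ids <- p$pedigree$id
  expect_equal(unclass(pedigree_relatedness(p$pedigree))[ids, ids],
               oracle_pedigree_relatedness(p$pedigree)[ids, ids],
               tolerance = 1e-12)
})

test_that("genotype transmission is Mendelian before null masking", {
  freqs <- simulate_allele_freqs(8, null_rates = 0.1, n_alleles = 4, seed = 3)
  sc <- herd_scenario(seed = 3)
  g <- simulate_genotypes(sc$pedigree, freqs, seed = 4)
  truth <- attr(g, "truth")
  ped <- sc$pedigree
  for (i in seq_along(truth$ids)) {
    id <- truth$ids[i]
    s <- ped$sire[ped$id == id]
    if (is.na(s)) next
    d <- ped$dam[ped$id == id]
    si <- match(s, truth$ids); di <- match(d, truth$ids)
    for (l in seq_along(truth$loci)) {
      kid <- c(truth$a1[i, l], truth$a2[i, l])
      parents <- c(truth$a1[si, l], truth$a2[si, l],
                   truth$a1[di, l], truth$a2[di, l])
      expect_true(all(kid %in% parents))
    }
  }
  expect_error(
    simulate_genotypes(ped, list(L1 = c("1" = 0.6, "2" = 0.5)), seed = 1),
    class = "kinclique_invalid")
})

test_that("generators are deterministic under a fixed seed", {
  sc1 <- herd_scenario(seed = 9)
  sc2 <- herd_scenario(seed = 9)
  expect_identical(sc1$individuals, sc2$individuals)
  b1 <- simulate_behaviour(sc1, n_scans = 60, n_groom_bouts = 30,
                           n_agonistic = 30)
  b2 <- simulate_behaviour(sc2, n_scans = 60, n_groom_bouts = 30,
                           n_agonistic = 30)
  expect_identical(b1, b2)
  d1 <- tempfile(); d2 <- tempfile()
  write_scenario_bundle(herd_scenario(n_families = 2, sizes = c(4, 4),
                                      n_loci = 4, n_days = 10, seed = 5),
                        d1, n_scans = 40, n_groom_bouts = 20,
                        n_agonistic = 20)
  write_scenario_bundle(herd_scenario(n_families = 2, sizes = c(4, 4),
                                      n_loci = 4, n_days = 10, seed = 5),
                        d2, n_scans = 40, n_groom_bouts = 20,
                        n_agonistic = 20)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("null behavioural effects give no kinship signal in the HWI matrix", {
  # type-I check: with all effects off, Mantel r between HWI and pedigree
  # relatedness rejects at about the nominal rate
  ps <- vapply(1:12, function(s) {
    sc <- herd_scenario(n_families = 2, sizes = c(6, 6), beta_kin = 0,
                        beta_age = 0, beta_rank = 0, subgroup_bonus = 0,
                        seed = 100 + s)
    beh <- simulate_behaviour(sc, n_scans = 150, n_groom_bouts = 30,
                              n_agonistic = 30)
    hwi <- compute_hwi(beh$scans)
    ids <- rownames(hwi)
    rel <- unclass(sc$relatedness)[ids, ids]
    mantel_test(hwi, dyad_matrix(rel), n_perm = 99,
                alternative = "greater")$p_value
  }, numeric(1))
  expect_gt(mean(ps), 0.2)             # far from systematic rejection
  expect_lt(mean(ps <= 0.05), 0.35)
})

test_that("behaviour simulation validates its inputs", {
  sc <- herd_scenario(seed = 1)
  expect_error(simulate_behaviour(sc, n_scans = 0),
               class = "kinclique_invalid")
  one <- herd_scenario(n_families = 1, sizes = 1, seed = 1)
  expect_error(simulate_behaviour(one), class = "kinclique_invalid")
})
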