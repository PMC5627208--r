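#' Simulate a kin-structured pedigree
#'
#' Builds the pedigree of a bachelor band organised into families (the
#' ground-truth all-male units). Each family holds up to two unrelated
#' founders; remaining members are offspring of founder 1, with the dam
#' being founder 2 or an unobserved outside female (probability
#' `half_sib_frac`), so families mix parent-offspring, full-sib and
#' paternal half-sib dyads. Outside dams appear in the pedigree (needed
#' for relatedness bookkeeping) but not among the band individuals.
#'
#' @param n_families number of families (>= 1).
#' @param sizes integer vector of family sizes (all >= 1).
#' @param seed integer seed.
#' @param half_sib_frac probability an offspring's dam is an outside
#'   female rather than the family founder dam (default 0.3).
#' @return list with `individuals` (tibble id, family, founder) and
#'   `pedigree` (tibble id, sire, dam with `NA` for founders, including
#'   unobserved dams).
#' @export
simulate_pedigree <- function(n_families, sizes, seed = 1,
                              half_sib_frac = 0.3) {
  if (n_families < 1 || length(sizes) != n_families || any(sizes < 1)) {
    rlang::abort("need n_families >= 1 and a positive size per family",
                 class = "kinclique_invalid")
  }
  withr_seed(seed)
  ped <- list(); inds <- list()
  for (f in seq_len(n_families)) {
    fam <- sprintf("F%d", f)
    s <- sizes[f]
    f1 <- sprintf("%s_A", fam)
    ped[[length(ped) + 1]] <- tibble::tibble(id = f1, sire = NA, dam = NA)
    inds[[length(inds) + 1]] <- tibble::tibble(id = f1, family = fam,
                                               founder = TRUE)
    if (s >= 2) {
      f2 <- sprintf("%s_B", fam)
      ped[[length(ped) + 1]] <- tibble::tibble(id = f2, sire = NA, dam = NA)
      inds[[length(inds) + 1]] <- tibble::tibble(id = f2, family = fam,
                                                 founder = TRUE)
      if (s > 2) {
        for (o in seq_len(s - 2)) {
          oid <- sprintf("%s_O%d", fam, o)
          if (stats::runif(1) < half_sib_frac) {
            dam <- sprintf("%s_X%d", fam, o)   # unobserved outside dam
            ped[[length(ped) + 1]] <- tibble::tibble(id = dam, sire = NA,
                                                     dam = NA)
          } else {
            dam <- f2
          }
          ped[[length(ped) + 1]] <- tibble::tibble(id = oid, sire = f1,
                                                   dam = dam)
          inds[[length(inds) + 1]] <- tibble::tibble(id = oid, family = fam,
                                                     founder = FALSE)
        }
      }
    }
  }
  list(individuals = dplyr::bind_rows(inds),
       pedigree = dplyr::mutate(dplyr::bind_rows(ped),
                                sire = as.character(.data$sire),
                                dam = as.character(.data$dam)))
}

# All generator functions are explicitly seeded; the seed argument fully
# determines their output (the determinism contract).
withr_seed <- function(seed) set.seed(as.integer(seed) %% .Machine$integer.max)

#' Additive pedigree relatedness
#'
#' Numerator (additive) relationship matrix by the tabular method,
#' restricted to the requested individuals: parent-offspring and full sibs
#' 0.5, half sibs 0.25, founders 0.
#'
#' @param pedigree tibble with `id`, `sire`, `dam` (`NA` for founders),
#'   ancestors listed (any order; sorted internally).
#' @param ids individuals to report (default: all).
#' @return symmetric [dyad_matrix()] of pedigree relatedness (diagonal
#'   holds 1 + inbreeding).
#' @export
pedigree_relatedness <- function(pedigree, ids = NULL) {
  ped <- pedigree
  # topological order: founders first
  ordered <- character(0)
  remaining <- ped
  while (nrow(remaining) > 0) {
    ready <- (is.na(remaining$sire) | remaining$sire %in% ordered) &
      (is.na(remaining$dam) | remaining$dam %in% ordered)
    if (!any(ready)) rlang::abort("pedigree is cyclic or incomplete",
                                  class = "kinclique_invalid")
    ordered <- c(ordered, remaining$id[ready])
    remaining <- remaining[!ready, , drop = FALSE]
  }
  n <- length(ordered)
  A <- matrix(0, n, n, dimnames = list(ordered, ordered))
  sire <- ped$sire[match(ordered, ped$id)]
  dam <- ped$dam[match(ordered, ped$id)]
  for (i in seq_len(n)) {
    si <- match(sire[i], ordered); di <- match(dam[i], ordered)
    A[i, i] <- 1 + 0.5 * (if (!is.na(si) && !is.na(di)) A[si, di] else 0)
    if (i > 1) {
      for (j in seq_len(i - 1)) {
        aj <- 0
        if (!is.na(si)) aj <- aj + 0.5 * A[j, si]
        if (!is.na(di)) aj <- aj + 0.5 * A[j, di]
        A[i, j] <- A[j, i] <- aj
      }
    }
  }
  ids <- ids %||% ordered
  dyad_matrix(A[ids, ids, drop = FALSE], directed = FALSE,
              type = "pedigree_relatedness")
}

#' Assemble a synthetic herd scenario
#'
#' The ground-truth object every downstream stage is validated against:
#' a kin-structured pedigree with ages and an age-linear true rank,
#' behavioural effect sizes (log-odds units), locus count and per-locus
#' null-allele rates. Defaults emulate a bachelor band of 21 males in 3
#' families typed at 19 tetranucleotide microsatellites, observed over 90
#' days.
#'
#' @param n_families,sizes passed to [simulate_pedigree()].
#' @param beta_kin,beta_age,beta_rank log-odds effects of pedigree
#'   relatedness, age difference (per year) and rank difference (per
#'   position) on dyadic co-presence.
#' @param subgroup_bonus log-odds bonus for same-family dyads.
#' @param b0 baseline log-odds of dyadic co-presence in a scan.
#' @param n_loci number of microsatellite loci.
#' @param null_rates per-locus null-allele frequencies (recycled).
#' @param n_days observation span in days.
#' @param age_cutoffs juvenile/sub-adult and sub-adult/adult age bounds in
#'   years (defaults 3.5 and 7).
#' @param p_win probability the older individual wins an agonistic bout.
#' @param seed integer master seed; stage streams use fixed offsets of it.
#' @return object of class `herd_scenario`.
#' @export
herd_scenario <- function(n_families = 3, sizes = c(7, 7, 7),
                          beta_kin = 2, beta_age = 0.1, beta_rank = 0.02,
                          subgroup_bonus = 0.8, b0 = -2.35,
                          n_loci = 19, null_rates = 0.05, n_days = 90,
                          age_cutoffs = c(3.5, 7), p_win = 0.9, seed = 1) {
  stopifnot(all(null_rates >= 0 & null_rates < 1))
  base <- simulate_pedigree(n_families, sizes, seed = seed * 13 + 1)
  withr_seed(seed * 13 + 2)
  inds <- base$individuals
  # founders are adults; offspring span juvenile to sub-adult ages
  inds$age_years <- ifelse(inds$founder,
                           stats::runif(nrow(inds), 8, 16),
                           stats::runif(nrow(inds), 1, 7))
  inds$age_class <- cut(inds$age_years, c(-Inf, age_cutoffs, Inf),
                        labels = c("JM", "SAM", "AM"))
  inds$true_rank <- rank(-inds$age_years, ties.method = "first")
  null_rates <- rep_len(null_rates, n_loci)
  structure(list(
    individuals = inds, pedigree = base$pedigree,
    relatedness = pedigree_relatedness(base$pedigree, inds$id),
    effects = list(beta_kin = beta_kin, beta_age = beta_age,
                   beta_rank = beta_rank, subgroup_bonus = subgroup_bonus,
                   b0 = b0, p_win = p_win),
    n_loci = n_loci, null_rates = null_rates, n_days = n_days,
    age_cutoffs = age_cutoffs, seed = seed),
    class = "herd_scenario")
}

#' @export
print.herd_scenario <- function(x, ...) {
  cat(sprintf("<herd_scenario: %d males in %d families, %d loci, %d days, seed %d>\n",
              nrow(x$individuals), length(unique(x$individuals$family)),
              x$n_loci, x$n_days, x$seed))
  invisible(x)
}

#' Default per-locus allele frequencies for simulation
#'
#' Draws a seeded set of visible-allele frequencies per locus (Dirichlet
#' via normalized gamma deviates over `n_alleles` visible alleles), with
#' the requested null-allele share carved out.
#'
#' @param n_loci number of loci.
#' @param null_rates per-locus null frequency (recycled).
#' @param n_alleles visible alleles per locus (recycled, default 5).
#' @param seed integer seed.
#' @return list of per-locus named frequency vectors; the null allele is
#'   named `".null"`.
#' @export
simulate_allele_freqs <- function(n_loci, null_rates = 0, n_alleles = 5,
                                  seed = 1) {
  withr_seed(seed)
  null_rates <- rep_len(null_rates, n_loci)
  n_alleles <- rep_len(n_alleles, n_loci)
  out <- lapply(seq_len(n_loci), function(l) {
    g <- stats::rgamma(n_alleles[l], shape = 2)
    p <- g / sum(g) * (1 - null_rates[l])
    stats::setNames(c(p, null_rates[l]),
                    c(as.character(seq_len(n_alleles[l])), ".null"))
  })
  names(out) <- sprintf("L%02d", seq_len(n_loci))
  out
}

#' Simulate genotypes down a pedigree with null-allele masking
#'
#' Founders draw two alleles from the locus frequencies; offspring receive
#' one random allele from each parent (Mendelian transmission). Scoring
#' then mimics microsatellite amplification: a heterozygote carrying the
#' null allele is recorded as a visible-allele homozygote, a null/null
#' genotype as missing, and further calls drop out at `missing_rate`.
#'
#' @param pedigree tibble (`id`, `sire`, `dam`).
#' @param allele_freqs list of per-locus frequency vectors (visible alleles
#'   plus optional `".null"` entry); each must sum to 1 (tolerance 1e-9).
#' @param missing_rate additional random missingness (default 0).
#' @param seed integer seed.
#' @param ids individuals to report (default all pedigree members).
#' @return a [genotype_table()]; the unmasked true genotypes are kept in
#'   attribute `truth` (a second `genotype_table` where the null allele is
#'   the label `".null"`).
#' @export
simulate_genotypes <- function(pedigree, allele_freqs, missing_rate = 0,
                               seed = 1, ids = NULL) {
  sums <- vapply(allele_freqs, sum, numeric(1))
  if (any(abs(sums - 1) > 1e-9)) {
    rlang::abort("allele frequencies must sum to 1 per locus",
                 class = "kinclique_invalid")
  }
  withr_seed(seed)
  # topological order via pedigree_relatedness' ordering rules
  ordered <- rownames(unclass_dyad(pedigree_relatedness(pedigree)))
  loci <- names(allele_freqs)
  n <- length(ordered); L <- length(loci)
  t1 <- t2 <- matrix(NA_character_, n, L, dimnames = list(ordered, loci))
  sire <- pedigree$sire[match(ordered, pedigree$id)]
  dam <- pedigree$dam[match(ordered, pedigree$id)]
  for (l in seq_len(L)) {
    f <- allele_freqs[[l]]
    for (i in seq_len(n)) {
      if (is.na(sire[i])) {
        draw <- sample(names(f), 2, replace = TRUE, prob = f)
      } else {
        si <- match(sire[i], ordered); di <- match(dam[i], ordered)
        draw <- c(sample(c(t1[si, l], t2[si, l]), 1),
                  sample(c(t1[di, l], t2[di, l]), 1))
      }
      t1[i, l] <- draw[1]; t2[i, l] <- draw[2]
    }
  }
  ids <- ids %||% ordered
  t1 <- t1[ids, , drop = FALSE]; t2 <- t2[ids, , drop = FALSE]
  # null masking + random dropout
  o1 <- t1; o2 <- t2
  null1 <- o1 == ".null"; null2 <- o2 == ".null"
  o1[null1] <- o2[null1]         # survivor allele shows as homozygote
  o2[null2] <- o1[null2]
  both_null <- null1 & null2
  o1[both_null] <- NA; o2[both_null] <- NA
  if (missing_rate > 0) {
    drop <- matrix(stats::runif(length(o1)) < missing_rate, nrow(o1))
    o1[drop] <- NA; o2[drop] <- NA
  }
  truth <- matrices_to_genotypes(t1, t2)
  out <- matrices_to_genotypes(o1, o2)
  attr(out, "truth") <- truth
  out
}

matrices_to_genotypes <- function(a1, a2) {
  swap <- !is.na(a1) & a1 > a2
  tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  structure(list(a1 = a1, a2 = a2, ids = rownames(a1),
                 loci = colnames(a1)),
            class = "genotype_table")
}

# dyadic log-odds of co-presence under the scenario's effect sizes
scenario_linear_predictor <- function(scenario) {
  inds <- scenario$individuals
  eff <- scenario$effects
  r <- unclass_dyad(scenario$relatedness)
  diag(r) <- 0
  dage <- abs(outer(inds$age_years, inds$age_years, "-"))
  drank <- abs(outer(inds$true_rank, inds$true_rank, "-"))
  same <- outer(inds$family, inds$family, "==")
  lp <- eff$b0 + eff$beta_kin * r - eff$beta_age * dage -
    eff$beta_rank * drank + eff$subgroup_bonus * same
  dimnames(lp) <- list(inds$id, inds$id)
  lp
}

#' Simulate behavioural event streams for a herd
#'
#' Generates the three observational tables downstream stages consume.
#' Per scan each individual is sighted with probability `p_obs`; each
#' sighted dyad is together with probability
#' logistic(b0 + beta_kin r_ij - beta_age |age_i - age_j| -
#' beta_rank |rank_i - rank_j| + bonus same_family). Grooming bouts pick
#' ordered dyads with probability proportional to exp of the same linear
#' predictor. Agonistic bouts pick dyads uniformly; the older individual
#' wins with probability `p_win` (the winner is the actor of a decided
#' bout), behaviour labels follow `behaviour_probs` over the agonistic
#' ethogram.
#'
#' @param scenario a [herd_scenario()].
#' @param n_scans,n_groom_bouts,n_agonistic event counts (all > 0).
#' @param p_obs per-scan sighting probability (default 0.95).
#' @param behaviour_probs probabilities over [agonistic_ethogram()].
#' @param p_undecided share of agonistic bouts with no clear outcome.
#' @param day_offset optional numeric vector of per-day log-odds offsets
#'   added to the co-presence predictor (length `n_days`); how inter-band
#'   distance modulates cohesion (see [distance_cohesion_offset()]).
#' @param seed integer seed (default: scenario seed offset).
#' @return list of tibbles `scans`, `grooming`, `agonistic`; scans carry
#'   `scan_id`, `day`, `id_a`, `id_b`, `together` (sighted dyads only).
#' @export
simulate_behaviour <- function(scenario, n_scans = 1500,
                               n_groom_bouts = 600, n_agonistic = 800,
                               p_obs = 0.95,
                               behaviour_probs = c(0.0059, 0.0191, 0.0169,
                                                   0.0925, 0.0597, 0.8059),
                               p_undecided = 0.05, day_offset = NULL,
                               seed = scenario$seed * 13 + 3) {
  inds <- scenario$individuals
  n <- nrow(inds)
  if (n < 2) rlang::abort("scenario needs at least 2 individuals",
                          class = "kinclique_invalid")
  if (min(n_scans, n_groom_bouts, n_agonistic) < 1) {
    rlang::abort("event counts must be positive", class = "kinclique_invalid")
  }
  withr_seed(seed)
  lp <- scenario_linear_predictor(scenario)
  ids <- inds$id
  ut <- which(upper.tri(lp), arr.ind = TRUE)
  lp_dyad <- lp[ut]
  nd <- nrow(ut)
  scan_day <- ceiling(seq_len(n_scans) * scenario$n_days / n_scans)
  offset <- if (is.null(day_offset)) rep(0, scenario$n_days) else
    rep_len(day_offset, scenario$n_days)
  # one big scan-by-dyad grid, vectorized draws
  sighted <- matrix(stats::runif(n_scans * n) < p_obs, n_scans, n)
  keep <- sighted[, ut[, 1]] & sighted[, ut[, 2]]   # n_scans x nd
  lp_grid <- outer(offset[scan_day], lp_dyad, "+")
  together <- matrix(stats::runif(n_scans * nd), n_scans, nd) <
    1 / (1 + exp(-lp_grid))
  idx <- which(keep, arr.ind = TRUE)
  scans <- tibble::tibble(
    scan_id = idx[, 1], day = scan_day[idx[, 1]],
    id_a = ids[ut[idx[, 2], 1]], id_b = ids[ut[idx[, 2], 2]],
    together = as.integer(together[idx]))
  scans <- dplyr::arrange(scans, .data$scan_id, .data$id_a, .data$id_b)

  # grooming: ordered dyads by softmax of the linear predictor
  w <- exp(lp); diag(w) <- 0
  pick <- sample.int(n * n, n_groom_bouts, replace = TRUE,
                     prob = as.vector(w))
  gi <- (pick - 1) %% n + 1
  gj <- (pick - 1) %/% n + 1
  grooming <- tibble::tibble(
    day = sample.int(scenario$n_days, n_groom_bouts, replace = TRUE),
    initiator = ids[gi], recipient = ids[gj],
    duration_s = round(stats::rgamma(n_groom_bouts, shape = 1.8,
                                     scale = 104)))
  grooming <- dplyr::arrange(grooming, .data$day)

  # agonism: uniform dyads, older individual wins with p_win
  ai <- sample.int(n, n_agonistic, replace = TRUE)
  aj <- vapply(ai, function(i) sample(seq_len(n)[-i], 1), integer(1))
  older_first <- inds$age_years[ai] >= inds$age_years[aj]
  older_wins <- stats::runif(n_agonistic) < scenario$effects$p_win
  winner <- ifelse(older_first == older_wins, ai, aj)
  loser <- ifelse(winner == ai, aj, ai)
  agonistic <- tibble::tibble(
    day = sample.int(scenario$n_days, n_agonistic, replace = TRUE),
    actor = ids[winner], recipient = ids[loser],
    behaviour = sample(agonistic_ethogram(), n_agonistic, replace = TRUE,
                       prob = behaviour_probs),
    outcome = ifelse(stats::runif(n_agonistic) < p_undecided,
                     "undecided", "decided"))
  agonistic <- dplyr::arrange(agonistic, .data$day)
  list(scans = scans, grooming = grooming, agonistic = agonistic)
}

#' Default inter-band distance profile
#'
#' A smooth 30-day oscillation between roughly 100 m and 1100 m,
#' exercising every distance regime the cohesion model distinguishes.
#'
#' @param n_days number of days.
#' @return numeric vector of daily AMB-BB distances in metres.
#' @export
default_distance_profile <- function(n_days) {
  600 + 500 * sin(2 * pi * seq_len(n_days) / 30)
}

#' Cohesion offset as a function of inter-band distance
#'
#' Log-odds offset added to dyadic co-presence by the distance between the
#' bachelor band and the breeding band: cohesion peaks at intermediate
#' separation (300-900 m), drops when the bands drift far apart, and
#' collapses steeply within 200 m, where males abandon alliances for
#' individual courtship opportunities.
#'
#' @param distance_m numeric distances in metres.
#' @return numeric log-odds offsets, one per distance.
#' @export
distance_cohesion_offset <- function(distance_m) {
  dplyr::case_when(
    distance_m < 200 ~ -1.2,
    distance_m < 300 ~ -0.2,
    distance_m <= 900 ~ 0.5,
    TRUE ~ -0.5
  )
}

#' Simulate GPS fix tables for two bands
#'
#' Places the all-male band at a fixed base location and the breeding band
#' due east at `distance_profile(day)` metres, then scatters `n_fixes`
#' fixes per band per day with isotropic jitter (metres converted to
#' degrees at the base latitude). WGS84 lon/lat output.
#'
#' @param n_days number of days.
#' @param distance_profile function day -> separation in metres (>= 0), or
#'   a numeric vector of length `n_days`.
#' @param jitter fix scatter s.d. in metres (>= 0).
#' @param n_fixes fixes per band per day.
#' @param base_lon,base_lat AMB base position.
#' @param seed integer seed.
#' @return list of tibbles `amb`, `bb` with `day`, `lon`, `lat`.
#' @export
simulate_gps <- function(n_days, distance_profile, jitter = 20,
                         n_fixes = 5, base_lon = 107.5, base_lat = 33.5,
                         seed = 1) {
  if (jitter < 0) rlang::abort("jitter must be >= 0",
                               class = "kinclique_invalid")
  dist_m <- if (is.function(distance_profile)) {
    vapply(seq_len(n_days), distance_profile, numeric(1))
  } else rep_len(distance_profile, n_days)
  if (any(dist_m < 0)) rlang::abort("distances must be >= 0",
                                    class = "kinclique_invalid")
  withr_seed(seed)
  m_per_deg_lat <- 111194.9   # pi * 6371000 / 180
  m_per_deg_lon <- m_per_deg_lat * cos(base_lat * pi / 180)
  one_band <- function(lon0, lat0_fn) {
    purrr::map_dfr(seq_len(n_days), function(d) {
      tibble::tibble(
        day = d,
        lon = lon0(d) + stats::rnorm(n_fixes, 0, jitter / m_per_deg_lon),
        lat = base_lat + stats::rnorm(n_fixes, 0, jitter / m_per_deg_lat))
    })
  }
  amb <- one_band(function(d) base_lon, NULL)
  bb <- one_band(function(d) base_lon + dist_m[d] / m_per_deg_lon, NULL)
  list(amb = amb, bb = bb)
}

#' Write a complete synthetic observation bundle to disk
#'
#' Emits the file set a field study would deposit: `scans.csv`,
#' `grooming.csv`, `agonistic.csv`, genotypes in GenePop format
#' (`genotypes.gen`), `gps_amb.csv` / `gps_bb.csv`, and `truth.json`
#' describing the scenario ground truth.
#'
#' @param scenario a [herd_scenario()].
#' @param dir output directory (created if needed).
#' @param ... passed to [simulate_behaviour()].
#' @return invisibly, the list of written paths.
#' @export
write_scenario_bundle <- function(scenario, dir, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  profile <- default_distance_profile(scenario$n_days)
  beh <- simulate_behaviour(scenario,
                            day_offset = distance_cohesion_offset(profile),
                            ...)
  freqs <- simulate_allele_freqs(scenario$n_loci, scenario$null_rates,
                                 seed = scenario$seed * 13 + 4)
  geno <- simulate_genotypes(scenario$pedigree, freqs,
                             seed = scenario$seed * 13 + 5,
                             ids = scenario$individuals$id)
  gps <- simulate_gps(scenario$n_days, profile,
                      seed = scenario$seed * 13 + 6)
  paths <- list(
    scans = file.path(dir, "scans.csv"),
    grooming = file.path(dir, "grooming.csv"),
    agonistic = file.path(dir, "agonistic.csv"),
    genotypes = file.path(dir, "genotypes.gen"),
    gps_amb = file.path(dir, "gps_amb.csv"),
    gps_bb = file.path(dir, "gps_bb.csv"),
    truth = file.path(dir, "truth.json"))
  utils::write.csv(beh$scans, paths$scans, row.names = FALSE)
  utils::write.csv(beh$grooming, paths$grooming, row.names = FALSE)
  utils::write.csv(beh$agonistic, paths$agonistic, row.names = FALSE)
  write_genepop(geno, paths$genotypes)
  utils::write.csv(gps$amb, paths$gps_amb, row.names = FALSE)
  utils::write.csv(gps$bb, paths$gps_bb, row.names = FALSE)
  truth <- list(
    individuals = scenario$individuals,
    effects = scenario$effects,
    n_loci = scenario$n_loci, null_rates = scenario$null_rates,
    n_days = scenario$n_days, seed = scenario$seed)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
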