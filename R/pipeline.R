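#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis in one list. All
#' thresholds surface here with their defaults: the sociogram display
#' cut-offs (HWI 0.17, DAI 0.19), the clique size `k` and edge threshold
#' `w_star` of the community stage, the affiliation-memory half-life, and
#' the permutation budget. Inputs are either a [herd_scenario()] (synthetic
#' mode) or a directory of observation files as written by
#' [write_scenario_bundle()].
#'
#' @param scenario optional [herd_scenario()].
#' @param input_dir optional directory with scans.csv, grooming.csv,
#'   agonistic.csv, genotypes.gen, gps_amb.csv, gps_bb.csv.
#' @param hwi_edge,dai_edge sociogram display thresholds.
#' @param k,w_star,half_life_days community-stage parameters.
#' @param n_perm permutations for all permutation tests.
#' @param seed master integer seed.
#' @param out_dir optional directory for report artefacts.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(scenario = NULL, input_dir = NULL,
                            hwi_edge = 0.17, dai_edge = 0.19,
                            k = 3, w_star = 2, half_life_days = 14,
                            n_perm = 999, seed = 1, out_dir = NULL) {
  if (is.null(scenario) && is.null(input_dir)) {
    rlang::abort("provide a scenario or an input_dir",
                 class = "kinclique_invalid")
  }
  stopifnot(hwi_edge >= 0, dai_edge >= 0, w_star >= 0, k >= 3,
            n_perm >= 1, seed == as.integer(seed))
  structure(list(scenario = scenario, input_dir = input_dir,
                 hwi_edge = hwi_edge, dai_edge = dai_edge, k = k,
                 w_star = w_star, half_life_days = half_life_days,
                 n_perm = n_perm, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Validate pipeline inputs
#'
#' Checks a file-based configuration before running: files exist and
#' parse, behavioural IDs are consistent with the genotype table,
#' duplicate records are flagged, and behavioural dates fall inside the
#' GPS coverage (a warning, not an error). Structured per-file diagnostics
#' are returned rather than thrown.
#'
#' @param config a [pipeline_config()] with `input_dir` set.
#' @return tibble with columns `file`, `severity` (`"error"`/`"warning"`),
#'   `message`; zero rows means a clean bundle.
#' @export
validate_inputs <- function(config) {
  issues <- list()
  note <- function(file, severity, message) {
    issues[[length(issues) + 1]] <<- tibble::tibble(
      file = file, severity = severity, message = message)
  }
  if (is.null(config$input_dir)) {
    return(tibble::tibble(file = character(), severity = character(),
                          message = character()))
  }
  need <- c("scans.csv", "grooming.csv", "agonistic.csv", "genotypes.gen",
            "gps_amb.csv", "gps_bb.csv")
  paths <- file.path(config$input_dir, need)
  missing <- !file.exists(paths)
  for (f in need[missing]) note(f, "error", "file missing")
  if (any(missing)) return(dplyr::bind_rows(issues))
  scans <- utils::read.csv(paths[1])
  grooming <- utils::read.csv(paths[2])
  agonistic <- utils::read.csv(paths[3])
  geno <- read_genepop(paths[4])
  gps_amb <- utils::read.csv(paths[5])
  gps_bb <- utils::read.csv(paths[6])
  known <- geno$ids
  check_ids <- function(tbl, cols, file) {
    for (col in cols) {
      bad <- which(!(tbl[[col]] %in% known))
      for (line in utils::head(bad, 5)) {
        note(file, "error",
             sprintf("line %d: id '%s' not genotyped", line + 1,
                     tbl[[col]][line]))
      }
      if (length(bad) > 5) {
        note(file, "error", sprintf("...and %d more unknown ids in %s",
                                    length(bad) - 5, col))
      }
    }
  }
  check_ids(scans, c("id_a", "id_b"), "scans.csv")
  check_ids(grooming, c("initiator", "recipient"), "grooming.csv")
  check_ids(agonistic, c("actor", "recipient"), "agonistic.csv")
  dup <- duplicated(scans)
  if (any(dup)) note("scans.csv", "warning",
                     sprintf("%d duplicate records", sum(dup)))
  gps_days <- range(c(gps_amb$day, gps_bb$day))
  out_of_range <- scans$day < gps_days[1] | scans$day > gps_days[2]
  if (any(out_of_range)) {
    note("scans.csv", "warning",
         sprintf("%d scans outside GPS day range", sum(out_of_range)))
  }
  if (length(issues) == 0) {
    tibble::tibble(file = character(), severity = character(),
                   message = character())
  } else dplyr::bind_rows(issues)
}

# outside-contact rate per member-day: share of an individual's together
# events that day whose partner was outside all of its communities.
outside_contact_rates <- function(timeline, together_events) {
  members_by_day <- split(timeline$members, timeline$members$day)
  ev <- together_events
  rows <- timeline$members |> dplyr::distinct(.data$day, .data$id)
  rate <- numeric(nrow(rows))
  for (r in seq_len(nrow(rows))) {
    d <- rows$day[r]; who <- rows$id[r]
    mday <- members_by_day[[as.character(d)]]
    own <- unique(mday$id[mday$community %in%
                            mday$community[mday$id == who]])
    e <- ev[ev$day == d & (ev$id_a == who | ev$id_b == who), , drop = FALSE]
    if (nrow(e) == 0) { rate[r] <- 0; next }
    partner <- ifelse(e$id_a == who, e$id_b, e$id_a)
    rate[r] <- mean(!(partner %in% own))
  }
  dplyr::mutate(rows, rate = rate)
}

#' Run the full analysis pipeline
#'
#' Executes affiliation, dominance, kinship, community, HPMT and ethogram
#' stages in order on a synthetic scenario or a file bundle, and returns a
#' single report. With `out_dir` set in the config, a JSON report plus CSV
#' and GraphML artefacts are written. Identical config and seed give an
#' identical report.
#'
#' @param config a [pipeline_config()].
#' @param n_scans,n_groom_bouts,n_agonistic event counts for synthetic
#'   mode (ignored when reading files).
#' @return object of class `pipeline_report` (a named list of stage
#'   results plus the config echo).
#' @export
run_pipeline <- function(config, n_scans = 1500, n_groom_bouts = 600,
                         n_agonistic = 800) {
  stage <- "inputs"
  tryCatch({
    if (!is.null(config$scenario)) {
      sc <- config$scenario
      profile <- default_distance_profile(sc$n_days)
      beh <- simulate_behaviour(sc, n_scans = n_scans,
                                n_groom_bouts = n_groom_bouts,
                                n_agonistic = n_agonistic,
                                day_offset = distance_cohesion_offset(profile))
      freqs_true <- simulate_allele_freqs(sc$n_loci, sc$null_rates,
                                          seed = sc$seed * 13 + 4)
      geno <- simulate_genotypes(sc$pedigree, freqs_true,
                                 seed = sc$seed * 13 + 5,
                                 ids = sc$individuals$id)
      gps <- simulate_gps(sc$n_days, profile, seed = sc$seed * 13 + 6)
      ages <- stats::setNames(sc$individuals$age_years, sc$individuals$id)
    } else {
      dir <- config$input_dir
      beh <- list(
        scans = tibble::as_tibble(utils::read.csv(file.path(dir, "scans.csv"))),
        grooming = tibble::as_tibble(utils::read.csv(file.path(dir, "grooming.csv"))),
        agonistic = tibble::as_tibble(utils::read.csv(file.path(dir, "agonistic.csv"))))
      geno <- read_genepop(file.path(dir, "genotypes.gen"))
      gps <- list(amb = utils::read.csv(file.path(dir, "gps_amb.csv")),
                  bb = utils::read.csv(file.path(dir, "gps_bb.csv")))
      ages <- NULL
      sc <- NULL
    }

    stage <- "affiliation"
    hwi <- compute_hwi(beh$scans)
    dai <- compute_dai(beh$grooming, ids = rownames(hwi))
    partition <- cluster_subgroups(hwi)

    stage <- "dominance"
    wins <- build_conflict_matrix(beh$agonistic, ids = rownames(hwi))
    dom <- david_scores(wins)
    steep <- hierarchy_steepness(dom, n_perm = config$n_perm,
                                 seed = config$seed + 11)
    linear <- hierarchy_linearity(wins, n_perm = config$n_perm,
                                  seed = config$seed + 12)

    stage <- "kinship"
    freqs <- estimate_allele_freqs_em(geno)
    rel <- lr_relatedness(geno, freqs, null_correction = TRUE)
    rel <- dyad_matrix(unclass_dyad(rel)[rownames(hwi), rownames(hwi)],
                       directed = FALSE, type = "relatedness")
    upgma <- upgma_relatedness(rel)
    divers <- diversity_stats(geno)
    hwe <- purrr::map(geno$loci, ~hwe_chisq(geno, .x))
    hwe_p <- vapply(hwe, function(h) {
      if (isTRUE(h$no_test)) NA_real_ else h$p_value
    }, numeric(1))
    hwe_holm <- sequential_bonferroni(hwe_p[!is.na(hwe_p)])

    stage <- "community"
    together <- dplyr::filter(beh$scans, .data$together == 1)
    n_days <- max(together$day)
    # config w_star is in mean-events-per-day units; scale by the decay
    # mass so early days are not under-thresholded
    hl <- config$half_life_days
    mass <- if (is.infinite(hl)) seq_len(n_days) else
      (1 - 2^(-seq_len(n_days) / hl)) / (1 - 2^(-1 / hl))
    daily <- lapply(seq_len(n_days), function(d) {
      g <- edge_weights(together, d, hl)
      cpm_communities(g, k = config$k, w_star = config$w_star * mass[d])
    })
    timeline <- track_communities(daily)
    dist <- band_distance(gps$amb, gps$bb)
    cdm <- tryCatch(community_distance_model(timeline, dist),
                    error = function(e) NULL)
    contact <- outside_contact_rates(timeline, together)
    leave <- tryCatch(leave_probability(timeline, contact),
                      error = function(e) NULL)

    stage <- "hpmt"
    ids <- rownames(hwi)
    nds <- stats::setNames(dom$scores$nds, dom$scores$id)[ids]
    if (is.null(ages)) {
      ages <- stats::setNames(rep(NA_real_, length(ids)), ids)
    }
    factors <- list(
      relatedness = rel,
      age = pairwise_difference(ages[ids], "age_diff"),
      rank = pairwise_difference(nds, "nds_diff"))
    have_age <- !anyNA(ages[ids])
    if (!have_age) factors$age <- NULL
    hpmt <- purrr::imap(factors, function(x, nm) {
      hpmt_test(x, hwi, z = factors[setdiff(names(factors), nm)],
                n_perm = config$n_perm, seed = config$seed + 21)
    })
    cr <- contribution_rates(hwi, factors)

    stage <- "ethogram"
    tal <- tally_ethogram(beh$agonistic, agonistic_ethogram())
    gof <- chisq_gof(tal$count)

    report <- structure(list(
      affiliation = list(hwi = hwi, dai = dai, partition = partition),
      dominance = list(result = dom, steepness = steep, linearity = linear),
      kinship = list(freqs = freqs, relatedness = rel, upgma = upgma,
                     diversity = divers, hwe_holm = hwe_holm),
      community = list(timeline = timeline, distances = dist,
                       distance_model = cdm, leave = leave),
      hpmt = list(tests = hpmt, contribution = cr),
      ethogram = list(tally = tal, gof = gof),
      config = config),
      class = "pipeline_report")
    if (!is.null(config$out_dir)) write_report(report, config$out_dir)
    report
  }, error = function(e) {
    rlang::abort(sprintf("pipeline failed at stage '%s': %s", stage,
                         conditionMessage(e)),
                 class = "kinclique_stage_error", parent = e)
  })
}

#' Within- vs between-group dyad means
#'
#' Mean dyadic value inside and across groups — the standard summary for
#' "do kin/subgroup members associate more".
#'
#' @param values symmetric dyadic matrix.
#' @param groups named vector of group labels covering the matrix ids.
#' @return tibble with `mean_within`, `mean_between`.
#' @export
subgroup_contrast <- function(values, groups) {
  g <- groups[rownames(values)]
  same <- outer(g, g, "==")[upper.tri(values)]
  v <- upper_vec(values)
  tibble::tibble(mean_within = mean(v[same], na.rm = TRUE),
                 mean_between = mean(v[!same], na.rm = TRUE))
}

#' Single seeded ground-truth recovery run
#'
#' Generates one kin-dominant synthetic herd, runs the affiliation,
#' kinship and dominance stages, and scores the headline quantities: the
#' per-factor HPMT contribution rates of relatedness, age and rank on the
#' HWI matrix, and the within/between-family contrasts of HWI and
#' estimated relatedness. Used (across many seeds) to check that the
#' pipeline recovers a kinship-driven society from raw events.
#'
#' @param seed integer seed for this replicate.
#' @param n_scans,n_groom_bouts,n_agonistic event counts.
#' @param ... passed to [herd_scenario()].
#' @return one-row tibble with cr_relatedness, cr_age, cr_rank,
#'   hwi_within, hwi_between, rel_within, rel_between.
#' @export
recovery_run <- function(seed, n_scans = 1000, n_groom_bouts = 300,
                         n_agonistic = 400, ...) {
  sc <- herd_scenario(seed = seed, ...)
  beh <- simulate_behaviour(sc, n_scans = n_scans,
                            n_groom_bouts = n_groom_bouts,
                            n_agonistic = n_agonistic)
  freqs_true <- simulate_allele_freqs(sc$n_loci, sc$null_rates,
                                      seed = sc$seed * 13 + 4)
  geno <- simulate_genotypes(sc$pedigree, freqs_true,
                             seed = sc$seed * 13 + 5,
                             ids = sc$individuals$id)
  hwi <- compute_hwi(beh$scans)
  ids <- rownames(hwi)
  freqs <- estimate_allele_freqs_em(geno)
  rel <- lr_relatedness(geno, freqs)
  rel <- dyad_matrix(unclass_dyad(rel)[ids, ids], type = "relatedness")
  dom <- david_scores(build_conflict_matrix(beh$agonistic, ids = ids))
  nds <- stats::setNames(dom$scores$nds, dom$scores$id)[ids]
  ages <- stats::setNames(sc$individuals$age_years, sc$individuals$id)[ids]
  cr <- contribution_rates(hwi, list(
    relatedness = rel,
    age = pairwise_difference(ages, "age_diff"),
    rank = pairwise_difference(nds, "nds_diff")))
  fam <- stats::setNames(sc$individuals$family, sc$individuals$id)
  hc <- subgroup_contrast(hwi, fam)
  rc <- subgroup_contrast(rel, fam)
  tibble::tibble(
    seed = seed,
    cr_relatedness = cr$cr[cr$factor == "relatedness"],
    cr_age = cr$cr[cr$factor == "age"],
    cr_rank = cr$cr[cr$factor == "rank"],
    hwi_within = hc$mean_within, hwi_between = hc$mean_between,
    rel_within = rc$mean_within, rel_between = rc$mean_between)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  subgroups: %d (Q = %.3f)\n",
              length(unique(x$affiliation$partition$assignment$subgroup)),
              x$affiliation$partition$cliquishness))
  cat(sprintf("  steepness K = %.3f (R2 = %.3f), linearity h' = %.3f\n",
              x$dominance$steepness$steepness,
              x$dominance$steepness$r_squared,
              x$dominance$linearity$h_prime))
  cr <- x$hpmt$contribution
  cat(sprintf("  HPMT CR: %s (R2 = %.3f)\n",
              paste(sprintf("%s=%.3f", cr$factor, cr$cr), collapse = ", "),
              attr(cr, "r.squared")))
  invisible(x)
}

# JSON + CSV artefact writer for a pipeline report.
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(tidy(report$affiliation$hwi),
                   file.path(out_dir, "hwi.csv"), row.names = FALSE)
  utils::write.csv(tidy(report$dominance$result),
                   file.path(out_dir, "dominance.csv"), row.names = FALSE)
  utils::write.csv(tidy(report$kinship$relatedness),
                   file.path(out_dir, "relatedness.csv"), row.names = FALSE)
  writeLines(report$kinship$upgma$newick,
             file.path(out_dir, "relatedness_upgma.nwk"))
  edges <- filter_sociogram(report$affiliation$hwi,
                            report$config$hwi_edge,
                            node_attrs = tidy(report$affiliation$partition))
  write_sociogram_graphml(edges, file.path(out_dir, "sociogram_hwi.graphml"))
  cr <- report$hpmt$contribution
  summary <- list(
    seed = report$config$seed,
    n_perm = report$config$n_perm,
    cliquishness = report$affiliation$partition$cliquishness,
    steepness = report$dominance$steepness$steepness,
    steepness_r2 = report$dominance$steepness$r_squared,
    linearity_h = report$dominance$linearity$h_prime,
    hpmt = purrr::map(report$hpmt$tests,
                      ~list(r = .x$statistic, p = .x$p_value)),
    contribution = stats::setNames(as.list(cr$cr), cr$factor),
    r_squared = attr(cr, "r.squared"),
    ethogram_chisq = report$ethogram$gof$statistic)
  jsonlite::write_json(summary, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
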