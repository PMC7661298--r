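#' Simulate a pedigree, fish table and census for a supplemented population
#'
#' Generates per-cohort wild- and captive-bred potential spawners, draws each
#' spawner's true number of adult offspring from a hurdle model, thins parents
#' and offspring by their sampling fractions, corrupts a fraction
#' `assignment_error` of the surviving parentage links, and returns the tables
#' the analysis pipeline consumes together with the generating truth.
#'
#' The hurdle model gives a fish zero adult offspring with probability
#' `zero_prob_wild` / `zero_prob_captive`; otherwise the count is
#' `1 + NegBin(mu - 1, theta)`.  The captive positive-part mean is scaled so
#' that the ratio of captive to wild overall means equals `true_rrs` exactly
#' at the level of the generating distribution.  A misassigned link is moved
#' to a uniformly random other sampled parent of the same cohort
#' (provenance-blind by default).  For a fraction `two_parent_frac` of
#' assigned offspring the mate is also recovered; mates are drawn with
#' probability proportional to their own true offspring count, which keeps
#' the provenance mean ratio at `true_rrs` in expectation.
#'
#' All randomness derives from `config$seed` through fixed per-stage
#' substreams, so output is reproducible byte for byte.
#'
#' @param config a [simulation_config()].
#'
#' @return A list of class `"pedigree_simulation"` with elements
#'   \describe{
#'     \item{fish}{data.frame of sampled fish: `fish_id`, `provenance`
#'       (`"wild"`/`"captive"`), `sex` (`"F"`/`"M"`), `return_year`,
#'       `sea_age` (`"grilse"`/`"MSW"`), `fork_length` (cm),
#'       `trap_direction`, `role` (`"spawner"`/`"recruit"`).}
#'     \item{parentage}{data.frame of links: `offspring_id`, `parent_id`,
#'       `n_parents_assigned`; attributes `epsilon` and `cohort_sampling`
#'       (per-cohort counts of offspring sampled).}
#'     \item{census}{data.frame of full (unthinned) counts: `year`,
#'       `provenance`, `sea_age`, `count`, `mean_female_length`.}
#'     \item{truth}{`"simulation_truth"`: config echo, per-cohort true means
#'       by provenance, and sampling/assignment tallies.}
#'   }
#' @examples
#' sim <- simulate_pedigree(simulation_config(n_wild = 80, n_captive = 30,
#'                                            seed = 7))
#' head(sim$parentage)
#' @export
simulate_pedigree <- function(config) {
  if (!inherits(config, "simulation_config")) {
    config <- do.call(simulation_config, as.list(config))
  }
  validate_simulation_config(config)
  seeds <- stage_seeds(config$seed, 4L)

  cohorts <- config$first_cohort + seq_len(config$n_cohorts) - 1L
  mu_w <- config$mu_positive
  mean_w <- (1 - config$zero_prob_wild) * mu_w
  mu_c <- if (config$zero_prob_captive < 1) {
    config$true_rrs * mean_w / (1 - config$zero_prob_captive)
  } else {
    mu_w  # unused: all captive counts are zero
  }

  set.seed(seeds[1L])
  parents <- do.call(rbind, lapply(cohorts, function(y) {
    # annual returns fluctuate around the configured cohort sizes
    n_w <- stats::rpois(1L, config$n_wild)
    n_c <- stats::rpois(1L, config$n_captive)
    n <- n_w + n_c
    prov <- rep(c("wild", "captive"), c(n_w, n_c))
    data.frame(
      fish_id = sprintf("P%d_%04d", y, seq_len(n)),
      provenance = prov,
      sex = ifelse(stats::runif(n) < config$sex_ratio, "F", "M"),
      return_year = y,
      sea_age = ifelse(stats::runif(n) < config$grilse_frac, "grilse", "MSW"),
      cohort = y,
      stringsAsFactors = FALSE
    )
  }))
  parents$fork_length <- round(ifelse(
    parents$sea_age == "grilse",
    stats::rnorm(nrow(parents), 63, 4),
    stats::rnorm(nrow(parents), 78, 5)
  ), 1)
  # provenances are sampled at different migration stages: wild-bred mostly as
  # kelts going downstream, captive-bred mostly on the upstream return
  p_up <- ifelse(parents$provenance == "captive", 0.95, 0.06)
  parents$trap_direction <- ifelse(stats::runif(nrow(parents)) < p_up,
                                   "upstream", "downstream")

  set.seed(seeds[2L])
  zp <- ifelse(parents$provenance == "wild",
               config$zero_prob_wild, config$zero_prob_captive)
  nonzero <- stats::runif(nrow(parents)) >= zp
  mu_pos <- ifelse(parents$provenance == "wild", mu_w, mu_c)
  count <- integer(nrow(parents))
  count[nonzero] <- 1L + stats::rnbinom(sum(nonzero),
                                        mu = mu_pos[nonzero] - 1,
                                        size = config$theta)
  parents$true_count <- count
  parents$sampled <- stats::runif(nrow(parents)) < config$parent_sampling_frac

  # offspring: wild-born recruits returning 4 (grilse) or 5 (MSW) years on
  set.seed(seeds[3L])
  off_parent <- rep.int(seq_len(nrow(parents)), parents$true_count)
  n_off <- length(off_parent)
  offspring <- data.frame(
    fish_id = sprintf("O%06d", seq_len(n_off)),
    true_parent = parents$fish_id[off_parent],
    cohort = parents$cohort[off_parent],
    sex = ifelse(stats::runif(n_off) < config$sex_ratio, "F", "M"),
    sea_age = ifelse(stats::runif(n_off) < config$grilse_frac,
                     "grilse", "MSW"),
    stringsAsFactors = FALSE
  )
  offspring$return_year <- offspring$cohort +
    ifelse(offspring$sea_age == "grilse", 4L, 5L)
  offspring$fork_length <- round(ifelse(
    offspring$sea_age == "grilse",
    stats::rnorm(n_off, 63, 4),
    stats::rnorm(n_off, 78, 5)
  ), 1)
  offspring$sampled <- stats::runif(n_off) < config$offspring_sampling_frac

  # pedigree links: sampled offspring of sampled parents are assigned;
  # a fraction epsilon of those links are corrupted
  set.seed(seeds[4L])
  parent_sampled <- parents$sampled[match(offspring$true_parent,
                                          parents$fish_id)]
  assigned <- offspring$sampled & parent_sampled
  links <- data.frame(
    offspring_id = offspring$fish_id[assigned],
    parent_id = offspring$true_parent[assigned],
    cohort = offspring$cohort[assigned],
    stringsAsFactors = FALSE
  )
  n_misassigned <- 0L
  if (config$assignment_error > 0 && nrow(links) > 0L) {
    corrupt <- which(stats::runif(nrow(links)) < config$assignment_error)
    if (length(corrupt) > 0L) {
      true_prov <- parents$provenance[match(links$parent_id[corrupt],
                                            parents$fish_id)]
      new_id <- vapply(seq_along(corrupt), function(j) {
        i <- corrupt[j]
        pool <- parents$sampled & parents$cohort == links$cohort[i] &
          parents$fish_id != links$parent_id[i]
        if (config$error_direction == "within") {
          pool <- pool & parents$provenance == true_prov[j]
        } else if (config$error_direction == "between") {
          pool <- pool & parents$provenance != true_prov[j]
        }
        idx <- which(pool)
        if (length(idx) == 0L) return(NA_character_)
        parents$fish_id[resample(idx, 1L)]
      }, character(1L))
      ok <- !is.na(new_id)
      links$parent_id[corrupt[ok]] <- new_id[ok]
      n_misassigned <- sum(ok)
    }
  }
  # second-parent recovery: mate drawn opposite-sex, size-biased by true count
  links$n_parents_assigned <- rep(1L, nrow(links))
  mate_links <- draw_mates(links, parents, config$two_parent_frac)
  if (!is.null(mate_links) && nrow(mate_links) > 0L) {
    links$n_parents_assigned[links$offspring_id %in%
                               mate_links$offspring_id] <- 2L
  }
  parentage <- rbind(links, mate_links)
  rownames(parentage) <- NULL

  cohort_sampling <- aggregate_count(
    offspring$cohort[offspring$sampled], cohorts, "n_offspring_sampled")
  cohort_assigned <- aggregate_count(links$cohort, cohorts, "n_assigned")

  fish <- rbind(
    data.frame(parents[parents$sampled,
                       c("fish_id", "provenance", "sex", "return_year",
                         "sea_age", "fork_length", "trap_direction")],
               role = "spawner", stringsAsFactors = FALSE),
    local({
      rec <- offspring[offspring$sampled,
                       c("fish_id", "sex", "return_year", "sea_age",
                         "fork_length"), drop = FALSE]
      rec$provenance <- rep("wild", nrow(rec))
      rec$trap_direction <- rep("downstream", nrow(rec))
      rec$role <- rep("recruit", nrow(rec))
      rec[, c("fish_id", "provenance", "sex", "return_year", "sea_age",
              "fork_length", "trap_direction", "role")]
    })
  )
  rownames(fish) <- NULL

  census <- build_census(parents, offspring)

  true_means <- stats::aggregate(
    list(true_mean_lrs = parents$true_count),
    by = list(cohort = parents$cohort, provenance = parents$provenance),
    FUN = mean)
  tallies <- merge(cohort_sampling, cohort_assigned, by = "cohort")
  tallies <- merge(tallies, stats::aggregate(
    list(n_parents_sampled = parents$sampled),
    by = list(cohort = parents$cohort), FUN = sum), by = "cohort")
  tallies$n_offspring_true <- as.vector(
    table(factor(offspring$cohort, levels = cohorts)))

  parentage$cohort <- NULL
  attr(parentage, "epsilon") <- config$assignment_error
  attr(parentage, "n_offspring_sampled") <- sum(offspring$sampled)
  attr(parentage, "cohort_sampling") <- cohort_sampling

  truth <- structure(list(
    config = config,
    true_mean_lrs = true_means,
    tallies = tallies,
    n_misassigned = n_misassigned,
    generating_means = c(wild = mean_w, captive = config$true_rrs * mean_w),
    parent_map = data.frame(offspring_id = offspring$fish_id,
                            true_parent_id = offspring$true_parent,
                            sampled = offspring$sampled,
                            stringsAsFactors = FALSE)
  ), class = "simulation_truth")

  structure(list(fish = fish, parentage = parentage, census = census,
                 truth = truth),
            class = "pedigree_simulation")
}

# full-population census: spawners at their return year, wild recruits at
# theirs, with female mean fork length carried for the ova-based measure
build_census <- function(parents, offspring) {
  spa <- data.frame(year = parents$return_year,
                    provenance = parents$provenance,
                    sea_age = parents$sea_age,
                    sex = parents$sex,
                    fork_length = parents$fork_length,
                    stringsAsFactors = FALSE)
  rec <- data.frame(year = offspring$return_year,
                    provenance = rep("wild", nrow(offspring)),
                    sea_age = offspring$sea_age,
                    sex = offspring$sex,
                    fork_length = offspring$fork_length,
                    stringsAsFactors = FALSE)
  all <- rbind(spa, rec)
  counts <- stats::aggregate(
    list(count = rep(1L, nrow(all))),
    by = list(year = all$year, provenance = all$provenance,
              sea_age = all$sea_age),
    FUN = sum)
  fem <- all[all$sex == "F", ]
  if (nrow(fem) > 0L) {
    flen <- stats::aggregate(
      list(mean_female_length = fem$fork_length),
      by = list(year = fem$year, provenance = fem$provenance,
                sea_age = fem$sea_age),
      FUN = mean)
    counts <- merge(counts, flen,
                    by = c("year", "provenance", "sea_age"), all.x = TRUE)
  } else {
    counts$mean_female_length <- NA_real_
  }
  counts[order(counts$year, counts$provenance, counts$sea_age), ]
}

#' Simulate a density-dependent productivity series with hatchery intrusion
#'
#' Draws a stationary positive spawner series, annual hatchery-intrusion
#' proportions, and log productivity (recruits per spawner) composed of a
#' Beverton-Holt-shaped density term, a linear intrusion effect on the log
#' scale, and Gaussian noise:
#' `log P_t = log(a) - log(1 + S_t / b) + beta_true * p_t + e_t`.
#'
#' @param n_years series length (>= 10).
#' @param density_params list with `mean_spawners`, `sd_spawners`, `ar1`
#'   (AR(1) coefficient of the spawner series) and Beverton-Holt shape
#'   parameters `bh_a` (maximum recruits per spawner as density tends to 0)
#'   and `bh_b` (spawner count at which productivity is halved).
#' @param beta_true true intrusion slope on log productivity.
#' @param noise_sd standard deviation of the Gaussian log-scale noise.
#' @param intrusion_range interval from which annual captive-bred proportions
#'   are drawn uniformly.
#' @param seed integer seed.
#' @param max_resample maximum redraws for a non-positive spawner count
#'   before the generator aborts.
#'
#' @return list with `series` (data.frame: `year`, `spawners`, `recruits`,
#'   `productivity`, `log_productivity`, `prop_captive`) and `truth`
#'   (`"simulation_truth"` echoing the generating parameters and the number
#'   of resampled spawner draws).
#' @examples
#' sim <- simulate_productivity_series(n_years = 43, beta_true = -0.686,
#'                                     seed = 11)
#' head(sim$series)
#' @export
simulate_productivity_series <- function(n_years = 43L,
                                         density_params = list(
                                           mean_spawners = 600,
                                           sd_spawners = 250,
                                           ar1 = 0.5,
                                           bh_a = 3,
                                           bh_b = 500),
                                         beta_true = -0.686,
                                         noise_sd = 0.25,
                                         intrusion_range = c(0.01, 0.59),
                                         seed = 1L,
                                         max_resample = 1000L) {
  if (!is.numeric(n_years) || n_years < 10) {
    stop("`n_years` must be >= 10")
  }
  n_years <- as.integer(n_years)
  dp <- utils::modifyList(list(mean_spawners = 600, sd_spawners = 250,
                               ar1 = 0.5, bh_a = 3, bh_b = 500),
                          density_params)
  if (!is.numeric(noise_sd) || noise_sd < 0 || !is.finite(noise_sd)) {
    stop("`noise_sd` must be a non-negative real")
  }
  if (length(intrusion_range) != 2L || any(intrusion_range < 0) ||
      any(intrusion_range > 1) || intrusion_range[1] > intrusion_range[2]) {
    stop("`intrusion_range` must be an interval within [0, 1]")
  }
  if (abs(dp$ar1) >= 1) stop("`ar1` must satisfy |ar1| < 1 (stationarity)")

  set.seed(as.integer(seed))
  # AR(1) around the mean, innovations scaled so the marginal sd is
  # sd_spawners; non-positive draws are redrawn year by year
  innov_sd <- dp$sd_spawners * sqrt(1 - dp$ar1^2)
  s <- numeric(n_years)
  n_resampled <- 0L
  prev <- 0
  for (t in seq_len(n_years)) {
    tries <- 0L
    repeat {
      x <- dp$ar1 * prev + stats::rnorm(1L, 0, innov_sd)
      if (dp$mean_spawners + x > 0) break
      tries <- tries + 1L
      if (tries > max_resample) {
        stop("spawner resampling exceeded `max_resample`; ",
             "check `density_params`")
      }
    }
    n_resampled <- n_resampled + tries
    prev <- x
    s[t] <- dp$mean_spawners + x
  }
  p <- stats::runif(n_years, intrusion_range[1], intrusion_range[2])
  g <- log(dp$bh_a) - log(1 + s / dp$bh_b)
  log_p <- g + beta_true * p + stats::rnorm(n_years, 0, noise_sd)
  series <- data.frame(
    year = seq_len(n_years),
    spawners = s,
    recruits = exp(log_p) * s,
    productivity = exp(log_p),
    log_productivity = log_p,
    prop_captive = p
  )
  truth <- structure(list(
    beta_true = beta_true,
    density_params = dp,
    noise_sd = noise_sd,
    intrusion_range = intrusion_range,
    n_resampled = n_resampled,
    seed = as.integer(seed)
  ), class = "simulation_truth")
  list(series = series, truth = truth)
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat("Simulation truth\n")
  if (!is.null(x$beta_true)) {
    cat(sprintf("  intrusion slope beta_true: %.4f; noise sd: %.3f\n",
                x$beta_true, x$noise_sd))
  }
  if (!is.null(x$generating_means)) {
    cat(sprintf("  generating mean LRS wild %.3f, captive %.3f (rho = %.3f)\n",
                x$generating_means["wild"], x$generating_means["captive"],
                x$config$true_rrs))
  }
  invisible(x)
}

#' @export
print.pedigree_simulation <- function(x, ...) {
  cat(sprintf("Synthetic pedigree: %d fish, %d parentage links, %d census rows\n",
              nrow(x$fish), nrow(x$parentage), nrow(x$census)))
  invisible(x)
}

# vectorised mate draws, grouped by cohort x mate sex; size-biased by the
# mate's own true offspring count so the provenance mean ratio is preserved
draw_mates <- function(links, parents, two_parent_frac) {
  if (two_parent_frac <= 0 || nrow(links) == 0L) return(NULL)
  take <- which(stats::runif(nrow(links)) < two_parent_frac)
  if (length(take) == 0L) return(NULL)
  focal_sex <- parents$sex[match(links$parent_id[take], parents$fish_id)]
  mate_sex <- ifelse(focal_sex == "F", "M", "F")
  key <- paste(links$cohort[take], mate_sex)
  out <- vector("list", 0L)
  for (k in unique(key)) {
    rows <- take[key == k]
    parts <- strsplit(k, " ")[[1L]]
    pool <- which(parents$sampled & parents$cohort == as.integer(parts[1L]) &
                    parents$sex == parts[2L] & parents$true_count > 0)
    if (length(pool) == 0L) next
    mates <- parents$fish_id[resample(pool, length(rows), replace = TRUE,
                                      prob = parents$true_count[pool])]
    # a fish cannot be its own mate; redraw the rare collisions
    for (r in which(mates == links$parent_id[rows])) {
      alt <- pool[parents$fish_id[pool] != links$parent_id[rows][r]]
      if (length(alt) == 0L) {
        mates[r] <- NA_character_
      } else {
        mates[r] <- parents$fish_id[resample(alt, 1L,
                                             prob = parents$true_count[alt])]
      }
    }
    keep <- !is.na(mates)
    if (!any(keep)) next
    out[[length(out) + 1L]] <- data.frame(
      offspring_id = links$offspring_id[rows][keep],
      parent_id = mates[keep],
      cohort = links$cohort[rows][keep],
      n_parents_assigned = 2L,
      stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0L) return(NULL)
  do.call(rbind, out)
}

# sample() with surprise-free behaviour when length(x) == 1
resample <- function(x, size, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}

# derive fixed per-stage substream seeds from one root seed
stage_seeds <- function(root, n) {
  set.seed(as.integer(root))
  sample.int(.Machine$integer.max - 1L, n)
}

aggregate_count <- function(values, levels, name) {
  out <- data.frame(cohort = levels,
                    n = as.vector(table(factor(values, levels = levels))))
  names(out)[2] <- name
  out
}
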