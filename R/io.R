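#' Read the fish metadata table
#'
#' CSV with header; required columns `fish_id`, `provenance`, `sex`,
#' `return_year`; optional `sea_age`, `fork_length`, `trap_direction`,
#' `role`.  `provenance` must be `"wild"` or `"captive"`; `sex` one of
#' `"F"`, `"M"`, `"unknown"` (unknown becomes `NA`).
#'
#' @param path file path (UTF-8 CSV).
#' @return validated data.frame of fish records.
#' @export
read_fish_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  require_columns(df, c("fish_id", "provenance", "sex", "return_year"),
                  "fish table")
  if (anyDuplicated(df$fish_id)) {
    stop("duplicate fish_id in ", path, ": ",
         df$fish_id[anyDuplicated(df$fish_id)])
  }
  bad <- setdiff(unique(df$provenance), c("wild", "captive"))
  if (length(bad) > 0L) {
    stop("unknown provenance value(s): ", paste(bad, collapse = ", "))
  }
  df$sex[df$sex %in% c("unknown", "")] <- NA_character_
  bad <- setdiff(unique(df$sex[!is.na(df$sex)]), c("F", "M"))
  if (length(bad) > 0L) {
    stop("unknown sex value(s): ", paste(bad, collapse = ", "))
  }
  df$return_year <- as.integer(df$return_year)
  df
}

#' Read the parentage table
#'
#' CSV with header; required columns `offspring_id`, `parent_id`; optional
#' `n_parents_assigned`.  The assignment-error rate and offspring-sampled
#' counts are analysis parameters, not file columns; supply them to
#' [cohort_fitness()] (or let [simulate_pedigree()] attach them).
#'
#' @param path file path.
#' @param epsilon optional assignment-error rate stored as an attribute.
#' @return data.frame of parentage links.
#' @export
read_parentage_table <- function(path, epsilon = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  require_columns(df, c("offspring_id", "parent_id"), "parentage table")
  if (is.null(df$n_parents_assigned)) df$n_parents_assigned <- 1L
  if (anyDuplicated(df[, c("offspring_id", "parent_id")])) {
    stop("duplicate (offspring, parent) pairs in ", path)
  }
  if (!is.null(epsilon)) attr(df, "epsilon") <- epsilon
  df
}

#' Read the annual census table
#'
#' CSV with header; required columns `year`, `provenance`, `sea_age`,
#' `count`; optional `mean_female_length`.
#'
#' @param path file path.
#' @return data.frame of census rows.
#' @export
read_census_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  require_columns(df, c("year", "provenance", "sea_age", "count"),
                  "census table")
  df$year <- as.integer(df$year)
  if (any(df$count < 0)) stop("census counts must be non-negative")
  df
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop(what, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  }
  invisible(df)
}

#' Write the tables of a synthetic data set to a directory
#'
#' Writes `fish.csv`, `parentage.csv`, `census.csv` and `truth.json` (the
#' generating parameters and tallies) so a simulated data set can be re-read
#' by the standard readers.
#'
#' @param sim a `"pedigree_simulation"` from [simulate_pedigree()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("fish.csv", "parentage.csv", "census.csv",
                            "truth.json"))
  utils::write.csv(sim$fish, paths[1], row.names = FALSE)
  utils::write.csv(sim$parentage, paths[2], row.names = FALSE)
  utils::write.csv(sim$census, paths[3], row.names = FALSE)
  truth <- sim$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(
    list(config = truth$config,
         generating_means = as.list(truth$generating_means),
         true_mean_lrs = truth$true_mean_lrs,
         tallies = truth$tallies,
         n_misassigned = truth$n_misassigned,
         epsilon = attr(sim$parentage, "epsilon"),
         n_offspring_sampled = attr(sim$parentage, "n_offspring_sampled"),
         cohort_sampling = attr(sim$parentage, "cohort_sampling")),
    paths[4], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Run the full analysis pipeline
#'
#' End-to-end composition: read (or accept in-memory) fish, parentage and
#' census tables; assign spawning cohorts; compute LRS; build the cohort
#' fitness table (overall and per sex) with permutation tests; combine
#' cohort p-values by Fisher's method and form the overall
#' weighted-geometric-mean RRS; run the zero-LRS proportion test and the
#' zero-excluded comparison; estimate the mixed-population mean-LRS
#' reduction; build the productivity series, density-correct it with the
#' spline GAM, regress the residuals on hatchery intrusion and
#' back-transform the slope.  Reports and a JSON manifest are written to
#' `output_dir` when given.
#'
#' @param fish,parentage,census tables (data.frames) or file paths.
#' @param epsilon assignment-error rate (default: `epsilon` attribute of
#'   `parentage`, else 0).
#' @param offspring_sampled per-cohort offspring-sampled counts (see
#'   [cohort_fitness()]).
#' @param cohorts cohorts for the RRS analysis (default: auto-detect).
#' @param cohort_overrides optional override table for
#'   [assign_spawning_cohorts()].
#' @param n_perm permutations per test.
#' @param tie_rule,weight_scheme,parent_pool analysis switches, recorded in
#'   the manifest.
#' @param knots GAM basis dimension.
#' @param lag_grilse,lag_msw life-cycle lags.
#' @param seed integer seed controlling every permutation stream.
#' @param output_dir optional directory for `rrs_report.csv`,
#'   `productivity_report.csv` and `manifest.json`.
#' @param by_sex also run female- and male-specific RRS comparisons.
#' @return list of class `"salmonrrs_run"`: `cohort_fitness`, `summary`,
#'   `sex_specific`, `zero_lrs_test`, `zero_excluded`, `productivity`
#'   (series, gam, regression, percent reduction at the mean intrusion),
#'   `manifest`.
#' @export
run_pipeline <- function(fish, parentage, census,
                         epsilon = NULL, offspring_sampled = NULL,
                         cohorts = NULL, cohort_overrides = NULL,
                         n_perm = 10000L,
                         tie_rule = c("weak", "strict"),
                         weight_scheme = "total",
                         parent_pool = "provenance",
                         knots = 9L, lag_grilse = 4L, lag_msw = 5L,
                         seed = 1L, output_dir = NULL, by_sex = TRUE) {
  tie_rule <- match.arg(tie_rule)
  if (is.character(fish)) fish <- read_fish_table(fish)
  if (is.character(parentage)) parentage <- read_parentage_table(parentage)
  if (is.character(census)) census <- read_census_table(census)
  if (is.null(epsilon)) {
    epsilon <- attr(parentage, "epsilon")
    if (is.null(epsilon)) epsilon <- 0
  }

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  fish <- stage("cohort assignment",
                assign_spawning_cohorts(fish, cohort_overrides))
  lrs <- stage("LRS", compute_lrs(parentage, fish))

  cft <- stage("cohort fitness", cohort_fitness(
    lrs, fish, parentage, cohorts = cohorts, epsilon = epsilon,
    offspring_sampled = offspring_sampled, n_perm = n_perm,
    tie_rule = tie_rule, seed = seed, parent_pool = parent_pool))
  summary_all <- stage("overall RRS",
                       rrs_summary(cft, weight_scheme = weight_scheme))

  sex_specific <- NULL
  if (by_sex) {
    sex_specific <- lapply(c(F_ = "F", M_ = "M"), function(sx) {
      tryCatch({
        s_cft <- cohort_fitness(
          lrs, fish, parentage, cohorts = cft$cohort, epsilon = epsilon,
          offspring_sampled = offspring_sampled, sex = sx, n_perm = n_perm,
          tie_rule = tie_rule, seed = seed + match(sx, c("F", "M")) * 1000L,
          parent_pool = parent_pool)
        list(table = s_cft, summary = rrs_summary(s_cft, weight_scheme))
      }, error = function(e) {
        warning("sex-specific run (", sx, ") skipped: ",
                conditionMessage(e))
        NULL
      })
    })
    names(sex_specific) <- c("F", "M")
  }

  # zero-LRS analyses over the parents of the analysed cohorts
  spawners <- fish
  if (!is.null(spawners$role)) {
    spawners <- spawners[spawners$role == "spawner", , drop = FALSE]
  }
  attr_long <- cohort_assignments(spawners)
  in_cohorts <- unique(attr_long$fish_id[attr_long$cohort %in% cft$cohort])
  sp <- spawners[spawners$fish_id %in% in_cohorts, , drop = FALSE]
  sp_lrs <- lrs$lrs[match(sp$fish_id, lrs$fish_id)]
  cap <- sp_lrs[sp$provenance == "captive"]
  wld <- sp_lrs[sp$provenance == "wild"]
  zero_test <- stage("zero-LRS proportion test", zero_lrs_proportion_test(
    sum(cap == 0), length(cap), sum(wld == 0), length(wld)))
  zero_excl <- stage("zero-excluded RRS", zero_excluded_rrs(
    cap, wld, n_perm = n_perm, tie_rule = tie_rule, seed = seed + 7L))

  prod <- stage("productivity series",
                recruits_per_spawner(census, lag_grilse = lag_grilse,
                                     lag_msw = lag_msw))
  gam_fit <- stage("density GAM", fit_density_gam(prod, k = knots))
  reg <- stage("intrusion regression", intrusion_regression(gam_fit))
  mean_intrusion <- mean(gam_fit$series$prop_captive)
  reduction <- percent_reduction(reg$slope, mean_intrusion)
  dens_cor <- stage("density-intrusion correlation",
                    density_intrusion_correlation(prod$spawners,
                                                  prod$prop_captive))

  manifest <- list(
    package_version = as.character(utils::packageVersion("salmonrrs")),
    seed = as.integer(seed),
    epsilon = epsilon,
    n_perm = as.integer(n_perm),
    tie_rule = tie_rule,
    weight_scheme = weight_scheme,
    parent_pool = parent_pool,
    knots = as.integer(knots),
    lags = c(grilse = lag_grilse, msw = lag_msw),
    cohorts = cft$cohort,
    n_fish = nrow(fish),
    n_links = nrow(parentage),
    n_productivity_years = nrow(prod),
    fcpt_substitutions = nrow(summary_all$fcpt$substitutions)
  )

  result <- structure(list(
    cohort_fitness = cft,
    summary = summary_all,
    sex_specific = sex_specific,
    zero_lrs_test = zero_test,
    zero_excluded = zero_excl,
    productivity = list(series = prod, gam = gam_fit, regression = reg,
                        mean_intrusion = mean_intrusion,
                        percent_reduction = reduction,
                        density_intrusion_correlation = dens_cor),
    manifest = manifest
  ), class = "salmonrrs_run")

  if (!is.null(output_dir)) write_run_reports(result, output_dir)
  result
}

write_run_reports <- function(result, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  ok <- FALSE
  paths <- file.path(output_dir, c("rrs_report.csv",
                                   "productivity_report.csv",
                                   "manifest.json"))
  on.exit(if (!ok) unlink(paths))
  report <- build_rrs_report(result)
  utils::write.csv(report, paths[1], row.names = FALSE)
  utils::write.csv(as.data.frame(result$productivity$series), paths[2],
                   row.names = FALSE)
  jsonlite::write_json(c(result$manifest, list(
    overall_rrs = result$summary$overall_rrs,
    fcpt_chi2 = result$summary$fcpt$chi2,
    fcpt_df = result$summary$fcpt$df,
    fcpt_p = result$summary$fcpt$p,
    mean_lrs_reduction_pct = result$summary$mean_lrs_reduction_pct,
    zero_excluded_rrs = result$zero_excluded$rrs,
    intrusion_slope = result$productivity$regression$slope,
    percent_reduction = result$productivity$percent_reduction
  )), paths[3], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  ok <- TRUE
  invisible(paths)
}

# Table-1-shaped long report: one row per cohort (and overall) x sex class
build_rrs_report <- function(result) {
  one <- function(cft, sm, label) {
    rbind(
      data.frame(cohort = as.character(cft$cohort), sex = label,
                 rrs = cft$rrs, p = cft$perm_p,
                 stringsAsFactors = FALSE),
      data.frame(cohort = "overall", sex = label,
                 rrs = sm$overall_rrs, p = sm$fcpt$p,
                 stringsAsFactors = FALSE)
    )
  }
  report <- one(result$cohort_fitness, result$summary, "both")
  for (sx in names(result$sex_specific)) {
    block <- result$sex_specific[[sx]]
    if (!is.null(block)) {
      report <- rbind(report, one(block$table, block$summary, sx))
    }
  }
  report
}

#' @export
print.salmonrrs_run <- function(x, ...) {
  cat("salmonrrs pipeline run\n\n")
  print(x$cohort_fitness)
  cat("\n")
  print(x$summary)
  cat(sprintf("Zero-excluded RRS: %.3f (p = %.3g)\n",
              x$zero_excluded$rrs, x$zero_excluded$p))
  cat("\n")
  print(x$productivity$regression)
  cat(sprintf("Productivity reduction at mean intrusion (%.2f): %.2f%%\n",
              x$productivity$mean_intrusion,
              x$productivity$percent_reduction))
  invisible(x)
}
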