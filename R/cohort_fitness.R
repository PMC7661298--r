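#' Per-cohort bias-corrected RRS with permutation tests
#'
#' Builds the cohort fitness table: for each spawning cohort and provenance,
#' the number of potential parents, raw and assignment-error-corrected mean
#' LRS, the cohort RRS (captive corrected mean over wild corrected mean),
#' and a one-tailed permutation p-value for the hypothesis that captive-bred
#' fish have lower mean LRS.
#'
#' The correction needs, per cohort, the number of offspring sampled `S` and
#' assigned `A`.  `A` is counted from the LRS table (links to that cohort's
#' parents of the provenance).  `S` is taken from `offspring_sampled`
#' (a data.frame `cohort`, `n_offspring_sampled`, or a scalar applied to all
#' cohorts); if missing, the `cohort_sampling` attribute of `parentage` is
#' used.  With `epsilon = 0` the correction vanishes and `S` is not needed.
#'
#' @param lrs an `lrs_table` from [compute_lrs()].
#' @param fish fish table; if [assign_spawning_cohorts()] has been run its
#'   attributions (with weights) are used, otherwise `return_year` is the
#'   cohort.  Rows with `role != "spawner"` (if a `role` column exists) are
#'   not treated as potential parents.
#' @param parentage parentage table (source of `epsilon` and per-cohort
#'   sampling counts when not supplied explicitly).
#' @param cohorts cohorts to analyse; default: all cohorts in which both
#'   provenances have at least 2 potential parents.
#' @param epsilon assignment-error rate; default: the `epsilon` attribute of
#'   `parentage`, else 0.
#' @param offspring_sampled per-cohort offspring sampled (see Details).
#' @param sex `"F"` or `"M"` for a sex-specific table (fish of unknown sex
#'   are excluded); `NULL` for both sexes.
#' @param n_perm,tie_rule,seed passed to [permutation_test()]; per-cohort
#'   permutation streams are derived from `seed`.
#' @param parent_pool `"provenance"`: `N` in the correction is the
#'   per-provenance parent count (the default); `"pooled"`: both provenances
#'   share `N` = total parents.
#' @param clamp passed to [unbiased_mean_lrs()].
#'
#' @return data.frame of class `"cohort_fitness_table"` with one row per
#'   cohort: `cohort`, `n_captive`, `n_wild`, `raw_mean_captive`,
#'   `raw_mean_wild`, `corrected_mean_captive`, `corrected_mean_wild`,
#'   `rrs`, `perm_p`, `n_perm`.  Attributes record `epsilon`, `tie_rule`,
#'   `sex` and `parent_pool`.
#' @seealso [rrs_summary()] for the overall weighted-geometric-mean RRS and
#'   Fisher's combined test over the cohort p-values.
#' @export
cohort_fitness <- function(lrs, fish, parentage = NULL, cohorts = NULL,
                           epsilon = NULL, offspring_sampled = NULL,
                           sex = NULL, n_perm = 10000L,
                           tie_rule = c("weak", "strict"), seed = NULL,
                           parent_pool = c("provenance", "pooled"),
                           clamp = FALSE) {
  tie_rule <- match.arg(tie_rule)
  parent_pool <- match.arg(parent_pool)
  if (is.null(epsilon)) {
    epsilon <- if (!is.null(parentage)) attr(parentage, "epsilon") else NULL
    if (is.null(epsilon)) epsilon <- 0
  }
  if (is.null(offspring_sampled) && !is.null(parentage)) {
    offspring_sampled <- attr(parentage, "cohort_sampling")
  }

  spawners <- fish
  if (!is.null(spawners$role)) {
    spawners <- spawners[spawners$role == "spawner", , drop = FALSE]
  }
  attribute <- function(f) {
    if (is.null(f$spawning_cohorts)) {
      data.frame(fish_id = f$fish_id, cohort = f$return_year, weight = 1,
                 stringsAsFactors = FALSE)
    } else {
      cohort_assignments(f)
    }
  }
  attributions_all <- attribute(spawners)
  cand <- spawners
  if (!is.null(sex)) {
    sex <- match.arg(sex, c("F", "M"))
    cand <- cand[!is.na(cand$sex) & cand$sex == sex, , drop = FALSE]
  }
  attributions <- attribute(cand)
  attributions$provenance <- cand$provenance[match(attributions$fish_id,
                                                   cand$fish_id)]
  attributions$lrs <- lrs$lrs[match(attributions$fish_id, lrs$fish_id)]
  if (anyNA(attributions$lrs)) {
    stop("some potential parents are missing from the LRS table; ",
         "run `compute_lrs()` on the full fish table")
  }

  if (is.null(cohorts)) {
    tab <- table(attributions$cohort, attributions$provenance)
    have <- rownames(tab)[apply(tab >= 2L, 1L, all) &
                            all(c("captive", "wild") %in% colnames(tab))]
    cohorts <- sort(as.numeric(have))
    if (length(cohorts) == 0L) {
      stop("no cohort has at least 2 potential parents of each provenance")
    }
  }

  # offspring assigned per cohort: distinct offspring linked to any of the
  # cohort's potential parents (both provenances and sexes); falls back to
  # the LRS totals when no parentage table is available
  all_lrs <- lrs$lrs[match(attributions_all$fish_id, lrs$fish_id)]
  A_for <- function(y) {
    ids <- attributions_all$fish_id[attributions_all$cohort == y]
    if (!is.null(parentage)) {
      length(unique(parentage$offspring_id[parentage$parent_id %in% ids]))
    } else {
      sum(all_lrs[attributions_all$cohort == y], na.rm = TRUE)
    }
  }

  S_for <- function(y) {
    if (is.null(offspring_sampled)) return(NA_real_)
    if (is.data.frame(offspring_sampled)) {
      i <- match(y, offspring_sampled$cohort)
      if (is.na(i)) return(NA_real_)
      return(offspring_sampled$n_offspring_sampled[i])
    }
    as.numeric(offspring_sampled)
  }

  rows <- lapply(seq_along(cohorts), function(j) {
    y <- cohorts[j]
    a <- attributions[attributions$cohort == y, , drop = FALSE]
    cap <- a[a$provenance == "captive", , drop = FALSE]
    wld <- a[a$provenance == "wild", , drop = FALSE]
    if (nrow(cap) == 0L || nrow(wld) == 0L) {
      stop("cohort ", y, " lacks potential parents of one provenance")
    }
    n_cap <- sum(cap$weight)
    n_wld <- sum(wld$weight)
    raw_cap <- stats::weighted.mean(cap$lrs, cap$weight)
    raw_wld <- stats::weighted.mean(wld$lrs, wld$weight)
    S <- S_for(y)
    if (epsilon > 0 && is.na(S)) {
      stop("epsilon > 0 but no offspring-sampled count available for cohort ", y)
    }
    if (epsilon == 0) {
      cor_cap <- raw_cap
      cor_wld <- raw_wld
    } else {
      A_tot <- A_for(y)
      if (S < A_tot) {
        warning("cohort ", y, ": offspring sampled (", S,
                ") is below offspring assigned (", A_tot,
                "); correction uses S = A")
        S <- A_tot
      }
      N_cap <- if (parent_pool == "pooled") n_cap + n_wld else n_cap
      N_wld <- if (parent_pool == "pooled") n_cap + n_wld else n_wld
      cor_cap <- unbiased_mean_lrs(raw_cap, S, A_tot, N_cap, epsilon,
                                   clamp = clamp)
      cor_wld <- unbiased_mean_lrs(raw_wld, S, A_tot, N_wld, epsilon,
                                   clamp = clamp)
    }
    pt_seed <- if (is.null(seed)) NULL else as.integer(seed) + j
    pt <- permutation_test(cap$lrs, wld$lrs, n_perm = n_perm,
                           tie_rule = tie_rule, seed = pt_seed)
    data.frame(cohort = y, n_captive = n_cap, n_wild = n_wld,
               raw_mean_captive = raw_cap, raw_mean_wild = raw_wld,
               corrected_mean_captive = cor_cap,
               corrected_mean_wild = cor_wld,
               rrs = cohort_rrs(cor_cap, cor_wld, cohort = y),
               perm_p = pt$p, n_perm = pt$n_perm)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out,
            class = c("cohort_fitness_table", "data.frame"),
            epsilon = epsilon, tie_rule = tie_rule,
            sex = if (is.null(sex)) "both" else sex,
            parent_pool = parent_pool)
}

#' Overall RRS and combined significance across cohorts
#'
#' Condenses a cohort fitness table into the overall RRS (weighted geometric
#' mean of the cohort estimates) and the Fisher's-combined-probability test
#' over the cohort permutation p-values (degrees of freedom = 2 x number of
#' cohorts).
#'
#' @param cft a `"cohort_fitness_table"` from [cohort_fitness()].
#' @param weight_scheme `"total"` (captive + wild parents per cohort, the
#'   default), `"captive"` (captive parents only) or `"custom"`.
#' @param custom_weights weights when `weight_scheme = "custom"`.
#' @param zero_policy,alt_p passed to [fisher_combined()].
#' @return list of class `"rrs_summary"`: `overall_rrs`, `fcpt`
#'   (a `"fisher_combined"`), `weight_scheme`, `weights`,
#'   `mean_lrs_reduction_pct` (mixed-population reduction across cohorts).
#' @export
rrs_summary <- function(cft, weight_scheme = c("total", "captive", "custom"),
                        custom_weights = NULL,
                        zero_policy = "substitute", alt_p = NULL) {
  weight_scheme <- match.arg(weight_scheme)
  w <- switch(weight_scheme,
              total = cft$n_captive + cft$n_wild,
              captive = cft$n_captive,
              custom = {
                if (is.null(custom_weights) ||
                    length(custom_weights) != nrow(cft)) {
                  stop("`custom_weights` must match the number of cohorts")
                }
                custom_weights
              })
  structure(list(
    overall_rrs = overall_rrs(cft$rrs, w),
    fcpt = fisher_combined(cft$perm_p, zero_policy = zero_policy,
                           n_perm = cft$n_perm[1], alt_p = alt_p),
    weight_scheme = weight_scheme,
    weights = w,
    mean_lrs_reduction_pct = mixed_population_reduction(
      cft$n_captive, cft$rrs, cft$n_wild)
  ), class = "rrs_summary")
}

#' @export
print.rrs_summary <- function(x, ...) {
  cat(sprintf("Overall RRS (weighted geometric mean, %s weights): %.3f\n",
              x$weight_scheme, x$overall_rrs))
  print(x$fcpt)
  cat(sprintf("Mixed-population mean-LRS reduction: %.1f%%\n",
              x$mean_lrs_reduction_pct))
  invisible(x)
}

#' @export
print.cohort_fitness_table <- function(x, ...) {
  cat(sprintf("Cohort fitness table (%s, epsilon = %.3g, %s tie rule)\n",
              attr(x, "sex"), attr(x, "epsilon"), attr(x, "tie_rule")))
  print.data.frame(x, digits = 4)
  invisible(x)
}
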