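#' Configuration for the synthetic pedigree generator
#'
#' Bundles and validates the generating parameters of the synthetic
#' pedigree/census generator.  The defaults describe a supplemented salmon
#' population in which captive-bred spawners have substantially lower
#' lifetime reproductive success (LRS) than wild-bred spawners, sampling of
#' returning adults is nearly but not perfectly complete, and a small
#' fraction of pedigree links are wrong.
#'
#' Offspring counts follow a hurdle model: a fish leaves zero adult
#' offspring with provenance-specific probability (`zero_prob_wild`,
#' `zero_prob_captive`), otherwise a positive count drawn from a shifted
#' negative binomial.  The positive-part mean of the captive group is scaled
#' so that the ratio of overall provenance means equals `true_rrs`.
#'
#' @param n_cohorts number of spawning cohorts to simulate.
#' @param n_wild,n_captive potential spawners per cohort by provenance.
#' @param true_rrs true ratio of captive to wild mean LRS (rho > 0).
#' @param zero_prob_wild,zero_prob_captive hurdle zero probabilities in
#'   \[0, 1\].
#' @param mu_positive mean of the positive (non-zero) part of the wild
#'   offspring-count distribution; must be >= 1.
#' @param theta dispersion (size) of the shifted negative binomial positive
#'   part; larger is closer to Poisson.
#' @param parent_sampling_frac,offspring_sampling_frac fractions of parents
#'   and offspring that are tissue-sampled, in (0, 1\].
#' @param assignment_error probability that a sampled offspring's parentage
#'   link is misassigned (epsilon, in \[0, 1)).
#' @param error_direction where a misassigned link lands: `"any"` (uniform
#'   over all other sampled parents, provenance-blind, the default),
#'   `"within"` (same provenance) or `"between"` (other provenance).
#' @param two_parent_frac fraction of assigned offspring for which a second
#'   parent (the mate) is also recovered in the pedigree.
#' @param grilse_frac probability that a fish returns as a grilse (one sea
#'   winter) rather than multi-sea-winter (MSW); the balance return a year
#'   later.
#' @param sex_ratio probability that a fish is female.
#' @param fecundity_multiplier_captive captive-to-wild ratio of eggs per
#'   female of equal size.
#' @param first_cohort calendar year of the first simulated spawning cohort.
#' @param seed integer root seed; all stages of the generator derive their
#'   randomness from it.
#'
#' @return An object of class `"simulation_config"` (a named list).
#' @seealso [simulate_pedigree()]
#' @export
simulation_config <- function(n_cohorts = 6L,
                              n_wild = 400L,
                              n_captive = 120L,
                              true_rrs = 0.36,
                              zero_prob_wild = 0.55,
                              zero_prob_captive = 0.75,
                              mu_positive = 2.4,
                              theta = 1.5,
                              parent_sampling_frac = 0.9,
                              offspring_sampling_frac = 0.9,
                              assignment_error = 0.02,
                              error_direction = c("any", "within", "between"),
                              two_parent_frac = 0.21,
                              grilse_frac = 0.9,
                              sex_ratio = 0.5,
                              fecundity_multiplier_captive = 1.4,
                              first_cohort = 1977L,
                              seed = 1L) {
  error_direction <- match.arg(error_direction)
  cfg <- list(
    n_cohorts = as.integer(n_cohorts),
    n_wild = as.integer(n_wild),
    n_captive = as.integer(n_captive),
    true_rrs = true_rrs,
    zero_prob_wild = zero_prob_wild,
    zero_prob_captive = zero_prob_captive,
    mu_positive = mu_positive,
    theta = theta,
    parent_sampling_frac = parent_sampling_frac,
    offspring_sampling_frac = offspring_sampling_frac,
    assignment_error = assignment_error,
    error_direction = error_direction,
    two_parent_frac = two_parent_frac,
    grilse_frac = grilse_frac,
    sex_ratio = sex_ratio,
    fecundity_multiplier_captive = fecundity_multiplier_captive,
    first_cohort = as.integer(first_cohort),
    seed = as.integer(seed)
  )
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
  cfg
}

validate_simulation_config <- function(cfg) {
  stop_cfg <- function(msg) {
    stop(structure(
      class = c("salmonrrs_config_error", "error", "condition"),
      list(message = msg, call = sys.call(-1))
    ))
  }
  num1 <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x)
  with(cfg, {
    if (!num1(n_cohorts) || n_cohorts < 1L) {
      stop_cfg("`n_cohorts` must be a positive integer")
    }
    if (!num1(n_wild) || !num1(n_captive) || n_wild < 0L || n_captive < 0L) {
      stop_cfg("per-cohort counts `n_wild` and `n_captive` must be >= 0")
    }
    if (!num1(true_rrs) || true_rrs <= 0) {
      stop_cfg("`true_rrs` must be a positive real")
    }
    for (p in c("zero_prob_wild", "zero_prob_captive", "grilse_frac",
                "sex_ratio", "two_parent_frac")) {
      v <- cfg[[p]]
      if (!num1(v) || v < 0 || v > 1) {
        stop_cfg(sprintf("`%s` must be a probability in [0, 1]", p))
      }
    }
    if (!num1(mu_positive) || mu_positive < 1) {
      stop_cfg("`mu_positive` must be >= 1 (positive part has support >= 1)")
    }
    if (!num1(theta) || theta <= 0) stop_cfg("`theta` must be positive")
    for (p in c("parent_sampling_frac", "offspring_sampling_frac")) {
      v <- cfg[[p]]
      if (!num1(v) || v <= 0 || v > 1) {
        stop_cfg(sprintf("`%s` must lie in (0, 1]", p))
      }
    }
    if (!num1(assignment_error) || assignment_error < 0 ||
        assignment_error >= 1) {
      stop_cfg("`assignment_error` must lie in [0, 1)")
    }
    if (!num1(fecundity_multiplier_captive) ||
        fecundity_multiplier_captive <= 0) {
      stop_cfg("`fecundity_multiplier_captive` must be positive")
    }
    # the captive positive-part mean implied by true_rrs must stay >= 1 so the
    # shifted negative binomial remains well defined
    if (zero_prob_captive < 1) {
      mu_c <- true_rrs * (1 - zero_prob_wild) * mu_positive /
        (1 - zero_prob_captive)
      if (mu_c < 1) {
        stop_cfg(paste0(
          "implied captive positive-part mean ", signif(mu_c, 4),
          " is < 1; increase `mu_positive` or `zero_prob_captive`"
        ))
      }
    }
    invisible(cfg)
  })
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Synthetic pedigree configuration\n")
  cat(sprintf("  cohorts: %d (first %d); %d wild + %d captive spawners each\n",
              x$n_cohorts, x$first_cohort, x$n_wild, x$n_captive))
  cat(sprintf("  true RRS: %.3f; zero prob (wild/captive): %.2f/%.2f\n",
              x$true_rrs, x$zero_prob_wild, x$zero_prob_captive))
  cat(sprintf("  sampling (parents/offspring): %.2f/%.2f; assignment error: %.3f (%s)\n",
              x$parent_sampling_frac, x$offspring_sampling_frac,
              x$assignment_error, x$error_direction))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
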