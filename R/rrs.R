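#' Bias-corrected mean lifetime reproductive success
#'
#' Corrects the arithmetic mean LRS of a provenance for parentage-assignment
#' error and incomplete sampling.  The correction (i) subtracts the number
#' of offspring successfully assigned, `A`, from the number sampled, `S`;
#' (ii) divides the difference by the number of potential parents `N`;
#' (iii) multiplies by `epsilon / (1 - epsilon)` where `epsilon` is the
#' pedigree-derived assignment error; and (iv) subtracts the result from the
#' raw mean:
#' \deqn{\bar{L}_{corr} = \bar{L} - \frac{S - A}{N}\cdot\frac{\epsilon}{1-\epsilon}.}
#'
#' At extreme `epsilon` the corrected mean can go negative; it is reported
#' as-is with a warning unless `clamp = TRUE`, because clamping would
#' reintroduce bias.
#'
#' @param raw_mean arithmetic mean LRS.
#' @param n_offspring_sampled,S number of offspring sampled.
#' @param n_offspring_assigned,A number of those assigned to a parent.
#' @param n_parents,N number of potential parents the mean is taken over.
#' @param epsilon assignment-error rate in \[0, 1).
#' @param clamp if `TRUE`, negative corrected means are truncated at 0.
#' @return corrected mean (scalar).
#' @examples
#' unbiased_mean_lrs(2.0, 100, 90, 50, 0.05)
#' @export
unbiased_mean_lrs <- function(raw_mean, n_offspring_sampled,
                              n_offspring_assigned, n_parents, epsilon,
                              clamp = FALSE) {
  S <- n_offspring_sampled
  A <- n_offspring_assigned
  N <- n_parents
  if (!is.numeric(epsilon) || anyNA(epsilon) || any(epsilon < 0) ||
      any(epsilon >= 1)) {
    stop("`epsilon` must lie in [0, 1)")
  }
  if (any(N < 1)) stop("`n_parents` must be >= 1")
  if (any(A > S)) stop("assigned offspring cannot exceed sampled offspring")
  out <- raw_mean - ((S - A) / N) * (epsilon / (1 - epsilon))
  if (any(out < 0)) {
    if (clamp) {
      out <- pmax(out, 0)
    } else {
      warning("corrected mean LRS is negative; reported as-is (set clamp = TRUE to truncate)")
    }
  }
  out
}

#' Cohort relative reproductive success
#'
#' RRS of captive-bred fish in a cohort: corrected captive mean LRS divided
#' by corrected wild mean LRS.  Wild-bred fish have RRS 1 by construction.
#'
#' @param corrected_captive,corrected_wild corrected mean LRS by provenance.
#' @param cohort optional label used in error messages.
#' @return the ratio (>= 0).
#' @export
cohort_rrs <- function(corrected_captive, corrected_wild, cohort = NULL) {
  if (!is.finite(corrected_wild) || corrected_wild <= 0) {
    stop("wild corrected mean LRS must be positive to define RRS",
         if (!is.null(cohort)) paste0(" (cohort ", cohort, ")") else "")
  }
  if (corrected_captive < 0) {
    warning("negative captive corrected mean; RRS truncated at 0")
    corrected_captive <- 0
  }
  corrected_captive / corrected_wild
}

#' One-tailed permutation test for a provenance difference in mean LRS
#'
#' Tests the a-priori directional hypothesis that captive-bred fish have
#' lower mean LRS than wild-bred fish.  The observed statistic is
#' `mean(wild) - mean(captive)`; group labels are permuted `n_perm` times
#' and the one-tailed p-value is the proportion of permuted differences
#' exceeding the observed one.  Under `tie_rule = "strict"` the proportion
#' counts strict exceedances and can be exactly 0; under `"weak"` the
#' p-value is `(1 + #\{perm >= obs\}) / (1 + n_perm)`, which is never 0.
#'
#' @param lrs_captive,lrs_wild non-negative LRS vectors, both non-empty.
#' @param n_perm number of label permutations (>= 1).
#' @param tie_rule `"strict"` or `"weak"` (see above).
#' @param seed optional integer seed for the permutation stream.
#' @param alternative `"captive_lower"` (one-tailed, default) or
#'   `"two_sided"`.
#' @return list: `observed_diff`, `p`, `n_perm`, `tie_rule`.
#' @examples
#' permutation_test(c(0, 0, 1), c(2, 3, 1), n_perm = 1000, seed = 1)
#' @export
permutation_test <- function(lrs_captive, lrs_wild, n_perm = 1e6L,
                             tie_rule = c("weak", "strict"), seed = NULL,
                             alternative = c("captive_lower", "two_sided")) {
  tie_rule <- match.arg(tie_rule)
  alternative <- match.arg(alternative)
  if (length(lrs_captive) == 0L || length(lrs_wild) == 0L) {
    stop("both groups must be non-empty")
  }
  if (n_perm < 1) stop("`n_perm` must be >= 1")
  n_perm <- as.integer(n_perm)
  if (!is.null(seed)) set.seed(as.integer(seed))
  pooled <- c(lrs_wild, lrs_captive)
  n_w <- length(lrs_wild)
  n_tot <- length(pooled)
  if (length(unique(pooled)) == 1L) {
    warning("pooled LRS is constant; permutation p is 1 under the weak rule")
  }
  obs <- mean(lrs_wild) - mean(lrs_captive)
  tot <- sum(pooled)
  # diff is a monotone function of the permuted wild-group sum, so only the
  # subset sum needs drawing each iteration
  to_diff <- function(sw) sw / n_w - (tot - sw) / (n_tot - n_w)
  perm <- vapply(seq_len(n_perm), function(i) {
    to_diff(sum(pooled[sample.int(n_tot, n_w)]))
  }, numeric(1L))
  count_tail <- function(stat_obs, stat_perm, weak) {
    if (weak) sum(stat_perm >= stat_obs - 1e-12) else
      sum(stat_perm > stat_obs + 1e-12)
  }
  if (alternative == "two_sided") {
    n_ge <- count_tail(abs(obs), abs(perm), tie_rule == "weak")
  } else {
    n_ge <- count_tail(obs, perm, tie_rule == "weak")
  }
  p <- if (tie_rule == "weak") (1 + n_ge) / (1 + n_perm) else n_ge / n_perm
  list(observed_diff = obs, p = p, n_perm = n_perm, tie_rule = tie_rule,
       alternative = alternative)
}

#' Fisher's combined probability test
#'
#' Combines independent one-tailed p-values as `chi2 = -2 * sum(log(p))`,
#' referred to a chi-squared distribution with `2k` degrees of freedom.
#' A p-value of exactly 0 (possible under the strict permutation rule) makes
#' the logarithm undefined; with `zero_policy = "substitute"` each zero is
#' replaced by the weak-rule permutation floor `1 / (n_perm + 1)`, or by the
#' user-supplied alternative for that test if it is larger (the more
#' conservative choice).  Substitutions are logged in the result.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @param zero_policy `"error"` or `"substitute"`.
#' @param n_perm permutation count used to form the substitution floor.
#' @param alt_p optional vector (recycled) of alternative p-values to
#'   consider for zero entries; the larger candidate wins.
#' @return list of class `"fisher_combined"`: `chi2`, `df` (= 2k), `p`,
#'   `substitutions` (data.frame of index, original, substituted).
#' @examples
#' fisher_combined(rep(0.5, 6))
#' @export
fisher_combined <- function(p_values, zero_policy = c("error", "substitute"),
                            n_perm = 1e6L, alt_p = NULL) {
  zero_policy <- match.arg(zero_policy)
  if (length(p_values) == 0L) stop("`p_values` must be non-empty")
  if (anyNA(p_values) || any(p_values < 0) || any(p_values > 1)) {
    stop("all p-values must lie in [0, 1]")
  }
  subs <- data.frame(index = integer(0), original = numeric(0),
                     substituted = numeric(0))
  zero <- p_values == 0
  if (any(zero)) {
    if (zero_policy == "error") {
      stop("p-value of 0 cannot enter Fisher's combined test; ",
           "use zero_policy = \"substitute\"")
    }
    floor_p <- 1 / (n_perm + 1)
    alt <- if (is.null(alt_p)) rep(floor_p, length(p_values)) else
      rep_len(alt_p, length(p_values))
    repl <- pmax(floor_p, alt[zero])
    subs <- data.frame(index = which(zero), original = 0, substituted = repl)
    p_values[zero] <- repl
  }
  chi2 <- -2 * sum(log(p_values))
  df <- 2L * length(p_values)
  structure(list(chi2 = chi2, df = df,
                 p = stats::pchisq(chi2, df, lower.tail = FALSE),
                 substitutions = subs),
            class = "fisher_combined")
}

#' @export
print.fisher_combined <- function(x, ...) {
  cat(sprintf("Fisher's combined probability test: X2 = %.2f, d.f. = %d, p = %.3g\n",
              x$chi2, x$df, x$p))
  if (nrow(x$substitutions) > 0L) {
    cat(sprintf("  (%d zero p-value(s) substituted by the permutation floor)\n",
                nrow(x$substitutions)))
  }
  invisible(x)
}

#' Overall RRS as a weighted geometric mean of cohort estimates
#'
#' @param rrs_by_cohort positive cohort RRS values; non-positive entries are
#'   excluded with a warning because their logarithm is undefined.
#' @param weights positive weights, same length (default equal).
#' @return `exp(sum(w * log(r)) / sum(w))` over the retained cohorts.
#' @examples
#' overall_rrs(c(0.25, 1.0), c(1, 1))  # 0.5
#' @export
overall_rrs <- function(rrs_by_cohort, weights = rep(1, length(rrs_by_cohort))) {
  if (length(rrs_by_cohort) != length(weights)) {
    stop("`rrs_by_cohort` and `weights` must have the same length")
  }
  if (any(weights <= 0)) stop("weights must be positive")
  keep <- is.finite(rrs_by_cohort) & rrs_by_cohort > 0
  if (!all(keep)) {
    warning(sum(!keep), " cohort(s) with non-positive RRS excluded from the ",
            "weighted geometric mean (log undefined)")
  }
  if (!any(keep)) stop("no cohort with positive RRS; overall RRS undefined")
  r <- rrs_by_cohort[keep]
  w <- weights[keep]
  exp(sum(w * log(r)) / sum(w))
}

#' Test for an excess of zero-LRS records among captive-bred fish
#'
#' Two-sample test of equal proportions of zero-LRS records, one-sided in
#' the direction captive > wild (a higher zero fraction among captive-bred
#' fish indicates spawning failure rather than offspring survival).
#' Wraps [stats::prop.test()].
#'
#' @param n_zero_captive,n_captive zero-LRS count and total, captive group.
#' @param n_zero_wild,n_wild same for the wild group.
#' @param continuity apply the Yates continuity correction.
#' @return list: `chi2`, `p` (one-sided), `prop_captive`, `prop_wild`.
#' @export
zero_lrs_proportion_test <- function(n_zero_captive, n_captive,
                                     n_zero_wild, n_wild,
                                     continuity = FALSE) {
  if (n_captive <= 0 || n_wild <= 0) stop("group totals must be positive")
  if (n_zero_captive > n_captive || n_zero_wild > n_wild ||
      n_zero_captive < 0 || n_zero_wild < 0) {
    stop("zero counts must lie between 0 and the group totals")
  }
  ht <- stats::prop.test(c(n_zero_captive, n_zero_wild),
                         c(n_captive, n_wild),
                         alternative = "greater", correct = continuity)
  list(chi2 = unname(ht$statistic), p = ht$p.value,
       prop_captive = n_zero_captive / n_captive,
       prop_wild = n_zero_wild / n_wild)
}

#' RRS restricted to fish that left at least one offspring
#'
#' Drops LRS = 0 records from both provenances, recomputes the raw means and
#' their ratio, and runs the one-tailed permutation test on the restricted
#' data.  No assignment-error correction is applied to the filtered subset:
#' the correction is defined for the full sample of potential parents, and
#' restricting to successful spawners changes the sampling frame.
#'
#' @inheritParams permutation_test
#' @return list: `rrs`, `p`, `n_captive`, `n_wild` (positive-record counts),
#'   `observed_diff`.
#' @export
zero_excluded_rrs <- function(lrs_captive, lrs_wild, n_perm = 1e6L,
                              tie_rule = c("weak", "strict"), seed = NULL) {
  tie_rule <- match.arg(tie_rule)
  pc <- lrs_captive[lrs_captive > 0]
  pw <- lrs_wild[lrs_wild > 0]
  if (length(pc) == 0L) stop("captive group has no positive-LRS records")
  if (length(pw) == 0L) stop("wild group has no positive-LRS records")
  pt <- permutation_test(pc, pw, n_perm = n_perm, tie_rule = tie_rule,
                         seed = seed)
  list(rrs = mean(pc) / mean(pw), p = pt$p,
       n_captive = length(pc), n_wild = length(pw),
       observed_diff = pt$observed_diff)
}

#' Reduction in mean LRS of the mixed population
#'
#' Percentage reduction in mean individual LRS of the mixed (wild plus
#' captive-bred) population relative to a hypothetical pure wild population:
#' cohort captive counts are multiplied by their cohort RRS, wild counts by
#' 1, the products are summed across cohorts and divided by the grand total
#' of fish, and the result is subtracted from 1 and multiplied by 100.
#'
#' @param n_captive_by_cohort,n_wild_by_cohort per-cohort counts.
#' @param rrs_by_cohort per-cohort captive RRS (wild RRS is 1).
#' @return percent reduction (positive when captive RRS < 1 on average).
#' @examples
#' mixed_population_reduction(50, 0.36, 50)  # 32
#' @export
mixed_population_reduction <- function(n_captive_by_cohort, rrs_by_cohort,
                                       n_wild_by_cohort) {
  k <- length(rrs_by_cohort)
  if (length(n_captive_by_cohort) != k || length(n_wild_by_cohort) != k) {
    stop("cohort count and RRS vectors must have equal length")
  }
  tot <- sum(n_captive_by_cohort) + sum(n_wild_by_cohort)
  if (tot <= 0) stop("no fish in any cohort")
  100 * (1 - sum(n_captive_by_cohort * rrs_by_cohort + n_wild_by_cohort) / tot)
}
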