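# Small in-code fixtures and independent oracles shared across test files.

# fish table with explicit provenances/sexes; ids p1..pn
make_fish <- function(provenance, sex = rep("F", length(provenance)),
                      return_year = rep(1977L, length(provenance))) {
  data.frame(fish_id = paste0("p", seq_along(provenance)),
             provenance = provenance, sex = sex,
             return_year = return_year, stringsAsFactors = FALSE)
}

# parentage table from a named list: parent_id -> number of offspring
make_parentage <- function(counts, n_parents_assigned = 1L) {
  parent <- rep(names(counts), unlist(counts))
  data.frame(offspring_id = sprintf("o%03d", seq_along(parent)),
             parent_id = parent,
             n_parents_assigned = n_parents_assigned,
             stringsAsFactors = FALSE)
}

# exhaustive one-tailed permutation distribution for small groups:
# returns P(perm diff > obs) and P(perm diff >= obs) over all C(n, n_w)
# label arrangements (the oracle is a direct enumeration, independent of
# the sampling-based implementation)
enumerate_permutation_p <- function(captive, wild) {
  pooled <- c(wild, captive)
  n_w <- length(wild)
  obs <- mean(wild) - mean(captive)
  sets <- utils::combn(length(pooled), n_w)
  diffs <- apply(sets, 2L, function(idx) {
    mean(pooled[idx]) - mean(pooled[-idx])
  })
  list(obs = obs,
       p_strict = mean(diffs > obs + 1e-12),
       p_weak_num = mean(diffs >= obs - 1e-12),
       n_arrangements = ncol(sets))
}

# independent 2x2 chi-squared arithmetic (no continuity correction)
chi2_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# hand-evaluated correction following the four steps in order
correction_steps_oracle <- function(raw_mean, S, A, N, eps) {
  step1 <- S - A
  step2 <- step1 / N
  step3 <- step2 * (eps / (1 - eps))
  raw_mean - step3
}

# census table with one wild/captive grilse/MSW row per year
make_census <- function(years, wild_grilse, wild_msw = 0,
                        captive_grilse = 0, captive_msw = 0) {
  k <- length(years)
  expand <- function(prov, age, count) {
    data.frame(year = years, provenance = prov, sea_age = age,
               count = rep_len(count, k), stringsAsFactors = FALSE)
  }
  rbind(expand("wild", "grilse", wild_grilse),
        expand("wild", "MSW", wild_msw),
        expand("captive", "grilse", captive_grilse),
        expand("captive", "MSW", captive_msw))
}
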