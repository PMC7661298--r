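test_that("config validation rejects out-of-range parameters", {
  expect_error(simulation_config(assignment_error = 1), "0, 1")
  expect_error(simulation_config(assignment_error = -0.1), "0, 1")
  expect_error(simulation_config(zero_prob_wild = 1.2), "probability")
  expect_error(simulation_config(true_rrs = 0), "positive")
  expect_error(simulation_config(theta = -1), "positive")
  expect_error(simulation_config(parent_sampling_frac = 0), "\\(0, 1\\]")
  expect_error(simulation_config(n_cohorts = 0), "positive integer")
  # implied captive positive-part mean below the support minimum
  expect_error(simulation_config(true_rrs = 0.05, mu_positive = 1.1,
                                 zero_prob_captive = 0.5),
               "positive-part mean")
})

test_that("identical seeds give identical output; different seeds differ", {
  cfg <- simulation_config(n_wild = 80, n_captive = 40, seed = 11)
  a <- simulate_pedigree(cfg)
  b <- simulate_pedigree(cfg)
  expect_identical(a$fish, b$fish)
  expect_identical(a$parentage, b$parentage)
  expect_identical(a$census, b$census)
  cfg2 <- simulation_config(n_wild = 80, n_captive = 40, seed = 12)
  expect_false(identical(simulate_pedigree(cfg2)$parentage, a$parentage))
})

test_that("with no error and full sampling every link is the true parent", {
  cfg <- simulation_config(n_cohorts = 2, n_wild = 150, n_captive = 60,
                           assignment_error = 0, parent_sampling_frac = 1,
                           offspring_sampling_frac = 1, two_parent_frac = 0,
                           seed = 4)
  sim <- simulate_pedigree(cfg)
  map <- sim$truth$parent_map
  expect_equal(nrow(sim$parentage), nrow(map))
  got <- sim$parentage$parent_id[match(map$offspring_id,
                                       sim$parentage$offspring_id)]
  expect_identical(got, map$true_parent_id)
})

test_that("null configuration has equal generating means by construction", {
  cfg <- simulation_config(true_rrs = 1, zero_prob_captive = 0.55,
                           zero_prob_wild = 0.55, seed = 2)
  sim <- simulate_pedigree(cfg)
  expect_equal(unname(sim$truth$generating_means["wild"]),
               unname(sim$truth$generating_means["captive"]))
})

test_that("degenerate all-zero hurdle gives all-zero LRS", {
  cfg <- simulation_config(n_cohorts = 1, n_wild = 50, n_captive = 20,
                           zero_prob_wild = 1, zero_prob_captive = 1,
                           seed = 3)
  sim <- simulate_pedigree(cfg)
  expect_equal(nrow(sim$parentage), 0L)
  fish <- assign_spawning_cohorts(sim$fish)
  lrs <- compute_lrs(sim$parentage, fish)
  expect_true(all(lrs$lrs == 0))
})

test_that("empirical zero-LRS fraction converges to the hurdle probability", {
  pi_w <- 0.55
  cfg <- simulation_config(n_cohorts = 1, n_wild = 10000, n_captive = 0,
                           zero_prob_wild = pi_w, assignment_error = 0,
                           parent_sampling_frac = 1,
                           offspring_sampling_frac = 1, two_parent_frac = 0,
                           seed = 21)
  sim <- simulate_pedigree(cfg)
  fish <- sim$fish[sim$fish$role == "spawner", ]
  lrs <- compute_lrs(sim$parentage, assign_spawning_cohorts(sim$fish))
  zero_frac <- mean(lrs$lrs[match(fish$fish_id, lrs$fish_id)] == 0)
  n <- nrow(fish)
  expect_lt(abs(zero_frac - pi_w), 3 * sqrt(pi_w * (1 - pi_w) / n))
})

test_that("sampling and assignment tallies respect their bounds", {
  sim <- simulate_pedigree(simulation_config(seed = 17))
  t <- sim$truth$tallies
  expect_true(all(t$n_assigned <= t$n_offspring_sampled))
  expect_true(all(t$n_offspring_sampled <= t$n_offspring_true))
})

test_that("productivity generator is deterministic and honours its contract", {
  a <- simulate_productivity_series(n_years = 30, seed = 5)
  b <- simulate_productivity_series(n_years = 30, seed = 5)
  expect_identical(a$series, b$series)
  expect_true(all(a$series$spawners > 0))
  expect_true(all(a$series$prop_captive >= 0.01 &
                    a$series$prop_captive <= 0.59))
  expect_error(simulate_productivity_series(n_years = 5), ">= 10")
  expect_error(
    simulate_productivity_series(
      n_years = 12,
      density_params = list(mean_spawners = -50, sd_spawners = 1),
      seed = 1, max_resample = 10),
    "max_resample")
})

test_that("noise-free null productivity series has a near-zero intrusion slope", {
  sim <- simulate_productivity_series(n_years = 120, beta_true = 0,
                                      noise_sd = 0, seed = 8)
  g <- fit_density_gam(sim$series, k = 9)
  reg <- intrusion_regression(g)
  expect_lt(abs(reg$slope), 1e-4)
})

test_that("constant intrusion proportions are flagged as degenerate downstream", {
  sim <- simulate_productivity_series(n_years = 40, intrusion_range = c(0.3, 0.3),
                                      seed = 13)
  g <- fit_density_gam(sim$series, k = 9)
  expect_error(intrusion_regression(g), "degenerate|constant")
})
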