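test_that("recruits per spawner follows the t+4 / t+5 rule", {
  census <- rbind(
    data.frame(year = 1970, provenance = c("wild", "captive"),
               sea_age = "grilse", count = c(60, 40)),
    data.frame(year = 1974, provenance = "wild", sea_age = "grilse",
               count = 30),
    data.frame(year = 1975, provenance = "wild", sea_age = "MSW",
               count = 10))
  out <- recruits_per_spawner(census, t_range = 1970)
  expect_equal(out$spawners, 100)
  expect_equal(out$recruits, 40)
  expect_equal(out$productivity, 0.4)
  expect_equal(out$prop_captive, 0.4)
  expect_equal(out$log_productivity, log(0.4))
})

test_that("productivity is invariant to scaling all census counts", {
  census <- make_census(1970:1985, wild_grilse = 80 + (1970:1985 %% 7) * 5,
                        wild_msw = 10, captive_grilse = 20)
  a <- recruits_per_spawner(census)
  census2 <- census
  census2$count <- census2$count * 2
  b <- recruits_per_spawner(census2)
  expect_equal(a$productivity, b$productivity)
  expect_equal(a$prop_captive, b$prop_captive)
  expect_equal(b$spawners, 2 * a$spawners)
})

test_that("incomplete recruit years are excluded and zero recruits guarded", {
  census <- make_census(1970:1980, wild_grilse = 50)
  out <- recruits_per_spawner(census)
  # 1976 needs 1981 returns; complete cohorts are 1970..1975
  expect_equal(out$year, 1970:1975)
  expect_error(recruits_per_spawner(census, t_range = 1979),
               "no year with complete")
  zc <- make_census(1970:1980, wild_grilse = c(rep(50, 4), 0, rep(50, 6)),
                    captive_grilse = c(rep(0, 4), 10, rep(0, 6)))
  expect_warning(out2 <- recruits_per_spawner(zc), "zero-recruit")
  y0 <- out2$year[out2$recruits == 0]
  expect_true(all(is.na(out2$log_productivity[out2$year %in% y0])))
  out3 <- suppressWarnings(recruits_per_spawner(zc, log_offset = 0.5))
  expect_true(all(is.finite(out3$log_productivity)))
})

test_that("census schema violations are named", {
  expect_error(recruits_per_spawner(data.frame(year = 1, count = 2)),
               "provenance")
})

test_that("spline fit absorbs constant and linear signals", {
  set.seed(2)
  n <- 40
  s <- runif(n, 100, 1000)
  base <- data.frame(spawners = s, prop_captive = runif(n),
                     log_productivity = rep(0.7, n))
  g1 <- fit_density_gam(base, k = 9)
  expect_lt(max(abs(g1$residuals)), 1e-9)
  lin <- base
  lin$log_productivity <- 2 - 0.001 * s
  g2 <- fit_density_gam(lin, k = 9)
  expect_lt(stats::var(g2$residuals), 1e-8 * stats::var(lin$log_productivity))
})

test_that("spline residuals are uncorrelated with density on curved truth", {
  set.seed(14)
  cors <- replicate(5, {
    sim <- simulate_productivity_series(n_years = 150, beta_true = 0,
                                        noise_sd = 0.2,
                                        seed = sample.int(1e6, 1))
    g <- fit_density_gam(sim$series, k = 9)
    cor(g$residuals, g$series$spawners)
  })
  expect_lt(max(abs(cors)), 0.1)
})

test_that("spline fit validates its inputs", {
  small <- data.frame(spawners = 1:8, log_productivity = rnorm(8))
  expect_error(fit_density_gam(small, k = 9), "k \\+ 2")
  dup <- data.frame(spawners = rep(c(1, 2), 10),
                    log_productivity = rnorm(20))
  expect_error(fit_density_gam(dup, k = 9), "rank deficient|distinct")
})

test_that("intrusion regression recovers an exact linear relationship", {
  p <- seq(0.05, 0.5, length.out = 20)
  reg <- suppressWarnings(intrusion_regression(-0.9 * p, p))
  expect_equal(reg$slope, -0.9)
  expect_equal(reg$r_squared, 1)
  expect_error(intrusion_regression(rnorm(10), rep(0.3, 10)), "degenerate")
  expect_error(intrusion_regression(rnorm(5), runif(6)), "equal length")
})

test_that("F, p and adjusted R2 satisfy their closed-form identities", {
  set.seed(9)
  for (i in 1:5) {
    n <- sample(20:60, 1)
    p <- runif(n, 0.01, 0.59)
    reg <- intrusion_regression(-0.5 * p + rnorm(n, 0, 0.3), p)
    expect_equal(reg$p, pf(reg$f_statistic, 1, reg$df[2], lower.tail = FALSE))
    r2 <- reg$f_statistic / (reg$f_statistic + reg$df[2])
    expect_equal(reg$r_squared, r2, tolerance = 1e-10)
    expect_equal(reg$adj_r_squared,
                 1 - (1 - r2) * (n - 1) / (n - 2), tolerance = 1e-10)
    expect_gte(reg$r_squared, reg$adj_r_squared)
  }
})

test_that("permuting the predictor destroys the slope on average", {
  set.seed(23)
  p <- runif(40, 0.01, 0.59)
  resid <- -0.8 * p + rnorm(40, 0, 0.1)
  slopes <- replicate(200, intrusion_regression(resid, sample(p))$slope)
  expect_lt(abs(mean(slopes)), 0.05)
  expect_lt(abs(mean(slopes)), abs(intrusion_regression(resid, p)$slope) / 5)
})

test_that("percent reduction is the back-transformed log-scale effect", {
  expect_equal(percent_reduction(-3, 0), 0)
  expect_equal(percent_reduction(0, 0.7), 0)
  expect_equal(percent_reduction(-0.686, 0.15),
               100 * (1 - exp(-0.686 * 0.15)))
  # monotone in |beta| for beta < 0
  betas <- seq(-0.1, -2, by = -0.1)
  expect_true(all(diff(percent_reduction(betas, 0.15)) > 0))
  expect_error(percent_reduction(-1, 1.5), "\\[0, 1\\]")
})

test_that("density-intrusion correlation matches the t closed form", {
  set.seed(4)
  s <- runif(43, 200, 1200)
  p <- runif(43, 0.01, 0.59)
  out <- density_intrusion_correlation(s, p)
  r_hand <- sum(scale(s) * scale(p)) / (length(s) - 1)
  expect_equal(out$r, r_hand, tolerance = 1e-12)
  expect_equal(out$df, 41)
  expect_equal(out$t_stat, out$r * sqrt(out$df / (1 - out$r^2)),
               tolerance = 1e-12)
  expect_equal(out$p, 2 * pt(-abs(out$t_stat), out$df), tolerance = 1e-12)
  expect_warning(density_intrusion_correlation(1:10, (1:10) / 20), "collinear")
  expect_error(density_intrusion_correlation(rep(1, 5), runif(5)),
               "zero-variance")
})

test_that("egg-based productivity reduces to the adult measure and splits eggs 1.4:1", {
  census <- make_census(1970:1980, wild_grilse = 60, captive_grilse = 60)
  census$mean_female_length <- 64
  fec <- fecundity_model(intercept = 0.5, slope = 1.9,
                         captive_multiplier = 1)
  adult <- recruits_per_spawner(census)
  ova <- ova_productivity(census, fec)
  expect_equal(ova$productivity, adult$productivity)
  # multiplier 1.4, equal counts and lengths: captive egg share 1.4 / 2.4
  fec14 <- fecundity_model(intercept = 0.5, slope = 1.9,
                           captive_multiplier = 1.4)
  ova14 <- ova_productivity(census, fec14)
  expect_equal(unique(ova14$prop_captive), 1.4 / 2.4)
  expect_error(ova_productivity(census, fecundity = list()),
               "fecundity_model")
  expect_error(fecundity_model(captive_multiplier = 2), "must be supplied")
})

test_that("years with no recruiting females contribute zero egg recruits", {
  census <- make_census(1970:1980, wild_grilse = 60, captive_grilse = 20)
  census$mean_female_length <- ifelse(census$year >= 1974, NA, 64)
  fec <- fecundity_model(intercept = 0.5, slope = 1.9)
  out <- suppressWarnings(
    ova_productivity(census, fec, t_range = 1970, log_offset = NULL))
  expect_equal(out$recruits, 0)  # recruit years 1974/1975 have no females
  expect_equal(out$productivity, 0)
})
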