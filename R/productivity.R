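#' Adult-to-adult productivity series from a census table
#'
#' Recruits produced by spawning cohort `t` are counted as wild-bred grilse
#' returning in year `t + lag_grilse` plus wild-bred MSW fish returning in
#' year `t + lag_msw` (all wild fish are assumed to smolt at age 2+, so the
#' defaults are 4 and 5).  Spawners in year `t` are all returning fish of
#' both provenances, which is also the denominator of the hatchery-intrusion
#' proportion.  Productivity is recruits per spawner.
#'
#' Years lacking either recruit year, or with zero spawners, are excluded
#' and counted in the `n_excluded` attribute.  Zero-recruit years have
#' `P_t = 0`; their log productivity is `NA` by default (dropped from any
#' subsequent fit) or `log(P_t + log_offset)` when a positive offset is
#' supplied.
#'
#' @param census data.frame: `year`, `provenance` (`"wild"`/`"captive"`),
#'   `sea_age` (`"grilse"`/`"MSW"`), `count`.
#' @param t_range optional integer vector of cohort years to evaluate;
#'   default: every year with complete life-cycle data.
#' @param lag_grilse,lag_msw years from spawning to adult return by sea-age
#'   class.
#' @param log_offset optional small constant added inside the log for
#'   zero-recruit years (default none).
#' @return data.frame of class `"productivity_series"`: `year`, `spawners`,
#'   `recruits`, `productivity`, `log_productivity`, `prop_captive`.
#' @examples
#' census <- expand.grid(year = 1970:1980, provenance = c("wild", "captive"),
#'                       sea_age = c("grilse", "MSW"))
#' census$count <- c(100, 40)[as.integer(census$provenance)]
#' recruits_per_spawner(census)
#' @export
recruits_per_spawner <- function(census, t_range = NULL,
                                 lag_grilse = 4L, lag_msw = 5L,
                                 log_offset = NULL) {
  need <- c("year", "provenance", "sea_age", "count")
  if (!all(need %in% names(census))) {
    stop("`census` must have columns: ", paste(need, collapse = ", "))
  }
  if (any(census$count < 0)) stop("census counts must be non-negative")
  years_obs <- sort(unique(census$year))
  if (is.null(t_range)) {
    t_range <- years_obs[(years_obs + lag_msw) %in% years_obs &
                           (years_obs + lag_grilse) %in% years_obs]
  }
  count_of <- function(year, prov = NULL, age = NULL) {
    keep <- census$year == year
    if (!is.null(prov)) keep <- keep & census$provenance == prov
    if (!is.null(age)) keep <- keep & census$sea_age == age
    sum(census$count[keep])
  }
  n_excluded <- 0L
  rows <- lapply(t_range, function(t) {
    if (!((t + lag_grilse) %in% years_obs && (t + lag_msw) %in% years_obs)) {
      n_excluded <<- n_excluded + 1L
      return(NULL)
    }
    s <- count_of(t)
    if (s <= 0) {
      warning("year ", t, " has no spawners; excluded")
      n_excluded <<- n_excluded + 1L
      return(NULL)
    }
    r <- count_of(t + lag_grilse, "wild", "grilse") +
      count_of(t + lag_msw, "wild", "MSW")
    p <- r / s
    lp <- if (p > 0) log(p) else if (!is.null(log_offset)) {
      log(p + log_offset)
    } else NA_real_
    data.frame(year = t, spawners = s, recruits = r, productivity = p,
               log_productivity = lp,
               prop_captive = count_of(t, "captive") / s)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0L) {
    stop("no year with complete life-cycle data in `t_range`")
  }
  rownames(out) <- NULL
  n_zero <- sum(out$productivity == 0)
  if (n_zero > 0L && is.null(log_offset)) {
    warning(n_zero, " zero-recruit year(s): log productivity set NA ",
            "(supply `log_offset` to retain them)")
  }
  structure(out, class = c("productivity_series", "data.frame"),
            n_excluded = n_excluded,
            lags = c(grilse = lag_grilse, msw = lag_msw))
}

#' Egg-based (ova-per-ovum) productivity series
#'
#' Converts adults into eggs before forming the productivity ratio, so that
#' shifts in the grilse:MSW ratio and the higher per-capita fecundity of
#' captive-bred females are reflected.  Potential egg deposition of a group
#' is `count * female_fraction * fecundity(length)`, with captive-bred
#' females multiplied by `fecundity$captive_multiplier`.  Productivity in
#' year `t` is eggs of the recruits (wild grilse `t+4`, wild MSW `t+5`)
#' per egg of the year-`t` spawners, and the intrusion measure becomes the
#' captive share of spawner eggs.
#'
#' @param census as in [recruits_per_spawner()], with a
#'   `mean_female_length` column (cm).
#' @param fecundity a [fecundity_model()]; there is no default because the
#'   underlying length-fecundity relationship must be supplied explicitly.
#' @param female_fraction fraction of each census group assumed female.
#' @inheritParams recruits_per_spawner
#' @return a `"productivity_series"` where `spawners`/`recruits` are egg
#'   totals and `prop_captive` is the captive egg share.
#' @export
ova_productivity <- function(census, fecundity, female_fraction = 0.5,
                             t_range = NULL, lag_grilse = 4L, lag_msw = 5L,
                             log_offset = NULL) {
  if (missing(fecundity) || !inherits(fecundity, "fecundity_model")) {
    stop("`fecundity` must be a fecundity_model(); the length-fecundity ",
         "relationship has no default and must be configured explicitly")
  }
  if (!"mean_female_length" %in% names(census)) {
    stop("`census` must have a `mean_female_length` column")
  }
  cen <- census
  mult <- ifelse(cen$provenance == "captive",
                 fecundity$captive_multiplier, 1)
  eggs_per_female <- predict(fecundity, cen$mean_female_length) * mult
  eggs_per_female[is.na(eggs_per_female)] <- 0  # groups with no females
  cen$count <- cen$count * female_fraction * eggs_per_female
  out <- recruits_per_spawner(cen, t_range = t_range,
                              lag_grilse = lag_grilse, lag_msw = lag_msw,
                              log_offset = log_offset)
  attr(out, "measure") <- "ova_per_ovum"
  out
}

#' Length-fecundity relationship
#'
#' Log-linear model of eggs per female on fork length:
#' `log(eggs) = intercept + slope * log(length_cm)`, with a multiplicative
#' adjustment for captive-bred females, whose egg counts per unit body mass
#' exceed those of wild-bred females.
#'
#' @param intercept,slope coefficients on the log-log scale.
#' @param captive_multiplier captive-to-wild egg ratio at equal length.
#' @return object of class `"fecundity_model"`.
#' @examples
#' fec <- fecundity_model(intercept = 0.5, slope = 1.9)
#' predict(fec, 65)
#' @export
fecundity_model <- function(intercept, slope, captive_multiplier = 1.4) {
  if (missing(intercept) || missing(slope)) {
    stop("`intercept` and `slope` of the length-fecundity relationship ",
         "must be supplied")
  }
  if (captive_multiplier <= 0) stop("`captive_multiplier` must be positive")
  structure(list(intercept = intercept, slope = slope,
                 captive_multiplier = captive_multiplier),
            class = "fecundity_model")
}

#' @export
predict.fecundity_model <- function(object, newdata, ...) {
  len <- if (is.data.frame(newdata)) newdata$fork_length else newdata
  eggs <- exp(object$intercept + object$slope * log(len))
  if (any(eggs <= 0, na.rm = TRUE)) {
    stop("fecundity model predicts non-positive eggs in the given length range")
  }
  eggs
}

#' Density correction of log productivity by a penalized regression spline
#'
#' Regresses log productivity on spawner abundance with a penalized cubic
#' regression spline (basis dimension `k`, default nine knots), smoothing
#' parameter chosen by generalized cross-validation via [mgcv::gam()].  The
#' residuals are the density-corrected productivity: what is left of log
#' recruits-per-spawner after the stock-recruitment relationship with
#' spawner density is removed.
#'
#' @param series a `"productivity_series"` (rows with `NA` log productivity
#'   are dropped).
#' @param k spline basis dimension (number of knots).
#' @param bs basis type passed to [mgcv::s()] (default cubic regression
#'   spline).
#' @param select_by smoothing-selection criterion passed to `mgcv::gam`'s
#'   `method` argument.
#' @return list of class `"density_gam"`: `fit` (the `gam` object),
#'   `fitted`, `residuals`, `edf` (effective degrees of freedom of the
#'   smooth), `k`, `series` (the rows used).
#' @export
fit_density_gam <- function(series, k = 9L, bs = "cr",
                            select_by = "GCV.Cp") {
  need <- c("spawners", "log_productivity")
  if (!all(need %in% names(series))) {
    stop("`series` must have columns `spawners` and `log_productivity`")
  }
  use <- series[is.finite(series$log_productivity), , drop = FALSE]
  if (nrow(use) < k + 2L) {
    stop("need at least k + 2 = ", k + 2L, " usable years; have ", nrow(use))
  }
  if (length(unique(use$spawners)) < k) {
    stop("spawner series has fewer than k = ", k,
         " distinct values; the \"", bs, "\" basis would be rank deficient")
  }
  fit <- mgcv::gam(log_productivity ~ s(spawners, k = k, bs = bs),
                   data = use, method = select_by)
  structure(list(fit = fit,
                 fitted = as.numeric(stats::fitted(fit)),
                 residuals = as.numeric(stats::residuals(fit)),
                 edf = sum(fit$edf),
                 k = k,
                 series = use),
            class = "density_gam")
}

#' @export
print.density_gam <- function(x, ...) {
  cat(sprintf("Density-correction GAM: %d years, k = %d, total edf = %.2f\n",
              nrow(x$series), x$k, x$edf))
  invisible(x)
}

#' Regression of density-corrected productivity on hatchery intrusion
#'
#' Ordinary least squares of the GAM residuals on the annual proportion of
#' captive-bred potential spawners.  A negative slope means productivity is
#' lower in years of stronger hatchery intrusion, after accounting for
#' density dependence.
#'
#' @param residuals density-corrected log productivity (from
#'   [fit_density_gam()]), or a `"density_gam"` object.
#' @param prop_captive annual captive-bred proportions, same length.
#' @return list of class `"intrusion_regression"`: `slope`, `intercept`,
#'   `r_squared`, `adj_r_squared`, `f_statistic`, `df` (c(1, n - 2)), `p`,
#'   `n`.
#' @export
intrusion_regression <- function(residuals, prop_captive) {
  if (inherits(residuals, "density_gam")) {
    if (missing(prop_captive)) prop_captive <- residuals$series$prop_captive
    residuals <- residuals$residuals
  }
  if (length(residuals) != length(prop_captive)) {
    stop("`residuals` and `prop_captive` must have equal length")
  }
  ok <- is.finite(residuals) & is.finite(prop_captive)
  if (!all(ok)) stop("inputs must be finite")
  if (length(residuals) < 3L) stop("need at least 3 years")
  if (stats::var(prop_captive) == 0) {
    stop("`prop_captive` is constant; the intrusion regression is degenerate")
  }
  fit <- stats::lm(residuals ~ prop_captive)
  sm <- summary(fit)
  n <- length(residuals)
  structure(list(
    slope = unname(stats::coef(fit)[2L]),
    intercept = unname(stats::coef(fit)[1L]),
    r_squared = sm$r.squared,
    adj_r_squared = sm$adj.r.squared,
    f_statistic = unname(sm$fstatistic["value"]),
    df = c(1L, n - 2L),
    p = unname(stats::pf(sm$fstatistic["value"], 1, n - 2,
                         lower.tail = FALSE)),
    n = n
  ), class = "intrusion_regression")
}

#' @export
print.intrusion_regression <- function(x, ...) {
  cat(sprintf(
    "Intrusion regression: slope = %.3f, adj. R2 = %.2f, F(1, %d) = %.2f, p = %.3g\n",
    x$slope, x$adj_r_squared, x$df[2L], x$f_statistic, x$p))
  invisible(x)
}

#' Back-transformed percent reduction in productivity
#'
#' Converts a slope on the log-productivity scale into the percent reduction
#' in productivity at intrusion level `x` relative to a hypothetical pure
#' wild population (`x = 0`): `100 * (1 - exp(beta * x))`.
#'
#' @param beta intrusion slope on the log scale.
#' @param x proportion captive-bred in \[0, 1\].
#' @return percent reduction (positive for `beta < 0`).
#' @examples
#' percent_reduction(-0.686, 0.15)  # ~9.78
#' @export
percent_reduction <- function(beta, x) {
  if (any(x < 0 | x > 1)) stop("`x` must lie in [0, 1]")
  100 * (1 - exp(beta * x))
}

#' Significance of a Pearson correlation given r and its degrees of freedom
#'
#' Recovers the t statistic and two-sided p-value from a correlation
#' coefficient and residual degrees of freedom (`df = n - 2`), for use when
#' only the summary statistics are available:
#' `t = r * sqrt(df / (1 - r^2))`.
#'
#' @param r Pearson correlation in (-1, 1).
#' @param df residual degrees of freedom (n - 2, >= 1).
#' @return list: `t_stat`, `df`, `p`.
#' @examples
#' correlation_significance(0.056, 41)
#' @export
correlation_significance <- function(r, df) {
  if (abs(r) >= 1) stop("`r` must lie strictly inside (-1, 1)")
  if (df < 1) stop("`df` must be >= 1")
  t_stat <- r * sqrt(df / (1 - r^2))
  list(t_stat = t_stat, df = df, p = 2 * stats::pt(-abs(t_stat), df))
}

#' Significance and fit of a simple regression given F and its df
#'
#' Recovers the p-value, R-squared and adjusted R-squared of a
#' single-predictor OLS fit from the F statistic with (1, df2) degrees of
#' freedom: `R2 = F / (F + df2)` and
#' `adjR2 = 1 - (1 - R2) * (df2 + 1) / df2`.
#'
#' @param f_statistic F value (>= 0).
#' @param df2 denominator degrees of freedom (n - 2).
#' @return list: `p`, `r_squared`, `adj_r_squared`, `df`.
#' @examples
#' regression_significance(6.44, 41)
#' @export
regression_significance <- function(f_statistic, df2) {
  if (f_statistic < 0) stop("`f_statistic` must be >= 0")
  if (df2 < 1) stop("`df2` must be >= 1")
  r2 <- f_statistic / (f_statistic + df2)
  n <- df2 + 2
  list(p = stats::pf(f_statistic, 1, df2, lower.tail = FALSE),
       r_squared = r2,
       adj_r_squared = 1 - (1 - r2) * (n - 1) / (n - 2),
       df = c(1, df2))
}

#' Correlation between spawner density and hatchery intrusion
#'
#' Pearson correlation between annual spawner counts (the density proxy)
#' and the proportion captive-bred, with `t = r * sqrt(df / (1 - r^2))`,
#' `df = n - 2`, and a two-sided p-value.  A weak correlation supports using
#' density correction and intrusion regression as separable steps.
#'
#' @param spawners,prop_captive equal-length numeric vectors, n >= 3.
#' @return list: `r`, `t_stat`, `df`, `p`.
#' @export
density_intrusion_correlation <- function(spawners, prop_captive) {
  if (length(spawners) != length(prop_captive)) {
    stop("inputs must have equal length")
  }
  if (length(spawners) < 3L) stop("need at least 3 years")
  if (stats::var(spawners) == 0 || stats::var(prop_captive) == 0) {
    stop("zero-variance input; correlation undefined")
  }
  ht <- stats::cor.test(spawners, prop_captive, method = "pearson")
  if (abs(unname(ht$estimate)) >= 1 - 1e-12) {
    warning("|r| = 1: inputs are perfectly collinear")
  }
  list(r = unname(ht$estimate), t_stat = unname(ht$statistic),
       df = unname(ht$parameter), p = ht$p.value)
}
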