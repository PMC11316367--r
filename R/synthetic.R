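# Synthetic unit-by-year panels with the statistical structure the analysis
# assumes: piecewise national trends in enrolment (including a one-off
# administrative purge of inactive records), FTE workforce and average list
# size; right-skewed unit sizes; contextual covariates with controlled
# correlations to the list ratio; and an age mix drifting between configured
# weighted-units-per-patient endpoints.  Unassigned patients are always
# derived through the accounting identity m = n - GP * L, never drawn.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
      rm(".Random.seed", envir = .GlobalEnv)
    }
  })
  set.seed(seed)
  force(code)
}

standardize <- function(x) {
  if (length(x) < 2L) return(rep(0, length(x)))
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# Latent with *sample* correlation exactly `r` against x (both standardized):
# project the raw noise off x, restandardize, recombine.
corr_latent <- function(x, r, noise) {
  xs <- standardize(x)
  resid <- noise - xs * sum(noise * xs) / max(sum(xs * xs), .Machine$double.eps)
  es <- standardize(resid)
  r * xs + sqrt(1 - r^2) * es
}

default_demand_growth <- function(years) {
  g <- vapply(years[-1L], function(y) {
    if (y <= 2012) -0.005 else if (y <= 2016) -0.006 else 0.006
  }, numeric(1))
  stats::setNames(g, years[-1L])
}

default_supply_growth <- function(years) {
  g <- vapply(years[-1L], function(y) {
    if (y <= 2014) -0.010
    else if (y <= 2018) 0.012
    else if (y == 2019) -0.006
    else if (y == 2020) 0.008
    else if (y %in% c(2021, 2022)) -0.012
    else 0.008
  }, numeric(1))
  stats::setNames(g, years[-1L])
}

#' Scenario configuration for the synthetic panel generator
#'
#' Parameterizes [generate_panel()].  The defaults emulate the Portuguese
#' primary-care panel of 2009–2023: 55 units in 5 regions, about 11.3 million
#' enrolled patients in the first year, enrolment declining until 2016 — with
#' a one-off administrative purge of roughly 7% of records between 2012 and
#' 2013 — then growing; FTE workforce declining to 2014, recovering to 2018
#' and falling again in 2021–2022; average list size drifting down 0.3% per
#' year; and an age mix moving from 1.24 to 1.32 weighted units per enrolled
#' patient.  Contextual covariates are generated with moderate negative
#' correlations of the list ratio with elderly share and diabetes prevalence
#' and a weak negative correlation with population density.
#'
#' @param seed Integer seed; mandatory, drives all randomness of the
#'   generator through one RNG stream.
#' @param n_units,n_regions Number of units and regions.
#' @param years Inclusive calendar-year range (length >= 2).
#' @param national_enrolled National enrolled patients in the first year.
#' @param baseline_unassigned_rate First-year national share of enrolled
#'   patients without a GP.
#' @param demand_growth,supply_growth Named per-year growth rates (names =
#'   `years[-1]`, each > -1) of national enrolment (purge excluded) and
#'   national FTE; `NULL` uses the defaults described above.
#' @param purge_year,purge_fraction One-off removal of enrolled records:
#'   calendar year it takes effect and fraction removed (0 disables).
#' @param list_drift Annual multiplicative drift of the average list size.
#' @param noise_sd Relative standard deviation of unit-level noise per series.
#' @param mean_list,list_spread Baseline mean list size per FTE GP and the
#'   log-scale spread of unit baseline list sizes.
#' @param unit_size_sdlog Log-normal sd of unit enrolment sizes.
#' @param unassigned_spread Logit-scale spread of unit baseline unassigned
#'   rates.
#' @param cov_targets Named vector of target correlations between the list
#'   ratio and `elderly_share`, `diabetes_prevalence`, `population_density`.
#' @param wu_start,wu_end National weighted units per enrolled patient in the
#'   first and last year (under the default [age_weights()]).
#' @param exact Internal switch used by [scenario_single_driver()]: integer
#'   baseline workforce and a common integer list size so that inactive
#'   effects are exactly zero despite integer rounding of counts.
#' @return An object of class `scenario_config` (a list).
#' @export
scenario_config <- function(seed,
                            n_units = 55, n_regions = 5, years = 2009:2023,
                            national_enrolled = 11.3e6,
                            baseline_unassigned_rate = 0.158,
                            demand_growth = NULL,
                            purge_year = 2013, purge_fraction = 0.07,
                            supply_growth = NULL,
                            list_drift = -0.003,
                            noise_sd = 0.02,
                            mean_list = 1680, list_spread = 0.08,
                            unit_size_sdlog = 0.7,
                            unassigned_spread = 0.3,
                            cov_targets = c(elderly_share = -0.45,
                                            diabetes_prevalence = -0.45,
                                            population_density = -0.20),
                            wu_start = 1.24, wu_end = 1.32,
                            exact = FALSE) {
  if (missing(seed) || length(seed) != 1L || is.na(seed) ||
      seed != trunc(seed)) {
    abort_gpc("a single integer `seed` is mandatory for reproducibility",
              "gpc_config_error")
  }
  years <- as.integer(years)
  if (length(years) < 2L || any(diff(years) != 1L)) {
    abort_gpc("`years` must be an inclusive run of >= 2 calendar years",
              "gpc_config_error")
  }
  if (is.null(demand_growth)) demand_growth <- default_demand_growth(years)
  if (is.null(supply_growth)) supply_growth <- default_supply_growth(years)
  for (nm in c("demand_growth", "supply_growth")) {
    g <- get(nm)
    if (length(g) != length(years) - 1L || any(g <= -1)) {
      abort_gpc(sprintf("`%s` needs one growth rate > -1 per year after the first",
                        nm), "gpc_config_error")
    }
  }
  if (noise_sd < 0) abort_gpc("noise_sd must be >= 0", "gpc_config_error")
  if (purge_fraction < 0 || purge_fraction >= 1) {
    abort_gpc("purge_fraction must be in [0, 1)", "gpc_config_error")
  }
  if (list_drift <= -1 || mean_list <= 0 || national_enrolled <= 0 ||
      baseline_unassigned_rate <= 0 || baseline_unassigned_rate >= 1) {
    abort_gpc("trend and baseline parameters out of range", "gpc_config_error")
  }
  structure(list(
    seed = as.integer(seed), n_units = as.integer(n_units),
    n_regions = as.integer(n_regions), years = years,
    national_enrolled = national_enrolled,
    baseline_unassigned_rate = baseline_unassigned_rate,
    demand_growth = stats::setNames(as.numeric(demand_growth), years[-1L]),
    purge_year = as.integer(purge_year), purge_fraction = purge_fraction,
    supply_growth = stats::setNames(as.numeric(supply_growth), years[-1L]),
    list_drift = list_drift, noise_sd = noise_sd,
    mean_list = mean_list, list_spread = list_spread,
    unit_size_sdlog = unit_size_sdlog,
    unassigned_spread = unassigned_spread,
    cov_targets = cov_targets, wu_start = wu_start, wu_end = wu_end,
    exact = isTRUE(exact)
  ), class = "scenario_config")
}

#' National trend multipliers implied by a scenario
#'
#' Cumulative multipliers (first year = 1) of national enrolment (purge
#' included), national FTE workforce and mean list size, per year.
#'
#' @param config A [scenario_config()].
#' @return Data frame with columns `year`, `demand_multiplier`,
#'   `supply_multiplier`, `list_multiplier`.
#' @export
scenario_trends <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  years <- config$years
  gd <- config$demand_growth
  purge_idx <- match(config$purge_year, years[-1L])
  mult_d <- 1 + gd
  if (!is.na(purge_idx) && config$purge_fraction > 0) {
    mult_d[purge_idx] <- mult_d[purge_idx] * (1 - config$purge_fraction)
  }
  data.frame(
    year = years,
    demand_multiplier = cumprod(c(1, mult_d)),
    supply_multiplier = cumprod(c(1, 1 + config$supply_growth)),
    list_multiplier = (1 + config$list_drift)^(seq_along(years) - 1L))
}

# age-band shares (0-6, 7-64, 65-74, 75+) whose weighted units per patient
# equal `wu` exactly under the default 1.5/1/2/2.5 weights; linear in wu.
shares_for_wu <- function(wu) {
  s_lo <- c(0.088, 0.749, 0.097, 0.066)    # wu = 1.24
  s_hi <- c(0.063, 0.7025, 0.1265, 0.108)  # wu = 1.32
  s <- s_lo + (wu - 1.24) / (1.32 - 1.24) * (s_hi - s_lo)
  if (any(s <= 0) || any(s >= 1)) {
    abort_gpc(sprintf("no feasible age mix for %.3f weighted units per patient",
                      wu), "gpc_feasibility_error")
  }
  s
}

#' Generate a synthetic coverage panel
#'
#' Draws a unit-by-year panel under a [scenario_config()].  National enrolment
#' and FTE series follow the configured piecewise trends exactly; unit-level
#' heterogeneity (log-normal unit sizes, list-size spread, per-series noise)
#' enters through the units' shares of the national totals.  Unassigned
#' patients are derived from the identity `m = n - GP * L` (with the list
#' size recomputed after integer rounding so the identity stays exact) and
#' clamped at full coverage.  The same seed reproduces the panel
#' bit-identically.
#'
#' @param config A [scenario_config()].
#' @return A validated `coverage_panel` at unit level with covariate and
#'   age-band columns.
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  tr <- scenario_trends(config)
  u0 <- config$baseline_unassigned_rate
  # feasibility before generation: the national trend must keep the implied
  # unassigned share inside (0, 1) in every year
  u_nat <- 1 - (1 - u0) * tr$supply_multiplier * tr$list_multiplier /
    tr$demand_multiplier
  if (any(u_nat <= 0) || any(u_nat >= 1)) {
    abort_gpc("infeasible scenario: implied national unassigned share leaves (0, 1)",
              "gpc_feasibility_error")
  }
  years <- config$years
  ny <- length(years)
  nu <- config$n_units
  with_seed(config$seed, {
    unit_id <- sprintf("U%03d", seq_len(nu))
    region_id <- sprintf("R%d", rep(seq_len(config$n_regions),
                                    times = largest_remainder(
                                      rep(1, config$n_regions), nu)))
    # baseline unit sizes: right-skewed, summing exactly to the national total
    size_w <- stats::rlnorm(nu, meanlog = 0, sdlog = config$unit_size_sdlog)
    n0 <- largest_remainder(size_w, round(config$national_enrolled))
    # unit latents: x drives the baseline list size; covariate latents carry
    # exact sample correlations with x
    x <- stats::rnorm(nu)
    y_eld <- corr_latent(x, config$cov_targets[["elderly_share"]],
                         stats::rnorm(nu))
    y_dia <- corr_latent(x, config$cov_targets[["diabetes_prevalence"]],
                         stats::rnorm(nu))
    y_den <- corr_latent(x, config$cov_targets[["population_density"]],
                         stats::rnorm(nu))
    if (config$exact) {
      L0 <- rep(round(config$mean_list), nu)
      u0_j <- rep(u0, nu)
      gp0 <- pmax(1, round((1 - u0_j) * n0 / L0))
    } else {
      L0 <- config$mean_list * exp(config$list_spread * standardize(x))
      u0_j <- stats::plogis(stats::qlogis(u0) +
                              config$unassigned_spread * stats::rnorm(nu))
      gp0 <- (1 - u0_j) * n0 / L0
    }
    eps <- function() {
      if (config$noise_sd == 0) matrix(0, nu, ny)
      else matrix(stats::rnorm(nu * ny, sd = config$noise_sd), nu, ny)
    }
    eps_n <- eps(); eps_g <- eps(); eps_l <- eps()
    # diabetes prevalence and population density are static unit traits
    diabetes <- pmin(pmax(0.075 + 0.012 * y_dia, 0.02), 0.15)
    density <- exp(4.6 + 0.6 * y_den)
    # elderly tilt: scales the two elderly bands; weighted de-meaned so the
    # national age mix stays on the configured weighted-units path
    k <- 1 + 0.25 * y_eld
    k <- pmin(pmax(k, 0.4), 1.8)
    k <- k - stats::weighted.mean(k - 1, n0)
    wu_path <- config$wu_start +
      (config$wu_end - config$wu_start) *
      (seq_len(ny) - 1L) / max(ny - 1L, 1L)
    rows <- vector("list", ny)
    for (t in seq_len(ny)) {
      n_t <- n0 * tr$demand_multiplier[t] * exp(eps_n[, t])
      n_t <- round(n_t * (sum(n0) * tr$demand_multiplier[t]) / sum(n_t))
      gp_t <- gp0 * tr$supply_multiplier[t] * exp(eps_g[, t])
      if (config$exact) {
        gp_t <- round(gp0 * tr$supply_multiplier[t])
      } else {
        gp_t <- round(gp_t * (sum(gp0) * tr$supply_multiplier[t]) / sum(gp_t),
                      3)
      }
      L_t <- L0 * tr$list_multiplier[t] * exp(eps_l[, t])
      m_t <- n_t - round(gp_t * L_t)
      m_t <- pmax(m_t, 0)
      m_t <- pmin(m_t, n_t)
      s_t <- shares_for_wu(wu_path[t])
      elder_w1 <- s_t[3L] * k
      elder_w2 <- s_t[4L] * k
      mid_w <- pmax(1 - s_t[1L] - elder_w1 - elder_w2, 0.05)
      ages <- t(mapply(function(ni, a, b, c2, d) {
        largest_remainder(c(a, b, c2, d), ni)
      }, n_t, rep(s_t[1L], nu), mid_w, elder_w1, elder_w2))
      rows[[t]] <- data.frame(
        unit_id = unit_id, region_id = region_id, year = years[t],
        enrolled = as.integer(n_t), unassigned = as.integer(m_t),
        gp_fte = gp_t,
        elderly_share = (ages[, 3L] + ages[, 4L]) / pmax(n_t, 1),
        diabetes_prevalence = diabetes,
        population_density = density,
        age_0_6 = ages[, 1L], age_7_64 = ages[, 2L],
        age_65_74 = ages[, 3L], age_75p = ages[, 4L],
        stringsAsFactors = FALSE)
    }
    as_panel(do.call(rbind, rows), level = "unit",
             provenance = sprintf("synthetic scenario (seed %d)", config$seed))
  })
}

#' Generate a physician roster consistent with a unit-year record
#'
#' Builds per-physician weekly hours and list sizes such that the roster's
#' total FTE equals the record's `gp_fte` (hours are rescaled after drawing)
#' and the list sizes sum exactly to `enrolled - unassigned`
#' (largest-remainder apportionment proportional to FTE).
#'
#' @param unit_record One unit-year record (one-row data frame or named list
#'   with `unit_id`, `enrolled`, `unassigned`, `gp_fte`).
#' @param mean_hours Mean effective weekly hours per physician.
#' @param hours_dispersion Log-scale relative dispersion of hours (0 gives
#'   identical physicians).
#' @param seed Integer seed.
#' @param standard_hours Hours of the full-time week.
#' @return A roster data frame (`physician_id`, `unit_id`, `weekly_hours`,
#'   `list_size`).
#' @export
generate_roster <- function(unit_record, mean_hours = 35,
                            hours_dispersion = 0.15, seed,
                            standard_hours = 40) {
  rec <- rec_fields(unit_record, "unit_record")
  if (rec$gp_fte <= 0) {
    abort_gpc("unit gp_fte must be positive to build a roster",
              "gpc_feasibility_error")
  }
  if (mean_hours <= 0 || hours_dispersion < 0) {
    abort_gpc("mean_hours must be positive and hours_dispersion >= 0",
              "gpc_domain_error")
  }
  k <- round(rec$gp_fte / (mean_hours / standard_hours))
  if (k < 1) {
    abort_gpc("gp_fte too small for a single physician at these mean hours",
              "gpc_feasibility_error")
  }
  with_seed(seed, {
    h <- mean_hours * exp(hours_dispersion * stats::rnorm(k))
    h <- h * (rec$gp_fte * standard_hours) / sum(h)
    fte <- h / standard_hours
    assigned <- rec$enrolled - rec$unassigned
    lists <- largest_remainder(fte, assigned)
    data.frame(
      physician_id = sprintf("%s-P%03d", rec$unit_id %||% "U", seq_len(k)),
      unit_id = rec$unit_id %||% "U",
      weekly_hours = h, list_size = lists,
      stringsAsFactors = FALSE)
  })
}

#' Single-driver scenario for parameter-recovery testing
#'
#' Returns a copy of `base` in which only the named driver's trend is active
#' (the other trends flat, all noise off) in exact-arithmetic mode, so that a
#' decomposition of the generated panel attributes 100% of the change to that
#' driver and exactly 0 to the others.
#'
#' @param base A [scenario_config()].
#' @param driver `"demand"`, `"supply"` or `"productivity"`.
#' @return A `scenario_config`.
#' @export
scenario_single_driver <- function(base,
                                   driver = c("demand", "supply",
                                              "productivity")) {
  stopifnot(inherits(base, "scenario_config"))
  driver <- tryCatch(match.arg(driver),
                     error = function(e) {
                       abort_gpc(sprintf("unknown driver '%s'",
                                         paste(driver, collapse = ", ")),
                                 "gpc_usage_error")
                     })
  zero <- stats::setNames(numeric(length(base$years) - 1L), base$years[-1L])
  cfg <- base
  cfg$noise_sd <- 0
  cfg$unassigned_spread <- 0
  cfg$list_spread <- 0
  cfg$exact <- TRUE
  if (driver != "demand") {
    cfg$demand_growth <- zero
    cfg$purge_fraction <- 0
  }
  if (driver != "supply") cfg$supply_growth <- zero
  if (driver != "productivity") cfg$list_drift <- 0
  cfg
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf("<scenario_config> %d units / %d regions, years %d-%d, seed %d\n",
              x$n_units, x$n_regions, min(x$years), max(x$years), x$seed))
  cat(sprintf("  national enrolled (first year): %.0f; baseline unassigned rate %.3f\n",
              x$national_enrolled, x$baseline_unassigned_rate))
  cat(sprintf("  purge: %.1f%% in %d; list drift %.2f%%/yr; noise sd %.1f%%%s\n",
              100 * x$purge_fraction, x$purge_year, 100 * x$list_drift,
              100 * x$noise_sd, if (x$exact) " [exact mode]" else ""))
  invisible(x)
}
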