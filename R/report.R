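#' Coverage summary series
#'
#' One row per scope and year with the coverage rate (share of enrolled
#' patients with an assigned GP, `(n - m)/n`), its complement
#' `percent_unassigned` (`m/n`; the two sum to 1 exactly) and the
#' patient-to-GP ratio, which is `NA` (flagged in `list_ratio_defined`) where
#' `gp_fte = 0`.
#'
#' @param panel A `coverage_panel`.
#' @return A data frame with columns `scope, year, enrolled, unassigned,
#'   gp_fte, coverage_rate, percent_unassigned, list_ratio,
#'   list_ratio_defined`.
#' @export
coverage_series <- function(panel) {
  validate_panel(panel)
  df <- as.data.frame(panel)
  cov_rate <- ifelse(df$enrolled > 0,
                     (df$enrolled - df$unassigned) / df$enrolled, 1)
  defined <- df$gp_fte > 0
  lr <- rep(NA_real_, nrow(df))
  lr[defined] <- (df$enrolled[defined] - df$unassigned[defined]) /
    df$gp_fte[defined]
  out <- data.frame(scope = df$unit_id, year = df$year,
                    enrolled = df$enrolled, unassigned = df$unassigned,
                    gp_fte = df$gp_fte,
                    coverage_rate = cov_rate,
                    percent_unassigned = 1 - cov_rate,
                    list_ratio = lr, list_ratio_defined = defined,
                    stringsAsFactors = FALSE)
  out[order(out$scope, out$year), , drop = FALSE]
}

#' Correlation of contextual covariates with an outcome variable
#'
#' Pairwise-complete correlations between each of `x_vars` and `y_var` across
#' the panel's records, with the sample size used for each pair.  `y_var` may
#' be any panel column or `"list_ratio"`, which is derived as
#' `(enrolled - unassigned)/gp_fte` (records with `gp_fte = 0` excluded).
#'
#' @param panel A `coverage_panel`.
#' @param x_vars Character vector of covariate column names.
#' @param y_var Outcome variable name (default `"list_ratio"`).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Data frame with columns `x_var, y_var, method, estimate, n`.
#' @export
correlation_table <- function(panel, x_vars, y_var = "list_ratio",
                              method = c("pearson", "spearman")) {
  method <- match.arg(method)
  validate_panel(panel)
  df <- as.data.frame(panel)
  if (y_var == "list_ratio" && !"list_ratio" %in% names(df)) {
    df$list_ratio <- ifelse(df$gp_fte > 0,
                            (df$enrolled - df$unassigned) / df$gp_fte,
                            NA_real_)
  }
  for (v in c(x_vars, y_var)) {
    if (!v %in% names(df)) {
      abort_gpc(sprintf("variable '%s' not present in panel", v),
                "gpc_schema_error")
    }
  }
  rows <- lapply(x_vars, function(v) {
    ok <- stats::complete.cases(df[, c(v, y_var)])
    n <- sum(ok)
    if (n < 3L) {
      abort_gpc(sprintf("fewer than 3 complete observations for '%s' vs '%s'",
                        v, y_var), "gpc_usage_error")
    }
    for (vv in c(v, y_var)) {
      if (stats::sd(df[[vv]][ok]) == 0) {
        abort_gpc(sprintf("variable '%s' has zero variance; correlation undefined",
                          vv), "gpc_undefined_correlation_error")
      }
    }
    data.frame(x_var = v, y_var = y_var, method = method,
               estimate = stats::cor(df[[v]][ok], df[[y_var]][ok],
                                     method = method),
               n = n, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Published national aggregates (reference example)
#'
#' The national 2009 and 2023 aggregates for mainland Portugal as printed on
#' the public NHS dashboards — enrolled patients (the 2009 value reconstructed
#' as 10.5 million plus the published 793 thousand decline), patients without
#' an assigned GP and FTE GPs.  Used as the worked example throughout the
#' package.
#'
#' @return A national-level `coverage_panel` with two records.
#' @export
#' @examples
#' p <- national_reference_panel()
#' decompose(p[1, ], p[2, ])
national_reference_panel <- function() {
  path <- system.file("extdata", "national_aggregates.csv",
                      package = "gpcoverage", mustWork = TRUE)
  read_panel(path, level = "national")
}

#' Run the full reporting pipeline
#'
#' Drives every stage end to end: obtain a panel (from a CSV file or by
#' generating a configured scenario), validate it, aggregate to national
#' level, and write the coverage series, the long-run and yearly national
#' decompositions, the per-unit share table, the covariate correlation table
#' and a run log.  Re-running with the same configuration reproduces
#' byte-identical tables.
#'
#' @param config A named list (or path to a YAML file) with fields:
#'   `panel` (path to a panel CSV) *or* `scenario` (a [scenario_config()] or
#'   a list of its arguments); `year_0`, `year_1` (defaults: first and last
#'   year present); `allocation` (default `"list"`); `x_vars` (covariates for
#'   the correlation table; default the three standard ones when present).
#' @param outdir Output directory, created if needed.
#' @return Invisibly, a list with the computed tables and output paths.
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) {
      abort_gpc(sprintf("config file not found: %s", config),
                "gpc_config_error")
    }
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) {
    abort_gpc("config must be a list or a YAML file path", "gpc_config_error")
  }
  has_panel <- !is.null(config$panel)
  has_scenario <- !is.null(config$scenario)
  if (has_panel == has_scenario) {
    abort_gpc("config: exactly one of `panel` (file) or `scenario` must be given",
              "gpc_config_error")
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort_gpc(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                "gpc_pipeline_error")
    })
  }
  panel <- if (has_panel) {
    stage("read", read_panel(config$panel))
  } else {
    sc <- config$scenario
    if (!inherits(sc, "scenario_config")) {
      sc <- stage("scenario", do.call(scenario_config, sc))
    }
    stage("generate", generate_panel(sc))
  }
  years <- sort(unique(panel$year))
  year_0 <- config$year_0 %||% min(years)
  year_1 <- config$year_1 %||% max(years)
  allocation <- config$allocation %||% "list"
  national <- if (panel_level(panel) == "national") panel
              else stage("aggregate", aggregate_panel(panel, "national"))
  coverage <- stage("coverage", coverage_series(national))
  nat_series <- as.data.frame(national)
  r0 <- nat_series[nat_series$year == year_0, , drop = FALSE]
  r1 <- nat_series[nat_series$year == year_1, , drop = FALSE]
  if (nrow(r0) != 1L || nrow(r1) != 1L) {
    abort_gpc(sprintf("config: years %s and %s must both be present",
                      year_0, year_1), "gpc_config_error")
  }
  longrun <- stage("decompose",
                   as.data.frame(decompose(r0, r1, allocation = allocation)))
  yearly <- stage("chain", chain_decompose(national, allocation = allocation,
                                           allow_gaps = TRUE))
  shares <- if (panel_level(panel) == "national") NULL else {
    stage("shares", as.data.frame(
      decompose_all(panel, year_0, year_1, allocation = allocation)))
  }
  default_x <- intersect(PANEL_COVARIATE_COLS, names(panel))
  x_vars <- config$x_vars %||% default_x
  correlations <- if (length(x_vars) > 0 && panel_level(panel) != "national") {
    stage("correlate", correlation_table(panel, x_vars))
  } else NULL
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  write_tab <- function(obj, name) {
    if (is.null(obj)) return(NULL)
    p <- file.path(outdir, paste0(name, ".csv"))
    df <- obj
    for (col in names(df)) {
      if (is.double(df[[col]])) df[[col]] <- format_full(df[[col]])
    }
    utils::write.csv(df, p, row.names = FALSE, quote = FALSE)
    paths[[name]] <<- p
    p
  }
  write_tab(coverage, "coverage")
  write_tab(longrun, "decomposition_longrun")
  write_tab(yearly, "decomposition_yearly")
  write_tab(shares, "unit_shares")
  write_tab(correlations, "correlations")
  residual <- abs(longrun$demand_effect + longrun$supply_effect +
                    longrun$productivity_effect - longrun$total_change)
  log_lines <- c(
    "gpcoverage pipeline run",
    sprintf("package version: %s",
            as.character(utils::packageVersion("gpcoverage"))),
    sprintf("input: %s", panel_provenance(panel)),
    sprintf("records: %d (%d unit(s), years %d-%d)", nrow(panel),
            length(unique(panel$unit_id)), min(years), max(years)),
    sprintf("decomposition: %d -> %d, allocation '%s'", year_0, year_1,
            allocation),
    sprintf("identity residual (long run): %.3g", residual),
    "validation: passed")
  log_path <- file.path(outdir, "run_log.txt")
  writeLines(log_lines, log_path)
  paths$run_log <- log_path
  invisible(list(panel = panel, coverage = coverage, longrun = longrun,
                 yearly = yearly, shares = shares,
                 correlations = correlations, paths = paths))
}
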