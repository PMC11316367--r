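PANEL_REQUIRED_COLS <- c("unit_id", "region_id", "year",
                         "enrolled", "unassigned", "gp_fte")
PANEL_COVARIATE_COLS <- c("elderly_share", "diabetes_prevalence",
                          "population_density")
PANEL_AGE_COLS <- c("age_0_6", "age_7_64", "age_65_74", "age_75p")
PANEL_LEVELS <- c("unit", "region", "national")

#' Construct a coverage panel
#'
#' A coverage panel is a data frame of unit-by-year records with one row per
#' `(unit_id, year)`, a level tag (`"unit"`, `"region"` or `"national"`) and a
#' provenance note.  Each record holds enrolled patients `enrolled` (\eqn{n}),
#' patients without an assigned GP `unassigned` (\eqn{m}) and the GP workforce
#' in full-time equivalents `gp_fte` (\eqn{GP}), plus optional contextual
#' covariates (`elderly_share`, `diabetes_prevalence`, `population_density`)
#' and age-band counts (`age_0_6`, `age_7_64`, `age_65_74`, `age_75p`) that
#' must sum to `enrolled`.
#'
#' @param records A data frame with at least the columns `unit_id`,
#'   `region_id`, `year`, `enrolled`, `unassigned`, `gp_fte`.
#' @param level Aggregation level of the records; one of `"unit"`, `"region"`,
#'   `"national"`.
#' @param provenance Free-text note on where the records came from (source
#'   file or generator seed).
#' @param validate Run [validate_panel()] on the result (default `TRUE`).
#' @return An object of class `coverage_panel` (a data frame).
#' @seealso [read_panel()], [validate_panel()], [aggregate_panel()]
#' @export
as_panel <- function(records, level = "unit", provenance = "in-memory",
                     validate = TRUE) {
  if (!is.data.frame(records)) {
    abort_gpc("`records` must be a data frame", "gpc_schema_error")
  }
  level <- match.arg(level, PANEL_LEVELS)
  missing_cols <- setdiff(PANEL_REQUIRED_COLS, names(records))
  if (length(missing_cols) > 0) {
    abort_gpc(sprintf("missing required column(s): %s",
                      paste(missing_cols, collapse = ", ")),
              "gpc_schema_error")
  }
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  records$unit_id <- as.character(records$unit_id)
  records$region_id <- as.character(records$region_id)
  records$year <- as.integer(records$year)
  records$enrolled <- as.integer(round(as.numeric(records$enrolled)))
  records$unassigned <- as.integer(round(as.numeric(records$unassigned)))
  records$gp_fte <- as.numeric(records$gp_fte)
  for (col in intersect(c(PANEL_COVARIATE_COLS, PANEL_AGE_COLS),
                        names(records))) {
    records[[col]] <- as.numeric(records[[col]])
  }
  ord <- c(PANEL_REQUIRED_COLS,
           intersect(c(PANEL_COVARIATE_COLS, PANEL_AGE_COLS), names(records)),
           setdiff(names(records),
                   c(PANEL_REQUIRED_COLS, PANEL_COVARIATE_COLS,
                     PANEL_AGE_COLS)))
  records <- records[order(records$unit_id, records$year), ord, drop = FALSE]
  rownames(records) <- NULL
  structure(records,
            class = c("coverage_panel", "data.frame"),
            level = level, provenance = provenance) -> panel
  if (validate) validate_panel(panel)
  panel
}

#' @rdname as_panel
#' @param panel A `coverage_panel`.
#' @export
panel_level <- function(panel) attr(panel, "level")

#' @rdname as_panel
#' @export
panel_provenance <- function(panel) attr(panel, "provenance")

#' Validate a coverage panel
#'
#' Checks the record-level invariants of the accounting identity: counts are
#' non-negative, `unassigned <= enrolled`, `gp_fte >= 0` with
#' `unassigned == enrolled` whenever `gp_fte == 0` (nobody can hold a list),
#' age-band counts (when present) sum exactly to `enrolled`, share-type
#' covariates lie in \[0, 1\], and `(unit_id, year)` keys are unique.
#' Violations raise classed conditions (`gpc_validation_error`,
#' `gpc_duplication_error`, `gpc_schema_error`) naming the offending record
#' and rule.
#'
#' @param panel A `coverage_panel` or plain data frame with panel columns.
#' @return `panel`, invisibly, if valid.
#' @export
validate_panel <- function(panel) {
  missing_cols <- setdiff(PANEL_REQUIRED_COLS, names(panel))
  if (length(missing_cols) > 0) {
    abort_gpc(sprintf("missing required column(s): %s",
                      paste(missing_cols, collapse = ", ")),
              "gpc_schema_error")
  }
  key <- paste(panel$unit_id, panel$year, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- panel[duplicated(key), , drop = FALSE][1L, ]
    abort_gpc(sprintf("duplicate record for unit '%s', year %d",
                      dup$unit_id, dup$year),
              "gpc_duplication_error")
  }
  fail <- function(i, rule) {
    abort_gpc(sprintf("record (unit '%s', year %d) violates: %s",
                      panel$unit_id[i], panel$year[i], rule),
              "gpc_validation_error")
  }
  base_na <- !stats::complete.cases(
    panel[, c("year", "enrolled", "unassigned", "gp_fte")])
  if (any(base_na)) fail(which(base_na)[1L], "missing value in required field")
  bad <- panel$enrolled < 0 | panel$unassigned < 0
  if (any(bad)) fail(which(bad)[1L], "counts must be non-negative")
  bad <- panel$unassigned > panel$enrolled
  if (any(bad)) fail(which(bad)[1L], "unassigned > enrolled")
  bad <- panel$gp_fte < 0
  if (any(bad)) fail(which(bad)[1L], "gp_fte must be non-negative")
  bad <- panel$gp_fte == 0 & panel$unassigned != panel$enrolled
  if (any(bad)) {
    fail(which(bad)[1L],
         "gp_fte = 0 but unassigned < enrolled (no GP can hold a list)")
  }
  for (col in c("elderly_share", "diabetes_prevalence")) {
    if (col %in% names(panel)) {
      bad <- !is.na(panel[[col]]) & (panel[[col]] < 0 | panel[[col]] > 1)
      if (any(bad)) fail(which(bad)[1L], paste(col, "outside [0, 1]"))
    }
  }
  if ("population_density" %in% names(panel)) {
    bad <- !is.na(panel$population_density) & panel$population_density < 0
    if (any(bad)) fail(which(bad)[1L], "population_density negative")
  }
  present_age <- intersect(PANEL_AGE_COLS, names(panel))
  if (length(present_age) > 0) {
    if (!setequal(present_age, PANEL_AGE_COLS)) {
      abort_gpc(sprintf(
        "age-band columns must be all present or all absent; found: %s",
        paste(present_age, collapse = ", ")), "gpc_schema_error")
    }
    agesum <- rowSums(panel[, PANEL_AGE_COLS, drop = FALSE])
    has_age <- stats::complete.cases(panel[, PANEL_AGE_COLS, drop = FALSE])
    bad <- has_age & agesum != panel$enrolled
    if (any(bad)) fail(which(bad)[1L], "age-band counts do not sum to enrolled")
  }
  invisible(panel)
}

#' @export
print.coverage_panel <- function(x, ...) {
  cat(sprintf("<coverage_panel> %d records, %d unit(s), years %s-%s, level '%s'\n",
              nrow(x), length(unique(x$unit_id)),
              if (nrow(x)) min(x$year) else NA, if (nrow(x)) max(x$year) else NA,
              panel_level(x)))
  cat(sprintf("provenance: %s\n", panel_provenance(x)))
  print(utils::head(as.data.frame(x), 10L))
  if (nrow(x) > 10L) cat(sprintf("... %d more rows\n", nrow(x) - 10L))
  invisible(x)
}

# keep attributes when subsetting rows
#' @export
`[.coverage_panel` <- function(x, i, j, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "level") <- attr(x, "level")
    attr(out, "provenance") <- attr(x, "provenance")
    class(out) <- class(x)
  }
  out
}
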