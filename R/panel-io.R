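#' Read a coverage panel from CSV
#'
#' The canonical interchange format is UTF-8 CSV with one header row, comma
#' separator and dot decimal: columns
#' `unit_id,region_id,year,enrolled,unassigned,gp_fte` plus the optional
#' covariate and age-band columns.  Records are validated on read; schema,
#' validation and duplication problems raise classed errors naming the column
#' or record at fault.
#'
#' @param path Path to a CSV file.
#' @param level Aggregation level tag to attach (default `"unit"`).
#' @return A [coverage panel][as_panel] with provenance set to `path`.
#' @export
read_panel <- function(path, level = "unit") {
  if (!file.exists(path)) {
    abort_gpc(sprintf("panel file not found: %s", path), "gpc_io_error")
  }
  hdr <- names(utils::read.csv(path, nrows = 1L, check.names = TRUE))
  cls <- stats::setNames(rep(NA_character_, length(hdr)), hdr)
  cls[intersect(c("unit_id", "region_id"), hdr)] <- "character"
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = cls,
                        fileEncoding = "UTF-8")
  as_panel(df, level = level, provenance = path)
}

#' Write a coverage panel to CSV
#'
#' Inverse of [read_panel()]: counts are written as integers and real-valued
#' columns (`gp_fte`, covariates) at full double precision, so
#' `read_panel(write_panel(p))` reproduces `p` exactly.
#'
#' @param panel A `coverage_panel`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  validate_panel(panel)
  df <- as.data.frame(panel)
  for (col in names(df)) {
    if (is.double(df[[col]])) df[[col]] <- format_full(df[[col]])
  }
  ok <- tryCatch({
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                     fileEncoding = "UTF-8")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) abort_gpc(sprintf("cannot write panel to: %s", path),
                     "gpc_io_error")
  invisible(path)
}

#' Read a unit crosswalk from CSV
#'
#' A crosswalk maps historical unit identifiers onto their successors after an
#' administrative reorganisation (many old units merging into one new unit).
#' Columns: `old_unit_id,new_unit_id,effective_year`.  Records dated before
#' `effective_year` are recorded under the old identifiers and are renamed and
#' merged by [apply_crosswalk()].
#'
#' @param path Path to a CSV file.
#' @return A data frame with class `unit_crosswalk`.
#' @export
read_crosswalk <- function(path) {
  if (!file.exists(path)) {
    abort_gpc(sprintf("crosswalk file not found: %s", path), "gpc_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_crosswalk(df)
}

#' @rdname read_crosswalk
#' @param mapping Data frame with columns `old_unit_id`, `new_unit_id`,
#'   `effective_year`.
#' @export
as_crosswalk <- function(mapping) {
  need <- c("old_unit_id", "new_unit_id", "effective_year")
  missing_cols <- setdiff(need, names(mapping))
  if (length(missing_cols) > 0) {
    abort_gpc(sprintf("crosswalk missing column(s): %s",
                      paste(missing_cols, collapse = ", ")),
              "gpc_schema_error")
  }
  mapping <- as.data.frame(mapping, stringsAsFactors = FALSE)
  mapping$old_unit_id <- as.character(mapping$old_unit_id)
  mapping$new_unit_id <- as.character(mapping$new_unit_id)
  mapping$effective_year <- as.integer(mapping$effective_year)
  if (anyDuplicated(mapping$old_unit_id)) {
    dup <- mapping$old_unit_id[duplicated(mapping$old_unit_id)][1L]
    abort_gpc(sprintf("old unit '%s' mapped more than once", dup),
              "gpc_mapping_error")
  }
  structure(mapping, class = c("unit_crosswalk", "data.frame"))
}

#' Apply a unit crosswalk to a panel
#'
#' Renames records dated before the crosswalk's effective year from old to new
#' unit identifiers and merges records that end up sharing a `(unit_id, year)`
#' key: `enrolled`, `unassigned`, `gp_fte` and age-band counts are summed;
#' covariates are combined as enrolled-weighted means.  National totals are
#' preserved for every year.
#'
#' Units observed before the effective year that appear in neither the old nor
#' the new identifier set raise a `gpc_mapping_error` (the crosswalk claims to
#' cover those years).
#'
#' @param panel A `coverage_panel` at unit level.
#' @param crosswalk A [unit_crosswalk][read_crosswalk].
#' @return A merged, validated `coverage_panel`.
#' @export
apply_crosswalk <- function(panel, crosswalk) {
  validate_panel(panel)
  crosswalk <- as_crosswalk(crosswalk)
  covered <- panel$year < max(crosswalk$effective_year)
  known <- union(crosswalk$old_unit_id, crosswalk$new_unit_id)
  unmapped <- setdiff(unique(panel$unit_id[covered]), known)
  if (length(unmapped) > 0) {
    abort_gpc(sprintf("unit(s) not covered by crosswalk in pre-effective years: %s",
                      paste(unmapped, collapse = ", ")),
              "gpc_mapping_error")
  }
  idx <- match(panel$unit_id, crosswalk$old_unit_id)
  rename <- !is.na(idx) & panel$year < crosswalk$effective_year[idx]
  panel$unit_id[rename] <- crosswalk$new_unit_id[idx[rename]]
  merge_panel_records(panel, by = c("unit_id", "year"),
                      level = panel_level(panel),
                      provenance = paste0(panel_provenance(panel),
                                          " + crosswalk"))
}

# Sum counts / FTE / age bands and enrolled-weight covariates within groups.
merge_panel_records <- function(panel, by, level, provenance,
                                region_from = NULL) {
  df <- as.data.frame(panel)
  key <- do.call(paste, c(df[by], sep = "\r"))
  split_idx <- split(seq_len(nrow(df)), key)
  rows <- lapply(split_idx, function(ii) {
    g <- df[ii, , drop = FALSE]
    out <- g[1L, , drop = FALSE]
    out$enrolled <- sum(g$enrolled)
    out$unassigned <- sum(g$unassigned)
    out$gp_fte <- sum(g$gp_fte)
    for (col in intersect(PANEL_AGE_COLS, names(g))) {
      out[[col]] <- sum(g[[col]])
    }
    for (col in intersect(PANEL_COVARIATE_COLS, names(g))) {
      w <- g$enrolled
      out[[col]] <- if (sum(w) > 0) sum(g[[col]] * w) / sum(w)
                    else mean(g[[col]])
    }
    if (!is.null(region_from)) {
      out$unit_id <- g[[region_from]][1L]
      out$region_id <- g[[region_from]][1L]
    } else if (length(unique(g$region_id)) > 1L) {
      out$region_id <- paste(sort(unique(g$region_id)), collapse = "+")
    }
    out
  })
  merged <- do.call(rbind, rows)
  as_panel(merged, level = level, provenance = provenance)
}

#' Aggregate a panel to region or national level
#'
#' Sums `enrolled`, `unassigned`, `gp_fte` and age-band counts per target
#' group and year; covariates are combined as enrolled-weighted means.  Note
#' that the aggregate patient-to-GP ratio equals total assigned patients over
#' total FTE, not the mean of unit-level ratios.
#'
#' @param panel A `coverage_panel`.
#' @param target_level `"region"` or `"national"`.
#' @param national_id Identifier used for the single national scope.
#' @return A `coverage_panel` at the target level.
#' @export
aggregate_panel <- function(panel, target_level = c("national", "region"),
                            national_id = "NATIONAL") {
  target_level <- match.arg(target_level)
  validate_panel(panel)
  lev <- panel_level(panel)
  if (lev == "national") {
    warn_gpc("panel already at national level; returning unchanged",
             "gpc_aggregate_warning")
    return(panel)
  }
  if (nrow(panel) == 0L) {
    return(as_panel(as.data.frame(panel), level = target_level,
                    provenance = panel_provenance(panel), validate = FALSE))
  }
  if (target_level == "region") {
    if (lev == "region") {
      warn_gpc("panel already at region level; returning unchanged",
               "gpc_aggregate_warning")
      return(panel)
    }
    merge_panel_records(panel, by = c("region_id", "year"),
                        level = "region",
                        provenance = paste0(panel_provenance(panel),
                                            " [region aggregate]"),
                        region_from = "region_id")
  } else {
    df <- as.data.frame(panel)
    df$.nat <- national_id
    out <- merge_panel_records(df, by = c(".nat", "year"),
                               level = "national",
                               provenance = paste0(panel_provenance(panel),
                                                   " [national aggregate]"),
                               region_from = ".nat")
    out$.nat <- NULL
    out
  }
}
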