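#' Full-time-equivalent weighting of working hours
#'
#' A physician's full-time equivalent (FTE) is their effective weekly working
#' hours divided by the standard working week (40 h for specialist and intern
#' physicians).  Values above 1 are permitted by default; set `cap = 1` to
#' truncate over-full-time contracts.
#'
#' @param weekly_hours Non-negative numeric vector of effective hours/week.
#' @param standard_hours Hours of the standard full-time week (default 40).
#' @param cap Optional upper bound on the returned FTE (default `Inf`).
#' @return Numeric vector of FTE values.
#' @export
#' @examples
#' fte_from_hours(c(40, 20, 60))  # 1.0 0.5 1.5
fte_from_hours <- function(weekly_hours, standard_hours = 40, cap = Inf) {
  if (any(is.na(weekly_hours)) || any(weekly_hours < 0)) {
    abort_gpc("weekly_hours must be non-negative", "gpc_domain_error")
  }
  if (length(standard_hours) != 1L || is.na(standard_hours) ||
      standard_hours <= 0) {
    abort_gpc("standard_hours must be a single positive number",
              "gpc_domain_error")
  }
  pmin(weekly_hours / standard_hours, cap)
}

#' Total FTE of a physician roster
#'
#' Sums [fte_from_hours()] over a roster of physician records, the
#' double-counting-safe way to measure a unit's GP workforce when physicians
#' split their hours across practices.
#'
#' @param roster Data frame with columns `physician_id`, `unit_id`,
#'   `weekly_hours`, `list_size` (see [read_roster()]); an empty roster gives
#'   0.
#' @inheritParams fte_from_hours
#' @return A single non-negative number.
#' @export
unit_fte <- function(roster, standard_hours = 40, cap = Inf) {
  validate_roster(roster)
  if (nrow(roster) == 0L) return(0)
  sum(fte_from_hours(roster$weekly_hours, standard_hours, cap))
}

#' Read a physician roster from CSV
#'
#' Columns: `physician_id,unit_id,weekly_hours,list_size`.
#'
#' @param path Path to a CSV file.
#' @return A validated roster data frame.
#' @export
read_roster <- function(path) {
  if (!file.exists(path)) {
    abort_gpc(sprintf("roster file not found: %s", path), "gpc_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(physician_id = "character",
                                       unit_id = "character"))
  validate_roster(df)
  df
}

validate_roster <- function(roster) {
  need <- c("physician_id", "unit_id", "weekly_hours", "list_size")
  missing_cols <- setdiff(need, names(roster))
  if (length(missing_cols) > 0) {
    abort_gpc(sprintf("roster missing column(s): %s",
                      paste(missing_cols, collapse = ", ")),
              "gpc_schema_error")
  }
  if (any(roster$weekly_hours < 0, na.rm = FALSE) ||
      any(is.na(roster$weekly_hours))) {
    abort_gpc("weekly_hours must be non-negative", "gpc_validation_error")
  }
  if (any(roster$list_size < 0) || any(roster$list_size != trunc(roster$list_size))) {
    abort_gpc("list_size must be a non-negative integer",
              "gpc_validation_error")
  }
  invisible(roster)
}

#' Unassigned patients from physician lists
#'
#' Micro-level accounting: patients without an assigned GP are the enrolled
#' patients not on any physician's list.  By default assigned patients are the
#' raw sum of list sizes, `enrolled - sum(list_size)`, which makes the
#' unit-level identity \eqn{m = n - GP \cdot L} exact with
#' \eqn{L = \sum L_i / \sum FTE_i}.  `method = "fte_weighted"` instead weights
#' each list by its physician's FTE (\eqn{n - \sum FTE_i L_i}), provided for
#' comparison; with part-time physicians it undercounts assigned patients.
#'
#' @param enrolled Number of patients enrolled in the unit.
#' @param roster Physician roster data frame (may be empty).
#' @param method `"raw"` (default) or `"fte_weighted"`.
#' @inheritParams fte_from_hours
#' @return Number of unassigned patients (never negative under `"raw"`).
#' @export
unassigned_from_lists <- function(enrolled, roster,
                                  method = c("raw", "fte_weighted"),
                                  standard_hours = 40) {
  method <- match.arg(method)
  validate_roster(roster)
  if (length(enrolled) != 1L || is.na(enrolled) || enrolled < 0) {
    abort_gpc("enrolled must be a single non-negative count",
              "gpc_domain_error")
  }
  assigned <- if (method == "raw") {
    sum(roster$list_size)
  } else {
    sum(fte_from_hours(roster$weekly_hours, standard_hours) *
          roster$list_size)
  }
  if (method == "raw" && assigned > enrolled) {
    abort_gpc(sprintf("sum of list sizes (%d) exceeds enrolled (%d)",
                      as.integer(assigned), as.integer(enrolled)),
              "gpc_consistency_error")
  }
  enrolled - assigned
}

#' Patient-to-GP ratio (average list size per FTE GP)
#'
#' The ratio between patients with an assigned GP and the FTE workforce,
#' \eqn{L = (n - m)/GP} — the productivity variable of the decomposition.
#'
#' @param enrolled Enrolled patients \eqn{n}.
#' @param unassigned Patients without an assigned GP \eqn{m}.
#' @param gp_fte GP workforce in FTE (must be positive).
#' @return Patients per FTE GP.
#' @export
list_ratio <- function(enrolled, unassigned, gp_fte) {
  if (any(gp_fte == 0)) {
    abort_gpc("list ratio undefined where gp_fte = 0",
              "gpc_undefined_ratio_error")
  }
  if (any(unassigned < 0) || any(unassigned > enrolled)) {
    abort_gpc("need 0 <= unassigned <= enrolled", "gpc_domain_error")
  }
  (enrolled - unassigned) / gp_fte
}

#' Age-band weights for weighted patient units
#'
#' Risk adjustment of GP list size by patient age: each age band carries a
#' workload weight.  The default encodes the Portuguese capitation weights —
#' ages 0–6: 1.5, 7–64: 1.0, 65–74: 2.0, 75+: 2.5 — under which the
#' regulatory list-size reference is [WEIGHTED_UNIT_LIST_CAP] weighted units.
#'
#' @param min_age,max_age,weight Parallel vectors defining ordered,
#'   non-overlapping integer-age bands covering 0 to infinity (`max_age = NA`
#'   means open-ended) and their positive weights.
#' @return A data frame with class `age_weights`.
#' @export
#' @examples
#' age_weights()  # the default 1.5 / 1.0 / 2.0 / 2.5 scheme
age_weights <- function(min_age = c(0, 7, 65, 75),
                        max_age = c(6, 64, 74, NA),
                        weight = c(1.5, 1.0, 2.0, 2.5)) {
  stopifnot(length(min_age) == length(max_age),
            length(min_age) == length(weight))
  if (any(weight <= 0)) {
    abort_gpc("age-band weights must be positive", "gpc_domain_error")
  }
  o <- order(min_age)
  min_age <- min_age[o]; max_age <- max_age[o]; weight <- weight[o]
  hi <- ifelse(is.na(max_age), Inf, max_age)
  if (min_age[1L] != 0 || any(is.na(hi[-length(hi)])) ||
      !is.infinite(hi[length(hi)]) ||
      (length(min_age) > 1L && any(min_age[-1L] != hi[-length(hi)] + 1))) {
    abort_gpc("age bands must partition 0..Inf without gaps or overlaps",
              "gpc_domain_error")
  }
  structure(data.frame(min_age = min_age, max_age = max_age, weight = weight),
            class = c("age_weights", "data.frame"))
}

# "age_0_6", "0-6", "0_6" -> c(0, 6); "age_75p", "75+" -> c(75, Inf)
parse_age_band <- function(name) {
  x <- sub("^age[_ ]?", "", tolower(name))
  open <- grepl("(p|\\+)$", x)
  nums <- as.numeric(regmatches(x, gregexpr("[0-9]+", x))[[1L]])
  if (open && length(nums) == 1L) return(c(nums, Inf))
  if (length(nums) == 2L) return(nums)
  c(NA_real_, NA_real_)
}

#' Age-weighted patient units
#'
#' Converts age-band patient counts into weighted units: the total
#' \eqn{\sum_b w_b c_b} and the average weighted units per patient
#' \eqn{\sum_b w_b c_b / \sum_b c_b}.  Band names such as `age_0_6`, `0-6` or
#' `75+` are resolved against the weight scheme; a count band must fall
#' entirely inside one weight band.
#'
#' @param age_band_counts Named non-negative numeric vector of patient counts
#'   per age band.
#' @param weights An [age_weights()] scheme.
#' @return A list with elements `total` (weighted units) and `per_patient`
#'   (weighted units per enrolled patient).
#' @export
#' @examples
#' weighted_units(c(age_0_6 = 100, age_7_64 = 100,
#'                  age_65_74 = 100, age_75p = 100))
weighted_units <- function(age_band_counts, weights = age_weights()) {
  if (is.null(names(age_band_counts)) || any(!nzchar(names(age_band_counts)))) {
    abort_gpc("age_band_counts must be a named vector", "gpc_mapping_error")
  }
  if (any(age_band_counts < 0)) {
    abort_gpc("age-band counts must be non-negative", "gpc_domain_error")
  }
  whi <- ifelse(is.na(weights$max_age), Inf, weights$max_age)
  w <- vapply(names(age_band_counts), function(nm) {
    band <- parse_age_band(nm)
    if (any(is.na(band))) {
      abort_gpc(sprintf("cannot parse age band '%s'", nm), "gpc_mapping_error")
    }
    hit <- which(weights$min_age <= band[1L] & band[2L] <= whi)
    if (length(hit) != 1L) {
      abort_gpc(sprintf("age band '%s' does not fit inside one weight band", nm),
                "gpc_mapping_error")
    }
    weights$weight[hit]
  }, numeric(1))
  total <- sum(w * age_band_counts)
  n <- sum(age_band_counts)
  if (n == 0) {
    abort_gpc("weighted units per patient undefined for zero patients",
              "gpc_undefined_ratio_error")
  }
  list(total = total, per_patient = total / n)
}

#' Additional GPs required by a case-mix shift
#'
#' When the average weighted units per enrolled patient rise from `wu0` to
#' `wu1` (e.g. through population ageing), holding the weighted workload per
#' FTE GP constant requires `gp_fte * (wu1/wu0 - 1)` additional FTE GPs to
#' cover the same number of patients.  Negative when the case-mix lightens.
#'
#' @param gp_fte Current GP workforce in FTE.
#' @param wu_per_patient_0 Baseline weighted units per enrolled patient.
#' @param wu_per_patient_1 New weighted units per enrolled patient.
#' @return Additional FTE GPs required (signed).
#' @export
#' @examples
#' required_additional_gps(5395, 1.24, 1.32)  # about 348 extra FTE
required_additional_gps <- function(gp_fte, wu_per_patient_0,
                                    wu_per_patient_1) {
  if (any(wu_per_patient_0 <= 0)) {
    abort_gpc("baseline weighted units per patient must be positive",
              "gpc_domain_error")
  }
  if (any(gp_fte < 0) || any(wu_per_patient_1 < 0)) {
    abort_gpc("inputs must be non-negative", "gpc_domain_error")
  }
  gp_fte * (wu_per_patient_1 / wu_per_patient_0 - 1)
}
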