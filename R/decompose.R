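rec_fields <- function(rec, what) {
  if (is.data.frame(rec)) {
    if (nrow(rec) != 1L) {
      abort_gpc(sprintf("%s must be a single record", what), "gpc_usage_error")
    }
    rec <- as.list(rec)
  }
  need <- c("enrolled", "unassigned", "gp_fte")
  if (!all(need %in% names(rec))) {
    abort_gpc(sprintf("%s needs fields enrolled, unassigned, gp_fte", what),
              "gpc_usage_error")
  }
  rec
}

#' Decompose the change in unassigned patients between two periods
#'
#' The accounting identity \eqn{m = n - GP \cdot L} (unassigned = enrolled
#' minus workforce times average list size) implies an exact three-way
#' decomposition of the change in \eqn{m} between periods 0 and 1:
#' \deqn{m(1)-m(0) = [n(1)-n(0)] - [(GP(1)-GP(0))\,L(0)] - [(L(1)-L(0))\,GP(1)]}
#' a demand effect (enrolment change), a supply effect (workforce change
#' valued at the baseline list size) and a productivity effect (list-size
#' change valued at the final workforce).  Positive effects increase the
#' number of patients without a GP.
#'
#' The interaction (cross) term of the change must be allocated to one
#' dimension for the identity to stay exact.  `allocation = "list"` (the
#' default shown above) allocates it to the list dimension; `"gp"` evaluates
#' supply at `L(1)` and productivity at `GP(0)`; `"symmetric"` averages the
#' two.  All three conventions sum exactly to `m(1) - m(0)`.
#'
#' @param rec0,rec1 Records for periods 0 and 1: one-row data frames or named
#'   lists with `enrolled`, `unassigned`, `gp_fte` (and optionally `unit_id`,
#'   `year`).  Both must refer to the same scope.
#' @param allocation Cross-term allocation: `"list"` (default), `"gp"` or
#'   `"symmetric"`.
#' @return An object of class `decomposition_result`: a list with `scope`,
#'   `year_0`, `year_1`, `total_change`, `demand_effect`, `supply_effect`,
#'   `productivity_effect`, `allocation`, `baseline_unassigned`.
#' @export
#' @examples
#' rec0 <- list(enrolled = 11293000, unassigned = 1800000, gp_fte = 5650)
#' rec1 <- list(enrolled = 10500000, unassigned = 1700000, gp_fte = 5395)
#' decompose(rec0, rec1)
decompose <- function(rec0, rec1, allocation = c("list", "gp", "symmetric")) {
  allocation <- match.arg(allocation)
  rec0 <- rec_fields(rec0, "rec0")
  rec1 <- rec_fields(rec1, "rec1")
  s0 <- rec0$unit_id %||% NA_character_
  s1 <- rec1$unit_id %||% NA_character_
  if (!is.na(s0) && !is.na(s1) && s0 != s1) {
    abort_gpc(sprintf("records belong to different scopes ('%s' vs '%s')",
                      s0, s1), "gpc_usage_error")
  }
  if (rec0$gp_fte == 0 || rec1$gp_fte == 0) {
    abort_gpc("gp_fte = 0 in an endpoint: list size undefined, decomposition degenerate",
              "gpc_degenerate_decomposition_error")
  }
  n0 <- as.numeric(rec0$enrolled); m0 <- as.numeric(rec0$unassigned)
  g0 <- as.numeric(rec0$gp_fte)
  n1 <- as.numeric(rec1$enrolled); m1 <- as.numeric(rec1$unassigned)
  g1 <- as.numeric(rec1$gp_fte)
  L0 <- (n0 - m0) / g0
  L1 <- (n1 - m1) / g1
  demand <- n1 - n0
  supply_list <- -(g1 - g0) * L0
  prod_list <- -(L1 - L0) * g1
  supply_gp <- -(g1 - g0) * L1
  prod_gp <- -(L1 - L0) * g0
  eff <- switch(allocation,
    list = c(supply_list, prod_list),
    gp = c(supply_gp, prod_gp),
    symmetric = c((supply_list + supply_gp) / 2, (prod_list + prod_gp) / 2))
  structure(list(
    scope = if (!is.na(s0)) s0 else s1,
    year_0 = rec0$year %||% NA_integer_,
    year_1 = rec1$year %||% NA_integer_,
    total_change = m1 - m0,
    demand_effect = demand,
    supply_effect = eff[1L],
    productivity_effect = eff[2L],
    allocation = allocation,
    baseline_unassigned = m0
  ), class = "decomposition_result")
}

#' @export
print.decomposition_result <- function(x, ...) {
  cat(sprintf("<decomposition_result> scope %s, %s -> %s (%s allocation)\n",
              x$scope, x$year_0, x$year_1, x$allocation))
  cat(sprintf("  total change in unassigned: %+.1f\n", x$total_change))
  cat(sprintf("  demand effect:       %+.1f\n", x$demand_effect))
  cat(sprintf("  supply effect:       %+.1f\n", x$supply_effect))
  cat(sprintf("  productivity effect: %+.1f\n", x$productivity_effect))
  invisible(x)
}

#' @export
as.data.frame.decomposition_result <- function(x, ...) {
  data.frame(scope = x$scope, year_0 = x$year_0, year_1 = x$year_1,
             total_change = x$total_change, demand_effect = x$demand_effect,
             supply_effect = x$supply_effect,
             productivity_effect = x$productivity_effect,
             allocation = x$allocation,
             baseline_unassigned = x$baseline_unassigned,
             stringsAsFactors = FALSE)
}

#' Yearly chained decomposition of a single scope's series
#'
#' Applies [decompose()] to every adjacent pair of years of one scope.  The
#' yearly `total_change` values telescope exactly to `m(last) - m(first)`, and
#' so do the demand effects (to `n(last) - n(first)`); supply and productivity
#' chains are path dependent and need not match the single long-run step.
#'
#' @param series Records of one scope: a `coverage_panel` (or data frame)
#'   whose rows share one `unit_id`, with unique years.
#' @inheritParams decompose
#' @param allow_gaps If `FALSE` (default), missing intermediate years raise a
#'   `gpc_gap_error`; if `TRUE`, adjacent available years are paired.
#' @return A data frame of one decomposition row per adjacent year pair.
#' @export
chain_decompose <- function(series, allocation = c("list", "gp", "symmetric"),
                            allow_gaps = FALSE) {
  allocation <- match.arg(allocation)
  series <- as.data.frame(series)
  if (nrow(series) < 2L) {
    abort_gpc("need at least two records to chain-decompose",
              "gpc_usage_error")
  }
  if (length(unique(series$unit_id)) > 1L) {
    abort_gpc("chain_decompose expects records of a single scope",
              "gpc_usage_error")
  }
  if (anyDuplicated(series$year)) {
    abort_gpc("duplicate years in series", "gpc_duplication_error")
  }
  series <- series[order(series$year), , drop = FALSE]
  gaps <- diff(series$year) != 1L
  if (any(gaps) && !allow_gaps) {
    abort_gpc(sprintf("gap in years after %d; set allow_gaps = TRUE to pair available years",
                      series$year[which(gaps)[1L]]), "gpc_gap_error")
  }
  out <- lapply(seq_len(nrow(series) - 1L), function(i) {
    d <- as.data.frame(decompose(series[i, ], series[i + 1L, ],
                                 allocation = allocation))
    d$gap <- series$year[i + 1L] - series$year[i] > 1L
    d
  })
  do.call(rbind, out)
}

#' Relative shares of the three effects
#'
#' Normalises the three effects by the sum of their absolute values, so the
#' unsigned shares add to exactly 100% per scope regardless of sign mixing;
#' the effects' signs are reported alongside.  The last share is set by
#' complement so the sum is exactly 100.
#'
#' @param result A [decompose()] result.
#' @return A list with `demand_share`, `supply_share`, `productivity_share`
#'   (percentages summing to 100) and `signs` (named -1/0/+1 vector).
#' @export
relative_shares <- function(result) {
  eff <- c(demand = result$demand_effect, supply = result$supply_effect,
           productivity = result$productivity_effect)
  denom <- sum(abs(eff))
  if (denom == 0) {
    abort_gpc("all three effects are zero; shares undefined",
              "gpc_undefined_shares_error")
  }
  sh <- abs(eff) / denom * 100
  sh[3L] <- 100 - sh[1L] - sh[2L]
  list(demand_share = unname(sh[1L]), supply_share = unname(sh[2L]),
       productivity_share = unname(sh[3L]), signs = sign(eff))
}

#' Per-scope decomposition and share table between two years
#'
#' Decomposes every scope of a panel between `year_0` and `year_1` and reports
#' signed effects, absolute-value shares (summing to 100 per scope) and an
#' ordering key — the change in the percentage of patients without a GP,
#' `m(1)/n(1) - m(0)/n(0)` — sorting scopes from the largest increase to the
#' largest reduction.
#'
#' @param panel A `coverage_panel`.
#' @param year_0,year_1 The two years to compare; scopes missing either year
#'   are dropped with a warning.
#' @inheritParams decompose
#' @return A data frame with class `share_table`, one row per scope, columns
#'   `scope, year_0, year_1, total_change, demand_effect, supply_effect,
#'   productivity_effect, demand_share, supply_share, productivity_share,
#'   pct_unassigned_change, allocation`.
#' @export
decompose_all <- function(panel, year_0, year_1,
                          allocation = c("list", "gp", "symmetric")) {
  allocation <- match.arg(allocation)
  validate_panel(panel)
  df <- as.data.frame(panel)
  scopes <- unique(df$unit_id)
  keep <- vapply(scopes, function(u) {
    all(c(year_0, year_1) %in% df$year[df$unit_id == u])
  }, logical(1))
  if (!any(keep)) {
    abort_gpc(sprintf("no scope has records for both %d and %d",
                      year_0, year_1), "gpc_empty_result_error")
  }
  if (any(!keep)) {
    warn_gpc(sprintf("dropping %d scope(s) missing year %d or %d: %s",
                     sum(!keep), year_0, year_1,
                     paste(scopes[!keep], collapse = ", ")),
             "gpc_dropped_scopes_warning")
  }
  rows <- lapply(scopes[keep], function(u) {
    r0 <- df[df$unit_id == u & df$year == year_0, , drop = FALSE]
    r1 <- df[df$unit_id == u & df$year == year_1, , drop = FALSE]
    d <- decompose(r0, r1, allocation = allocation)
    sh <- relative_shares(d)
    data.frame(scope = u, year_0 = year_0, year_1 = year_1,
               total_change = d$total_change,
               demand_effect = d$demand_effect,
               supply_effect = d$supply_effect,
               productivity_effect = d$productivity_effect,
               demand_share = sh$demand_share,
               supply_share = sh$supply_share,
               productivity_share = sh$productivity_share,
               pct_unassigned_change =
                 r1$unassigned / r1$enrolled - r0$unassigned / r0$enrolled,
               allocation = allocation,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$pct_unassigned_change), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("share_table", "data.frame"))
}
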