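# Fixtures are built in code: small panels with the accounting identity
# satisfied by construction.

panel_df <- function(unit_id, region_id, year, enrolled, unassigned, gp_fte,
                     ...) {
  data.frame(unit_id = unit_id, region_id = region_id, year = year,
             enrolled = enrolled, unassigned = unassigned, gp_fte = gp_fte,
             ..., stringsAsFactors = FALSE)
}

tiny_panel <- function() {
  as_panel(panel_df(
    unit_id = rep(c("A", "B", "C"), each = 2),
    region_id = rep(c("R1", "R1", "R2"), each = 2),
    year = rep(c(2020L, 2021L), 3),
    enrolled = c(1000L, 1020L, 3000L, 2950L, 2000L, 2100L),
    unassigned = c(100L, 120L, 500L, 450L, 200L, 260L),
    gp_fte = c(2, 2.1, 5, 5.2, 3.5, 3.4)))
}

# random valid record for property tests: n, m, GP with GP > 0 and 0 <= m <= n
random_record <- function() {
  n <- sample.int(5e6, 1L)
  m <- sample.int(n + 1L, 1L) - 1L
  list(enrolled = n, unassigned = m, gp_fte = stats::runif(1, 0.5, 8000))
}

# random single-scope yearly series of valid records
random_series <- function(n_years, start_year = 2009L) {
  do.call(rbind, lapply(seq_len(n_years), function(i) {
    r <- random_record()
    data.frame(unit_id = "S", region_id = "R", year = start_year + i - 1L,
               enrolled = r$enrolled, unassigned = r$unassigned,
               gp_fte = r$gp_fte, stringsAsFactors = FALSE)
  }))
}

national_example_records <- function() {
  list(
    rec0 = list(unit_id = "NATIONAL", year = 2009L, enrolled = 11293000,
                unassigned = 1800000, gp_fte = 5650),
    rec1 = list(unit_id = "NATIONAL", year = 2023L, enrolled = 10500000,
                unassigned = 1700000, gp_fte = 5395))
}
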