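test_that("the national 2009-2023 example decomposes into the known effects", {
  ex <- national_example_records()
  d <- decompose(ex$rec0, ex$rec1)
  # frozen values recomputed by hand from the aggregates:
  # L0 = 9493000/5650 = 1680.17699...; L1 = 8800000/5395 = 1631.13994...
  expect_equal(d$demand_effect, -793000)
  expect_equal(d$supply_effect, 255 * 9493000 / 5650, tolerance = 1e-12)
  expect_equal(d$supply_effect, 428445.133, tolerance = 1e-6)
  expect_equal(d$productivity_effect, 264554.867, tolerance = 1e-6)
  expect_equal(d$total_change, -100000)
  expect_equal(d$demand_effect + d$supply_effect + d$productivity_effect,
               d$total_change, tolerance = 1e-9)
  expect_equal(d$baseline_unassigned, 1800000)
})

test_that("no change means all effects are zero", {
  r <- list(enrolled = 1000, unassigned = 100, gp_fte = 3)
  d <- decompose(r, r)
  expect_equal(d$total_change, 0)
  expect_equal(d$demand_effect, 0)
  expect_equal(d$supply_effect, 0)
  expect_equal(d$productivity_effect, 0)
})

test_that("offsetting supply and productivity can leave unassigned unchanged", {
  # L falls from 300 to 225 while one FTE is added: m stays 100
  d <- decompose(list(enrolled = 1000, unassigned = 100, gp_fte = 3),
                 list(enrolled = 1000, unassigned = 100, gp_fte = 4))
  expect_equal(d$demand_effect, 0)
  expect_equal(d$supply_effect, -300)
  expect_equal(d$productivity_effect, 300)
  expect_equal(d$total_change, 0)
})

test_that("all three allocation conventions are exact and agree on the total", {
  set.seed(101)
  for (i in 1:500) {
    r0 <- random_record()
    r1 <- random_record()
    if (r0$enrolled == r0$unassigned) r0$unassigned <- r0$unassigned - 1L
    totals <- vapply(c("list", "gp", "symmetric"), function(a) {
      d <- decompose(r0, r1, allocation = a)
      expect_equal(d$demand_effect + d$supply_effect + d$productivity_effect,
                   d$total_change,
                   tolerance = 1e-9 * max(1, abs(d$total_change)))
      d$total_change
    }, numeric(1))
    expect_equal(unname(totals), rep(r1$unassigned - r0$unassigned, 3))
  }
})

test_that("degenerate endpoints (gp_fte = 0) and scope mismatches are refused", {
  r0 <- list(unit_id = "A", enrolled = 100, unassigned = 100, gp_fte = 0)
  r1 <- list(unit_id = "A", enrolled = 100, unassigned = 10, gp_fte = 1)
  expect_error(decompose(r0, r1),
               class = "gpc_degenerate_decomposition_error")
  expect_error(decompose(list(unit_id = "A", enrolled = 1, unassigned = 0,
                              gp_fte = 1),
                         list(unit_id = "B", enrolled = 1, unassigned = 0,
                              gp_fte = 1)),
               class = "gpc_usage_error")
})

test_that("yearly chains telescope to the long-run totals", {
  s <- data.frame(unit_id = "S", region_id = "R", year = 2009:2011,
                  enrolled = c(1000L, 1000L, 1000L),
                  unassigned = c(100L, 120L, 90L),
                  gp_fte = c(2, 2, 2))
  ch <- chain_decompose(s)
  expect_equal(ch$total_change, c(20, -30))
  expect_equal(sum(ch$total_change), -10)
  set.seed(202)
  for (i in 1:20) {
    s <- random_series(15)
    ch <- chain_decompose(s)
    expect_equal(sum(ch$total_change),
                 s$unassigned[15] - s$unassigned[1])
    expect_equal(sum(ch$demand_effect), s$enrolled[15] - s$enrolled[1])
  }
})

test_that("chained per-year effects match the single-step identity on a hand series", {
  # constructed so L is exactly 400 every year
  s <- data.frame(unit_id = "S", region_id = "R", year = 2009:2011,
                  enrolled = c(1000L, 1000L, 1100L),
                  unassigned = c(200L, 120L, 220L),
                  gp_fte = c(2, 2.2, 2.2))
  ch <- chain_decompose(s)
  expect_equal(ch$demand_effect, c(0, 100))
  expect_equal(ch$supply_effect, c(-80, 0))      # -(0.2 * 400)
  expect_equal(ch$productivity_effect, c(0, 0))  # L constant at 400
  # each row equals an independent pairwise call
  for (i in 1:2) {
    d <- decompose(s[i, ], s[i + 1, ])
    expect_equal(ch$total_change[i], d$total_change)
    expect_equal(ch$supply_effect[i], d$supply_effect)
  }
})

test_that("gaps in the year series are refused unless explicitly allowed", {
  s <- data.frame(unit_id = "S", region_id = "R", year = c(2009L, 2011L),
                  enrolled = c(1000L, 900L), unassigned = c(100L, 90L),
                  gp_fte = c(2, 2))
  expect_error(chain_decompose(s), class = "gpc_gap_error")
  ch <- chain_decompose(s, allow_gaps = TRUE)
  expect_true(ch$gap)
  expect_equal(ch$total_change, -10)
})

test_that("relative shares use absolute-value normalization and sum to exactly 100", {
  d <- structure(list(demand_effect = -793000, supply_effect = 428445.133,
                      productivity_effect = 264554.867),
                 class = "decomposition_result")
  sh <- relative_shares(d)
  expect_equal(sh$demand_share, 53.4, tolerance = 1e-3)
  expect_equal(sh$supply_share, 28.8, tolerance = 1e-2)
  expect_equal(sh$productivity_share, 17.8, tolerance = 1e-2)
  expect_equal(sh$demand_share + sh$supply_share + sh$productivity_share, 100)
  expect_equal(unname(sh$signs), c(-1, 1, 1))

  one <- structure(list(demand_effect = 5, supply_effect = 0,
                        productivity_effect = 0),
                   class = "decomposition_result")
  expect_equal(relative_shares(one)[1:3],
               list(demand_share = 100, supply_share = 0,
                    productivity_share = 0))
  prop <- structure(list(demand_effect = 1, supply_effect = 1,
                         productivity_effect = 2),
                    class = "decomposition_result")
  expect_equal(relative_shares(prop)[1:3],
               list(demand_share = 25, supply_share = 25,
                    productivity_share = 50))
  zero <- structure(list(demand_effect = 0, supply_effect = 0,
                         productivity_effect = 0),
                    class = "decomposition_result")
  expect_error(relative_shares(zero), class = "gpc_undefined_shares_error")
})

test_that("the share table matches per-unit decompose calls and orders by coverage change", {
  cfg <- scenario_config(seed = 7, n_units = 10, n_regions = 2,
                         years = 2012:2023)
  p <- generate_panel(cfg)
  tab <- decompose_all(p, 2012, 2023)
  expect_s3_class(tab, "share_table")
  expect_equal(nrow(tab), 10L)
  expect_equal(tab$demand_share + tab$supply_share + tab$productivity_share,
               rep(100, 10))
  # oracle: every row equals an independent pairwise decomposition
  df <- as.data.frame(p)
  for (i in seq_len(nrow(tab))) {
    u <- tab$scope[i]
    d <- decompose(df[df$unit_id == u & df$year == 2012, ],
                   df[df$unit_id == u & df$year == 2023, ])
    sh <- relative_shares(d)
    expect_equal(tab$total_change[i], d$total_change)
    expect_equal(tab$demand_effect[i], d$demand_effect)
    expect_equal(tab$supply_effect[i], d$supply_effect)
    expect_equal(tab$productivity_effect[i], d$productivity_effect)
    expect_equal(tab$demand_share[i], sh$demand_share)
  }
  expect_false(is.unsorted(rev(tab$pct_unassigned_change)))
})

test_that("single-scope tables work and increases order before reductions", {
  p <- as_panel(panel_df(
    unit_id = rep(c("up", "down"), each = 2), region_id = "R1",
    year = rep(c(2012L, 2023L), 2),
    enrolled = c(1000L, 1000L, 1000L, 1000L),
    unassigned = c(100L, 300L, 300L, 100L),
    gp_fte = c(2, 2, 2, 2)))
  tab <- decompose_all(p, 2012, 2023)
  expect_equal(tab$scope, c("up", "down"))
  single <- decompose_all(p[p$unit_id == "up", ], 2012, 2023)
  expect_equal(nrow(single), 1L)
  expect_equal(single$demand_share + single$supply_share +
                 single$productivity_share, 100)
  expect_warning(decompose_all(p[-1, ], 2012, 2023),
                 class = "gpc_dropped_scopes_warning")
  expect_error(decompose_all(p, 2012, 2024), class = "gpc_empty_result_error")
})

test_that("unassigned changes are additive across units but effects are not", {
  # counterexample: national effects on aggregated records differ from the
  # sum of unit effects, while total changes agree
  p <- as_panel(panel_df(
    unit_id = rep(c("A", "B"), each = 2), region_id = "R1",
    year = rep(c(2009L, 2023L), 2),
    enrolled = c(1000L, 900L, 5000L, 5500L),
    unassigned = c(100L, 200L, 500L, 300L),
    gp_fte = c(2, 1.5, 8, 11)))
  nat <- aggregate_panel(p, "national")
  d_nat <- decompose(nat[nat$year == 2009, ], nat[nat$year == 2023, ])
  df <- as.data.frame(p)
  d_units <- lapply(c("A", "B"), function(u) {
    decompose(df[df$unit_id == u & df$year == 2009, ],
              df[df$unit_id == u & df$year == 2023, ])
  })
  sum_units <- Reduce(`+`, lapply(d_units, `[[`, "total_change"))
  expect_equal(d_nat$total_change, sum_units)
  sum_supply <- Reduce(`+`, lapply(d_units, `[[`, "supply_effect"))
  expect_false(isTRUE(all.equal(d_nat$supply_effect, sum_supply)))
})
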