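test_that("parameter sampling matches each distribution's moment rule", {
  fixed <- param_spec("x", "prices.atezolizumab", 5, 5, 5, "fixed")
  expect_equal(sample_param(fixed, 10), rep(5, 10))

  gam <- param_spec("price", "prices.atezolizumab", 7.83, 5.87, 9.78, "gamma")
  draws <- withr::with_seed(1, sample_param(gam, 1e5))
  expect_equal(mean(draws), 7.83, tolerance = 0.01)
  expect_true(all(draws > 0))

  bet <- param_spec("u", "utilities.pfs", 0.673, 0.538, 0.808, "beta")
  bdraws <- withr::with_seed(2, sample_param(bet, 1e5))
  expect_equal(mean(bdraws), 0.673, tolerance = 0.01)
  expect_true(all(bdraws >= 0 & bdraws <= 1))

  lno <- param_spec("hr", "survival.dep_hr.os.hr", 1.04, 0.83, 1.25,
                    "lognormal")
  ldraws <- withr::with_seed(3, sample_param(lno, 1e5))
  expect_equal(median(ldraws), 1.04, tolerance = 0.02)

  # beta moment-matching infeasibility is a validation error
  wide <- param_spec("u", "utilities.pfs", 0.01, 0, 1, "beta")
  expect_error(sample_param(wide, 1), "infeasible")
  expect_error(param_spec("u", "utilities.pfs", 1.2, 1.1, 1.3, "beta"),
               "\\[0, 1\\]")
})

test_that("one-way sensitivity reproduces the base case at zero-width ranges", {
  cfg <- default_config()
  base <- icer(
    with(evaluate_strategy(cfg, "AEP", detail = FALSE), c(cost, qaly)),
    with(evaluate_strategy(cfg, "EP", detail = FALSE), c(cost, qaly)))
  degenerate <- lapply(c("prices.atezolizumab", "utilities.ps",
                         "care_costs.death_cost"), function(p) {
    v <- get_config_value(cfg, p)
    param_spec(p, p, v, v, v, "fixed")
  })
  tor <- one_way_dsa(cfg, c("AEP", "EP"), degenerate)
  expect_equal(tor$spread, rep(0, 3))
  expect_equal(tor$icer_low, rep(base$icer, 3), tolerance = 1e-9)
  expect_equal(tor$icer_high, rep(base$icer, 3), tolerance = 1e-9)
})

test_that("the ICER rises with the intervention drug price and ignores carboplatin", {
  cfg <- default_config()
  specs <- param_specs_from_config(cfg)
  names(specs) <- vapply(specs, `[[`, character(1), "path")

  atezo <- specs[["prices.atezolizumab"]]
  tor <- one_way_dsa(cfg, c("AEP", "EP"), list(atezo))
  expect_lt(tor$icer_low, tor$icer_high)

  carbo <- specs[["prices.carboplatin"]]
  tor_c <- one_way_dsa(cfg, c("AEP", "EP"), list(carbo))
  rel_change <- abs(tor_c$icer_high - tor_c$icer_low) /
    ((tor_c$icer_high + tor_c$icer_low) / 2)
  expect_lt(rel_change, 0.01)
})

test_that("the full tornado runs and sorts by spread", {
  cfg <- default_config()
  tor <- one_way_dsa(cfg, c("AEP", "EP"))
  expect_equal(nrow(tor), length(cfg$sensitivity))
  ok <- !is.na(tor$spread)
  expect_true(all(diff(tor$spread[ok]) <= 1e-9))
  # drug price tops the tornado, as in the published analysis
  expect_identical(tor$parameter[1], "Atezolizumab price/mg")
})

test_that("price thresholds are roots of the ICER-WTP equation", {
  cfg <- default_config()
  th <- price_threshold(cfg, "atezolizumab", c("AEP", "EP"), wtp = 1e5)
  expect_true(th$attainable)
  expect_lt(abs(th$icer - 1e5), 500)
  # independent verification: re-run the model at the returned multiplier
  cfg2 <- set_config_value(cfg, "prices.atezolizumab",
                           7.83 * (1 - th$multiplier))
  re <- icer(
    with(evaluate_strategy(cfg2, "AEP", detail = FALSE), c(cost, qaly)),
    with(evaluate_strategy(cfg2, "EP", detail = FALSE), c(cost, qaly)))
  expect_lt(abs(re$icer - 1e5), 500)

  # a WTP at the baseline ICER needs no price cut
  base <- icer(
    with(evaluate_strategy(cfg, "AEP", detail = FALSE), c(cost, qaly)),
    with(evaluate_strategy(cfg, "EP", detail = FALSE), c(cost, qaly)))
  th0 <- price_threshold(cfg, "atezolizumab", c("AEP", "EP"),
                         wtp = base$icer + 1)
  expect_equal(th0$multiplier, 0)

  # an unattainable target is reported as such
  cheap <- set_config_value(cfg, "prices.atezolizumab", 0.01)
  thx <- price_threshold(cheap, "atezolizumab", c("AEP", "EP"), wtp = 1e4)
  expect_false(thx$attainable)
  expect_true(is.na(thx$multiplier))
})

test_that("an all-fixed PSA collapses to the base case and seeds reproduce", {
  cfg <- default_config()
  fixed <- lapply(c("prices.atezolizumab", "utilities.pfs"), function(p) {
    v <- get_config_value(cfg, p)
    param_spec(p, p, v, v, v, "fixed")
  })
  psa <- run_psa(cfg, n_draws = 3, seed = 1, params = fixed)
  base <- run_base_case(cfg)
  for (nm in c("EP", "AEP", "DEP")) {
    rows <- psa$draws[psa$draws$strategy == nm, ]
    expect_equal(rows$cost, rep(base$totals$cost[base$totals$name == nm], 3),
                 tolerance = 1e-12)
    expect_equal(rows$qaly, rep(base$totals$qaly[base$totals$name == nm], 3),
                 tolerance = 1e-12)
  }

  p1 <- run_psa(cfg, n_draws = 25, seed = 77)
  p2 <- run_psa(cfg, n_draws = 25, seed = 77)
  expect_identical(p1$draws, p2$draws)      # byte-identical draws
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(p1$draws, f1, row.names = FALSE)
  write.csv(p2$draws, f2, row.names = FALSE)
  expect_identical(readLines(f1), readLines(f2))
  p3 <- run_psa(cfg, n_draws = 25, seed = 78)
  expect_false(identical(p1$draws, p3$draws))
})

test_that("acceptability curves are proper probabilities", {
  cfg <- default_config()
  psa <- run_psa(cfg, n_draws = 50, seed = 9)
  grid <- seq(0, 3e5, by = 5e4)
  cc <- ceac(psa, grid)
  for (w in grid) {
    p <- cc$probability[cc$wtp == w]
    expect_true(all(p >= 0 & p <= 1))
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }

  # a single-strategy PSA is certain everywhere
  solo <- psa
  solo$draws <- solo$draws[solo$draws$strategy == "EP", ]
  cs <- ceac(solo, grid)
  expect_equal(cs$probability, rep(1, length(grid)))

  # two-strategy CEAC is monotone when one arm costs and yields more in
  # every draw
  fake <- structure(list(draws = data.frame(
    draw = rep(1:100, each = 2),
    strategy = rep(c("cheap", "rich"), 100),
    cost = as.vector(rbind(runif(100, 0, 1e4), runif(100, 4e4, 6e4))),
    qaly = as.vector(rbind(runif(100, 0.2, 0.4), runif(100, 0.5, 0.9)))),
    n = 100, seed = 1), class = "psa_result")
  cf <- ceac(fake, seq(0, 3e5, by = 1e4))
  rich <- cf$probability[cf$strategy == "rich"]
  expect_true(all(diff(rich) >= -1e-12))
})

test_that("the until-progression scenario only touches the ICI strategies", {
  cfg <- default_config()
  base <- run_base_case(cfg)
  sc <- scenario_until_progression(cfg)
  get <- function(res, nm, col) res$totals[[col]][res$totals$name == nm]
  expect_equal(get(sc, "EP", "cost"), get(base, "EP", "cost"))
  expect_equal(get(sc, "EP", "qaly"), get(base, "EP", "qaly"))
  expect_gt(get(sc, "AEP", "cost"), get(base, "AEP", "cost"))
  expect_gt(get(sc, "DEP", "cost"), get(base, "DEP", "cost"))
  # the disutility window is pinned to the planned duration: QALYs unchanged
  expect_equal(get(sc, "AEP", "qaly"), get(base, "AEP", "qaly"))
  # AEP still dominates DEP in the scenario
  inc <- sc$incremental
  expect_identical(inc$status[inc$intervention == "DEP" &
                                inc$comparator == "AEP"], "dominated")
})
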