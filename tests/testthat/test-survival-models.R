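test_that("closed-form survival values match their defining formulas", {
  ll <- aep_os_curve()
  expect_identical(survival_at(ll, 0), 1)
  # log-logistic median (1/theta)^(1/kappa), cross-checked by numerical root
  med <- (1 / 0.003072)^(1 / 2.297440)
  expect_equal(med, 12.406316, tolerance = 1e-6)
  expect_equal(survival_at(ll, med), 0.5, tolerance = 1e-12)
  expect_equal(uniroot(function(t) survival_at(ll, t) - 0.5,
                       c(1, 100), tol = 1e-12)$root, med, tolerance = 1e-8)

  wb <- ep_os_curve()
  med_w <- (log(2) / 0.016073)^(1 / 1.593409)
  expect_equal(med_w, 10.615282, tolerance = 1e-6)
  expect_equal(survival_at(wb, med_w), 0.5, tolerance = 1e-12)
  expect_equal(median_survival(wb), med_w)
  expect_equal(median_survival(ll), med)
  expect_equal(median_survival(aep_pfs_curve()), (1 / 0.008895)^(1 / 2.852489))
  expect_equal(median_survival(aep_pfs_curve()), 5.235643, tolerance = 1e-6)
  expect_equal(median_survival(ep_pfs_curve()), 5.084421, tolerance = 1e-6)
  expect_equal(median_survival(parametric_survival("exponential", log(2) / 12)),
               12)
})

test_that("the fitted curve parameters are on the month scale: published trial medians are reproduced", {
  # AEP OS ~12.4 mo, AEP PFS ~5.2 mo, pooled EP OS ~10.6 mo
  expect_equal(median_survival(aep_os_curve()), 12.4, tolerance = 0.01)
  expect_equal(median_survival(aep_pfs_curve()), 5.2, tolerance = 0.01)
  expect_equal(median_survival(ep_os_curve()), 10.6, tolerance = 0.01)
})

test_that("all families give valid, monotone survival with S(0) = 1", {
  grid <- seq(0, 120, length.out = 1000)
  for (m in family_zoo()) {
    s <- survival_at(m, grid)
    expect_identical(s[1], 1)
    expect_true(all(s >= 0 & s <= 1))
    expect_true(all(diff(s) <= 0), info = m$family)
  }
})

test_that("constructor and evaluation reject invalid inputs", {
  expect_error(parametric_survival("weibull", c(-1, 2)), "positive")
  expect_error(parametric_survival("weibull", 1), "parameter")
  expect_error(parametric_survival("loglogistic", c(0, 2)), "positive")
  expect_error(survival_at(aep_os_curve(), -1), "non-negative")
  expect_error(adjust_by_hr(aep_os_curve(), 0), "positive")
  expect_error(adjust_by_hr(aep_os_curve(), -2), "positive")
})

test_that("hazard-ratio adjustment is proportional hazards on the survival scale", {
  base <- aep_os_curve()
  t <- c(0.5, 3, 12, 40, 100)
  expect_equal(survival_at(adjust_by_hr(base, 1), t), survival_at(base, t))
  expect_equal(0.180^1.04, 0.168067, tolerance = 1e-5)
  expect_equal(survival_at(adjust_by_hr(base, 1.04), t),
               survival_at(base, t)^1.04)
  # hr > 1 worsens survival, hr < 1 improves it, at every time
  expect_true(all(survival_at(adjust_by_hr(base, 1.5), t) <=
                    survival_at(base, t)))
  expect_true(all(survival_at(adjust_by_hr(base, 0.7), t) >=
                    survival_at(base, t)))
  # the base-case DEP hazard ratios are accepted from configuration
  cfg <- default_config()
  expect_equal(cfg$survival$dep_hr$os$hr, 1.04)
  expect_equal(cfg$survival$dep_hr$pfs$hr, 1.01)
})

test_that("interval event probabilities compose and honour memorylessness", {
  pol <- extrapolation_policy()
  for (m in family_zoo()) {
    expect_identical(interval_event_prob(m, 3, 3, pol), 0)
    p01 <- interval_event_prob(m, 0, 5, pol)
    p12 <- interval_event_prob(m, 5, 11, pol)
    p02 <- interval_event_prob(m, 0, 11, pol)
    expect_equal(1 - (1 - p01) * (1 - p12), p02, tolerance = 1e-12)
  }
  h <- log(2) / 12
  ex <- parametric_survival("exponential", h)
  expect_equal(interval_event_prob(ex, 0, 2), 1 - exp(-2 * h))
  expect_equal(interval_event_prob(ex, 37.3, 39.3), 1 - exp(-2 * h))
  # one 21-day cycle for the pooled EP OS curve
  cyc <- 21 / 30.4375
  expect_equal(interval_event_prob(ep_os_curve(), 0, cyc),
               1 - exp(-0.016073 * cyc^1.593409))
  expect_error(interval_event_prob(ex, 5, 4), ">=")
})

test_that("extrapolation continues parametrically or switches to a hazard table, continuously", {
  m <- aep_os_curve()
  ident <- extrapolation_policy(24, "parametric_continuation")
  t <- c(0, 10, 24, 30, 90)
  expect_equal(extrapolated_survival(m, ident, t), survival_at(m, t))

  tab <- data.frame(time_months = c(24, 36), monthly_hazard = c(0.05, 0.05))
  pol <- extrapolation_policy(24, "external_hazard_table", tab)
  # piecewise-exponential tail: S(36) = S(24) * exp(-0.05 * 12)
  s24 <- survival_at(m, 24)
  expect_equal(extrapolated_survival(m, pol, 36), s24 * exp(-0.6))
  expect_equal(0.18 * exp(-0.05 * 12), 0.098786, tolerance = 1e-5)
  # continuity at the cutoff in both modes
  eps <- 1e-9
  expect_equal(extrapolated_survival(m, pol, 24 + eps),
               extrapolated_survival(m, pol, 24 - eps), tolerance = 1e-7)
  expect_equal(extrapolated_survival(m, pol, 24), survival_at(m, 24),
               tolerance = 1e-12)

  expect_error(extrapolation_policy(24, "external_hazard_table"),
               "hazard_table")
  expect_error(
    extrapolation_policy(24, "external_hazard_table",
                         data.frame(time_months = c(24, 24),
                                    monthly_hazard = c(0.1, 0.1))),
    "increasing")
  expect_error(
    extrapolation_policy(24, "external_hazard_table",
                         data.frame(time_months = c(24, 30),
                                    monthly_hazard = c(0.1, -0.1))),
    "non-negative")
})

test_that("hazard tables round-trip through CSV", {
  tab <- data.frame(time_months = c(24, 30, 48),
                    monthly_hazard = c(0.08, 0.05, 0.02))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(tab, path, row.names = FALSE)
  got <- read_hazard_table(path)
  expect_equal(got$time_months, tab$time_months)
  expect_equal(got$monthly_hazard, tab$monthly_hazard)
  # last hazard carried forward beyond the table
  pol <- extrapolation_policy(24, "external_hazard_table", got)
  m <- aep_os_curve()
  s48 <- extrapolated_survival(m, pol, 48)
  expect_equal(extrapolated_survival(m, pol, 60), s48 * exp(-0.02 * 12))
})
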