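test_that("digitized curves are validated on construction", {
  expect_error(digitized_km(c(1, 2), c(1, 0.9), 0, 10), "first digitized")
  expect_error(digitized_km(c(0, 2), c(1, 1.1), 0, 10), "\\[0, 1\\]")
  expect_error(digitized_km(c(0, 2, 4), c(1, 0.8, 0.9), c(0, 4), c(10, 5)),
               "survival increases between t=2 and t=4")
  expect_error(digitized_km(c(0, 2), c(1, 0.9), c(0, 2), c(10, 12)),
               "number at risk increases")
  expect_silent(digitized_km(c(0, 2), c(1, 0.9), c(0, 2), c(10, 8)))
})

test_that("reconstruction does the no-censoring and no-event bookkeeping", {
  # 100 -> 80 at risk while S drops 1.0 -> 0.8: 20 events, 0 censored
  km <- digitized_km(time = c(0, 2, 4, 6, 8),
                     surv = c(1, 0.95, 0.9, 0.85, 0.8),
                     risk_time = c(0, 9), n_risk = c(100, 80))
  ipd <- reconstruct_ipd(km)
  expect_equal(sum(ipd$event), 20)
  # no censoring strictly inside the curve; survivors are administratively
  # censored at the last digitized time
  expect_equal(sum(ipd$event == 0 & ipd$time < 8), 0)
  expect_equal(sum(ipd$event == 0 & ipd$time == 8), 80)

  # S flat while n at risk decreases: the whole decrease is censoring
  km2 <- digitized_km(time = c(0, 6), surv = c(1, 1),
                      risk_time = c(0, 6), n_risk = c(50, 30))
  ipd2 <- reconstruct_ipd(km2)
  expect_equal(sum(ipd2$event[ipd2$time < 6]), 0)
  expect_equal(sum(ipd2$time < 6 & ipd2$event == 0), 20)
})

test_that("reconstructed data reproduce the source KM curve (roundtrip)", {
  set.seed(404)
  n_opts <- c(100, 200, 400)
  for (trial in 1:50) {
    n <- n_opts[(trial %% 3) + 1]
    fam <- if (trial %% 2 == 0) {
      parametric_survival("weibull", c(0.016073, 1.593409))
    } else {
      parametric_survival("loglogistic", c(0.003072, 2.297440))
    }
    spec <- trial_sim_spec(n, list(a = fam), accrual_months = 10,
                           max_followup_months = 30,
                           seed = 1000 + trial)
    ipd <- simulate_trial(spec)
    risk_times <- seq(0, 24, by = 4)
    km <- km_estimator(ipd, risk_times = risk_times)
    rec <- reconstruct_ipd(km)
    km_rec <- km_estimator(rec, risk_times = risk_times)
    # compare the two product-limit curves at the risk-table times
    s_at <- function(k, tt) {
      vapply(tt, function(x) {
        idx <- which(k$coords$time <= x)
        k$coords$surv[max(idx)]
      }, numeric(1))
    }
    err <- abs(s_at(km, risk_times) - s_at(km_rec, risk_times))
    expect_lt(max(err), 0.02)
  }
})

test_that("reconstruction honours a reported total event count", {
  spec <- trial_sim_spec(150, list(a = ep_os_curve()), accrual_months = 8,
                         max_followup_months = 24, seed = 99)
  ipd <- simulate_trial(spec)
  km <- km_estimator(ipd, risk_times = seq(0, 20, by = 5))
  rec <- reconstruct_ipd(km)
  expect_equal(sum(rec$event), sum(ipd$event))    # total_events carried over
})

test_that("maximum likelihood matches closed forms and recovers the truth", {
  # exponential with complete data: rate = events / total time
  t <- c(2, 5, 1, 8, 4, 3.5, 6)
  ipd <- data.frame(time = t, event = 1)
  fit <- fit_parametric(ipd, "exponential")
  expect_equal(fit$params, length(t) / sum(t), tolerance = 1e-8)
  expect_equal(fit$aic, 2 - 2 * fit$log_likelihood)
  expect_equal(fit$bic, log(7) - 2 * fit$log_likelihood)

  # Weibull parameter recovery at n = 2,000 without censoring
  spec <- trial_sim_spec(2000, list(
    a = parametric_survival("weibull", c(0.016, 1.6))), seed = 7)
  sim <- simulate_trial(spec)
  wfit <- fit_parametric(sim, "weibull")
  expect_equal(wfit$params[1], 0.016, tolerance = 0.10)
  expect_equal(wfit$params[2], 1.6, tolerance = 0.10)
  expect_equal(wfit$aic, 4 - 2 * wfit$log_likelihood)

  expect_error(fit_parametric(data.frame(time = t, event = 0), "weibull"),
               "no events")
  expect_error(fit_parametric(data.frame(time = 1:2, event = c(1, 0)),
                              "weibull"), "2 events")
})

test_that("fits agree with independent survreg/flexsurv estimates", {
  skip_if_not_installed("survival")
  skip_if_not_installed("flexsurv")
  spec <- trial_sim_spec(800, list(
    a = parametric_survival("weibull", c(0.016073, 1.593409))),
    accrual_months = 6, max_followup_months = 30, seed = 21)
  sim <- simulate_trial(spec)

  wfit <- fit_parametric(sim, "weibull")
  sr <- survival::survreg(survival::Surv(time, event) ~ 1, data = sim,
                          dist = "weibull")
  gamma_sr <- 1 / sr$scale
  lambda_sr <- exp(-gamma_sr * unname(coef(sr)[1]))
  expect_equal(wfit$params[2], gamma_sr, tolerance = 1e-4)
  expect_equal(wfit$params[1], lambda_sr, tolerance = 1e-3)

  lfit <- fit_parametric(sim, "loglogistic")
  fs <- flexsurv::flexsurvreg(survival::Surv(time, event) ~ 1, data = sim,
                              dist = "llogis")
  kappa_fs <- unname(fs$res["shape", "est"])
  theta_fs <- unname(fs$res["scale", "est"])^(-kappa_fs)
  expect_equal(lfit$params[2], kappa_fs, tolerance = 1e-3)
  expect_equal(lfit$params[1], theta_fs, tolerance = 1e-2)
  expect_equal(lfit$log_likelihood, unname(fs$loglik), tolerance = 1e-6)
})

test_that("MLE bias shrinks as the sample grows", {
  truth <- c(0.016073, 1.593409)
  fits <- lapply(c(500, 5000), function(n) {
    spec <- trial_sim_spec(n, list(
      a = parametric_survival("weibull", truth)), seed = 313)
    fit_parametric(simulate_trial(spec), "weibull")$params
  })
  err <- vapply(fits, function(p) sum(abs(p - truth) / truth), numeric(1))
  expect_lt(err[2], err[1])
})

test_that("information criteria select the generating family", {
  aic_vals <- c(100.0, 98.5, 99.1)
  fits <- lapply(aic_vals, function(a) {
    structure(list(family = "weibull", params = c(1, 1),
                   log_likelihood = (4 - a) / 2, aic = a, bic = a + 1,
                   n_used = 10, n_events = 10),
              class = "surv_fit_result")
  })
  expect_equal(select_best(fits)$aic, 98.5)
  expect_equal(select_best(fits[1])$aic, 100.0)
  mismatch <- fits
  mismatch[[2]]$n_used <- 11
  expect_error(select_best(mismatch), "same data")

  spec <- trial_sim_spec(3000, list(
    a = parametric_survival("loglogistic", c(0.003, 2.3))), seed = 5)
  sim <- simulate_trial(spec)
  fit_ll <- fit_parametric(sim, "loglogistic")
  fit_ex <- fit_parametric(sim, "exponential")
  expect_lt(fit_ll$aic, fit_ex$aic)
  best <- select_best(list(fit_ex, fit_ll))
  expect_identical(best$family, "loglogistic")
  expect_identical(attr(best, "ranking")$family[1], "loglogistic")
})

test_that("family selection succeeds in most censored replicates", {
  hits <- 0
  n_rep <- 40
  for (r in 1:n_rep) {
    spec <- trial_sim_spec(1000, list(
      a = parametric_survival("weibull", c(0.016073, 1.593409))),
      max_followup_months = 19, seed = 7000 + r)   # ~20% censored
    sim <- simulate_trial(spec)
    fits <- lapply(c("weibull", "exponential", "lognormal"),
                   function(f) fit_parametric(sim, f))
    if (select_best(fits)$family == "weibull") hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.8)
})

test_that("pooling concatenates and preserves counts", {
  a <- data.frame(time = c(1, 2), event = c(1, 0), arm = "a")
  b <- data.frame(time = c(3), event = c(1), arm = "b")
  p <- pool_ipd(a, b, "pooled")
  expect_equal(nrow(p), 3)
  expect_identical(unique(p$arm), "pooled")
  expect_error(pool_ipd(a, a[0, ]), "empty")

  # the pooled KM lies between the arm curves
  s1 <- trial_sim_spec(400, list(good = parametric_survival("exponential",
                                                            log(2) / 18)),
                       seed = 31)
  s2 <- trial_sim_spec(400, list(bad = parametric_survival("exponential",
                                                           log(2) / 6)),
                       seed = 32)
  ia <- simulate_trial(s1); ib <- simulate_trial(s2)
  pool <- pool_ipd(ia, ib)
  tt <- c(3, 6, 12, 18)
  s_of <- function(ipd) {
    km <- km_estimator(ipd, risk_times = c(0, tt))
    vapply(tt, function(x) {
      km$coords$surv[max(which(km$coords$time <= x))]
    }, numeric(1))
  }
  sa <- s_of(ia); sb <- s_of(ib); sp <- s_of(pool)
  expect_true(all(sp <= pmax(sa, sb) + 0.03))
  expect_true(all(sp >= pmin(sa, sb) - 0.03))
})

test_that("the Bucher contrast reproduces the base-case hazard ratio", {
  same <- bucher_indirect_hr(c(0.8, 0.6, 1.05), c(0.8, 0.6, 1.05))
  expect_equal(same$hr, 1.0)
  expect_gte(same$se_log, (log(1.05) - log(0.6)) / (2 * 1.96))

  # trial-level HRs vs the shared chemo comparator give the 1.04 input
  ind <- bucher_indirect_hr(c(0.73, 0.59, 0.91), c(0.70, 0.54, 0.91))
  expect_equal(ind$hr, 0.73 / 0.70, tolerance = 1e-12)
  expect_equal(round(ind$hr, 2), 1.04)
  expect_lte(ind$ci_low, ind$hr)
  expect_gte(ind$ci_high, ind$hr)
  expect_error(bucher_indirect_hr(c(0.73, 0.91, 0.59), c(0.7, 0.54, 0.91)),
               "inverted")
})

test_that("pseudo-IPD round-trips through its CSV writer", {
  ipd <- data.frame(time = c(1.5, 2), event = c(1L, 0L), arm = "x")
  path <- withr::local_tempfile(fileext = ".csv")
  write_ipd(ipd, path)
  got <- read.csv(path)
  expect_equal(got$time_months, ipd$time)
  expect_equal(got$event, ipd$event)
})
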