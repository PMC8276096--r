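#' Quantile function of a survival curve
#'
#' Time at which survival equals `u` (inverse of [survival_at()]),
#' closed form for every supported family; hazard-ratio-adjusted curves
#' invert through the base curve.
#'
#' @inheritParams survival_at
#' @param u Survival probability in `(0, 1]`, vectorised.
#' @export
quantile_survival <- function(model, u) {
  stopifnot(all(u > 0), all(u <= 1))
  UseMethod("quantile_survival")
}

#' @export
quantile_survival.parametric_survival <- function(model, u) {
  p <- model$params
  switch(model$family,
         weibull      = (-log(u) / p[1])^(1 / p[2]),
         loglogistic  = ((1 - u) / (u * p[1]))^(1 / p[2]),
         exponential  = -log(u) / p[1],
         lognormal    = stats::qlnorm(u, p[1], p[2], lower.tail = FALSE),
         gompertz     = log(1 - (p[1] / p[2]) * log(u)) / p[1])
}

#' @export
quantile_survival.hr_adjusted_survival <- function(model, u) {
  quantile_survival(model$base, u^(1 / model$hr))
}

#' Specification of a synthetic two-arm trial
#'
#' Ground-truth generator for validating reconstruction and fitting:
#' event times are drawn from each arm's parametric curve by inverse
#' transform, entry is uniform over an accrual window, follow-up ends at
#' an administrative cutoff measured from study start, and random
#' dropout is exponential.
#'
#' @param n_per_arm Patients per arm.
#' @param arms Named list of survival curves ([parametric_survival()] or
#'   [adjust_by_hr()]); names become arm labels.
#' @param accrual_months Uniform accrual window (0 = simultaneous entry).
#' @param max_followup_months Administrative cutoff from study start
#'   (`Inf` = none); a patient entering at `e` is censored at
#'   `max_followup_months - e` on the patient clock.
#' @param dropout_rate Exponential dropout hazard per month (0 = none).
#' @param seed Integer seed making the trial reproducible.
#' @return An object of class `trial_sim_spec`.
#' @export
trial_sim_spec <- function(n_per_arm, arms, accrual_months = 0,
                           max_followup_months = Inf, dropout_rate = 0,
                           seed = 1L) {
  stopifnot(n_per_arm >= 1, length(arms) >= 1, !is.null(names(arms)),
            accrual_months >= 0, max_followup_months > 0, dropout_rate >= 0)
  structure(list(n_per_arm = as.integer(n_per_arm), arms = arms,
                 accrual_months = accrual_months,
                 max_followup_months = max_followup_months,
                 dropout_rate = dropout_rate, seed = as.integer(seed)),
            class = "trial_sim_spec")
}

#' Simulate a trial from a specification
#'
#' @param spec A [trial_sim_spec()].
#' @return A `pseudo_ipd` data frame (`time`, `event`, `arm`).
#' @export
simulate_trial <- function(spec) {
  stopifnot(inherits(spec, "trial_sim_spec"))
  out <- withr_seed(spec$seed, {
    res <- lapply(names(spec$arms), function(lbl) {
      n <- spec$n_per_arm
      ev_t <- quantile_survival(spec$arms[[lbl]], stats::runif(n))
      entry <- if (spec$accrual_months > 0) {
        stats::runif(n, 0, spec$accrual_months)
      } else rep(0, n)
      admin <- spec$max_followup_months - entry
      drop_t <- if (spec$dropout_rate > 0) {
        stats::rexp(n, spec$dropout_rate)
      } else rep(Inf, n)
      obs <- pmin(ev_t, drop_t, admin)
      data.frame(time = pmax(obs, 1e-9),
                 event = as.integer(ev_t <= pmin(drop_t, admin)),
                 arm = lbl)
    })
    do.call(rbind, res)
  })
  out <- out[order(out$arm, out$time, -out$event), ]
  rownames(out) <- NULL
  class(out) <- c("pseudo_ipd", "data.frame")
  out
}

# evaluate expr under a local RNG seed without disturbing the global stream
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Product-limit (Kaplan-Meier) estimate of one arm
#'
#' Computes the KM curve of a pseudo-IPD arm, with events processed
#' before censorings at tied times, and a numbers-at-risk table at the
#' requested times.  The result is a [digitized_km()], making it directly
#' usable as reconstruction input or as the oracle in roundtrip checks.
#'
#' @param ipd A `pseudo_ipd` data frame holding a single arm (or pass
#'   `arm` to select one).
#' @param risk_times Times for the numbers-at-risk table (default: eight
#'   evenly spaced times from 0 to the last observed time).
#' @param arm Optional arm label to subset on.
#' @export
km_estimator <- function(ipd, risk_times = NULL, arm = NULL) {
  d <- as.data.frame(ipd)
  if (!is.null(arm)) d <- d[d$arm == arm, , drop = FALSE]
  if (length(unique(d$arm)) > 1) {
    stop("ipd contains several arms; pass `arm` to select one",
         call. = FALSE)
  }
  stopifnot(nrow(d) >= 1)
  lbl <- as.character(d$arm[1])
  t_max <- max(d$time)
  if (is.null(risk_times)) {
    risk_times <- seq(0, t_max, length.out = 9)[-9]
  }
  ev_times <- sort(unique(d$time[d$event == 1]))
  s <- 1
  surv <- numeric(length(ev_times))
  for (i in seq_along(ev_times)) {
    ti <- ev_times[i]
    n_at_risk <- sum(d$time >= ti)      # ties: events leave after censorings counted in
    d_i <- sum(d$time == ti & d$event == 1)
    s <- s * (1 - d_i / n_at_risk)
    surv[i] <- s
  }
  n_risk <- vapply(risk_times, function(tt) sum(d$time >= tt), numeric(1))
  digitized_km(time = c(0, ev_times), surv = c(1, surv),
               risk_time = risk_times, n_risk = n_risk, arm = lbl,
               total_events = sum(d$event))
}

#' Write a reproducible fixture suite of synthetic trials
#'
#' Generates a bundle of single-arm trials with known ground truth and
#' writes them as plain CSV: the individual-patient data
#' (`<name>_ipd.csv`), the digitized-style KM coordinates
#' (`<name>_curve.csv`), the risk table (`<name>_risk.csv`) and the
#' generating parameters (`truth.csv`).  Scenarios cover a clean
#' exponential arm, the Weibull and log-logistic curves used by the
#' base-case model, a heavily censored arm and a tiny-n edge case.
#'
#' @param dir Output directory (created if missing).
#' @param seed Integer seed; the same seed reproduces identical files.
#' @return Invisibly, a named list of the per-scenario truths.
#' @export
make_fixture_suite <- function(dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scen <- list(
    clean_exponential = list(
      model = parametric_survival("exponential", log(2) / 12),
      n = 500, followup = Inf, accrual = 0),
    weibull_ep = list(
      model = parametric_survival("weibull", c(0.016073, 1.593409)),
      n = 2000, followup = 36, accrual = 12),
    loglogistic_aep = list(
      model = parametric_survival("loglogistic", c(0.003072, 2.297440)),
      n = 2000, followup = 36, accrual = 12),
    heavy_censoring = list(
      model = parametric_survival("weibull", c(0.016073, 1.593409)),
      n = 1000, followup = 12, accrual = 6),
    tiny_n = list(
      model = parametric_survival("weibull", c(0.016073, 1.593409)),
      n = 5, followup = 24, accrual = 0)
  )
  truths <- list()
  for (nm in names(scen)) {
    sc <- scen[[nm]]
    spec <- trial_sim_spec(sc$n, stats::setNames(list(sc$model), nm),
                           accrual_months = sc$accrual,
                           max_followup_months = sc$followup,
                           seed = seed + which(names(scen) == nm))
    ipd <- simulate_trial(spec)
    km <- km_estimator(ipd)
    write_ipd(ipd, file.path(dir, paste0(nm, "_ipd.csv")))
    utils::write.csv(data.frame(time_months = km$coords$time,
                                survival = km$coords$surv),
                     file.path(dir, paste0(nm, "_curve.csv")),
                     row.names = FALSE)
    utils::write.csv(data.frame(time_months = km$risk_table$time,
                                n_risk = km$risk_table$n_risk),
                     file.path(dir, paste0(nm, "_risk.csv")),
                     row.names = FALSE)
    truths[[nm]] <- data.frame(scenario = nm, family = sc$model$family,
                               param1 = sc$model$params[1],
                               param2 = if (length(sc$model$params) > 1) {
                                 sc$model$params[2]
                               } else NA_real_,
                               n = sc$n)
  }
  utils::write.csv(do.call(rbind, truths), file.path(dir, "truth.csv"),
                   row.names = FALSE)
  invisible(truths)
}
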