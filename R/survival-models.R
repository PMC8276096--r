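#' Parametric survival curve
#'
#' Constructs a parametric survival function \eqn{S(t)} in one of the
#' families used by the cohort model.  Time is measured in months
#' throughout the package.
#'
#' Parameterisations (all parameters strictly positive):
#' \describe{
#'   \item{weibull}{scale-rate form, \eqn{S(t) = \exp(-\lambda t^{\gamma})};
#'     `params = c(lambda, gamma)`.}
#'   \item{loglogistic}{odds form, \eqn{S(t) = 1 / (1 + \theta t^{\kappa})};
#'     `params = c(theta, kappa)`.}
#'   \item{exponential}{\eqn{S(t) = \exp(-\rho t)}; `params = c(rate)`.}
#'   \item{lognormal}{`params = c(meanlog, sdlog)` on the natural-log time
#'     scale; `meanlog` may be any real.}
#'   \item{gompertz}{\eqn{S(t) = \exp(-(b/a)(e^{at} - 1))};
#'     `params = c(shape, rate)` \eqn{= (a, b)}.}
#' }
#'
#' @param family One of `"weibull"`, `"loglogistic"`, `"exponential"`,
#'   `"lognormal"`, `"gompertz"`.
#' @param params Numeric vector of family parameters, in the order above.
#' @return An object of class `parametric_survival`.
#' @examples
#' os_aep <- parametric_survival("loglogistic", c(theta = 0.003072, kappa = 2.297440))
#' survival_at(os_aep, 12)
#' median_survival(os_aep)
#' @export
parametric_survival <- function(family = c("weibull", "loglogistic",
                                           "exponential", "lognormal",
                                           "gompertz"),
                                params) {
  family <- match.arg(family)
  params <- as.numeric(params)
  k <- n_params(family)
  if (length(params) != k) {
    stop(sprintf("family '%s' takes %d parameter(s), got %d",
                 family, k, length(params)), call. = FALSE)
  }
  if (any(!is.finite(params))) {
    stop("survival parameters must be finite", call. = FALSE)
  }
  positive <- if (family == "lognormal") params[2] else params
  if (any(positive <= 0)) {
    stop(sprintf("family '%s' requires positive parameters", family),
         call. = FALSE)
  }
  structure(list(family = family, params = params, time_unit = "months"),
            class = "parametric_survival")
}

n_params <- function(family) {
  switch(family,
         exponential = 1L,
         weibull = , loglogistic = , lognormal = , gompertz = 2L,
         stop("unknown family: ", family, call. = FALSE))
}

#' @export
print.parametric_survival <- function(x, ...) {
  cat(sprintf("<parametric_survival> %s(%s), time in %s\n",
              x$family, paste(signif(x$params, 6), collapse = ", "),
              x$time_unit))
  invisible(x)
}

#' Hazard-ratio adjusted survival curve
#'
#' Applies proportional hazards to a base curve:
#' \eqn{S_{adj}(t) = S_{base}(t)^{HR}}.  Used to derive the DEP arm's
#' curves from the AEP log-logistic fits via the indirect-comparison
#' hazard ratios.
#'
#' @param base A `parametric_survival` object.
#' @param hr Positive hazard ratio of the adjusted arm versus the base arm.
#' @return An object of class `hr_adjusted_survival` usable wherever a
#'   survival curve is accepted.
#' @export
adjust_by_hr <- function(base, hr) {
  stopifnot(inherits(base, "parametric_survival") ||
              inherits(base, "hr_adjusted_survival"))
  if (!is.numeric(hr) || length(hr) != 1L || !is.finite(hr) || hr <= 0) {
    stop("hr must be a single positive number", call. = FALSE)
  }
  structure(list(base = base, hr = hr), class = "hr_adjusted_survival")
}

#' @export
print.hr_adjusted_survival <- function(x, ...) {
  cat(sprintf("<hr_adjusted_survival> hr = %g on\n  ", x$hr))
  print(x$base)
  invisible(x)
}

#' Evaluate a survival curve
#'
#' @param model A `parametric_survival` or `hr_adjusted_survival` object.
#' @param t Time(s) in months, non-negative.
#' @return \eqn{S(t)}, a probability in `[0, 1]` (vectorised over `t`).
#' @export
survival_at <- function(model, t) {
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  UseMethod("survival_at")
}

#' @export
survival_at.parametric_survival <- function(model, t) {
  p <- model$params
  switch(model$family,
         weibull      = exp(-p[1] * t^p[2]),
         loglogistic  = 1 / (1 + p[1] * t^p[2]),
         exponential  = exp(-p[1] * t),
         lognormal    = stats::plnorm(t, p[1], p[2], lower.tail = FALSE),
         gompertz     = exp(-(p[2] / p[1]) * (exp(p[1] * t) - 1)))
}

#' @export
survival_at.hr_adjusted_survival <- function(model, t) {
  survival_at(model$base, t)^model$hr
}

# log density, used by the maximum-likelihood fitter
surv_log_density <- function(family, params, t) {
  p <- params
  switch(family,
         weibull = log(p[1]) + log(p[2]) + (p[2] - 1) * log(t) - p[1] * t^p[2],
         loglogistic = {
           u <- p[1] * t^p[2]
           log(p[1]) + log(p[2]) + (p[2] - 1) * log(t) - 2 * log1p(u)
         },
         exponential = log(p[1]) - p[1] * t,
         lognormal = stats::dlnorm(t, p[1], p[2], log = TRUE),
         gompertz = log(p[2]) + p[1] * t - (p[2] / p[1]) * (exp(p[1] * t) - 1))
}

surv_log_survival <- function(family, params, t) {
  p <- params
  switch(family,
         weibull = -p[1] * t^p[2],
         loglogistic = -log1p(p[1] * t^p[2]),
         exponential = -p[1] * t,
         lognormal = stats::plnorm(t, p[1], p[2], lower.tail = FALSE,
                                   log.p = TRUE),
         gompertz = -(p[2] / p[1]) * (exp(p[1] * t) - 1))
}

#' Median survival time
#'
#' Solves \eqn{S(t) = 0.5}, by closed form where the family admits one and
#' by bisection otherwise (tolerance `1e-10` on the survival scale).
#'
#' @inheritParams survival_at
#' @return Median time in months.
#' @export
median_survival <- function(model) {
  if (inherits(model, "hr_adjusted_survival")) {
    return(surv_root(model, 0.5))
  }
  p <- model$params
  switch(model$family,
         weibull      = (log(2) / p[1])^(1 / p[2]),
         loglogistic  = (1 / p[1])^(1 / p[2]),
         exponential  = log(2) / p[1],
         lognormal    = exp(p[1]),
         gompertz     = surv_root(model, 0.5))
}

# bisection for S(t) = s_target
surv_root <- function(model, s_target, tol = 1e-10) {
  hi <- 1
  while (survival_at(model, hi) > s_target) {
    hi <- hi * 2
    if (hi > 1e9) stop("median beyond search range", call. = FALSE)
  }
  lo <- 0
  while (hi - lo > 1e-12 && abs(survival_at(model, (lo + hi) / 2) - s_target) > tol) {
    mid <- (lo + hi) / 2
    if (survival_at(model, mid) > s_target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Long-term extrapolation policy
#'
#' Beyond a cutoff (default 24 months, the trials' follow-up) the survival
#' curve either continues parametrically or switches to an external
#' background-hazard table (e.g. registry-based hazards for long-term
#' survivors), applied piecewise-exponentially on top of the parametric
#' value at the cutoff so the composite curve is continuous.
#'
#' @param cutoff Cutoff time in months (default 24).
#' @param mode `"parametric_continuation"` or `"external_hazard_table"`.
#' @param hazard_table Data frame with columns `time_months` and
#'   `monthly_hazard` (strictly increasing times, non-negative hazards);
#'   required for mode `"external_hazard_table"`.  The hazard is
#'   piecewise-constant from each row's time to the next, with the last
#'   value carried forward.
#' @return An object of class `extrapolation_policy`.
#' @export
extrapolation_policy <- function(cutoff = 24,
                                 mode = c("parametric_continuation",
                                          "external_hazard_table"),
                                 hazard_table = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(cutoff), length(cutoff) == 1L, cutoff >= 0)
  if (mode == "external_hazard_table") {
    if (is.null(hazard_table)) {
      stop("mode 'external_hazard_table' requires a hazard_table",
           call. = FALSE)
    }
    hazard_table <- validate_hazard_table(hazard_table)
  }
  structure(list(cutoff = cutoff, mode = mode, hazard_table = hazard_table),
            class = "extrapolation_policy")
}

validate_hazard_table <- function(tab) {
  tab <- as.data.frame(tab)
  if (!all(c("time_months", "monthly_hazard") %in% names(tab))) {
    stop("hazard table needs columns time_months and monthly_hazard",
         call. = FALSE)
  }
  if (nrow(tab) == 0) stop("hazard table is empty", call. = FALSE)
  if (any(diff(tab$time_months) <= 0)) {
    stop("hazard table times must be strictly increasing", call. = FALSE)
  }
  if (any(tab$monthly_hazard < 0)) {
    stop("hazards must be non-negative", call. = FALSE)
  }
  tab
}

#' Read a background-hazard table from CSV
#'
#' Expects a header `time_months,monthly_hazard`.
#'
#' @param path CSV file path.
#' @return Validated hazard-table data frame.
#' @export
read_hazard_table <- function(path) {
  validate_hazard_table(utils::read.csv(path))
}

# cumulative hazard accumulated by the table from `from` to `to`
# (piecewise-constant hazard, last value carried forward)
table_cum_hazard <- function(tab, from, to) {
  breaks <- c(tab$time_months, Inf)
  vapply(to, function(t1) {
    if (t1 <= from) return(0)
    h <- 0
    for (i in seq_len(nrow(tab))) {
      a <- max(from, breaks[i])
      b <- min(t1, breaks[i + 1])
      if (b > a) h <- h + tab$monthly_hazard[i] * (b - a)
    }
    # before the first table row, carry the first hazard backwards
    if (from < breaks[1]) {
      h <- h + tab$monthly_hazard[1] * (min(t1, breaks[1]) - from)
    }
    h
  }, numeric(1))
}

#' Survival under an extrapolation policy
#'
#' For `t <= cutoff` returns the parametric value.  Beyond the cutoff,
#' mode `"parametric_continuation"` keeps the parametric curve while
#' `"external_hazard_table"` returns
#' \eqn{S(cutoff) \exp(-\int_{cutoff}^{t} h(u) du)} with \eqn{h} from the
#' table.  Continuous at the cutoff in both modes.
#'
#' @inheritParams survival_at
#' @param policy An [extrapolation_policy()].
#' @export
extrapolated_survival <- function(model, policy, t) {
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  stopifnot(inherits(policy, "extrapolation_policy"))
  s <- survival_at(model, t)
  if (policy$mode == "parametric_continuation") return(s)
  beyond <- t > policy$cutoff
  if (any(beyond)) {
    s_cut <- survival_at(model, policy$cutoff)
    ch <- table_cum_hazard(policy$hazard_table, policy$cutoff, t[beyond])
    s[beyond] <- s_cut * exp(-ch)
  }
  s
}

#' Conditional probability of an event within an interval
#'
#' Probability of the event in `(t0, t1]` given survival to `t0`:
#' \eqn{1 - S(t_1)/S(t_0)}, with \eqn{S} evaluated through the
#' extrapolation policy.  Returns 1 when \eqn{S(t_0) = 0} (absorbing by
#' convention).
#'
#' @inheritParams extrapolated_survival
#' @param t0,t1 Interval bounds in months, `0 <= t0 < t1` (equal bounds
#'   give probability 0).
#' @export
interval_event_prob <- function(model, t0, t1,
                                policy = extrapolation_policy()) {
  if (any(t0 < 0)) stop("t0 must be non-negative", call. = FALSE)
  if (any(t1 < t0)) stop("t1 must be >= t0", call. = FALSE)
  s0 <- extrapolated_survival(model, policy, t0)
  s1 <- extrapolated_survival(model, policy, t1)
  out <- ifelse(s0 <= 0, 1, 1 - s1 / s0)
  pmin(pmax(out, 0), 1)
}
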