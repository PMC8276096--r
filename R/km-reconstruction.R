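#' Digitized Kaplan-Meier curve with its numbers-at-risk table
#'
#' Container for the coordinates read off a published KM plot plus the
#' numbers-at-risk row printed beneath it, the inputs to pseudo
#' individual-patient-data reconstruction.
#'
#' @param time,surv Digitized coordinates: months and survival
#'   probability.  The first coordinate must be `(0, 1)` and `surv` must
#'   be non-increasing in `[0, 1]`.
#' @param risk_time,n_risk Numbers-at-risk table: months and the
#'   non-increasing, non-negative patient counts.  `risk_time[1]` must
#'   be 0.
#' @param arm Arm label carried into the reconstructed data.
#' @param total_events Optional total event count reported by the trial;
#'   when supplied, reconstruction rebalances the final interval to match
#'   it.
#' @return An object of class `digitized_km`.
#' @export
digitized_km <- function(time, surv, risk_time, n_risk, arm = "arm",
                         total_events = NULL) {
  stopifnot(length(time) == length(surv), length(risk_time) == length(n_risk),
            length(time) >= 1, length(risk_time) >= 1)
  if (time[1] != 0 || abs(surv[1] - 1) > 1e-9) {
    stop("first digitized coordinate must be (0, 1)", call. = FALSE)
  }
  if (any(diff(time) < 0)) stop("times must be non-decreasing", call. = FALSE)
  if (any(surv < -1e-9 | surv > 1 + 1e-9)) {
    stop("survival must lie in [0, 1]", call. = FALSE)
  }
  if (any(diff(surv) > 1e-9)) {
    bad <- which(diff(surv) > 1e-9)[1]
    stop(sprintf("survival increases between t=%g and t=%g",
                 time[bad], time[bad + 1]), call. = FALSE)
  }
  if (risk_time[1] != 0) stop("risk table must start at time 0", call. = FALSE)
  if (any(diff(n_risk) > 0)) {
    bad <- which(diff(n_risk) > 0)[1]
    stop(sprintf("number at risk increases between t=%g and t=%g",
                 risk_time[bad], risk_time[bad + 1]), call. = FALSE)
  }
  if (any(n_risk < 0)) stop("numbers at risk must be non-negative",
                            call. = FALSE)
  structure(list(arm = arm,
                 coords = data.frame(time = as.numeric(time),
                                     surv = pmin(pmax(surv, 0), 1)),
                 risk_table = data.frame(time = as.numeric(risk_time),
                                         n_risk = as.integer(round(n_risk))),
                 total_events = total_events),
            class = "digitized_km")
}

#' Read a digitized KM curve and risk table from CSV
#'
#' Curve CSV needs columns `time_months,survival`; risk-table CSV needs
#' `time_months,n_risk`.
#'
#' @param curve_path,risk_path CSV file paths.
#' @inheritParams digitized_km
#' @export
read_digitized_km <- function(curve_path, risk_path, arm = "arm",
                              total_events = NULL) {
  cu <- utils::read.csv(curve_path)
  ri <- utils::read.csv(risk_path)
  digitized_km(cu$time_months, cu$survival, ri$time_months, ri$n_risk,
               arm = arm, total_events = total_events)
}

#' Reconstruct pseudo individual-patient data from a digitized KM curve
#'
#' Interval-solving reconstruction in the style of Guyot and Hoyle:
#' within each risk-table interval the number of censorings is iterated
#' until the reconstructed number at risk at the start of the next
#' interval matches the printed one, censoring times are spread uniformly
#' over the interval, and events are placed at the digitized step times
#' with multiplicities recovered from the product-limit ratios.  When the
#' curve gives no step across an interval the whole decrease in numbers
#' at risk is attributed to censoring.  If `total_events` was supplied, a
#' final rebalancing pass converts trailing events to censorings (or the
#' reverse) until the overall event count matches.
#'
#' @param km A [digitized_km()].
#' @return A `pseudo_ipd` data frame with columns `time`, `event`
#'   (1 = event, 0 = censored) and `arm`.
#' @export
reconstruct_ipd <- function(km) {
  stopifnot(inherits(km, "digitized_km"))
  co <- km$coords
  rt <- km$risk_table
  t_click <- co$time
  s_click <- co$surv
  J <- length(t_click)
  I <- nrow(rt)
  # interval i spans [risk_time[i], risk_time[i+1]); the last runs to the
  # end of the digitized curve
  bounds <- c(rt$time, max(t_click) + 1e-9)
  lower <- upper <- integer(I)
  for (i in seq_len(I)) {
    idx <- which(t_click >= bounds[i] & t_click < bounds[i + 1])
    lower[i] <- if (length(idx)) min(idx) else NA_integer_
    upper[i] <- if (length(idx)) max(idx) else NA_integer_
  }

  d <- integer(J)            # events at click j
  cen_times <- numeric(0)
  n_start <- rt$n_risk[1]
  km_last <- 1               # reconstructed KM value at the last event
  n_cur <- n_start

  for (i in seq_len(I)) {
    target_next <- if (i < I) rt$n_risk[i + 1] else NA_integer_
    lo <- lower[i]; up <- upper[i]
    # iterate over the censor count for this interval
    ncen <- if (i < I) {
      s_next <- approx_surv(t_click, s_click, bounds[i + 1])
      guess <- n_cur - target_next -
        round(n_cur * (1 - s_next / max(km_last, 1e-12)))
      max(0L, as.integer(guess))
    } else 0L
    best <- NULL
    for (iter in 1:60) {
      res <- run_interval(i, ncen, n_cur, km_last, lower, upper, t_click,
                          s_click, bounds)
      if (i == I) { best <- res; break }
      err <- res$n_out - target_next
      if (is.null(best) || abs(err) < abs(best$err)) {
        best <- res; best$err <- err
      }
      if (err == 0) break
      ncen <- ncen + err
      if (ncen < 0) { ncen <- 0L
        res0 <- run_interval(i, 0L, n_cur, km_last, lower, upper, t_click,
                             s_click, bounds)
        res0$err <- res0$n_out - target_next
        if (abs(res0$err) < abs(best$err)) best <- res0
        break
      }
    }
    res <- best
    d <- d + res$d
    cen_times <- c(cen_times, res$cen)
    n_cur <- if (i < I) rt$n_risk[i + 1] else res$n_out
    km_last <- res$km_out
  }

  # anyone still at risk after the last digitized time is censored there
  if (n_cur > 0) {
    cen_times <- c(cen_times, rep(max(t_click), n_cur))
  }

  times <- c(rep(t_click, d), cen_times)
  event <- c(rep(1L, sum(d)), rep(0L, length(cen_times)))
  if (!is.null(km$total_events)) {
    excess <- sum(event) - km$total_events
    if (excess > 0) {
      # convert the latest events to censorings
      ev_idx <- which(event == 1L)
      drop <- ev_idx[order(times[ev_idx], decreasing = TRUE)][seq_len(excess)]
      event[drop] <- 0L
    } else if (excess < 0) {
      cn_idx <- which(event == 0L)
      take <- cn_idx[order(times[cn_idx], decreasing = TRUE)]
      take <- take[seq_len(min(-excess, length(take)))]
      event[take] <- 1L
    }
  }
  out <- data.frame(time = pmax(times, 1e-9), event = event, arm = km$arm)
  out <- out[order(out$time, -out$event), ]
  rownames(out) <- NULL
  class(out) <- c("pseudo_ipd", "data.frame")
  out
}

# linear interpolation of a right-continuous step function at time t
approx_surv <- function(t_click, s_click, t) {
  idx <- which(t_click <= t)
  if (length(idx) == 0) return(1)
  s_click[max(idx)]
}

# process one risk-table interval with a fixed censor count
run_interval <- function(i, ncen, n_in, km_in, lower, upper, t_click,
                         s_click, bounds) {
  lo <- lower[i]; up <- upper[i]
  ct <- if (ncen > 0) {
    bounds[i] + (seq_len(ncen) - 0.5) * (bounds[i + 1] - bounds[i]) / ncen
  } else numeric(0)
  dj <- integer(length(t_click))
  n <- n_in
  kml <- km_in
  consumed <- 0
  if (!is.na(lo)) {
    for (j in lo:up) {
      before <- sum(ct < t_click[j]) - consumed
      n <- n - before
      consumed <- consumed + before
      ev <- if (kml > 0 && n > 0) round(n * (1 - s_click[j] / kml)) else 0
      ev <- max(0L, min(as.integer(ev), n))
      if (ev > 0) {
        kml <- kml * (1 - ev / n)
        n <- n - ev
      }
      dj[j] <- ev
    }
  }
  n <- n - (length(ct) - consumed)
  list(d = dj, cen = ct, n_out = max(n, 0L), km_out = kml)
}

#' Pool two pseudo-IPD sets under a new label
#'
#' @param a,b `pseudo_ipd` data frames (non-empty).
#' @param pooled_label Arm label of the pooled data.
#' @export
pool_ipd <- function(a, b, pooled_label = "pooled") {
  if (nrow(a) == 0 || nrow(b) == 0) {
    stop("cannot pool an empty pseudo-IPD set", call. = FALSE)
  }
  out <- rbind(as.data.frame(a)[c("time", "event")],
               as.data.frame(b)[c("time", "event")])
  out$arm <- pooled_label
  out <- out[order(out$time, -out$event), ]
  rownames(out) <- NULL
  class(out) <- c("pseudo_ipd", "data.frame")
  out
}

#' Write pseudo-IPD to CSV
#'
#' Columns `time_months,event,arm`.
#' @param ipd A `pseudo_ipd` data frame.
#' @param path Output CSV path.
#' @export
write_ipd <- function(ipd, path) {
  utils::write.csv(data.frame(time_months = ipd$time, event = ipd$event,
                              arm = ipd$arm),
                   path, row.names = FALSE)
  invisible(path)
}

#' Censoring-aware maximum-likelihood parametric fit
#'
#' Maximises \eqn{\sum_{events} \log f(t) + \sum_{censored} \log S(t)}
#' over the family's parameters (optimised on the log scale, multi-start
#' from moment-style seeds).
#'
#' @param ipd Data frame with columns `time` and `event`.
#' @param family Survival family name (see [parametric_survival()]).
#' @return An object of class `surv_fit_result`: `family`, `params`,
#'   `model` (a [parametric_survival()]), `log_likelihood`, `aic`, `bic`,
#'   `n_used`, `n_events`.
#' @export
fit_parametric <- function(ipd, family) {
  t <- ipd$time
  ev <- ipd$event
  stopifnot(all(t > 0), all(ev %in% c(0, 1)))
  n_ev <- sum(ev)
  if (n_ev == 0) stop("no events in the data: cannot fit", call. = FALSE)
  if (n_ev < 2) stop("at least 2 events are required", call. = FALSE)
  k <- n_params(family)

  negll <- function(theta) {
    params <- decode_params(family, theta)
    ll <- sum(surv_log_density(family, params, t[ev == 1])) +
      sum(surv_log_survival(family, params, t[ev == 0]))
    if (!is.finite(ll)) return(1e12)
    -ll
  }

  if (family == "exponential") {
    rate <- n_ev / sum(t)      # closed-form MLE
    params <- rate
    ll <- -negll(log(rate))
  } else {
    starts <- fit_starts(family, t, ev)
    best <- NULL
    for (s in starts) {
      fit <- tryCatch(
        stats::optim(encode_params(family, s), negll, method = "BFGS",
                     control = list(maxit = 500, reltol = 1e-12)),
        error = function(e) NULL)
      if (!is.null(fit) &&
          (is.null(best) || fit$value < best$value - 1e-10)) best <- fit
    }
    if (is.null(best) || best$value >= 1e12) {
      stop("parametric fit failed to converge for family ", family,
           call. = FALSE)
    }
    params <- decode_params(family, best$par)
    ll <- -best$value
  }
  n <- length(t)
  structure(list(family = family,
                 params = params,
                 model = parametric_survival(family, params),
                 log_likelihood = ll,
                 aic = 2 * k - 2 * ll,
                 bic = k * log(n) - 2 * ll,
                 n_used = n,
                 n_events = n_ev),
            class = "surv_fit_result")
}

#' @export
print.surv_fit_result <- function(x, ...) {
  cat(sprintf("<surv_fit_result> %s(%s)  logLik %.3f  AIC %.2f  BIC %.2f  (n=%d, events=%d)\n",
              x$family, paste(signif(x$params, 6), collapse = ", "),
              x$log_likelihood, x$aic, x$bic, x$n_used, x$n_events))
  invisible(x)
}

encode_params <- function(family, p) {
  if (family == "lognormal") c(p[1], log(p[2])) else log(p)
}

decode_params <- function(family, theta) {
  if (family == "lognormal") c(theta[1], exp(theta[2])) else exp(theta)
}

fit_starts <- function(family, t, ev) {
  rate <- max(sum(ev) / sum(t), 1e-8)
  med <- stats::median(t[ev == 1])
  shapes <- c(0.7, 1, 1.5, 2.5)
  switch(family,
         weibull = lapply(shapes, function(g) c(log(2) / med^g, g)),
         loglogistic = lapply(shapes, function(k) c(1 / med^k, k)),
         lognormal = {
           lt <- log(t[ev == 1])
           list(c(mean(lt), max(stats::sd(lt), 0.1)),
                c(log(med), 0.5), c(log(med), 1.5))
         },
         gompertz = lapply(c(0.01, 0.05, 0.15), function(a) c(a, rate)),
         list(rate))
}

#' Select the best parametric fit by information criteria
#'
#' Minimum AIC wins; ties are broken by minimum BIC, then fewer
#' parameters, then alphabetical family order.  All candidates must have
#' been fitted to the same data.
#'
#' @param fits List of [fit_parametric()] results.
#' @return The winning `surv_fit_result`, with the full ranking attached
#'   as attribute `"ranking"` (a data frame).
#' @export
select_best <- function(fits) {
  stopifnot(length(fits) >= 1)
  n_used <- vapply(fits, `[[`, numeric(1), "n_used")
  n_ev <- vapply(fits, `[[`, numeric(1), "n_events")
  if (length(unique(n_used)) != 1 || length(unique(n_ev)) != 1) {
    stop("candidate fits were not computed on the same data", call. = FALSE)
  }
  tab <- data.frame(
    family = vapply(fits, `[[`, character(1), "family"),
    k = vapply(fits, function(f) length(f$params), numeric(1)),
    aic = vapply(fits, `[[`, numeric(1), "aic"),
    bic = vapply(fits, `[[`, numeric(1), "bic")
  )
  ord <- order(tab$aic, tab$bic, tab$k, tab$family)
  best <- fits[[ord[1]]]
  attr(best, "ranking") <- tab[ord, , drop = FALSE]
  best
}

#' Bucher indirect hazard ratio
#'
#' Anchored indirect comparison of B versus A through a common comparator
#' C: \eqn{\log HR_{B/A} = \log HR_{B/C} - \log HR_{A/C}}, with standard
#' errors recovered from the 95\% confidence intervals
#' (\eqn{se = (\log hi - \log lo) / (2 \times 1.96)}) and added in
#' quadrature.
#'
#' @param hr_b_vs_c,hr_a_vs_c Numeric vectors `c(hr, ci_low, ci_high)`.
#' @return A list with `hr`, `ci_low`, `ci_high`, `se_log`.
#' @export
bucher_indirect_hr <- function(hr_b_vs_c, hr_a_vs_c) {
  chk <- function(x) {
    stopifnot(length(x) == 3, all(x > 0))
    if (x[2] > x[3]) stop("confidence bounds are inverted", call. = FALSE)
    x
  }
  b <- chk(as.numeric(hr_b_vs_c))
  a <- chk(as.numeric(hr_a_vs_c))
  z <- 1.96
  se_b <- (log(b[3]) - log(b[2])) / (2 * z)
  se_a <- (log(a[3]) - log(a[2])) / (2 * z)
  lhr <- log(b[1]) - log(a[1])
  se <- sqrt(se_b^2 + se_a^2)
  list(hr = exp(lhr), ci_low = exp(lhr - z * se), ci_high = exp(lhr + z * se),
       se_log = se)
}
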