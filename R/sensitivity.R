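#' One sensitivity parameter
#'
#' Binds a model quantity (addressed by its dotted configuration path) to
#' a deterministic range and a sampling distribution for probabilistic
#' analysis.  The `[low, high]` range is interpreted as a 95% interval,
#' so the implied standard error is `(high - low) / (2 * 1.96)`.
#'
#' @param name Human-readable parameter name.
#' @param path Dotted configuration path (see [get_config_value()]).
#' @param baseline Baseline value; defaults to the value found in
#'   `config` when specs are built via [param_specs_from_config()].
#' @param low,high Range bounds, `low <= baseline <= high`.
#' @param distribution `"gamma"`, `"beta"`, `"lognormal"` or `"fixed"`.
#' @return An object of class `param_spec`.
#' @export
param_spec <- function(name, path, baseline, low, high,
                       distribution = c("gamma", "beta", "lognormal",
                                        "fixed")) {
  distribution <- match.arg(distribution)
  stopifnot(low <= baseline, baseline <= high)
  if (distribution == "beta" && (low < 0 || high > 1)) {
    stop("beta distribution requires values in [0, 1]", call. = FALSE)
  }
  if (distribution == "lognormal" && low <= 0) {
    stop("lognormal distribution requires positive values", call. = FALSE)
  }
  structure(list(name = name, path = path, baseline = baseline,
                 low = low, high = high, distribution = distribution),
            class = "param_spec")
}

#' Build the parameter specifications listed in a configuration
#'
#' Reads `config$sensitivity` and resolves each baseline from the live
#' configuration value at that path.
#'
#' @param config An `escea_config`.
#' @return List of [param_spec()]s.
#' @export
param_specs_from_config <- function(config) {
  lapply(config$sensitivity, function(r) {
    param_spec(r$name, r$path, get_config_value(config, r$path),
               r$low, r$high, r$distribution)
  })
}

#' Sample a parameter for probabilistic analysis
#'
#' Gamma and beta are moment-matched to the baseline (mean) and the
#' standard error implied by the 95% range; the lognormal keeps the
#' baseline as its median with `sdlog` from the range on the log scale;
#' `"fixed"` always returns the baseline.
#'
#' @param spec A [param_spec()].
#' @param n Number of draws.
#' @return Numeric vector of `n` draws (uses the current RNG stream).
#' @export
sample_param <- function(spec, n = 1) {
  mu <- spec$baseline
  se <- (spec$high - spec$low) / (2 * 1.96)
  switch(spec$distribution,
         fixed = rep(mu, n),
         gamma = {
           if (se == 0 || mu == 0) return(rep(mu, n))
           shape <- mu^2 / se^2
           rate <- mu / se^2
           stats::rgamma(n, shape = shape, rate = rate)
         },
         beta = {
           if (se == 0) return(rep(mu, n))
           if (se^2 >= mu * (1 - mu)) {
             stop(sprintf(
               "beta moment-matching infeasible for '%s': variance %.4g >= mu(1-mu) %.4g",
               spec$name, se^2, mu * (1 - mu)), call. = FALSE)
           }
           nu <- mu * (1 - mu) / se^2 - 1
           stats::rbeta(n, shape1 = mu * nu, shape2 = (1 - mu) * nu)
         },
         lognormal = {
           sdlog <- (log(spec$high) - log(spec$low)) / (2 * 1.96)
           stats::rlnorm(n, meanlog = log(mu), sdlog = sdlog)
         })
}

# ICER of intervention vs comparator under a modified config; both
# strategies fully re-evaluated
comparison_icer <- function(config, comparison) {
  a <- evaluate_strategy(config, comparison[1])
  b <- evaluate_strategy(config, comparison[2])
  icer(c(a$cost, a$qaly), c(b$cost, b$qaly))
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Re-runs the comparison with each parameter at its low and high bound,
#' all others at baseline, and reports the resulting ICERs sorted by
#' spread.  Dominance at a bound is encoded as `icer = NA` with the
#' status recorded, so such rows carry a qualitative rather than numeric
#' spread.
#'
#' @param config An `escea_config`.
#' @param comparison `c(intervention, comparator)` strategy names.
#' @param params List of [param_spec()]s (default: the config's table).
#' @return Data frame `parameter, low_value, high_value, icer_low,
#'   icer_high, status_low, status_high, spread`, sorted by decreasing
#'   spread.
#' @export
one_way_dsa <- function(config, comparison = c("AEP", "EP"),
                        params = param_specs_from_config(config)) {
  rows <- lapply(params, function(sp) {
    at <- function(v) {
      comparison_icer(set_config_value(config, sp$path, v), comparison)
    }
    lo <- at(sp$low)
    hi <- at(sp$high)
    data.frame(parameter = sp$name,
               low_value = sp$low, high_value = sp$high,
               icer_low = lo$icer, icer_high = hi$icer,
               status_low = lo$status, status_high = hi$status,
               spread = abs(hi$icer - lo$icer))
  })
  out <- do.call(rbind, rows)
  out[order(-out$spread), , drop = FALSE]
}

#' Price-reduction threshold for cost-effectiveness
#'
#' Bisects a multiplier `m` in `[0, 1]` applied to a drug's price
#' (`price * (1 - m)`) until the comparison's ICER equals the
#' willingness-to-pay threshold.
#'
#' @param config An `escea_config`.
#' @param drug Name of a drug in `config$prices`.
#' @param comparison `c(intervention, comparator)` strategy names.
#' @param wtp Willingness-to-pay ($/QALY); default from the config.
#' @param tolerance Convergence tolerance on `|ICER - wtp|` in $/QALY.
#' @return A list with `multiplier` (the reduction fraction `m`), `icer`
#'   at that multiplier and `attainable` (`FALSE` when even a free drug
#'   leaves the ICER above `wtp`, in which case `multiplier` is `NA`).
#' @export
price_threshold <- function(config, drug, comparison = c("AEP", "EP"),
                            wtp = config$settings$wtp_per_qaly,
                            tolerance = 500) {
  path <- paste0("prices.", drug)
  price0 <- get_config_value(config, path)
  icer_at <- function(m) {
    comparison_icer(set_config_value(config, path, price0 * (1 - m)),
                    comparison)
  }
  base <- icer_at(0)
  if (base$status != "icer" || base$icer <= wtp) {
    return(list(multiplier = 0, icer = base$icer, attainable = TRUE))
  }
  full <- icer_at(1)
  if (full$status == "icer" && full$icer > wtp) {
    return(list(multiplier = NA_real_, icer = full$icer, attainable = FALSE))
  }
  lo <- 0; hi <- 1
  res <- full
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    res <- icer_at(mid)
    val <- if (res$status == "icer") res$icer else -Inf
    if (is.finite(val) && abs(val - wtp) < tolerance) {
      return(list(multiplier = mid, icer = val, attainable = TRUE))
    }
    if (val > wtp) lo <- mid else hi <- mid
  }
  list(multiplier = (lo + hi) / 2,
       icer = if (res$status == "icer") res$icer else NA_real_,
       attainable = TRUE)
}

#' Probabilistic sensitivity analysis
#'
#' Draws all non-fixed parameters jointly (independent sampling), rebuilds
#' the three strategies per draw and records discounted cost and QALYs.
#' Deterministic for a fixed seed.  Traces of strategies whose survival
#' curves carry no sampled parameter (EP and AEP) are reused across
#' draws; the DEP trace is rebuilt whenever a hazard ratio is sampled.
#'
#' @param config An `escea_config`.
#' @param n_draws Number of Monte Carlo draws.
#' @param seed Integer seed.
#' @param params List of [param_spec()]s (default: the config's table).
#' @return An object of class `psa_result`: `draws` (data frame
#'   `draw,strategy,cost,qaly`), `samples` (draws by parameter), `seed`,
#'   `n`.
#' @export
run_psa <- function(config, n_draws = config$psa$n_draws,
                    seed = config$psa$seed,
                    params = param_specs_from_config(config)) {
  stopifnot(n_draws >= 1)
  samples <- withr_seed(seed, {
    out <- lapply(params, function(sp) {
      tryCatch(sample_param(sp, n_draws),
               error = function(e) {
                 stop("sampling '", sp$name, "': ", conditionMessage(e),
                      call. = FALSE)
               })
    })
    names(out) <- vapply(params, `[[`, character(1), "path")
    out
  })
  paths <- names(samples)
  strategies <- c("EP", "AEP", "DEP")

  # curves with no sampled parameter: trace computed once
  base_curves <- build_survival(config)
  settings0 <- config_settings(config)
  fixed_traces <- list(
    EP = build_trace(base_curves$EP$pfs, base_curves$EP$os, settings0,
                     base_curves$EP$pfs_policy, base_curves$EP$os_policy),
    AEP = build_trace(base_curves$AEP$pfs, base_curves$AEP$os, settings0,
                      base_curves$AEP$pfs_policy, base_curves$AEP$os_policy)
  )

  res <- vector("list", n_draws)
  for (i in seq_len(n_draws)) {
    cfg_i <- config
    for (p in paths) cfg_i <- set_config_value(cfg_i, p, samples[[p]][i])
    draw <- lapply(strategies, function(nm) {
      # the sampled survival parameters (the HRs) only enter the DEP curves
      trace <- fixed_traces[[nm]]
      ev <- evaluate_strategy(cfg_i, nm, trace = trace, detail = FALSE)
      c(cost = ev$cost, qaly = ev$qaly)
    })
    res[[i]] <- draw
  }
  draws <- data.frame(
    draw = rep(seq_len(n_draws), each = length(strategies)),
    strategy = rep(strategies, times = n_draws),
    cost = unlist(lapply(res, function(d) vapply(d, `[`, numeric(1), "cost"))),
    qaly = unlist(lapply(res, function(d) vapply(d, `[`, numeric(1), "qaly")))
  )
  structure(list(draws = draws, samples = samples, seed = seed, n = n_draws),
            class = "psa_result")
}

#' Probability of cost-effectiveness in a pairwise comparison
#'
#' Fraction of PSA draws in which the intervention's net monetary benefit
#' exceeds the comparator's at the given willingness-to-pay.
#'
#' @param psa A [run_psa()] result.
#' @param intervention,comparator Strategy names.
#' @param wtp Willingness-to-pay ($/QALY).
#' @export
psa_prob_cost_effective <- function(psa, intervention, comparator, wtp) {
  d <- psa$draws
  a <- d[d$strategy == intervention, ]
  b <- d[d$strategy == comparator, ]
  a <- a[order(a$draw), ]; b <- b[order(b$draw), ]
  nmb_a <- net_monetary_benefit(a$cost, a$qaly, wtp)
  nmb_b <- net_monetary_benefit(b$cost, b$qaly, wtp)
  mean(nmb_a > nmb_b)
}

#' Cost-effectiveness acceptability curves
#'
#' At each willingness-to-pay on the grid, the probability that each
#' strategy has the maximum net monetary benefit among all strategies in
#' the PSA (ties split equally).
#'
#' @param psa A [run_psa()] result.
#' @param wtp_grid Willingness-to-pay grid (default $0 to $300,000 in
#'   $5,000 steps).
#' @return Data frame `wtp, strategy, probability`; probabilities sum to
#'   1 at every grid point.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 3e5, by = 5e3)) {
  stopifnot(length(wtp_grid) >= 1)
  d <- psa$draws
  strategies <- unique(d$strategy)
  cost <- matrix(d$cost[order(d$draw, match(d$strategy, strategies))],
                 ncol = length(strategies), byrow = TRUE)
  qaly <- matrix(d$qaly[order(d$draw, match(d$strategy, strategies))],
                 ncol = length(strategies), byrow = TRUE)
  out <- lapply(wtp_grid, function(w) {
    nmb <- w * qaly - cost
    best <- nmb == apply(nmb, 1, max)
    share <- best / rowSums(best)          # ties split equally
    data.frame(wtp = w, strategy = strategies, probability = colMeans(share))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Scenario analysis: immune-checkpoint inhibitor until progression
#'
#' Rebuilds the chemo-immunotherapy strategies with the ICI given until
#' disease progression (drug and administration costs accrue with
#' progression-free occupancy over the whole horizon) and re-runs the
#' base-case comparison.  EP carries no ICI and is unchanged; QALYs are
#' unchanged because the adverse-event disutility window follows the
#' planned median duration.
#'
#' @param config An `escea_config`.
#' @return A [run_base_case()]-shaped result under the scenario.
#' @export
scenario_until_progression <- function(config) {
  cfg <- set_config_value(config, "treatment.ici_duration_mode",
                          "until_progression")
  run_base_case(cfg)
}
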