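#' Default model configuration
#'
#' The packaged base-case configuration of the three-strategy ES-SCLC
#' model: survival distribution parameters, the indirect-comparison
#' hazard ratios for DEP, per-mg drug prices, adverse-event cost
#' aggregates, administration/follow-up/supportive/death unit costs,
#' utilities and disutilities, subsequent-therapy proportions, patient
#' constants, treatment-schedule assumptions, the sensitivity-analysis
#' parameter table and probabilistic-analysis settings.
#'
#' A verbatim YAML copy ships in `inst/extdata/default_config.yaml`.
#'
#' @return A nested list of class `escea_config`.
#' @export
default_config <- function() {
  cfg <- list(
    settings = list(
      cycle_days = 21,
      horizon_years = 10,
      annual_discount_rate = 0.03,
      wtp_per_qaly = 100000,
      body_surface_area = 1.80,
      creatinine_clearance = 70.00,
      half_cycle_correction = FALSE
    ),
    survival = list(
      aep = list(
        os = list(family = "loglogistic", theta = 0.003072, kappa = 2.297440),
        pfs = list(family = "loglogistic", theta = 0.008895, kappa = 2.852489)
      ),
      dep_hr = list(
        os = list(hr = 1.04, low = 0.83, high = 1.25),
        pfs = list(hr = 1.01, low = 0.81, high = 1.21)
      ),
      ep = list(
        os = list(family = "weibull", lambda = 0.016073, gamma = 1.593409),
        pfs = list(family = "weibull", lambda = 0.042826, gamma = 1.712046)
      )
    ),
    extrapolation = list(
      cutoff_months = 24,
      os_mode = "parametric_continuation",
      pfs_mode = "parametric_continuation",
      hazard_table_csv = NULL
    ),
    prices = list(
      atezolizumab = 7.83,
      durvalumab = 7.60,
      etoposide = 1.51,
      carboplatin = 0.06,
      topotecan = 12.75
    ),
    ae_costs = list(
      aep = 4959.82,
      dep = 4743.05,
      ep = 6100.94,
      topotecan = 14487.33
    ),
    care_costs = list(
      admin_first_hour = 142.55,
      admin_additional_hour = 30.68,
      monthly_physician_visit = 148.33,
      three_monthly_imaging = 122.71,
      monthly_supportive_care = 637.00,
      death_cost = 9433.00
    ),
    utilities = list(pfs = 0.673, ps = 0.473),
    disutilities = list(aep = 0.090, dep = 0.094, ep = 0.112),
    subsequent_therapy = list(aep = 0.517, dep = 0.420, ep = 0.516),
    treatment = list(
      chemo_cycles = 4,
      ici_cycles = list(aep = 7, dep = 7),
      ici_duration_mode = "median_cycles",
      induction_infusion_hours = list(chemo_immuno = 4, chemo_only = 3),
      maintenance_infusion_hours = 1,
      etoposide_mg_per_m2 = 100,
      etoposide_days_per_cycle = 3,
      carboplatin_auc = 5,
      ici_dose_mg = list(atezolizumab = 1200, durvalumab = 1500),
      topotecan_mg_per_m2 = 1.5,
      topotecan_days_per_cycle = 5,
      topotecan_max_cycles = 4,
      topotecan_infusions_per_cycle = 5,
      disutility_policy = "during_first_line"
    ),
    psa = list(n_draws = 10000, seed = 20210629)
  )
  cfg$sensitivity <- default_param_table()
  class(cfg) <- c("escea_config", "list")
  cfg
}

# sensitivity table: one row per varied parameter, with the documented
# ranges (95% CIs for utilities/disutilities/proportions/HRs, +/-25% bands
# as printed for the cost parameters) and distribution families
default_param_table <- function() {
  row <- function(name, path, low, high, dist) {
    list(name = name, path = path, low = low, high = high,
         distribution = dist)
  }
  list(
    row("Atezolizumab price/mg", "prices.atezolizumab", 5.87, 9.78, "gamma"),
    row("Durvalumab price/mg", "prices.durvalumab", 5.70, 9.50, "gamma"),
    row("Etoposide price/mg", "prices.etoposide", 1.13, 1.89, "gamma"),
    row("Carboplatin price/mg", "prices.carboplatin", 0.04, 0.07, "gamma"),
    row("Topotecan price/mg", "prices.topotecan", 9.56, 15.94, "gamma"),
    row("AE cost (1st-line AEP)", "ae_costs.aep", 3719.87, 6199.78, "gamma"),
    row("AE cost (1st-line DEP)", "ae_costs.dep", 3557.29, 5928.81, "gamma"),
    row("AE cost (1st-line EP)", "ae_costs.ep", 4508.96, 7514.93, "gamma"),
    row("AE cost (2nd-line topotecan)", "ae_costs.topotecan",
        10865.50, 18109.16, "gamma"),
    row("Administration IV, first hour", "care_costs.admin_first_hour",
        106.91, 178.19, "gamma"),
    row("Administration IV, additional hour",
        "care_costs.admin_additional_hour", 23.01, 38.35, "gamma"),
    row("Monthly physician visit", "care_costs.monthly_physician_visit",
        111.25, 185.41, "gamma"),
    row("Three-monthly imaging", "care_costs.three_monthly_imaging",
        92.03, 153.39, "gamma"),
    row("Monthly supportive care", "care_costs.monthly_supportive_care",
        477.75, 796.25, "gamma"),
    row("Death associated costs", "care_costs.death_cost",
        7074.75, 11791.25, "gamma"),
    row("Utility PFS", "utilities.pfs", 0.538, 0.808, "beta"),
    row("Utility PS", "utilities.ps", 0.378, 0.568, "beta"),
    row("Disutility AEP", "disutilities.aep", 0.072, 0.108, "beta"),
    row("Disutility DEP", "disutilities.dep", 0.075, 0.113, "beta"),
    row("Disutility EP", "disutilities.ep", 0.090, 0.134, "beta"),
    row("Subsequent therapy AEP", "subsequent_therapy.aep",
        0.414, 0.620, "beta"),
    row("Subsequent therapy DEP", "subsequent_therapy.dep",
        0.336, 0.504, "beta"),
    row("Subsequent therapy EP", "subsequent_therapy.ep",
        0.413, 0.619, "beta"),
    row("Body surface area", "settings.body_surface_area",
        1.35, 2.25, "gamma"),
    row("Creatinine clearance", "settings.creatinine_clearance",
        52.50, 87.50, "gamma"),
    row("OS HR DEP vs AEP", "survival.dep_hr.os.hr", 0.83, 1.25,
        "lognormal"),
    row("PFS HR DEP vs AEP", "survival.dep_hr.pfs.hr", 0.81, 1.21,
        "lognormal")
  )
}

#' Get or set a value inside a configuration by dotted path
#'
#' @param config An `escea_config` (or any nested list).
#' @param path Dotted path, e.g. `"prices.atezolizumab"`.
#' @param value Replacement value (for the setter).
#' @return The value at the path, or the modified config.
#' @export
get_config_value <- function(config, path) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  node <- config
  for (k in keys) {
    if (!is.list(node) || is.null(node[[k]])) {
      stop("no such configuration key: ", path, call. = FALSE)
    }
    node <- node[[k]]
  }
  node
}

#' @rdname get_config_value
#' @export
set_config_value <- function(config, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  set_rec <- function(node, keys) {
    if (is.null(node[[keys[1]]])) {
      stop("no such configuration key: ", path, call. = FALSE)
    }
    if (length(keys) == 1) {
      node[[keys[1]]] <- value
    } else {
      node[[keys[1]]] <- set_rec(node[[keys[1]]], keys[-1])
    }
    node
  }
  out <- set_rec(unclass(config), keys)
  class(out) <- class(config)
  out
}

#' Load and validate a model configuration from YAML
#'
#' Unknown keys are rejected; keys missing from the file are filled from
#' [default_config()].  All value constraints (positivity, probabilities
#' in `[0, 1]`, survival-family parameter counts) are enforced.
#'
#' @param path YAML file path.
#' @return A validated `escea_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  cfg <- merge_config(unclass(default_config()), raw, "")
  class(cfg) <- c("escea_config", "list")
  validate_config(cfg)
}

# fill defaults and reject unknown keys, recursively; list-of-records
# nodes (the sensitivity table) are replaced wholesale
merge_config <- function(default, user, where) {
  if (is.null(user)) return(default)
  if (!is.list(default) || is.null(names(default)) ||
      any(names(default) == "")) {
    return(user)
  }
  unknown <- setdiff(names(user), names(default))
  if (length(unknown) > 0) {
    stop(sprintf("unknown configuration key%s: %s",
                 if (length(unknown) > 1) "s" else "",
                 paste0(sub("^\\.", "", paste0(where, ".", unknown)),
                        collapse = ", ")),
         call. = FALSE)
  }
  for (k in names(user)) {
    # [k] <- list(...) keeps keys whose merged value is NULL
    default[k] <- list(merge_config(default[[k]], user[[k]],
                                    paste0(where, ".", k)))
  }
  default
}

#' Validate a model configuration
#'
#' @param config An `escea_config`.
#' @return The config, invisibly usable, after all checks pass.
#' @export
validate_config <- function(config) {
  chk <- function(cond, msg) if (!cond) stop(msg, call. = FALSE)
  s <- config$settings
  chk(s$cycle_days > 0, "settings.cycle_days must be positive")
  chk(s$horizon_years > 0, "settings.horizon_years must be positive")
  chk(s$annual_discount_rate >= 0,
      "settings.annual_discount_rate must be non-negative")
  chk(s$body_surface_area > 0, "settings.body_surface_area must be positive")
  chk(s$creatinine_clearance > 0,
      "settings.creatinine_clearance must be positive")
  for (u in names(config$utilities)) {
    v <- config$utilities[[u]]
    chk(v >= 0 && v <= 1,
        sprintf("utilities.%s must lie in [0, 1], got %g", u, v))
  }
  for (d in names(config$disutilities)) {
    v <- config$disutilities[[d]]
    chk(v >= 0 && v <= 1,
        sprintf("disutilities.%s must lie in [0, 1], got %g", d, v))
  }
  for (p in names(config$subsequent_therapy)) {
    v <- config$subsequent_therapy[[p]]
    chk(v >= 0 && v <= 1,
        sprintf("subsequent_therapy.%s must lie in [0, 1], got %g", p, v))
  }
  chk(all(unlist(config$prices) >= 0), "prices must be non-negative")
  chk(all(unlist(config$ae_costs) >= 0), "ae_costs must be non-negative")
  chk(all(unlist(config$care_costs) >= 0), "care_costs must be non-negative")
  chk(config$survival$dep_hr$os$hr > 0, "survival.dep_hr.os.hr must be > 0")
  chk(config$survival$dep_hr$pfs$hr > 0, "survival.dep_hr.pfs.hr must be > 0")
  chk(config$extrapolation$os_mode %in%
        c("parametric_continuation", "external_hazard_table"),
      "extrapolation.os_mode must be parametric_continuation or external_hazard_table")
  chk(config$treatment$ici_duration_mode %in%
        c("median_cycles", "until_progression"),
      "treatment.ici_duration_mode must be median_cycles or until_progression")
  # the survival blocks must build
  invisible(build_survival(config))
  config
}

#' Serialise a configuration to YAML
#'
#' @param config An `escea_config`.
#' @param path Output YAML path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_settings <- function(config) {
  s <- config$settings
  model_settings(cycle_days = s$cycle_days,
                 horizon_years = s$horizon_years,
                 annual_discount_rate = s$annual_discount_rate,
                 wtp_per_qaly = s$wtp_per_qaly,
                 body_surface_area = s$body_surface_area,
                 creatinine_clearance = s$creatinine_clearance,
                 half_cycle_correction = s$half_cycle_correction)
}

curve_from_config <- function(node) {
  if (node$family == "loglogistic") {
    parametric_survival("loglogistic", c(node$theta, node$kappa))
  } else if (node$family == "weibull") {
    parametric_survival("weibull", c(node$lambda, node$gamma))
  } else {
    stop("unsupported survival family in config: ", node$family,
         call. = FALSE)
  }
}

#' Build the per-strategy survival curves and policies from a config
#'
#' AEP and EP take their fitted parametric curves directly; DEP applies
#' the indirect-comparison hazard ratios to the AEP curves.  The OS
#' extrapolation policy is shared by all arms (background mortality is
#' arm-independent); PFS always continues parametrically beyond the
#' cutoff.
#'
#' @param config An `escea_config`.
#' @return Named list (`EP`, `AEP`, `DEP`) of lists with `pfs`, `os`,
#'   `pfs_policy`, `os_policy`.
#' @export
build_survival <- function(config) {
  ex <- config$extrapolation
  tab <- if (!is.null(ex$hazard_table_csv)) {
    read_hazard_table(ex$hazard_table_csv)
  } else NULL
  os_policy <- extrapolation_policy(ex$cutoff_months, ex$os_mode, tab)
  pfs_policy <- extrapolation_policy(ex$cutoff_months, ex$pfs_mode)
  aep_os <- curve_from_config(config$survival$aep$os)
  aep_pfs <- curve_from_config(config$survival$aep$pfs)
  list(
    EP = list(pfs = curve_from_config(config$survival$ep$pfs),
              os = curve_from_config(config$survival$ep$os),
              pfs_policy = pfs_policy, os_policy = os_policy),
    AEP = list(pfs = aep_pfs, os = aep_os,
               pfs_policy = pfs_policy, os_policy = os_policy),
    DEP = list(pfs = adjust_by_hr(aep_pfs, config$survival$dep_hr$pfs$hr),
               os = adjust_by_hr(aep_os, config$survival$dep_hr$os$hr),
               pfs_policy = pfs_policy, os_policy = os_policy)
  )
}

#' Build a strategy specification from a config
#'
#' @param config An `escea_config`.
#' @param name `"EP"`, `"AEP"` or `"DEP"`.
#' @return A [strategy_spec()].
#' @export
build_strategy <- function(config, name = c("EP", "AEP", "DEP")) {
  name <- match.arg(name)
  tr <- config$treatment
  pr <- config$prices
  key <- tolower(name)
  chemo <- list(
    regimen_line("etoposide",
                 dose_per_bsa(tr$etoposide_mg_per_m2,
                              tr$etoposide_days_per_cycle),
                 pr$etoposide),
    regimen_line("carboplatin", dose_calvert(tr$carboplatin_auc),
                 pr$carboplatin)
  )
  topo <- regimen_line("topotecan",
                       dose_per_bsa(tr$topotecan_mg_per_m2,
                                    tr$topotecan_days_per_cycle),
                       pr$topotecan)
  if (name == "EP") {
    ici_line <- NULL
    ici_cycles <- 0
    hours <- tr$induction_infusion_hours$chemo_only
  } else {
    ici_drug <- if (name == "AEP") "atezolizumab" else "durvalumab"
    ici_line <- regimen_line(ici_drug, dose_flat(tr$ici_dose_mg[[ici_drug]]),
                             pr[[ici_drug]])
    ici_cycles <- if (tr$ici_duration_mode == "until_progression") {
      Inf
    } else {
      tr$ici_cycles[[key]]
    }
    hours <- tr$induction_infusion_hours$chemo_immuno
  }
  # the disutility window follows the planned (median) first-line duration
  # even in the until-progression scenario
  disutility_cycles <- if (name == "EP") tr$chemo_cycles else
    max(tr$chemo_cycles, tr$ici_cycles[[key]])
  strategy_spec(
    name = name,
    chemo_lines = chemo,
    chemo_cycles = tr$chemo_cycles,
    ici_line = ici_line,
    ici_cycles = ici_cycles,
    induction_infusion_hours = hours,
    maintenance_infusion_hours = tr$maintenance_infusion_hours,
    ae_cost_first_line = config$ae_costs[[key]],
    ae_disutility = config$disutilities[[key]],
    disutility_policy = tr$disutility_policy,
    disutility_cycles = disutility_cycles,
    subsequent_therapy_proportion = config$subsequent_therapy[[key]],
    second_line = topo,
    second_line_cycles = tr$topotecan_max_cycles,
    second_line_infusions = tr$topotecan_infusions_per_cycle,
    ae_cost_second_line = config$ae_costs$topotecan
  )
}

#' Evaluate one strategy: trace, discounted cost, discounted QALYs
#'
#' @param config An `escea_config`.
#' @param name Strategy name.
#' @param curves Optional precomputed [build_survival()] output.
#' @param trace Optional precomputed trace (skips curve evaluation).
#' @param detail Keep the itemised cost ledger? (`FALSE` for tight loops.)
#' @return List with `name`, `cost`, `qaly`, `trace`, `cost_detail`.
#' @export
evaluate_strategy <- function(config, name, curves = NULL, trace = NULL,
                              detail = TRUE) {
  settings <- config_settings(config)
  if (is.null(trace)) {
    if (is.null(curves)) curves <- build_survival(config)
    cv <- curves[[name]]
    trace <- build_trace(cv$pfs, cv$os, settings,
                         pfs_policy = cv$pfs_policy,
                         os_policy = cv$os_policy)
  }
  strat <- build_strategy(config, name)
  costs <- do.call(care_costs, config$care_costs)
  utils_ <- utilities(config$utilities$pfs, config$utilities$ps)
  cost <- accrue_costs(trace, strat, costs, settings, ledger = detail)
  qaly <- accrue_qalys(trace, strat, utils_, settings)
  list(name = name, cost = cost$total, qaly = qaly, trace = trace,
       cost_detail = cost)
}

#' Run the base-case analysis
#'
#' Evaluates every strategy under the configuration and assembles the
#' base-case results block: per-strategy discounted totals plus the three
#' pairwise comparisons (DEP vs AEP, AEP vs EP, DEP vs EP).
#'
#' @param config An `escea_config` (default: packaged base case).
#' @param out_dir Optional directory; when given, writes `totals.csv`,
#'   `incremental.csv`, `trace_<strategy>.csv`, `ledger.csv` and a JSON
#'   summary `results.json`.
#' @return A list with `totals` (data frame `name,cost,qaly`),
#'   `incremental` (pairwise block), `frontier` and the per-strategy
#'   evaluations (`strategies`).
#' @export
run_base_case <- function(config = default_config(), out_dir = NULL) {
  validate_config(config)
  curves <- build_survival(config)
  evals <- lapply(names(curves), function(nm) {
    evaluate_strategy(config, nm, curves = curves)
  })
  names(evals) <- names(curves)
  totals <- data.frame(
    name = names(evals),
    cost = vapply(evals, `[[`, numeric(1), "cost"),
    qaly = vapply(evals, `[[`, numeric(1), "qaly"),
    row.names = NULL
  )
  tab <- cea_table(totals, pairs = list(c("DEP", "AEP"), c("AEP", "EP"),
                                        c("DEP", "EP")))
  front <- frontier(totals)
  out <- list(totals = tab$totals, incremental = tab$incremental,
              frontier = front, strategies = evals)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(out$totals, file.path(out_dir, "totals.csv"),
                     row.names = FALSE)
    utils::write.csv(out$incremental, file.path(out_dir, "incremental.csv"),
                     row.names = FALSE)
    ledger <- do.call(rbind, lapply(evals, function(e) e$cost_detail$ledger))
    write_cost_ledger(ledger, file.path(out_dir, "ledger.csv"))
    for (nm in names(evals)) {
      write_trace(evals[[nm]]$trace,
                  file.path(out_dir, paste0("trace_", nm, ".csv")))
    }
    jsonlite::write_json(
      list(package_version = as.character(utils::packageVersion("escea")),
           totals = out$totals, incremental = out$incremental),
      file.path(out_dir, "results.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  out
}

#' Dispatch a sensitivity analysis
#'
#' @param config An `escea_config`.
#' @param mode `"dsa"`, `"threshold"`, `"psa"` or `"scenario"`.
#' @param out_dir Optional output directory for the CSV artefacts.
#' @param n_draws,seed PSA overrides (default from `config$psa`).
#' @return The mode's result object (tornado data frame, threshold table,
#'   [run_psa()] result plus CEAC, or scenario comparison).
#' @export
run_sensitivity <- function(config = default_config(),
                            mode = c("dsa", "threshold", "psa", "scenario"),
                            out_dir = NULL, n_draws = NULL, seed = NULL) {
  mode <- match.arg(mode)
  validate_config(config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  }
  if (mode == "dsa") {
    res <- one_way_dsa(config)
    if (!is.null(out_dir)) {
      utils::write.csv(res, file.path(out_dir, "tornado.csv"),
                       row.names = FALSE)
    }
    res
  } else if (mode == "threshold") {
    wtp <- config$settings$wtp_per_qaly
    res <- rbind(
      data.frame(drug = "atezolizumab", comparison = "AEP vs EP",
                 reduction = price_threshold(config, "atezolizumab",
                                             c("AEP", "EP"), wtp)$multiplier),
      data.frame(drug = "durvalumab", comparison = "DEP vs EP",
                 reduction = price_threshold(config, "durvalumab",
                                             c("DEP", "EP"), wtp)$multiplier)
    )
    if (!is.null(out_dir)) {
      utils::write.csv(res, file.path(out_dir, "thresholds.csv"),
                       row.names = FALSE)
    }
    res
  } else if (mode == "psa") {
    if (is.null(n_draws)) n_draws <- config$psa$n_draws
    if (is.null(seed)) seed <- config$psa$seed
    psa <- run_psa(config, n_draws = n_draws, seed = seed)
    cc <- ceac(psa)
    if (!is.null(out_dir)) {
      utils::write.csv(psa$draws, file.path(out_dir, "psa_draws.csv"),
                       row.names = FALSE)
      utils::write.csv(cc, file.path(out_dir, "ceac.csv"), row.names = FALSE)
    }
    list(psa = psa, ceac = cc)
  } else {
    res <- scenario_until_progression(config)
    if (!is.null(out_dir)) {
      utils::write.csv(res$totals, file.path(out_dir, "scenario_totals.csv"),
                       row.names = FALSE)
      utils::write.csv(res$incremental,
                       file.path(out_dir, "scenario_incremental.csv"),
                       row.names = FALSE)
    }
    res
  }
}
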