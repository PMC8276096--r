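# Shared fixtures: the base-case survival curves and a few constructors
# used across test files.

aep_os_curve <- function() parametric_survival("loglogistic", c(0.003072, 2.297440))
aep_pfs_curve <- function() parametric_survival("loglogistic", c(0.008895, 2.852489))
ep_os_curve <- function() parametric_survival("weibull", c(0.016073, 1.593409))
ep_pfs_curve <- function() parametric_survival("weibull", c(0.042826, 1.712046))

# all five families with representative valid parameter sets
family_zoo <- function() {
  list(
    weibull = parametric_survival("weibull", c(0.016073, 1.593409)),
    loglogistic = parametric_survival("loglogistic", c(0.003072, 2.297440)),
    exponential = parametric_survival("exponential", log(2) / 12),
    lognormal = parametric_survival("lognormal", c(2.4, 0.8)),
    gompertz = parametric_survival("gompertz", c(0.05, 0.03))
  )
}

# a strategy with every unit cost zeroed except selected overrides
zero_costs <- function(...) {
  over <- list(...)
  base <- list(admin_first_hour = 0, admin_additional_hour = 0,
               monthly_physician_visit = 0, three_monthly_imaging = 0,
               monthly_supportive_care = 0, death_cost = 0)
  base[names(over)] <- over
  do.call(care_costs, base)
}

bare_strategy <- function(name = "bare", ...) {
  args <- list(...)
  defaults <- list(name = name, chemo_lines = list(), chemo_cycles = 0,
                   induction_infusion_hours = 0,
                   subsequent_therapy_proportion = 0)
  defaults[names(args)] <- args
  do.call(strategy_spec, defaults)
}
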