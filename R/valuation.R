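#' Dose rules
#'
#' Helpers describing how the per-cycle dose of a drug is computed:
#' a flat dose in mg, a body-surface-area dose given for a number of days
#' per cycle, or the Calvert carboplatin formula
#' \eqn{dose = AUC \times (CrCl + 25)} mg.
#'
#' @param amount Flat dose in mg per cycle.
#' @param mg_per_m2 Dose in mg per square metre per administration day.
#' @param days_per_cycle Number of administration days per cycle.
#' @param auc Target area-under-curve for the Calvert formula.
#' @return A dose-rule list consumed by [regimen_line()].
#' @name dose_rules
NULL

#' @rdname dose_rules
#' @export
dose_flat <- function(amount) {
  stopifnot(amount > 0)
  list(rule = "flat_mg", amount = amount)
}

#' @rdname dose_rules
#' @export
dose_per_bsa <- function(mg_per_m2, days_per_cycle = 1) {
  stopifnot(mg_per_m2 > 0, days_per_cycle > 0)
  list(rule = "per_bsa", mg_per_m2 = mg_per_m2, days_per_cycle = days_per_cycle)
}

#' @rdname dose_rules
#' @export
dose_calvert <- function(auc) {
  stopifnot(auc > 0)
  list(rule = "calvert", auc = auc)
}

#' One drug line of a regimen
#'
#' @param drug Drug name.
#' @param dose A dose rule from [dose_flat()], [dose_per_bsa()] or
#'   [dose_calvert()].
#' @param price_per_mg Price in $/mg (linear per-mg pricing, no vial
#'   rounding).
#' @return An object of class `regimen_line`.
#' @export
regimen_line <- function(drug, dose, price_per_mg) {
  stopifnot(is.character(drug), is.list(dose), price_per_mg >= 0)
  structure(list(drug = drug, dose = dose, price_per_mg = price_per_mg),
            class = "regimen_line")
}

#' Drug cost per cycle for one regimen line
#'
#' mg per cycle from the dose rule times the per-mg price.
#'
#' @param line A [regimen_line()].
#' @param settings A [model_settings()] supplying body surface area and
#'   creatinine clearance.
#' @export
drug_cost_per_cycle <- function(line, settings = model_settings()) {
  stopifnot(inherits(line, "regimen_line"))
  d <- line$dose
  mg <- switch(d$rule,
               flat_mg = d$amount,
               per_bsa = d$mg_per_m2 * settings$body_surface_area *
                 d$days_per_cycle,
               calvert = d$auc * (settings$creatinine_clearance + 25),
               stop("unknown dose rule: ", d$rule, call. = FALSE))
  mg * line$price_per_mg
}

#' Care-cost aggregates
#'
#' Unit costs for intravenous administration, routine follow-up,
#' supportive care and death-associated care.  Defaults are the US payer
#' values used by the base-case model.
#'
#' @param admin_first_hour,admin_additional_hour $/hour of intravenous
#'   administration (first hour billed at a higher rate).
#' @param monthly_physician_visit,three_monthly_imaging Routine follow-up
#'   unit costs while alive.
#' @param monthly_supportive_care Monthly cost of supportive care in the
#'   progressed state for patients not on subsequent chemotherapy.
#' @param death_cost One-time terminal-care cost per death.
#' @return An object of class `care_costs`.
#' @export
care_costs <- function(admin_first_hour = 142.55,
                       admin_additional_hour = 30.68,
                       monthly_physician_visit = 148.33,
                       three_monthly_imaging = 122.71,
                       monthly_supportive_care = 637.00,
                       death_cost = 9433.00) {
  x <- list(admin_first_hour = admin_first_hour,
            admin_additional_hour = admin_additional_hour,
            monthly_physician_visit = monthly_physician_visit,
            three_monthly_imaging = three_monthly_imaging,
            monthly_supportive_care = monthly_supportive_care,
            death_cost = death_cost)
  if (any(unlist(x) < 0)) stop("care costs must be non-negative", call. = FALSE)
  structure(x, class = "care_costs")
}

#' Health-state utilities
#'
#' @param u_pfs,u_ps Utilities of the progression-free and progressed
#'   states, in `[0, 1]`.
#' @export
utilities <- function(u_pfs = 0.673, u_ps = 0.473) {
  stopifnot(u_pfs >= 0, u_pfs <= 1, u_ps >= 0, u_ps <= 1)
  structure(list(u_pfs = u_pfs, u_ps = u_ps), class = "utilities")
}

#' Intravenous administration cost
#'
#' First infusion hour at the first-hour rate, each additional hour at the
#' additional-hour rate; zero hours cost nothing.
#'
#' @param infusion_hours Non-negative hours of infusion in one cycle.
#' @param costs A [care_costs()].
#' @export
administration_cost <- function(infusion_hours, costs = care_costs()) {
  if (any(infusion_hours < 0)) {
    stop("infusion hours must be non-negative", call. = FALSE)
  }
  ifelse(infusion_hours == 0, 0,
         costs$admin_first_hour +
           (infusion_hours - 1) * costs$admin_additional_hour)
}

#' A treatment strategy
#'
#' Describes one model arm: the first-line chemotherapy lines with their
#' induction cap, an optional immune-checkpoint-inhibitor (ICI) line with
#' its duration, adverse-event cost and disutility, and the subsequent
#' topotecan line applied to the fraction of progressing patients who
#' receive active second-line therapy.
#'
#' @param name Strategy label.
#' @param chemo_lines List of [regimen_line()]s given during induction.
#' @param chemo_cycles Number of induction chemotherapy cycles.
#' @param ici_line Optional [regimen_line()] for the ICI, `NULL` for
#'   chemotherapy-only strategies.
#' @param ici_cycles ICI duration in cycles; `Inf` means treatment until
#'   disease progression.
#' @param induction_infusion_hours Infusion hours per cycle while
#'   chemotherapy is given (4 for chemo-immunotherapy, 3 for chemotherapy
#'   alone).
#' @param maintenance_infusion_hours Infusion hours per ICI maintenance
#'   cycle (default 1).
#' @param ae_cost_first_line One-time first-line adverse-event management
#'   cost, applied in cycle 1.
#' @param ae_disutility Utility decrement for first-line adverse events.
#' @param disutility_policy How the decrement is applied:
#'   `"during_first_line"` subtracts it from the PFS utility over
#'   `disutility_cycles`; `"one_time_cycle"` applies it for cycle 1 only;
#'   `"one_time_absolute"` subtracts it once as an absolute QALY loss.
#' @param disutility_cycles Cycles over which `"during_first_line"`
#'   applies; defaults to the planned first-line duration
#'   (`max(chemo_cycles, ici_cycles)` when the ICI duration is finite,
#'   `chemo_cycles` otherwise) and deliberately does not grow in the
#'   until-progression scenario, so the scenario changes costs only.
#' @param subsequent_therapy_proportion Fraction of progressing patients
#'   receiving subsequent topotecan, in `[0, 1]`.
#' @param second_line Optional [regimen_line()] for subsequent topotecan.
#' @param second_line_cycles Cap on topotecan cycles per patient.
#' @param second_line_infusions Number of separate (1-hour) infusions per
#'   topotecan cycle.
#' @param ae_cost_second_line One-time second-line adverse-event cost per
#'   patient starting topotecan.
#' @return An object of class `strategy_spec`.
#' @export
strategy_spec <- function(name,
                          chemo_lines = list(),
                          chemo_cycles = 4,
                          ici_line = NULL,
                          ici_cycles = 7,
                          induction_infusion_hours = 3,
                          maintenance_infusion_hours = 1,
                          ae_cost_first_line = 0,
                          ae_disutility = 0,
                          disutility_policy = c("during_first_line",
                                                "one_time_cycle",
                                                "one_time_absolute"),
                          disutility_cycles = NULL,
                          subsequent_therapy_proportion = 0,
                          second_line = NULL,
                          second_line_cycles = 4,
                          second_line_infusions = 5,
                          ae_cost_second_line = 0) {
  disutility_policy <- match.arg(disutility_policy)
  stopifnot(subsequent_therapy_proportion >= 0,
            subsequent_therapy_proportion <= 1,
            ae_cost_first_line >= 0, ae_cost_second_line >= 0,
            ae_disutility >= 0, chemo_cycles >= 0, ici_cycles >= 0)
  if (is.null(disutility_cycles)) {
    disutility_cycles <- if (!is.null(ici_line) && is.finite(ici_cycles)) {
      max(chemo_cycles, ici_cycles)
    } else {
      chemo_cycles
    }
  }
  structure(list(name = name,
                 chemo_lines = chemo_lines,
                 chemo_cycles = chemo_cycles,
                 ici_line = ici_line,
                 ici_cycles = ici_cycles,
                 induction_infusion_hours = induction_infusion_hours,
                 maintenance_infusion_hours = maintenance_infusion_hours,
                 ae_cost_first_line = ae_cost_first_line,
                 ae_disutility = ae_disutility,
                 disutility_policy = disutility_policy,
                 disutility_cycles = disutility_cycles,
                 subsequent_therapy_proportion = subsequent_therapy_proportion,
                 second_line = second_line,
                 second_line_cycles = second_line_cycles,
                 second_line_infusions = second_line_infusions,
                 ae_cost_second_line = ae_cost_second_line),
            class = "strategy_spec")
}

# per-cycle cost components shared by accrue_costs and the fast PSA path
cost_components <- function(trace, strategy, costs, settings) {
  n <- nrow(trace) - 1L
  k <- seq_len(n)
  pfs <- trace$pfs[-1]
  ps <- trace$ps[-1]
  alive <- pfs + ps
  new_deaths <- trace$new_deaths[-1]
  entrants <- trace$new_progressions[-1]
  cyc_per_month <- settings$cycle_days / DAYS_PER_MONTH

  chemo_per_cycle <- sum(vapply(strategy$chemo_lines, drug_cost_per_cycle,
                                numeric(1), settings = settings))
  ici_per_cycle <- if (is.null(strategy$ici_line)) 0 else
    drug_cost_per_cycle(strategy$ici_line, settings)

  on_chemo <- k <= strategy$chemo_cycles
  on_ici <- !is.null(strategy$ici_line) & k <= strategy$ici_cycles
  first_line_drug <- (chemo_per_cycle * on_chemo + ici_per_cycle * on_ici) * pfs

  hours <- ifelse(on_chemo, strategy$induction_infusion_hours,
                  ifelse(on_ici, strategy$maintenance_infusion_hours, 0))
  first_line_admin <- administration_cost(hours, costs) * pfs

  ae_first <- c(strategy$ae_cost_first_line, rep(0, n - 1L))

  followup <- (costs$monthly_physician_visit +
                 costs$three_monthly_imaging / 3) * cyc_per_month * alive

  # subsequent topotecan: the configured proportion of patients leaving the
  # progression-free state start a capped course; occupancy on topotecan at
  # cycle k is the rolling sum of recent starters, bounded by the progressed
  # occupancy
  prop <- strategy$subsequent_therapy_proportion
  if (!is.null(strategy$second_line) && prop > 0) {
    cap <- strategy$second_line_cycles
    starters <- prop * entrants
    roll <- stats::filter(starters, rep(1, cap), sides = 1)
    roll[is.na(roll)] <- cumsum(starters)[is.na(roll)]
    topo_occ <- pmin(as.numeric(roll), ps)
    topo_drug_cc <- drug_cost_per_cycle(strategy$second_line, settings)
    topo_admin_cc <- strategy$second_line_infusions *
      administration_cost(1, costs)
    second_line_drug <- topo_drug_cc * topo_occ
    second_line_admin <- topo_admin_cc * topo_occ
    ae_second <- strategy$ae_cost_second_line * starters
  } else {
    topo_occ <- rep(0, n)
    second_line_drug <- second_line_admin <- ae_second <- rep(0, n)
  }

  supportive <- costs$monthly_supportive_care * cyc_per_month *
    pmax(0, ps - topo_occ)
  death <- costs$death_cost * new_deaths

  list(first_line_drug = first_line_drug,
       first_line_admin = first_line_admin,
       ae_first_line = ae_first,
       followup = followup,
       second_line_drug = second_line_drug,
       second_line_admin = second_line_admin,
       ae_second_line = ae_second,
       supportive_care = supportive,
       death = death)
}

#' Accrue discounted costs for a strategy
#'
#' Applies the per-cycle costing rules to a cohort trace: first-line drug
#' and administration costs weighted by progression-free occupancy while
#' each line is active, one-time first-line adverse-event cost in cycle 1,
#' routine follow-up while alive, subsequent topotecan (drug,
#' administration and one-time adverse-event cost) for the configured
#' proportion of progressing patients up to the topotecan cycle cap,
#' supportive care for progressed person-time not on topotecan, and a
#' death cost per incremental death.
#'
#' @param trace A [build_trace()] result.
#' @param strategy A [strategy_spec()].
#' @param costs A [care_costs()].
#' @param settings The [model_settings()] used for the trace.
#' @param ledger Build the long per-cycle ledger data frame?  Disable in
#'   tight loops (probabilistic analysis) where only the total is needed.
#' @return A list with `total` (discounted total cost), `by_category`
#'   (named discounted totals) and `ledger` (long data frame
#'   `cycle,category,strategy,amount` of discounted per-cycle amounts;
#'   `NULL` when `ledger = FALSE`).
#' @export
accrue_costs <- function(trace, strategy, costs = care_costs(),
                         settings = model_settings(), ledger = TRUE) {
  comp <- cost_components(trace, strategy, costs, settings)
  disc <- trace$discount[-1]
  by_category <- vapply(comp, function(x) sum(x * disc), numeric(1))
  led <- NULL
  if (ledger) {
    n <- nrow(trace) - 1L
    disc_comp <- lapply(comp, function(x) x * disc)
    led <- data.frame(
      cycle = rep(seq_len(n), times = length(disc_comp)),
      category = rep(names(disc_comp), each = n),
      strategy = strategy$name,
      amount = unlist(disc_comp, use.names = FALSE)
    )
  }
  list(total = sum(by_category), by_category = by_category, ledger = led)
}

#' Accrue discounted QALYs for a strategy
#'
#' Discounted sum over cycles of
#' \eqn{(u_{PFS} \cdot pfs + u_{PS} \cdot ps) \times} cycle length in
#' years, with the strategy's adverse-event disutility applied according
#' to its policy (default: decrement on the PFS utility during first-line
#' treatment cycles).
#'
#' @inheritParams accrue_costs
#' @param utils_ A [utilities()] object.
#' @return Total discounted QALYs.
#' @export
accrue_qalys <- function(trace, strategy, utils_ = utilities(),
                         settings = model_settings()) {
  n <- nrow(trace) - 1L
  k <- seq_len(n)
  pfs <- trace$pfs[-1]
  ps <- trace$ps[-1]
  disc <- trace$discount[-1]
  u_pfs <- rep(utils_$u_pfs, n)
  d <- strategy$ae_disutility
  one_time <- 0
  if (d > 0) {
    switch(strategy$disutility_policy,
           during_first_line = {
             u_pfs[k <= strategy$disutility_cycles] <-
               u_pfs[k <= strategy$disutility_cycles] - d
           },
           one_time_cycle = {
             u_pfs[1] <- u_pfs[1] - d
           },
           one_time_absolute = {
             one_time <- d * pfs[1] * disc[1]
           })
    u_pfs <- pmax(u_pfs, 0)
  }
  sum((u_pfs * pfs + utils_$u_ps * ps) * disc) * settings$cycle_years -
    one_time
}

#' Write an itemised cost ledger to CSV
#'
#' @param ledger The `ledger` component of [accrue_costs()] (or several
#'   row-bound together).
#' @param path Output CSV path.
#' @export
write_cost_ledger <- function(ledger, path) {
  utils::write.csv(ledger, path, row.names = FALSE)
  invisible(path)
}
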