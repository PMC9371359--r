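#' Discount factor for a cycle
#'
#' Cycle 0 (the first model year) is undiscounted; the same factor applies to
#' costs, life years and QALYs.
#'
#' @param cycle Cycle index (vectorised).
#' @param r Annual discount rate, `>= 0`.
#' @return `(1 + r)^(-cycle)`.
#' @export
discount_factor <- function(cycle, r) {
  if (r < 0) stop("discount rate must be non-negative")
  (1 + r)^(-cycle)
}

# 13-vectors of per-cycle rewards for one strategy at one cycle
reward_vectors <- function(ps, strategy, cycle) {
  eco <- ps$economics
  age <- eco$entry_age + cycle * eco$cycle_length
  cov <- strategy$coverage
  cs <- ps$costs
  ut <- ps$utilities
  exe <- cs$exenatide_annual

  cost <- numeric(13)
  dm_med <- lookup_band(cs$dm_medical, age)
  dm_prod <- lookup_band(cs$dm_productivity, age)
  cost[S_DM] <- dm_med + dm_prod + if ("DM" %in% cov) exe else 0
  cost[S_PD] <- cs$pd_medical$value + cs$home_care$value +
    cs$pd_productivity$value + if ("PD" %in% cov) exe else 0
  cost[S_PDDM] <- cs$pddm_medical$value + cs$home_care$value +
    cs$pd_productivity$value + dm_prod +
    (if (eco$pddm_includes_dm_medical) dm_med else 0) +
    (if ("PDDM" %in% cov) exe else 0)

  u_norm <- lookup_band(ut$normal, age)
  decline <- if (identical(eco$dm_utility_decline_mode, "model_time"))
    ut$dm_annual_decline * cycle else 0
  util <- numeric(13)
  util[S_NORMAL] <- u_norm
  util[S_DM] <- u_norm - ut$dm_decrement - decline +
    if ("DM" %in% cov) ps$effects$dm_utility_increment else 0
  util[S_PD] <- ut$pd$value
  util[S_PDDM] <- ut$pd$value - ut$dm_decrement - decline +
    if ("PDDM" %in% cov) ps$effects$dm_utility_increment else 0
  util <- pmin(pmax(util, 0), 1)

  alive <- c(rep(1, 10), 0, 0, 0)
  list(cost = cost, utility = util, alive = alive)
}

#' Annual societal cost of occupying one health state
#'
#' Normal costs nothing; DM accrues age-banded medical plus productivity-loss
#' costs; PD stages accrue stage-specific medical, home-care and
#' productivity-loss costs; PD+DM stages accrue the PD+DM medical cost (which
#' subsumes diabetes care) plus home care, PD productivity loss and the
#' age-banded DM productivity loss. Covered states additionally accrue the
#' annual exenatide acquisition cost.
#'
#' @param state State name (see [health_states()]); must be a living state.
#' @param ps A [cea_parameters()] set.
#' @param strategy A [cea_strategy()].
#' @param cycle Cycle index (sets the cohort age).
#' @return Annual cost in NT$.
#' @export
state_cost <- function(state, ps, strategy = cea_strategy("conventional"),
                       cycle = 0) {
  i <- match(state, STATE_NAMES)
  if (is.na(i)) stop("unknown state: ", state)
  if (i > 10) stop("death states accrue no cost")
  reward_vectors(ps, strategy, cycle)$cost[i]
}

#' Utility of occupying one health state
#'
#' Normal takes the age-banded population utility; DM subtracts the DM
#' decrement and (by default) an annual decline proportional to model time;
#' PD stages take the stage utilities; PD+DM stages subtract the DM terms
#' from the stage utility. Covered DM-type states add the exenatide utility
#' increment. Results are clamped to \[0, 1\].
#'
#' @inheritParams state_cost
#' @return Utility weight in \[0, 1\].
#' @export
state_utility <- function(state, ps, strategy = cea_strategy("conventional"),
                          cycle = 0) {
  i <- match(state, STATE_NAMES)
  if (is.na(i)) stop("unknown state: ", state)
  if (i > 10) stop("death states have utility 0 by convention; not accrued")
  reward_vectors(ps, strategy, cycle)$utility[i]
}

#' Accrue life years, QALYs and costs over a cohort trace
#'
#' Rewards accrue on start-of-cycle occupancy for cycles `0..horizon-1`
#' (switchable to the half-cycle average via
#' `economics$reward_timing = "half_cycle"`), discounted by
#' [discount_factor()]. With `economics$dm_cost_basis = "matched"` and a
#' `dm_reference_trace` supplied, diabetes-care costs (DM medical and DM
#' productivity loss) are accrued on the reference trace's occupancy instead
#' of the trace's own, holding DM-care totals equal across strategies; drug,
#' PD-care and all other components always follow the trace itself.
#'
#' @param trace A `cea_trace` from [run_cohort()].
#' @param ps The same parameter set the trace was produced with.
#' @param strategy The same strategy the trace was produced with.
#' @param dm_reference_trace Optional `cea_trace` supplying the occupancy on
#'   which DM-care costs are accrued (used by [run_cea()] under the matched
#'   basis); `NULL` accrues them on `trace` itself.
#' @return An `outcome_summary`: per-person discounted and undiscounted life
#'   years, QALYs and costs, plus a discounted cost-component breakdown.
#' @export
accrue <- function(trace, ps, strategy, dm_reference_trace = NULL) {
  eco <- ps$economics
  h <- eco$horizon_cycles
  if (nrow(trace) != h + 1L)
    stop("trace and parameter set disagree on the horizon")
  n <- eco$cohort_size
  half <- identical(eco$reward_timing, "half_cycle")
  comp <- c(exenatide = 0, dm_medical = 0, dm_productivity = 0,
            pd_medical = 0, home_care = 0, pd_productivity = 0)
  disc <- c(ly = 0, qaly = 0, cost = 0)
  undisc <- disc
  cov <- strategy$coverage
  for (t in 0:(h - 1L)) {
    occ <- if (half) (trace[t + 1L, ] + trace[t + 2L, ]) / 2 else trace[t + 1L, ]
    occ_dm <- occ
    if (!is.null(dm_reference_trace)) {
      ref <- if (half) (dm_reference_trace[t + 1L, ] + dm_reference_trace[t + 2L, ]) / 2
             else dm_reference_trace[t + 1L, ]
      occ_dm <- ref
    }
    rw <- reward_vectors(ps, strategy, t)
    age <- eco$entry_age + t * eco$cycle_length
    dm_med <- lookup_band(ps$costs$dm_medical, age)
    dm_prod <- lookup_band(ps$costs$dm_productivity, age)

    # component split; DM-care components may follow the reference occupancy
    c_exe <- ps$costs$exenatide_annual *
      sum(occ[c(if ("DM" %in% cov) S_DM,
                if ("PD" %in% cov) S_PD,
                if ("PDDM" %in% cov) S_PDDM)])
    c_dm_med <- dm_med * (occ_dm[S_DM] +
      if (eco$pddm_includes_dm_medical) sum(occ_dm[S_PDDM]) else 0)
    c_dm_prod <- dm_prod * (occ_dm[S_DM] + sum(occ_dm[S_PDDM]))
    c_pd_med <- sum(occ[S_PD] * ps$costs$pd_medical$value) +
      sum(occ[S_PDDM] * ps$costs$pddm_medical$value)
    c_home <- sum((occ[S_PD] + occ[S_PDDM]) * ps$costs$home_care$value)
    c_pd_prod <- sum((occ[S_PD] + occ[S_PDDM]) * ps$costs$pd_productivity$value)
    cost_t <- c_exe + c_dm_med + c_dm_prod + c_pd_med + c_home + c_pd_prod

    ly_t <- sum(occ * rw$alive)
    qaly_t <- sum(occ * rw$utility)
    d <- discount_factor(t, eco$discount_rate)
    disc <- disc + d * c(ly_t, qaly_t, cost_t)
    undisc <- undisc + c(ly_t, qaly_t, cost_t)
    comp <- comp + d * c(c_exe, c_dm_med, c_dm_prod, c_pd_med, c_home, c_pd_prod)
  }
  structure(list(strategy = strategy$label,
                 ly = disc[["ly"]] / n, qaly = disc[["qaly"]] / n,
                 cost = disc[["cost"]] / n,
                 ly_undiscounted = undisc[["ly"]] / n,
                 qaly_undiscounted = undisc[["qaly"]] / n,
                 cost_undiscounted = undisc[["cost"]] / n,
                 cost_components = comp / n),
            class = "outcome_summary")
}

#' @export
print.outcome_summary <- function(x, ...) {
  cat(sprintf("<outcome_summary> %s\n", x$strategy))
  cat(sprintf("  discounted per person: %.2f LY, %.2f QALY, NT$%s\n",
              x$ly, x$qaly, format(round(x$cost), big.mark = ",")))
  cat(sprintf("  undiscounted:          %.2f LY, %.2f QALY, NT$%s\n",
              x$ly_undiscounted, x$qaly_undiscounted,
              format(round(x$cost_undiscounted), big.mark = ",")))
  invisible(x)
}

#' WHO willingness-to-pay classification of an ICER
#'
#' @param icer ICER in NT$/QALY.
#' @param gdp GDP per capita anchor (NT$).
#' @return `"very cost-effective"` below 1x GDP, `"cost-effective"` between
#'   1x and 3x, otherwise `"not cost-effective"`.
#' @export
who_classification <- function(icer, gdp) {
  if (is.na(icer)) return(NA_character_)
  if (icer < gdp) "very cost-effective"
  else if (icer <= 3 * gdp) "cost-effective"
  else "not cost-effective"
}

#' Incremental cost-effectiveness of one strategy over another
#'
#' @param reference The comparator [accrue()] summary (conventional arm).
#' @param intervention The intervention summary (add-on exenatide arm).
#' @param wtp Willingness-to-pay in NT$/QALY for the net monetary benefit.
#' @param gdp GDP per capita anchor for the WHO classification; defaults to
#'   `wtp`.
#' @return An `incremental_result` with `delta_cost`, `delta_qaly`,
#'   `delta_ly`, `icer_per_qaly`, `icer_per_ly`, `nmb` and `classification`.
#'   Dominance cases are labelled rather than divided: `"dominant"` (cheaper
#'   and more effective), `"dominated"` (costlier and less effective), or
#'   `"undefined (no QALY difference)"`.
#' @export
incremental <- function(reference, intervention, wtp, gdp = wtp) {
  stopifnot(inherits(reference, "outcome_summary"),
            inherits(intervention, "outcome_summary"))
  dC <- intervention$cost - reference$cost
  dE <- intervention$qaly - reference$qaly
  dL <- intervention$ly - reference$ly
  icer_q <- if (dE != 0) dC / dE else NA_real_
  icer_l <- if (dL != 0) dC / dL else NA_real_
  label <-
    if (dE == 0) "undefined (no QALY difference)"
    else if (dC <= 0 && dE > 0) "dominant"
    else if (dC >= 0 && dE < 0) "dominated"
    else who_classification(icer_q, gdp)
  structure(list(delta_cost = dC, delta_qaly = dE, delta_ly = dL,
                 icer_per_qaly = icer_q, icer_per_ly = icer_l,
                 nmb = wtp * dE - dC, wtp = wtp,
                 classification = label),
            class = "incremental_result")
}

#' @export
print.incremental_result <- function(x, ...) {
  cat("<incremental_result>\n")
  cat(sprintf("  dC NT$%s  dQALY %.4f  dLY %.4f\n",
              format(round(x$delta_cost), big.mark = ","),
              x$delta_qaly, x$delta_ly))
  cat(sprintf("  ICER NT$%s/QALY (NT$%s/LY)  NMB NT$%s at WTP %s\n",
              format(round(x$icer_per_qaly), big.mark = ","),
              format(round(x$icer_per_ly), big.mark = ","),
              format(round(x$nmb), big.mark = ","),
              format(x$wtp, big.mark = ",")))
  cat("  ", x$classification, "\n")
  invisible(x)
}

#' Run the full base-case cost-effectiveness comparison
#'
#' Propagates the cohort under both strategies, accrues outcomes (under the
#' matched DM-cost basis the add-on arm's diabetes-care costs are accrued on
#' the conventional arm's occupancy), and returns the per-arm summaries with
#' the incremental result.
#'
#' @param ps A [cea_parameters()] set.
#' @param wtp Willingness-to-pay (NT$/QALY); defaults to the GDP-per-capita
#'   anchor in `ps`.
#' @param coverage Exenatide coverage passed to [cea_strategy()].
#' @param check Validate the parameter set before running (disabled
#'   internally for one-way excursions that intentionally break only the
#'   ordinal stage-utility rule).
#' @return A `cea_result` list: `conventional`, `exenatide`
#'   (`outcome_summary`), `incremental` (`incremental_result`), `traces`.
#' @examples
#' res <- run_cea(cea_parameters())
#' res$incremental
#' @export
run_cea <- function(ps, wtp = ps$economics$wtp_gdp,
                    coverage = c("DM", "PD", "PDDM"), check = TRUE) {
  conv <- cea_strategy("conventional")
  exe <- cea_strategy("exenatide", coverage = coverage)
  tr_c <- run_cohort(ps, conv, check = check)
  tr_e <- run_cohort(ps, exe, check = check)
  matched <- identical(ps$economics$dm_cost_basis, "matched")
  out_c <- accrue(tr_c, ps, conv)
  out_e <- accrue(tr_e, ps, exe,
                  dm_reference_trace = if (matched) tr_c else NULL)
  structure(list(conventional = out_c, exenatide = out_e,
                 incremental = incremental(out_c, out_e, wtp,
                                           gdp = ps$economics$wtp_gdp),
                 traces = list(conventional = tr_c, exenatide = tr_e)),
            class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  print(x$conventional); print(x$exenatide); print(x$incremental)
  invisible(x)
}
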