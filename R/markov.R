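# 13-state structure: a normal state, a DM state, four Hoehn-Yahr stages of
# PD without and with comorbid DM, and three cause-specific absorbing death
# states. PD progression is irreversible, DM is never lost, and incident PD
# always enters at H-Y 1 (DM-after-PD is deliberately not modelled).

STATE_NAMES <- c("Normal", "DM",
                 paste0("PD_HY", 1:4), paste0("PDDM_HY", 1:4),
                 "Death_PD", "Death_DM", "Death_Other")
S_NORMAL <- 1L; S_DM <- 2L; S_PD <- 3:6; S_PDDM <- 7:10
S_DEATH_PD <- 11L; S_DEATH_DM <- 12L; S_DEATH_OTHER <- 13L
LIVING <- 1:10

#' Names of the thirteen model health states
#' @return Character vector of state names in model order.
#' @export
health_states <- function() STATE_NAMES

#' Treatment strategy
#'
#' The conventional strategy applies no exenatide effect or cost anywhere.
#' The add-on strategy applies exenatide from state entry onward to the
#' living disease-state groups named in `coverage`: `"DM"` (diabetes only),
#' `"PD"` (PD only) and `"PDDM"` (PD with comorbid DM). Coverage of a group
#' carries the full bundle for that group: stage-transition rate multipliers
#' for PD-type groups, the DM-mortality factor and utility increment for
#' DM-type groups, and the annual drug cost for all covered groups.
#'
#' @param label `"conventional"` or `"exenatide"`.
#' @param coverage Character subset of `c("DM", "PD", "PDDM")`; ignored for
#'   the conventional strategy.
#' @return A list with class `cea_strategy`.
#' @export
cea_strategy <- function(label = c("conventional", "exenatide"),
                         coverage = c("DM", "PD", "PDDM")) {
  label <- match.arg(label)
  coverage <- if (label == "conventional") character(0)
              else match.arg(coverage, several.ok = TRUE)
  structure(list(label = label,
                 exenatide = label == "exenatide",
                 coverage = coverage),
            class = "cea_strategy")
}

#' Convert an annual transition rate to an annual probability
#'
#' @param rate Non-negative per-year hazard(s).
#' @param mode `"exponential"` for `1 - exp(-rate)` (constant hazard over the
#'   1-year cycle) or `"identity"` to read the rate directly as a probability,
#'   capped at 1.
#' @return Annual transition probability, same length as `rate`.
#' @export
rate_to_probability <- function(rate, mode = c("exponential", "identity")) {
  mode <- match.arg(mode)
  if (any(rate < 0)) stop("transition rate must be non-negative")
  if (mode == "exponential") 1 - exp(-rate) else pmin(rate, 1)
}

#' Combine cause-specific annual death probabilities within one cycle
#'
#' The total cycle death probability is `1 - prod(1 - p)`, allocated to causes
#' proportionally to their constant-hazard shares `-log(1 - p)`. A cause with
#' probability 1 dominates: the whole unit mass goes to it (split evenly if
#' several causes are certain).
#'
#' @param p Named numeric vector of per-cause annual death probabilities.
#' @return Named vector of per-cause cycle probabilities summing to the total
#'   death probability.
#' @export
combine_competing_risks <- function(p) {
  if (any(p < 0 | p > 1)) stop("cause-specific probabilities must be in [0, 1]")
  if (any(p == 1)) {
    out <- p * 0
    out[p == 1] <- 1 / sum(p == 1)
    return(out)
  }
  total <- 1 - prod(1 - p)
  h <- -log1p(-p)
  hs <- sum(h)
  if (hs == 0) return(p * 0)
  total * h / hs
}

# effective per-cycle inputs for one strategy at one cycle
cycle_inputs <- function(ps, strategy, cycle) {
  age <- ps$economics$entry_age + cycle * ps$economics$cycle_length
  cov <- strategy$coverage
  mode <- ps$economics$rate_conversion
  p_dm_mort <- lookup_band(ps$mortality$dm, age)
  fac <- ps$effects$dm_mortality_factor
  list(
    age = age,
    p_other = lookup_band(ps$mortality$other, age),
    p_dm_inc = lookup_band(ps$incidence$dm, age),
    p_pd_inc = lookup_band(ps$incidence$pd, age),
    p_pddm_inc = lookup_band(ps$incidence$pd_dm, age) *
      (if ("DM" %in% cov) 1 - ps$effects$pd_incidence_reduction else 1),
    p_dm_mort_dm = if ("DM" %in% cov) p_dm_mort * fac else p_dm_mort,
    p_dm_mort_pddm = if ("PDDM" %in% cov) p_dm_mort * fac else p_dm_mort,
    q_pd = rate_to_probability(
      treated_rates(ps, "pd", treated = "PD" %in% cov), mode),
    q_pddm = rate_to_probability(
      treated_rates(ps, "pd_dm", treated = "PDDM" %in% cov), mode),
    p_pd_mort = ps$mortality$pd_stage$value
  )
}

#' Per-cycle transition matrix for one strategy
#'
#' Builds the 13x13 row-stochastic matrix for the given cycle. Within a cycle
#' death acts first (cause-specific probabilities combined by
#' [combine_competing_risks()]), then disease transitions among survivors,
#' then stage progression; incident PD enters at H-Y 1 and cannot progress in
#' its incidence cycle. Death states are absorbing; no edge lowers an H-Y
#' stage or removes DM.
#'
#' @param ps A [cea_parameters()] set.
#' @param strategy A [cea_strategy()].
#' @param cycle Cycle index, `0 <= cycle < horizon_cycles`.
#' @return 13x13 matrix with state dimnames and attributes `cycle` and `age`.
#' @export
transition_matrix <- function(ps, strategy, cycle) {
  eco <- ps$economics
  if (cycle < 0 || cycle >= eco$horizon_cycles)
    stop("cycle must be in [0, horizon_cycles)")
  ci <- cycle_inputs(ps, strategy, cycle)
  M <- matrix(0, 13L, 13L, dimnames = list(STATE_NAMES, STATE_NAMES))

  # Normal: other-cause death, then DM or PD incidence among survivors
  surv <- 1 - ci$p_other
  M[S_NORMAL, S_DEATH_OTHER] <- ci$p_other
  M[S_NORMAL, S_DM] <- surv * ci$p_dm_inc
  M[S_NORMAL, S_PD[1]] <- surv * ci$p_pd_inc
  M[S_NORMAL, S_NORMAL] <- surv * (1 - ci$p_dm_inc - ci$p_pd_inc)

  # DM: competing DM/other death, then PD incidence among survivors
  al <- combine_competing_risks(c(dm = ci$p_dm_mort_dm, other = ci$p_other))
  surv <- 1 - sum(al)
  M[S_DM, S_DEATH_DM] <- al[["dm"]]
  M[S_DM, S_DEATH_OTHER] <- al[["other"]]
  M[S_DM, S_PDDM[1]] <- surv * ci$p_pddm_inc
  M[S_DM, S_DM] <- surv * (1 - ci$p_pddm_inc)

  # PD and PD+DM Hoehn-Yahr stages
  for (k in 1:4) {
    s <- S_PD[k]
    al <- combine_competing_risks(c(pd = ci$p_pd_mort[k], other = ci$p_other))
    surv <- 1 - sum(al)
    M[s, S_DEATH_PD] <- al[["pd"]]
    M[s, S_DEATH_OTHER] <- al[["other"]]
    if (k < 4) {
      M[s, s + 1L] <- surv * ci$q_pd[k]
      M[s, s] <- surv * (1 - ci$q_pd[k])
    } else M[s, s] <- surv

    s <- S_PDDM[k]
    al <- combine_competing_risks(c(pd = ci$p_pd_mort[k],
                                    dm = ci$p_dm_mort_pddm,
                                    other = ci$p_other))
    surv <- 1 - sum(al)
    M[s, S_DEATH_PD] <- al[["pd"]]
    M[s, S_DEATH_DM] <- al[["dm"]]
    M[s, S_DEATH_OTHER] <- al[["other"]]
    if (k < 4) {
      M[s, s + 1L] <- surv * ci$q_pddm[k]
      M[s, s] <- surv * (1 - ci$q_pddm[k])
    } else M[s, s] <- surv
  }
  M[S_DEATH_PD, S_DEATH_PD] <- 1
  M[S_DEATH_DM, S_DEATH_DM] <- 1
  M[S_DEATH_OTHER, S_DEATH_OTHER] <- 1

  if (any(M < 0) || any(abs(rowSums(M) - 1) > 1e-12))
    stop("transition matrix row failed the stochasticity invariant at cycle ",
         cycle, " (incidences too large for the survivor mass?)")
  attr(M, "cycle") <- cycle
  attr(M, "age") <- ci$age
  M
}

#' Initial cohort occupancy vector
#'
#' Splits the cohort between the normal and DM states according to the DM
#' prevalence at the entry age; fractional persons are allowed (the cohort is
#' an expected-value construct).
#'
#' @param ps A [cea_parameters()] set.
#' @return Named numeric vector of length 13 (persons).
#' @export
initial_cohort <- function(ps) {
  occ <- stats::setNames(numeric(13), STATE_NAMES)
  n <- ps$economics$cohort_size
  prev <- ps$economics$dm_prevalence_at_entry
  occ[S_DM] <- n * prev
  occ[S_NORMAL] <- n * (1 - prev)
  occ
}

#' Propagate the cohort over the model horizon
#'
#' Applies the per-cycle transition matrices to the initial occupancy for
#' `horizon_cycles` steps and records every cycle boundary.
#'
#' @param ps A [cea_parameters()] set; must pass [validate_parameters()].
#' @param strategy A [cea_strategy()].
#' @param check Validate the parameter set first.
#' @return A `cea_trace`: a `(horizon_cycles + 1) x 13` occupancy matrix in
#'   persons, rows named by cycle boundary `0..horizon`, with the cohort age
#'   per boundary in `attr(, "age")`.
#' @export
run_cohort <- function(ps, strategy = cea_strategy("conventional"),
                       check = TRUE) {
  viol <- if (check) validate_parameters(ps) else character(0)
  if (length(viol))
    stop("invalid parameter set:\n  - ", paste(viol, collapse = "\n  - "))
  h <- ps$economics$horizon_cycles
  occ <- matrix(0, h + 1L, 13L,
                dimnames = list(0:h, STATE_NAMES))
  occ[1L, ] <- initial_cohort(ps)
  for (t in 0:(h - 1L))
    occ[t + 2L, ] <- occ[t + 1L, ] %*% transition_matrix(ps, strategy, t)
  structure(occ,
            age = ps$economics$entry_age + (0:h) * ps$economics$cycle_length,
            strategy = strategy$label,
            class = c("cea_trace", "matrix"))
}

#' @export
as.data.frame.cea_trace <- function(x, ...) {
  data.frame(cycle = as.integer(rownames(x)),
             age = attr(x, "age"),
             unclass(x)[, , drop = FALSE],
             row.names = NULL, check.names = FALSE)
}

#' @export
print.cea_trace <- function(x, ...) {
  cat("<cea_trace> strategy:", attr(x, "strategy"), "\n")
  h <- nrow(x) - 1L
  alive <- rowSums(x[, LIVING])
  cat(sprintf("  %d cycles, cohort %.1f persons; alive at end: %.1f\n",
              h, sum(x[1L, ]), alive[h + 1L]))
  print(utils::head(round(unclass(x), 2), 4L))
  cat("  ...\n")
  invisible(x)
}
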