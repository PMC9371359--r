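# Independent oracles for the cohort engine and accrual logic: a two-state
# toy model with geometric-series closed forms, random valid parameter
# perturbations, and an individual-level microsimulation that shares only the
# per-cycle transition-probability construction with the cohort engine (the
# propagation and accrual paths under test are disjoint).

#' Two-state toy model specification
#'
#' One living state with a constant per-cycle death probability, constant
#' cost and utility, and a discount rate -- small enough that discounted
#' outcomes have exact geometric-series closed forms.
#'
#' @param p Per-cycle death probability in \[0, 1\].
#' @param cost Annual cost while alive (NT$).
#' @param utility Utility while alive, in \[0, 1\].
#' @param discount Annual discount rate.
#' @param horizon Number of cycles.
#' @return A list with class `toy_model_spec`.
#' @export
toy_model_spec <- function(p, cost = 0, utility = 1, discount = 0,
                           horizon = 10L) {
  stopifnot(p >= 0, p <= 1, utility >= 0, utility <= 1,
            cost >= 0, discount >= 0, horizon >= 1)
  structure(list(p = p, cost = cost, utility = utility,
                 discount = discount, horizon = as.integer(horizon)),
            class = "toy_model_spec")
}

#' Closed-form outcomes of the two-state toy model
#'
#' With start-of-cycle accrual, survival `s = 1 - p` and discount factor
#' `d = 1/(1 + r)`, the discounted life years are the geometric sum
#' `sum_{t=0}^{T-1} (s d)^t`; QALYs and costs scale it by the utility and the
#' annual cost.
#'
#' @param spec A [toy_model_spec()].
#' @return List with discounted and undiscounted `ly`, `qaly`, `cost`.
#' @export
closed_form_outcomes <- function(spec) {
  stopifnot(inherits(spec, "toy_model_spec"))
  s <- 1 - spec$p
  geom <- function(x, T) {
    if (abs(x - 1) < 1e-15) T else (1 - x^T) / (1 - x)
  }
  ly <- geom(s / (1 + spec$discount), spec$horizon)
  ly_u <- geom(s, spec$horizon)
  list(ly = ly, qaly = spec$utility * ly, cost = spec$cost * ly,
       ly_undiscounted = ly_u, qaly_undiscounted = spec$utility * ly_u,
       cost_undiscounted = spec$cost * ly_u)
}

# remove every sensitivity range so no registry entry is generated
strip_ranges <- function(ps) {
  for (g in c("incidence", "mortality", "costs", "utilities")) {
    for (nm in names(ps[[g]])) {
      if (is.data.frame(ps[[g]][[nm]]) && "low" %in% names(ps[[g]][[nm]])) {
        ps[[g]][[nm]]$low <- NA_real_
        ps[[g]][[nm]]$high <- NA_real_
      }
    }
  }
  ps$effects$multipliers_printed$low <- NA_real_
  ps$effects$multipliers_printed$high <- NA_real_
  for (nm in c("dm_mortality_factor", "dm_utility_increment")) {
    ps$effects[[paste0(nm, "_low")]] <- NA_real_
    ps$effects[[paste0(nm, "_high")]] <- NA_real_
  }
  for (nm in c("dm_decrement", "dm_annual_decline")) {
    ps$utilities[[paste0(nm, "_low")]] <- NA_real_
    ps$utilities[[paste0(nm, "_high")]] <- NA_real_
  }
  ps$economics$discount_rate_low <- NA_real_
  ps$economics$discount_rate_high <- NA_real_
  ps
}

#' Collapse every sensitivity range onto its base value
#'
#' Useful for degenerate-range tests: a PSA over the collapsed set reproduces
#' the deterministic base case in every iteration.
#'
#' @param ps A [cea_parameters()] set.
#' @return A copy of `ps` with `low = high = value` for every ranged entry.
#' @export
degenerate_ranges <- function(ps) {
  for (g in c("incidence", "mortality", "costs", "utilities")) {
    for (nm in names(ps[[g]])) {
      tab <- ps[[g]][[nm]]
      if (is.data.frame(tab) && "low" %in% names(tab)) {
        keep <- !is.na(tab$low)
        tab$low[keep] <- tab$value[keep]
        tab$high[keep] <- tab$value[keep]
        ps[[g]][[nm]] <- tab
      }
    }
  }
  mp <- ps$effects$multipliers_printed
  mp$low <- mp$value; mp$high <- mp$value
  ps$effects$multipliers_printed <- mp
  ps$effects$dm_mortality_factor_low <- ps$effects$dm_mortality_factor
  ps$effects$dm_mortality_factor_high <- ps$effects$dm_mortality_factor
  ps$effects$dm_utility_increment_low <- ps$effects$dm_utility_increment
  ps$effects$dm_utility_increment_high <- ps$effects$dm_utility_increment
  ps$utilities$dm_decrement_low <- ps$utilities$dm_decrement
  ps$utilities$dm_decrement_high <- ps$utilities$dm_decrement
  ps$utilities$dm_annual_decline_low <- ps$utilities$dm_annual_decline
  ps$utilities$dm_annual_decline_high <- ps$utilities$dm_annual_decline
  ps$economics$discount_rate_low <- ps$economics$discount_rate
  ps$economics$discount_rate_high <- ps$economics$discount_rate
  ps
}

#' Embed the two-state toy model in the full parameter structure
#'
#' Produces a degenerate [cea_parameters()] set whose cohort model reduces
#' exactly to the toy: the whole cohort starts in the DM state, all
#' incidences and all other mortality are zero, the DM death probability is
#' the toy's `p` at every age, and the DM state carries the toy's constant
#' cost and utility (decrement and decline switched off).
#'
#' @param spec A [toy_model_spec()].
#' @return A valid [cea_parameters()] set.
#' @export
toy_parameters <- function(spec) {
  stopifnot(inherits(spec, "toy_model_spec"))
  ps <- strip_ranges(cea_parameters())
  ps$economics$dm_prevalence_at_entry <- 1
  ps$economics$discount_rate <- spec$discount
  ps$economics$horizon_cycles <- spec$horizon
  ps$economics$dm_utility_decline_mode <- "off"
  ps$economics$dm_cost_basis <- "occupancy"
  for (nm in c("pd", "dm", "pd_dm")) ps$incidence[[nm]]$value[] <- 0
  ps$mortality$dm$value[] <- spec$p
  ps$mortality$dm_exenatide_printed$value[] <-
    spec$p * ps$effects$dm_mortality_factor
  ps$mortality$other$value[] <- 0
  ps$costs$dm_medical$value[] <- spec$cost
  ps$costs$dm_productivity$value[] <- 0
  ps$utilities$normal$value[] <- spec$utility
  ps$utilities$dm_decrement <- 0
  ps$utilities$dm_annual_decline <- 0
  ps
}

#' Randomly perturb every ranged parameter within its bounds
#'
#' Draws each registered parameter uniformly within its sensitivity range,
#' re-derives dependent quantities, and returns a valid set (invalid draws
#' are rejected and redrawn). Deterministic given `seed`; a set without
#' ranges is returned unchanged.
#'
#' @param ps A valid [cea_parameters()] set.
#' @param seed RNG seed.
#' @return A valid perturbed [cea_parameters()] copy.
#' @export
perturb_parameters <- function(ps, seed = 1L) {
  sa <- sa_parameters(ps)
  if (nrow(sa) == 0L || all(sa$low == sa$high)) return(ps)
  set.seed(seed)
  for (tries in 1:1000) {
    psi <- apply_draw(ps, sa, draw_one(sa, "uniform"))
    if (length(validate_parameters(psi)) == 0L) return(psi)
  }
  stop("perturb_parameters: no valid draw in 1000 attempts")
}

#' Individual-level microsimulation of the cohort model
#'
#' Samples `n` independent individual trajectories. Each cycle, every living
#' individual's next state is drawn from the corresponding row of the same
#' per-cycle transition matrix the cohort engine uses, and the same rewards
#' are accrued at the same timing and discounting. Sample means estimate the
#' cohort model's per-person expectations; Monte-Carlo standard errors
#' quantify the agreement to expect.
#'
#' @param ps A valid [cea_parameters()] set.
#' @param strategy A [cea_strategy()].
#' @param n Number of individuals.
#' @param seed RNG seed; trajectories are reproducible given `seed`.
#' @return List with `mean` and `se` (each with `ly`, `qaly`, `cost`,
#'   discounted per person), `n` and `seed`.
#' @export
microsimulate <- function(ps, strategy = cea_strategy("conventional"),
                          n = 10000L, seed = 1L) {
  viol <- validate_parameters(ps)
  if (length(viol))
    stop("invalid parameter set:\n  - ", paste(viol, collapse = "\n  - "))
  stopifnot(n >= 1)
  eco <- ps$economics
  h <- eco$horizon_cycles
  half <- identical(eco$reward_timing, "half_cycle")
  set.seed(seed)
  state <- ifelse(stats::runif(n) < eco$dm_prevalence_at_entry, S_DM, S_NORMAL)
  ly <- qaly <- cost <- numeric(n)
  for (t in 0:(h - 1L)) {
    rw <- reward_vectors(ps, strategy, t)
    d <- discount_factor(t, eco$discount_rate)
    w <- if (half) 0.5 else 1
    ly <- ly + w * d * rw$alive[state]
    qaly <- qaly + w * d * rw$utility[state]
    cost <- cost + w * d * rw$cost[state]
    M <- transition_matrix(ps, strategy, t)
    newstate <- state
    for (k in unique(state[state <= 10L])) {
      idx <- which(state == k)
      newstate[idx] <- sample.int(13L, length(idx), replace = TRUE,
                                  prob = M[k, ])
    }
    state <- newstate
    if (half) {
      ly <- ly + w * d * rw$alive[state]
      qaly <- qaly + w * d * rw$utility[state]
      cost <- cost + w * d * rw$cost[state]
    }
  }
  list(mean = list(ly = mean(ly), qaly = mean(qaly), cost = mean(cost)),
       se = list(ly = stats::sd(ly) / sqrt(n),
                 qaly = stats::sd(qaly) / sqrt(n),
                 cost = stats::sd(cost) / sqrt(n)),
       n = n, seed = seed)
}
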