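#' Age-banded parameter table
#'
#' Builds a table of values defined on contiguous age bands. Bands are
#' inclusive on the lower bound and exclusive on the upper bound; the last
#' band may be open-ended (`upper = Inf`). `low`/`high` are optional bounds
#' used by the sensitivity analyses; `NA` marks a parameter held fixed.
#'
#' @param lower,upper Numeric vectors of band boundaries in years of age.
#' @param value Numeric vector of band values (probabilities or NT$ amounts).
#' @param low,high Optional sensitivity-analysis bounds per band.
#' @return A `data.frame` with class `band_table`.
#' @export
band_table <- function(lower, upper, value, low = NA_real_, high = NA_real_) {
  stopifnot(length(lower) == length(upper), length(lower) == length(value))
  tab <- data.frame(lower = as.numeric(lower), upper = as.numeric(upper),
                    value = as.numeric(value), low = as.numeric(low),
                    high = as.numeric(high))
  if (is.unsorted(tab$lower, strictly = TRUE))
    stop("band lower bounds must be strictly increasing")
  class(tab) <- c("band_table", "data.frame")
  tab
}

#' Look up an age-banded value
#'
#' Returns the value of the band containing `age`. Band boundaries are
#' inclusive-lower / exclusive-upper, so age 50 falls in the 50-59 band.
#'
#' @param table A [band_table()].
#' @param age Age in years (scalar or vector).
#' @return Numeric vector of band values.
#' @export
lookup_band <- function(table, age) {
  if (any(age < table$lower[1]))
    stop("age ", min(age), " is below the first band (", table$lower[1], ")")
  idx <- findInterval(age, table$lower)
  if (any(age >= table$upper[nrow(table)]) && is.finite(table$upper[nrow(table)]))
    stop("age above the last band")
  table$value[idx]
}

#' Stage-indexed parameter table
#'
#' Values indexed by Hoehn-Yahr stage 1 to 4+ with optional sensitivity bounds.
#' @param value Numeric vector of length 4 (stages 1, 2, 3, 4+).
#' @param low,high Optional sensitivity-analysis bounds per stage.
#' @return A `data.frame` with class `stage_table`.
#' @export
stage_table <- function(value, low = NA_real_, high = NA_real_) {
  stopifnot(length(value) == 4)
  tab <- data.frame(stage = 1:4, value = as.numeric(value),
                    low = as.numeric(low), high = as.numeric(high))
  class(tab) <- c("stage_table", "data.frame")
  tab
}

#' Full model parameter set with the published base-case inputs
#'
#' Returns the complete parameter inventory of the model: age-banded
#' incidences of PD, DM and PD-given-DM; age-banded DM and other-cause
#' mortality and Hoehn-Yahr stage-specific PD mortality; annual H-Y stage
#' transition rates for PD and PD-comorbid-with-DM and the exenatide rate
#' multipliers; the societal cost schedule; the utility schedule; and the
#' economic settings (1,000-person cohort entering at age 40, DM prevalence
#' 0.0605 at entry, 50 annual cycles, 3% discount, willingness-to-pay anchored
#' at Taiwan's 2020 GDP per capita of NT$839,558).
#'
#' Two inventory details deserve attention. The published treated transition
#' rates imply stage multipliers (0.947, 0.239, 0.206); the separately printed
#' effect rows (0.981, 0.245, 0.214 with ranges) are carried in the
#' sensitivity-analysis registry only. And the published treated rate for the
#' PD+DM stage 3 to 4+ transition (0.0210) disagrees with the product of its
#' own stated factors (0.3192 x 0.206 = 0.0658); the default uses the product,
#' with `economics$pddm_lambda3 = "printed"` switching to the printed value.
#'
#' @param ... Named overrides applied on top of the defaults, e.g.
#'   `economics = list(discount_rate = 0)`. Lists are merged recursively.
#' @return A list with class `cea_parameters`.
#' @seealso [validate_parameters()], [sa_parameters()], [read_parameters()]
#' @export
cea_parameters <- function(...) {
  age5 <- list(lower = c(40, 50, 60, 70, 80), upper = c(50, 60, 70, 80, Inf))
  ps <- list(
    meta = list(schema = "exeCEA-parameters", schema_version = 1L),
    economics = list(
      discount_rate = 0.03,
      discount_rate_low = 0, discount_rate_high = 0.05,
      horizon_cycles = 50L,
      cycle_length = 1,
      cohort_size = 1000,
      entry_age = 40,
      dm_prevalence_at_entry = 0.0605,
      wtp_gdp = 839558,
      rate_conversion = "exponential",  # or "identity"
      reward_timing = "start",          # or "half_cycle"
      dm_cost_basis = "matched",        # or "occupancy"
      pddm_includes_dm_medical = FALSE,
      dm_utility_decline_mode = "model_time",  # or "off"
      pddm_lambda3 = "product",         # or "printed"
      scenario2_mode = "multiplier"     # or "rate"
    ),
    incidence = list(
      pd = band_table(age5$lower, age5$upper,
        value = c(0, 0.000211, 0.000995, 0.003005, 0.003699),
        low   = c(NA, 0.000193, 0.000773, 0.002577, 0.003280),
        high  = c(NA, 0.000229, 0.001218, 0.003435, 0.004118)),
      dm = band_table(age5$lower, age5$upper,
        value = c(0.00964, 0.00964, 0.01906, 0.01906, 0.01637),
        low   = c(0.00911, 0.00911, 0.01699, 0.01699, 0.01419),
        high  = c(0.01017, 0.01017, 0.02112, 0.02112, 0.01854)),
      pd_dm = band_table(age5$lower, age5$upper,
        value = c(0, 0.000464, 0.001542, 0.004658, 0.005733),
        low   = c(NA, 0.000371, 0.001453, 0.004387, 0.005401),
        high  = c(NA, 0.000578, 0.001711, 0.005169, 0.006362))
    ),
    mortality = list(
      dm = band_table(c(40, 50, 60, 70, 75), c(50, 60, 70, 75, Inf),
        value = c(0.01510, 0.02195, 0.03931, 0.05288, 0.08150),
        low   = c(0.0099, 0.0123, 0.0273, 0.0486, 0.0778),
        high  = c(0.0203, 0.0350, 0.0547, 0.0580, 0.0863)),
      # printed add-on column; the engine derives it as dm x factor unrounded
      dm_exenatide_printed = band_table(c(40, 50, 60, 70, 75), c(50, 60, 70, 75, Inf),
        value = c(0.01329, 0.01932, 0.03459, 0.04653, 0.07172),
        low   = c(0.0129, 0.0189, 0.0338, 0.0455, 0.0701),
        high  = c(0.0136, 0.0198, 0.0353, 0.0476, 0.0734)),
      other = band_table(age5$lower, age5$upper,
        value = c(0.00266, 0.00507, 0.01028, 0.02677, 0.05722),
        low   = c(0.0017, 0.0038, 0.0070, 0.0164, 0.0432),
        high  = c(0.0035, 0.0065, 0.0148, 0.0393, 0.0628)),
      pd_stage = stage_table(c(0.01, 0.048, 0.080, 0.199))
    ),
    rates = list(
      pd    = c(lambda1 = 0.3237, lambda2 = 0.068,  lambda3 = 0.3192),
      pd_dm = c(lambda1 = 0.4369, lambda2 = 0.1462, lambda3 = 0.3192),
      treated_printed = list(
        pd    = c(lambda1 = 0.3065, lambda2 = 0.0163, lambda3 = 0.0658),
        pd_dm = c(lambda1 = 0.4137, lambda2 = 0.0349, lambda3 = 0.0210))
    ),
    effects = list(
      # base-case multipliers implied by the treated-rate arithmetic
      multipliers = c(m1 = 0.947, m2 = 0.239, m3 = 0.206),
      # separately printed effect values and ranges; SA registry only
      multipliers_printed = data.frame(
        id = c("m1", "m2", "m3"),
        value = c(0.981, 0.245, 0.214),
        low = c(0.95, 0.20, 0.17),
        high = c(0.99, 0.32, 0.28)),
      dm_mortality_factor = 0.88,
      dm_mortality_factor_low = 0.86, dm_mortality_factor_high = 0.90,
      dm_utility_increment = 0.08,
      dm_utility_increment_low = 0.06, dm_utility_increment_high = 0.10,
      pd_incidence_reduction = 0
    ),
    costs = list(
      pd_medical = stage_table(c(21821.9, 69074.2, 71969.3, 133558.1),
        low  = c(NA, 17470.5, 22218.5, 50890.6),
        high = c(NA, 254268.4, 152150.8, 172994.6)),
      pddm_medical = stage_table(c(21821.9, 90217.1, 77079.1, 148740.9),
        low  = c(NA, 24685.3, 43927.4, NA),
        high = c(NA, 264341, 123334.5, NA)),
      home_care = stage_table(c(0, 0, 22220, 22220)),
      pd_productivity = stage_table(c(17261.2, 52185.1, 95538.9, 54593.7),
        low  = c(5218.5, 40142.4, 83496.2, 42550.9),
        high = c(29304.0, 64227.8, 107581.6, 66636.4)),
      dm_medical = band_table(age5$lower, age5$upper,
        value = c(43903.6, 58903.6, 73903.6, 88903.6, 103903.6),
        low   = c(39887.8, 54887.8, 69887.8, 84887.8, 99887.8),
        high  = c(47919.4, 62919.4, 77919.4, 92919.4, 107919.4)),
      # no amount printed for ages 70+ (retirement): zero
      dm_productivity = band_table(c(40, 50, 60, 70), c(50, 60, 70, Inf),
        value = c(635049, 605055.6, 481893, 0)),
      exenatide_annual = 33926.8
    ),
    utilities = list(
      normal = band_table(c(40, 65), c(65, Inf),
        value = c(0.92, 0.84), low = c(0.74, 0.39), high = c(1.00, 1.00)),
      pd = stage_table(c(0.708, 0.678, 0.622, 0.499),
        low  = c(0.638, 0.608, 0.552, 0.429),
        high = c(0.778, 0.748, 0.692, 0.569)),
      dm_decrement = 0.04,
      dm_decrement_low = 0.0352, dm_decrement_high = 0.0448,
      dm_annual_decline = 0.003,
      dm_annual_decline_low = 0.00214, dm_annual_decline_high = 0.00387
    )
  )
  class(ps) <- "cea_parameters"
  dots <- list(...)
  if (length(dots)) {
    if (is.null(names(dots)) || any(names(dots) == ""))
      stop("overrides must be named")
    ps <- modify_list_deep(ps, dots)
    class(ps) <- "cea_parameters"
  }
  ps
}

modify_list_deep <- function(base, new) {
  for (nm in names(new)) {
    if (is.list(new[[nm]]) && !is.data.frame(new[[nm]]) &&
        is.list(base[[nm]]) && !is.data.frame(base[[nm]])) {
      base[[nm]] <- modify_list_deep(base[[nm]], new[[nm]])
    } else {
      base[[nm]] <- new[[nm]]
    }
  }
  base
}

#' Apply the exenatide rate multipliers to a set of transition rates
#'
#' Multiplies the annual stage-transition rates (lambda1, lambda2, lambda3) by
#' the stage-specific rate factors, reproducing the treated-rate arithmetic of
#' the published transition-rate table. Values are returned unrounded; set
#' `rounded = TRUE` for the 4-decimal display convention.
#'
#' @param rates Named numeric vector `c(lambda1=, lambda2=, lambda3=)`.
#' @param multipliers Numeric vector of three multiplicative factors.
#' @param rounded Round to 4 decimals for display.
#' @return Named numeric vector of treated rates.
#' @examples
#' derive_treated_rates(c(lambda1 = 0.3237, lambda2 = 0.068, lambda3 = 0.3192),
#'                      c(0.947, 0.239, 0.206), rounded = TRUE)
#' @export
derive_treated_rates <- function(rates, multipliers, rounded = FALSE) {
  stopifnot(length(rates) == 3, length(multipliers) == 3)
  if (any(rates < 0) || any(multipliers < 0))
    stop("rates and multipliers must be non-negative")
  out <- unname(rates) * unname(multipliers)
  names(out) <- c("lambda1", "lambda2", "lambda3")
  if (rounded) round(out, 4) else out
}

#' Annual stage-transition rates for one disease condition and strategy
#'
#' @param ps A [cea_parameters()] set.
#' @param condition `"pd"` or `"pd_dm"`.
#' @param treated Apply the exenatide multipliers?
#' @return Named numeric vector of annual rates (unrounded).
#' @export
treated_rates <- function(ps, condition = c("pd", "pd_dm"), treated = TRUE) {
  condition <- match.arg(condition)
  lam <- ps$rates[[condition]]
  if (!treated) return(lam)
  out <- derive_treated_rates(lam, ps$effects$multipliers)
  ov <- ps$effects$lambda1_override
  if (!is.null(ov) && !is.null(ov[[condition]])) out["lambda1"] <- ov[[condition]]
  if (condition == "pd_dm" && identical(ps$economics$pddm_lambda3, "printed"))
    out["lambda3"] <- ps$rates$treated_printed$pd_dm[["lambda3"]]
  out
}

#' Registry of parameters with sensitivity-analysis ranges
#'
#' Enumerates every model input that carries a printed plausible range, one row
#' per scalar (age bands and H-Y stages are separate entries). The one-way
#' tornado sweep and the probabilistic sensitivity analysis draw from this
#' registry; parameters without a printed range are held fixed. The three
#' exenatide rate-multiplier entries use the separately printed effect values
#' as their registry base, while the deterministic base case keeps the
#' multipliers implied by the treated-rate arithmetic.
#'
#' @param ps A [cea_parameters()] set.
#' @return `data.frame` with columns `id`, `base`, `low`, `high`.
#' @export
sa_parameters <- function(ps) {
  ids <- character(0); base <- low <- high <- numeric(0)
  add <- function(id, b, lo, hi) {
    keep <- !is.na(lo) & !is.na(hi)
    ids <<- c(ids, id[keep]); base <<- c(base, b[keep])
    low <<- c(low, lo[keep]); high <<- c(high, hi[keep])
  }
  band_rows <- function(prefix, tab)
    add(paste0(prefix, ".", seq_len(nrow(tab))), tab$value, tab$low, tab$high)
  band_rows("incidence.pd", ps$incidence$pd)
  band_rows("incidence.dm", ps$incidence$dm)
  band_rows("incidence.pd_dm", ps$incidence$pd_dm)
  band_rows("mortality.dm", ps$mortality$dm)
  band_rows("mortality.other", ps$mortality$other)
  eff <- ps$effects
  add("effects.dm_mortality_factor", eff$dm_mortality_factor,
      eff$dm_mortality_factor_low, eff$dm_mortality_factor_high)
  mp <- eff$multipliers_printed
  add(paste0("effects.", mp$id), mp$value, mp$low, mp$high)
  add("effects.dm_utility_increment", eff$dm_utility_increment,
      eff$dm_utility_increment_low, eff$dm_utility_increment_high)
  band_rows("costs.pd_medical", ps$costs$pd_medical)
  band_rows("costs.pddm_medical", ps$costs$pddm_medical)
  band_rows("costs.pd_productivity", ps$costs$pd_productivity)
  band_rows("costs.dm_medical", ps$costs$dm_medical)
  band_rows("utilities.pd", ps$utilities$pd)
  band_rows("utilities.normal", ps$utilities$normal)
  add("utilities.dm_decrement", ps$utilities$dm_decrement,
      ps$utilities$dm_decrement_low, ps$utilities$dm_decrement_high)
  add("utilities.dm_annual_decline", ps$utilities$dm_annual_decline,
      ps$utilities$dm_annual_decline_low, ps$utilities$dm_annual_decline_high)
  add("economics.discount_rate", ps$economics$discount_rate,
      ps$economics$discount_rate_low, ps$economics$discount_rate_high)
  data.frame(id = ids, base = base, low = low, high = high)
}

#' Set a registered parameter to a new value
#'
#' `id` follows the `sa_parameters()` naming (`"table.component.index"` for
#' banded/staged entries, `"group.name"` for scalars). Setting one of the
#' `effects.m*` entries overrides the corresponding base-case model multiplier,
#' so treated rates are re-derived from the new value.
#'
#' @param ps A [cea_parameters()] set.
#' @param id Registry id string.
#' @param value Replacement numeric value.
#' @return A modified copy of `ps`; the input is untouched.
#' @export
param_set <- function(ps, id, value) {
  value <- unname(value)
  parts <- strsplit(id, ".", fixed = TRUE)[[1]]
  if (parts[1] == "effects" && parts[2] %in% c("m1", "m2", "m3")) {
    k <- match(parts[2], c("m1", "m2", "m3"))
    ps$effects$multipliers[k] <- value
    return(refresh_treated_cache(ps))
  }
  if (length(parts) == 2) {
    if (is.null(ps[[parts[1]]][[parts[2]]])) stop("unknown parameter id: ", id)
    ps[[parts[1]]][[parts[2]]] <- value
    return(ps)
  }
  if (length(parts) == 3) {
    tab <- ps[[parts[1]]][[parts[2]]]
    i <- as.integer(parts[3])
    if (is.null(tab) || is.na(i) || i < 1 || i > nrow(tab))
      stop("unknown parameter id: ", id)
    tab$value[i] <- value
    ps[[parts[1]]][[parts[2]]] <- tab
    return(ps)
  }
  stop("unknown parameter id: ", id)
}

# keep the printed-treated-rate cache consistent with the current base rates
# and multipliers; the flagged PD+DM lambda3 print is preserved as-is
refresh_treated_cache <- function(ps) {
  der_pd <- round(derive_treated_rates(ps$rates$pd, ps$effects$multipliers), 4)
  der_dm <- round(derive_treated_rates(ps$rates$pd_dm, ps$effects$multipliers), 4)
  ps$rates$treated_printed$pd <- der_pd
  ps$rates$treated_printed$pd_dm[1:2] <- der_dm[1:2]
  ps
}

#' Read a registered parameter value
#' @inheritParams param_set
#' @return Numeric value currently held by the model for `id`.
#' @export
param_get <- function(ps, id) {
  parts <- strsplit(id, ".", fixed = TRUE)[[1]]
  if (parts[1] == "effects" && parts[2] %in% c("m1", "m2", "m3"))
    return(unname(ps$effects$multipliers[match(parts[2], c("m1", "m2", "m3"))]))
  if (length(parts) == 2) return(ps[[parts[1]]][[parts[2]]])
  if (length(parts) == 3)
    return(ps[[parts[1]]][[parts[2]]]$value[as.integer(parts[3])])
  stop("unknown parameter id: ", id)
}

#' Validate a parameter set against the model invariants
#'
#' Checks every structural invariant of the inventory: probabilities in
#' \[0, 1\], band coverage from the entry age upward, PD incidence zero in the
#' first band and never above the PD-given-DM incidence, monotone PD stage
#' mortality, an exenatide DM-mortality factor not exceeding 1, non-negative
#' costs and rates, utilities in \[0, 1\] strictly decreasing over H-Y stages,
#' sensitivity ranges bracketing their base values, and the consistency of the
#' published treated transition rates with base rates times multipliers to 4
#' decimals (the flagged PD+DM stage-3 cell excepted).
#'
#' Violations are returned as data, not thrown.
#'
#' @param ps A [cea_parameters()] set.
#' @return Character vector of violation descriptions; empty when valid.
#' @export
validate_parameters <- function(ps) {
  v <- character()
  say <- function(...) v <<- c(v, paste0(...))
  chk_bands <- function(tab, name, from = 40) {
    if (tab$lower[1] != from) say(name, ": bands must start at age ", from)
    if (nrow(tab) > 1 && any(tab$upper[-nrow(tab)] != tab$lower[-1]))
      say(name, ": bands must be contiguous and non-overlapping")
    if (is.finite(tab$upper[nrow(tab)])) say(name, ": top band must be open-ended")
    has <- !is.na(tab$low) & !is.na(tab$high)
    if (any(has & (tab$low > tab$value | tab$value > tab$high)))
      say(name, ": value outside its sensitivity range")
  }
  chk_prob <- function(x, name) {
    if (any(x < 0 | x > 1)) say(name, ": probability outside [0, 1]")
  }
  chk_pos <- function(x, name) {
    if (any(x < 0)) say(name, ": negative value")
  }

  for (nm in c("pd", "dm", "pd_dm")) {
    chk_bands(ps$incidence[[nm]], paste0("incidence.", nm))
    chk_prob(ps$incidence[[nm]]$value, paste0("incidence.", nm))
  }
  if (ps$incidence$pd$value[1] != 0) say("incidence.pd: first band must be 0")
  if (any(ps$incidence$pd_dm$value < ps$incidence$pd$value))
    say("incidence.pd_dm: must be >= PD incidence at every band")

  for (nm in c("dm", "dm_exenatide_printed", "other")) {
    chk_bands(ps$mortality[[nm]], paste0("mortality.", nm))
    chk_prob(ps$mortality[[nm]]$value, paste0("mortality.", nm))
  }
  pdm <- ps$mortality$pd_stage$value
  chk_prob(pdm, "mortality.pd_stage")
  if (is.unsorted(pdm)) say("mortality.pd_stage: must be non-decreasing in stage")
  # the engine derives treated DM mortality as conventional x factor, so the
  # exenatide-never-worse invariant reduces to factor <= 1
  if (ps$effects$dm_mortality_factor > 1)
    say("effects.dm_mortality_factor: must be <= 1 so treated DM mortality ",
        "does not exceed conventional")

  for (nm in c("pd", "pd_dm")) {
    if (any(ps$rates[[nm]] < 0)) say("rates.", nm, ": negative rate")
  }
  eff <- ps$effects
  if (any(eff$multipliers < 0)) say("effects.multipliers: negative factor")
  if (eff$dm_mortality_factor < 0) say("effects.dm_mortality_factor: negative")
  if (eff$pd_incidence_reduction < 0 || eff$pd_incidence_reduction > 1)
    say("effects.pd_incidence_reduction: outside [0, 1]")
  if (eff$dm_utility_increment < 0) say("effects.dm_utility_increment: negative")

  chk_pos(ps$costs$pd_medical$value, "costs.pd_medical")
  chk_pos(ps$costs$pddm_medical$value, "costs.pddm_medical")
  chk_pos(ps$costs$home_care$value, "costs.home_care")
  chk_pos(ps$costs$pd_productivity$value, "costs.pd_productivity")
  chk_pos(ps$costs$dm_medical$value, "costs.dm_medical")
  chk_pos(ps$costs$dm_productivity$value, "costs.dm_productivity")
  chk_pos(ps$costs$exenatide_annual, "costs.exenatide_annual")
  chk_bands(ps$costs$dm_medical, "costs.dm_medical")
  chk_bands(ps$costs$dm_productivity, "costs.dm_productivity")

  chk_bands(ps$utilities$normal, "utilities.normal")
  chk_prob(ps$utilities$normal$value, "utilities.normal")
  chk_prob(ps$utilities$pd$value, "utilities.pd")
  if (any(diff(ps$utilities$pd$value) >= 0))
    say("utilities.pd: must be strictly decreasing in stage")
  chk_prob(ps$utilities$dm_decrement, "utilities.dm_decrement")
  chk_prob(ps$utilities$dm_annual_decline, "utilities.dm_annual_decline")

  eco <- ps$economics
  if (eco$discount_rate < 0) say("economics.discount_rate: negative")
  if (eco$horizon_cycles < 1) say("economics.horizon_cycles: must be >= 1")
  if (eco$dm_prevalence_at_entry < 0 || eco$dm_prevalence_at_entry > 1)
    say("economics.dm_prevalence_at_entry: outside [0, 1]")
  if (!eco$rate_conversion %in% c("exponential", "identity"))
    say("economics.rate_conversion: must be 'exponential' or 'identity'")
  if (!eco$reward_timing %in% c("start", "half_cycle"))
    say("economics.reward_timing: must be 'start' or 'half_cycle'")
  if (!eco$dm_cost_basis %in% c("matched", "occupancy"))
    say("economics.dm_cost_basis: must be 'matched' or 'occupancy'")

  sa <- sa_parameters(ps)
  bad <- sa$low > sa$base | sa$base > sa$high
  for (id in sa$id[bad])
    say("sa_range.", id, ": base outside [low, high]")

  # treated-rate consistency with the printed treated rows (4 decimals);
  # the PD+DM lambda3 cell is a documented print discrepancy and is skipped
  tp <- ps$rates$treated_printed
  der_pd <- round(derive_treated_rates(ps$rates$pd, ps$effects$multipliers), 4)
  der_dm <- round(derive_treated_rates(ps$rates$pd_dm, ps$effects$multipliers), 4)
  if (any(der_pd != tp$pd))
    say("rates.treated_printed.pd: inconsistent with base rates x multipliers")
  if (any(der_dm[1:2] != tp$pd_dm[1:2]))
    say("rates.treated_printed.pd_dm: inconsistent with base rates x multipliers")
  v
}

#' @export
print.cea_parameters <- function(x, ...) {
  eco <- x$economics
  cat("<cea_parameters>\n")
  cat(sprintf("  cohort %d entering at age %d, %d annual cycles, %.1f%% discount\n",
              as.integer(eco$cohort_size), as.integer(eco$entry_age),
              as.integer(eco$horizon_cycles), 100 * eco$discount_rate))
  cat(sprintf("  DM prevalence at entry %.4f, WTP anchor NT$%s/QALY\n",
              eco$dm_prevalence_at_entry, format(eco$wtp_gdp, big.mark = ",")))
  cat(sprintf("  switches: conversion=%s timing=%s dm_cost_basis=%s\n",
              eco$rate_conversion, eco$reward_timing, eco$dm_cost_basis))
  nv <- length(validate_parameters(x))
  cat(sprintf("  %d registered SA ranges; %d validation violations\n",
              nrow(sa_parameters(x)), nv))
  invisible(x)
}
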