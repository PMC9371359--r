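# shared fixtures, all built in code

paper_ps <- cea_parameters()

# a faster model for structural tests: same inputs, shorter horizon
short_ps <- cea_parameters(economics = list(horizon_cycles = 10L))

conv <- cea_strategy("conventional")
exe <- cea_strategy("exenatide")

# a parameter set where nobody moves: no incidence, no death
frozen_ps <- local({
  ps <- cea_parameters(economics = list(horizon_cycles = 10L))
  for (nm in c("pd", "dm", "pd_dm")) ps$incidence[[nm]]$value[] <- 0
  ps$incidence$dm$low[] <- 0; ps$incidence$dm$high[] <- 0
  ps$incidence$pd$low[!is.na(ps$incidence$pd$low)] <- 0
  ps$incidence$pd$high[!is.na(ps$incidence$pd$high)] <- 0
  ps$incidence$pd_dm$low[!is.na(ps$incidence$pd_dm$low)] <- 0
  ps$incidence$pd_dm$high[!is.na(ps$incidence$pd_dm$high)] <- 0
  ps$mortality$dm$value[] <- 0
  ps$mortality$dm$low[] <- 0; ps$mortality$dm$high[] <- 0
  ps$mortality$dm_exenatide_printed$value[] <- 0
  ps$mortality$dm_exenatide_printed$low[] <- 0
  ps$mortality$dm_exenatide_printed$high[] <- 0
  ps$mortality$other$value[] <- 0
  ps$mortality$other$low[] <- 0; ps$mortality$other$high[] <- 0
  ps$mortality$pd_stage$value[] <- 0
  ps
})

# scale every cost input by a factor, including sensitivity bounds
scale_costs <- function(ps, k) {
  for (nm in c("pd_medical", "pddm_medical", "home_care", "pd_productivity",
               "dm_medical", "dm_productivity")) {
    tab <- ps$costs[[nm]]
    tab$value <- tab$value * k
    tab$low <- tab$low * k
    tab$high <- tab$high * k
    ps$costs[[nm]] <- tab
  }
  ps$costs$exenatide_annual <- ps$costs$exenatide_annual * k
  ps
}
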