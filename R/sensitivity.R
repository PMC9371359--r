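# One-way (tornado) and probabilistic sensitivity analyses over the
# registered parameter ranges. All perturbations are copy-on-write: the base
# parameter set is never mutated, so a full sweep leaves no state behind.

run_icer <- function(ps, wtp, check = TRUE) {
  res <- run_cea(ps, wtp = wtp, check = check)
  res$incremental
}

# the printed stage-utility ranges overlap adjacent stages, so a one-way
# excursion may transiently break the ordinal (strictly decreasing) rule;
# that rule alone is tolerated during excursions, anything else propagates
excursion_check <- function(ps) {
  viol <- validate_parameters(ps)
  hard <- viol[!grepl("strictly decreasing", viol)]
  if (length(hard))
    stop("perturbed run failed validation:\n  - ",
         paste(hard, collapse = "\n  - "))
  invisible(ps)
}

#' One-way sensitivity analysis with tornado ordering
#'
#' Recomputes the full base-case ICER with each registered parameter set to
#' its lower and upper bound in turn, all other parameters held at base.
#' Entries are ordered by the width of the ICER excursion, widest first
#' (ties broken alphabetically by parameter id).
#'
#' @param ps A [cea_parameters()] set.
#' @param wtp Willingness-to-pay anchor (NT$/QALY) for classification.
#' @return A `data.frame` (class `cea_tornado`) with columns `parameter`,
#'   `low`, `high` (the bounds), `icer_low`, `icer_high`, `width`, plus the
#'   base-case ICER in `attr(, "base_icer")`.
#' @export
one_way_tornado <- function(ps, wtp = ps$economics$wtp_gdp) {
  sa <- sa_parameters(ps)
  base_icer <- run_icer(ps, wtp)$icer_per_qaly
  icer_low <- icer_high <- numeric(nrow(sa))
  for (i in seq_len(nrow(sa))) {
    lo <- excursion_check(param_set(ps, sa$id[i], sa$low[i]))
    hi <- excursion_check(param_set(ps, sa$id[i], sa$high[i]))
    icer_low[i] <- run_icer(lo, wtp, check = FALSE)$icer_per_qaly
    icer_high[i] <- run_icer(hi, wtp, check = FALSE)$icer_per_qaly
  }
  out <- data.frame(parameter = sa$id, low = sa$low, high = sa$high,
                    icer_low = icer_low, icer_high = icer_high,
                    width = abs(icer_high - icer_low))
  out <- out[order(-out$width, out$parameter), ]
  rownames(out) <- NULL
  attr(out, "base_icer") <- base_icer
  class(out) <- c("cea_tornado", "data.frame")
  out
}

draw_one <- function(sa, distribution) {
  u <- stats::runif(nrow(sa))
  if (distribution == "uniform") {
    sa$low + u * (sa$high - sa$low)
  } else {  # triangular with mode at the base value
    lo <- sa$low; hi <- sa$high; md <- sa$base
    fc <- (md - lo) / (hi - lo)
    ifelse(u < fc,
           lo + sqrt(u * (hi - lo) * (md - lo)),
           hi - sqrt((1 - u) * (hi - lo) * (hi - md)))
  }
}

apply_draw <- function(ps, sa, values) {
  for (i in seq_len(nrow(sa))) ps <- param_set(ps, sa$id[i], values[i])
  ps
}

#' Probabilistic sensitivity analysis
#'
#' Runs `n` Monte Carlo iterations. Each iteration draws every registered
#' parameter independently from its plausible range (uniform by default,
#' matching the published description of the draws; a triangular mode peaked
#' at the base value is available), re-derives all dependent quantities
#' (treated transition rates from the drawn multipliers, treated DM mortality
#' from the drawn factor), and runs the full two-strategy model. Draws that
#' violate a structural invariant (e.g. non-monotone stage utilities from
#' overlapping ranges) are redrawn and counted.
#'
#' @param ps A [cea_parameters()] set.
#' @param n Number of iterations (published analysis: 1,000).
#' @param seed RNG seed; the result is fully reproducible given `seed`.
#' @param wtp Willingness-to-pay (NT$/QALY) for the per-iteration NMB.
#' @param distribution `"uniform"` or `"triangular"`.
#' @return A `cea_psa` list: `results` (per-iteration `delta_cost`,
#'   `delta_qaly`, `delta_ly`, `icer`, `nmb`), `draws` (n x parameters),
#'   `n`, `seed`, `wtp`, `distribution`, `redraws`.
#' @export
run_psa <- function(ps, n = 1000, seed = 1L, wtp = ps$economics$wtp_gdp,
                    distribution = c("uniform", "triangular")) {
  stopifnot(n >= 1)
  distribution <- match.arg(distribution)
  sa <- sa_parameters(ps)
  set.seed(seed)
  draws <- matrix(NA_real_, n, nrow(sa), dimnames = list(NULL, sa$id))
  res <- data.frame(delta_cost = numeric(n), delta_qaly = numeric(n),
                    delta_ly = numeric(n), icer = numeric(n), nmb = numeric(n))
  redraws <- 0L
  for (i in seq_len(n)) {
    repeat {
      vals <- draw_one(sa, distribution)
      psi <- apply_draw(ps, sa, vals)
      if (length(validate_parameters(psi)) == 0L) break
      redraws <- redraws + 1L
      if (redraws > 100L * n) stop("PSA: too many invalid draws")
    }
    draws[i, ] <- vals
    inc <- run_icer(psi, wtp)
    res$delta_cost[i] <- inc$delta_cost
    res$delta_qaly[i] <- inc$delta_qaly
    res$delta_ly[i] <- inc$delta_ly
    res$icer[i] <- inc$icer_per_qaly
    res$nmb[i] <- inc$nmb
  }
  structure(list(results = res, draws = draws, n = n, seed = seed,
                 wtp = wtp, distribution = distribution, redraws = redraws),
            class = "cea_psa")
}

#' @export
print.cea_psa <- function(x, ...) {
  cat(sprintf("<cea_psa> %d iterations (%s draws, seed %s, %d redraws)\n",
              x$n, x$distribution, format(x$seed), x$redraws))
  cat(sprintf("  P(NMB > 0 at WTP %s) = %.3f\n",
              format(x$wtp, big.mark = ","), mean(x$results$nmb > 0)))
  cat(sprintf("  mean dQALY %.3f, mean dC NT$%s\n",
              mean(x$results$delta_qaly),
              format(round(mean(x$results$delta_cost)), big.mark = ",")))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the probability that the add-on
#' strategy is cost-effective: the fraction of PSA iterations with positive
#' incremental net monetary benefit at that threshold.
#'
#' @param psa A [run_psa()] result.
#' @param wtp_grid Numeric vector of WTP values (NT$/QALY); the default spans
#'   0 to 3x the GDP-per-capita anchor used in the PSA.
#' @return `data.frame` with columns `wtp` and `probability`.
#' @export
ceac <- function(psa, wtp_grid = NULL) {
  stopifnot(inherits(psa, "cea_psa"))
  if (is.null(wtp_grid))
    wtp_grid <- seq(0, 3 * psa$wtp, length.out = 61L)
  if (length(wtp_grid) == 0L) stop("wtp_grid must be non-empty")
  prob <- vapply(wtp_grid, function(w)
    mean(w * psa$results$delta_qaly - psa$results$delta_cost > 0), numeric(1))
  data.frame(wtp = wtp_grid, probability = prob)
}

#' Incremental cost-effectiveness plane
#'
#' @param psa A [run_psa()] result.
#' @return `data.frame` of per-iteration `(delta_qaly, delta_cost)` points;
#'   `attr(, "quadrants")` counts the points per quadrant (NE: more effective
#'   and costlier; SE: more effective and cheaper; NW/SW mirrored), summing
#'   to the iteration count.
#' @export
icer_plane <- function(psa) {
  stopifnot(inherits(psa, "cea_psa"))
  dE <- psa$results$delta_qaly
  dC <- psa$results$delta_cost
  quad <- c(NE = sum(dE > 0 & dC > 0), NW = sum(dE <= 0 & dC > 0),
            SE = sum(dE > 0 & dC <= 0), SW = sum(dE <= 0 & dC <= 0))
  out <- data.frame(delta_qaly = dE, delta_cost = dC)
  attr(out, "quadrants") <- quad
  out
}
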