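# Markov cohort engine: annual-cycle recursion over NGT/IGT/T2D/Dead with
# intervention-effect decay, band-level mortality, and discounted rewards.

#' Scenario definition for a cohort run
#'
#' @param sex \code{"male"} or \code{"female"}.
#' @param start_age Age at cohort entry (years).
#' @param initial Occupancy vector over (NGT, IGT, T2D, Dead); defaults to
#'   84\% NGT, 16\% IGT.
#' @param max_age Age at which the simulation terminates; the residual
#'   alive mass at \code{max_age} contributes its final-cycle rewards only.
#' @return An object of class \code{"t2d_scenario"}.
#' @export
t2d_scenario <- function(sex = c("male", "female"), start_age = 30,
                         initial = c(NGT = 0.84, IGT = 0.16, T2D = 0, Dead = 0),
                         max_age = 100) {
  sex <- match.arg(sex)
  if (length(initial) != 4 || any(initial < 0) || abs(sum(initial) - 1) > 1e-12)
    stop("t2d_scenario: 'initial' must be four non-negative shares summing to 1")
  if (start_age >= max_age)
    stop("t2d_scenario: 'start_age' must be below 'max_age'")
  out <- list(sex = sex, start_age = start_age,
              initial = stats::setNames(as.numeric(initial), ALL_STATES),
              max_age = max_age)
  class(out) <- "t2d_scenario"
  out
}

#' Effect-blended transition matrix for a cycle
#'
#' The intervention achieves its full effect in the first programme year
#' and loses it linearly, so that from the effect horizon onwards both arms
#' share the no-intervention transition probabilities. With horizon
#' \eqn{H}, cycle-year \eqn{t} uses weight
#' \eqn{w = \max(0, (H - t)/(H - 1))} on the difference between the
#' intervention and control probabilities (\eqn{w = 1} in year 1, 0 from
#' year \eqn{H}). With \code{decay = "none"} the full effect applies for
#' years \code{1 .. H-1} and vanishes from year \code{H}.
#'
#' @param cycle_year 1-based year since cohort entry.
#' @param params Parameter bundle.
#' @param arm \code{"control"} or \code{"intervention"}; the control arm
#'   always receives the control matrix.
#' @param effect Effect profile (defaults to \code{params$effect}).
#' @return A [transition_matrix()] whose rows sum to one exactly.
#' @export
blend_transition <- function(cycle_year, params,
                             arm = c("control", "intervention"),
                             effect = params$effect) {
  arm <- match.arg(arm)
  if (cycle_year < 1) stop("blend_transition: 'cycle_year' is 1-based")
  ctrl <- params$transitions$control
  if (arm == "control")
    return(transition_matrix(ctrl$ngt2igt, ctrl$igt2ngt, ctrl$igt2t2d, ctrl$t2d2igt))
  H <- effect$horizon
  w <- if (identical(effect$decay, "linear")) {
    if (H < 2) stop("blend_transition: linear decay requires an effect horizon >= 2")
    max(0, (H - cycle_year) / (H - 1))
  } else {
    as.numeric(cycle_year < H)
  }
  intv <- params$transitions$intervention
  bl <- function(nm) ctrl[[nm]] + w * (intv[[nm]] - ctrl[[nm]])
  transition_matrix(bl("ngt2igt"), bl("igt2ngt"), bl("igt2t2d"), bl("t2d2igt"))
}

#' Embed mortality into an alive-state transition matrix
#'
#' Expands the 3x3 alive-state matrix to the full four-state matrix by
#' scaling each alive row's glycaemic transitions by the state-specific
#' survival probability and routing the complement to Dead: NGT and IGT die
#' with the non-diabetes probability \code{mr}, T2D with
#' \code{mr + t2d2d}. Dead is absorbing.
#'
#' @param alive_matrix A 3x3 [transition_matrix()].
#' @param mortality A [mortality_model()].
#' @param age Current age (years), used to look up the age band.
#' @param sex \code{"male"} or \code{"female"}.
#' @return A 4x4 row-stochastic matrix over (NGT, IGT, T2D, Dead).
#' @export
embed_mortality <- function(alive_matrix, mortality, age, sex) {
  d <- state_death_probs(mortality, age, sex)
  P <- matrix(0, 4, 4, dimnames = list(from = ALL_STATES, to = ALL_STATES))
  for (i in 1:3) {
    P[i, 1:3] <- alive_matrix[i, ] * (1 - d[i])
    P[i, 4] <- d[i]
  }
  P[4, 4] <- 1
  P
}

#' Per-cycle intervention cost
#'
#' Programme costs accrue only while participants attend: the full year-1
#' total (screening, course and first-year follow-up) in cycle-year 1, the
#' follow-up total in years 2 through the participation horizon, and zero
#' afterwards.
#'
#' @param cycle_year 1-based year since cohort entry.
#' @param schedule A [intervention_cost_schedule()].
#' @param effect Effect profile supplying \code{participation_years}
#'   (defaults to the schedule's own value).
#' @return Cost in EUR for that cycle-year, per participating person.
#' @export
intervention_cost_stream <- function(cycle_year, schedule, effect = NULL) {
  if (cycle_year < 1) stop("intervention_cost_stream: 'cycle_year' is 1-based")
  yrs <- if (!is.null(effect)) effect$participation_years else schedule$participation_years
  if (cycle_year == 1 && yrs >= 1) schedule$year1_total
  else if (cycle_year <= yrs) schedule$followup_total
  else 0
}

#' Run the cohort recursion for one arm
#'
#' Propagates the occupancy vector annually from \code{start_age} to
#' \code{max_age}. In each cycle \eqn{t} (0-based) the current occupancy
#' accrues state costs, the arm's programme cost (paid by the alive
#' fraction), and utilities, discounted by \eqn{(1+r)^{-t}}; rewards accrue
#' at cycle start with no half-cycle correction. The dead state carries
#' zero cost and zero utility.
#'
#' @param scenario A [t2d_scenario()].
#' @param arm \code{"control"} or \code{"intervention"}.
#' @param params Parameter bundle.
#' @param mortality A [mortality_model()].
#' @param keep_trace Keep the per-cycle trace (default \code{TRUE}).
#' @return An object of class \code{"cohort_sim"}: discounted and
#'   undiscounted totals plus (optionally) a per-cycle trace with columns
#'   \code{cycle, age, share_ngt, share_igt, share_t2d, share_dead,
#'   cycle_cost, cycle_qalys, discount_factor}.
#' @export
simulate_cohort <- function(scenario, arm = c("control", "intervention"),
                            params, mortality, keep_trace = TRUE) {
  arm <- match.arg(arm)
  stopifnot(inherits(scenario, "t2d_scenario"), inherits(mortality, "mortality_model"))
  occ <- scenario$initial
  costs <- params$costs
  u <- params$utilities[[scenario$sex]]
  rc <- params$discount[["costs"]]
  rq <- params$discount[["qalys"]]
  sched <- params$intervention_cost
  n_cycles <- scenario$max_age - scenario$start_age + 1L

  tr <- if (keep_trace) matrix(NA_real_, n_cycles, 9) else NULL
  cost_d <- qaly_d <- cost_u <- qaly_u <- 0
  for (t in 0:(n_cycles - 1L)) {
    age <- scenario$start_age + t
    cyc_year <- t + 1L
    ic <- if (arm == "intervention")
      intervention_cost_stream(cyc_year, sched, params$effect) else 0
    cyc_cost <- sum(occ[1:3] * costs) + ic * (1 - occ[[4]])
    cyc_qaly <- sum(occ[1:3] * u)
    dfc <- (1 + rc)^(-t); dfq <- (1 + rq)^(-t)
    cost_d <- cost_d + dfc * cyc_cost
    qaly_d <- qaly_d + dfq * cyc_qaly
    cost_u <- cost_u + cyc_cost
    qaly_u <- qaly_u + cyc_qaly
    if (keep_trace) tr[t + 1L, ] <- c(t, age, occ, cyc_cost, cyc_qaly, dfq)
    if (t < n_cycles - 1L) {
      P <- embed_mortality(blend_transition(cyc_year, params, arm),
                           mortality, age, scenario$sex)
      occ <- as.numeric(occ %*% P)
      names(occ) <- ALL_STATES
    }
  }
  if (keep_trace) {
    tr <- as.data.frame(tr)
    names(tr) <- c("cycle", "age", "share_ngt", "share_igt", "share_t2d",
                   "share_dead", "cycle_cost", "cycle_qalys", "discount_factor")
  }
  out <- list(arm = arm, scenario = scenario,
              discounted_cost = cost_d, discounted_qalys = qaly_d,
              undiscounted_cost = cost_u, undiscounted_qalys = qaly_u,
              trace = tr)
  class(out) <- "cohort_sim"
  out
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat(sprintf("Cohort simulation: %s arm, %s, entry age %d, horizon to %d\n",
              x$arm, x$scenario$sex, x$scenario$start_age, x$scenario$max_age))
  cat(sprintf("  discounted   cost %12.2f EUR   QALYs %8.4f\n",
              x$discounted_cost, x$discounted_qalys))
  cat(sprintf("  undiscounted cost %12.2f EUR   QALYs %8.4f\n",
              x$undiscounted_cost, x$undiscounted_qalys))
  invisible(x)
}

#' Export a cohort trace to CSV
#'
#' @param sim A \code{"cohort_sim"} with a trace.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_trace_csv <- function(sim, path) {
  stopifnot(inherits(sim, "cohort_sim"))
  if (is.null(sim$trace)) stop("write_trace_csv: simulation was run without a trace")
  utils::write.csv(sim$trace, path, row.names = FALSE)
  invisible(path)
}
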