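# Individual-level microsimulation: an independent Monte-Carlo route to the
# same quantities the cohort recursion computes analytically. Used as a
# validation oracle — the cohort engine's discounted totals must agree with
# the microsimulation mean within Monte-Carlo error.

#' Individual-level microsimulation of one arm
#'
#' Simulates \code{n} individuals through the same annual-cycle process as
#' [simulate_cohort()]: initial states are drawn from the scenario's
#' initial distribution, each cycle accrues state cost, programme cost
#' (alive individuals only, intervention arm) and utility discounted by
#' \eqn{(1+r)^{-t}}, and the next state is drawn from the same four-state
#' transition matrix the cohort engine uses for that cycle.
#'
#' By the law of large numbers the mean discounted cost and QALYs converge
#' to the cohort values; the function also returns their Monte-Carlo
#' standard errors.
#'
#' @param scenario A [t2d_scenario()].
#' @param arm \code{"control"} or \code{"intervention"}.
#' @param params Parameter bundle.
#' @param mortality A [mortality_model()].
#' @param n Number of simulated individuals.
#' @param seed Optional integer seed.
#' @return A list with \code{cost}, \code{qalys} (means over individuals),
#'   \code{se_cost}, \code{se_qalys}, and \code{n}.
#' @export
microsimulate_cohort <- function(scenario, arm = c("control", "intervention"),
                                 params, mortality, n = 50000L, seed = NULL) {
  arm <- match.arg(arm)
  if (!is.null(seed)) set.seed(seed)
  state <- sample.int(4L, n, replace = TRUE, prob = scenario$initial)
  costs4 <- c(params$costs, Dead = 0)
  u4 <- c(params$utilities[[scenario$sex]], Dead = 0)
  rc <- params$discount[["costs"]]
  rq <- params$discount[["qalys"]]
  sched <- params$intervention_cost
  n_cycles <- scenario$max_age - scenario$start_age + 1L

  cost_i <- numeric(n); qaly_i <- numeric(n)
  for (t in 0:(n_cycles - 1L)) {
    age <- scenario$start_age + t
    cyc_year <- t + 1L
    ic <- if (arm == "intervention")
      intervention_cost_stream(cyc_year, sched, params$effect) else 0
    alive <- state != 4L
    cost_i <- cost_i + (1 + rc)^(-t) * (costs4[state] + ic * alive)
    qaly_i <- qaly_i + (1 + rq)^(-t) * u4[state]
    if (t < n_cycles - 1L) {
      P <- embed_mortality(blend_transition(cyc_year, params, arm),
                           mortality, age, scenario$sex)
      cum <- t(apply(P, 1, cumsum))
      r <- stats::runif(n)
      state <- 1L + (r > cum[state, 1L]) + (r > cum[state, 2L]) + (r > cum[state, 3L])
    }
  }
  list(cost = mean(cost_i), qalys = mean(qaly_i),
       se_cost = stats::sd(cost_i) / sqrt(n),
       se_qalys = stats::sd(qaly_i) / sqrt(n),
       n = n)
}
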