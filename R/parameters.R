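#' @keywords internal
"_PACKAGE"

# Alive-state and full-state labels used throughout the package.
ALIVE_STATES <- c("NGT", "IGT", "T2D")
ALL_STATES <- c("NGT", "IGT", "T2D", "Dead")

#' One-year transition matrix among the alive glycaemic states
#'
#' Builds the 3x3 row-stochastic matrix over NGT, IGT and T2D from the four
#' annual transition probabilities that define the model. The two remaining
#' transitions (NGT to T2D and T2D back to NGT) are structural zeros: the
#' model assumes diabetes develops and remits only through impaired glucose
#' tolerance. Stay probabilities are the row residuals, so each row sums to
#' one exactly.
#'
#' @param ngt2igt Annual probability of moving from NGT to IGT.
#' @param igt2ngt Annual probability of reverting from IGT to NGT.
#' @param igt2t2d Annual probability of progressing from IGT to T2D.
#' @param t2d2igt Annual probability of remission from T2D to IGT.
#' @return A 3x3 matrix of class \code{"transition_matrix"} with dimnames
#'   \code{NGT/IGT/T2D}.
#' @examples
#' transition_matrix(0.163, 0.162, 0.06, 0.005)  # no-intervention arm
#' @export
transition_matrix <- function(ngt2igt, igt2ngt, igt2t2d, t2d2igt) {
  p <- c(ngt2igt = ngt2igt, igt2ngt = igt2ngt, igt2t2d = igt2t2d, t2d2igt = t2d2igt)
  bad <- names(p)[!is.finite(p) | p < 0 | p > 1]
  if (length(bad))
    stop("transition_matrix: probabilities outside [0, 1]: ",
         paste(sprintf("%s = %g", bad, p[bad]), collapse = ", "))
  if (igt2ngt + igt2t2d > 1)
    stop("transition_matrix: igt2ngt + igt2t2d = ", igt2ngt + igt2t2d,
         " exceeds 1; the IGT row residual would be negative")
  m <- matrix(0, 3, 3, dimnames = list(from = ALIVE_STATES, to = ALIVE_STATES))
  m["NGT", "IGT"] <- ngt2igt
  m["IGT", "NGT"] <- igt2ngt
  m["IGT", "T2D"] <- igt2t2d
  m["T2D", "IGT"] <- t2d2igt
  diag(m) <- 1 - rowSums(m)
  class(m) <- c("transition_matrix", class(m))
  m
}

#' Derive the IGT utility from the NGT utility
#'
#' The utility weight for impaired glucose tolerance is defined as a 1\%
#' decrement from the NGT weight, rounded to three decimals (the precision
#' at which utility weights are reported).
#'
#' @param u_ngt NGT utility weight in (0, 1].
#' @return The IGT utility weight.
#' @examples
#' derive_uigt(0.772)  # 0.764 (men)
#' derive_uigt(0.747)  # 0.740 (women)
#' @export
derive_uigt <- function(u_ngt) {
  if (!is.numeric(u_ngt) || any(u_ngt <= 0) || any(u_ngt > 1))
    stop("derive_uigt: 'u_ngt' must lie in (0, 1]")
  round(0.99 * u_ngt, 3)
}

#' Itemised intervention cost schedule
#'
#' Builds the per-participant cost schedule of the lifestyle programme from
#' its itemised components: screening (folder preparation and mailing,
#' apportioned over the participants recruited), the eight-week group
#' course, yearly follow-up mentoring, and participant transportation.
#' All amounts are 2007 EUR. Internally full precision is kept; rounding to
#' cents happens only when printing or exporting.
#'
#' The default arguments reproduce the programme analysed by the model:
#' 244 information folders at EUR 24.15 recruit 52 participants; the course
#' bundles hotline, mentoring, newsletters, journals, data collection,
#' postage and 26 prevention-manager hours at EUR 32 split over a group of
#' ten; follow-up repeats the mentoring items with four events per year and
#' 124/3 manager hours. \code{followup_year1} is the follow-up portion of
#' the first programme year (the course occupies its first weeks), a
#' published summary figure with no itemised build-up.
#'
#' @param folder_cost Cost of one information folder (EUR).
#' @param n_folders Folders prepared and mailed.
#' @param n_recruited Participants recruited by the mailing.
#' @param course_items Named numeric vector of per-person course components.
#' @param followup_items Named numeric vector of per-person yearly follow-up
#'   components.
#' @param course_trips,followup_trips Round trips to educational locations
#'   per year for the course and for follow-up events.
#' @param trip_cost Cost of one round trip (EUR).
#' @param followup_year1 Follow-up cost (incl. transportation) falling in
#'   year 1 (EUR).
#' @param participation_years Years during which programme costs accrue.
#' @return An object of class \code{"cost_schedule"} with components
#'   \code{screening}, \code{course}, \code{followup} (annual, excl.
#'   transport), \code{course_total}/\code{followup_total} (incl.
#'   transport), \code{year1_total} and \code{annualised}.
#' @export
intervention_cost_schedule <- function(folder_cost = 24.15,
                                       n_folders = 244,
                                       n_recruited = 52,
                                       course_items = c(
                                         phone_hotline  = 3.80,
                                         email_mentoring = 3.80,
                                         newsletter     = 8 * 1.75,
                                         journal        = 2 * 1.68,
                                         data_collection = 2 * 0.15,
                                         postage        = 2 * 0.35,
                                         manager        = 26 * 32 / 10),
                                       followup_items = c(
                                         phone_hotline  = 2 * 3.80,
                                         email_mentoring = 2 * 3.80,
                                         newsletter     = 12 * 0.90,
                                         journal        = 4 * 1.49,
                                         data_collection = 2 * 0.15,
                                         postage        = 4 * 0.35,
                                         events         = 4 * 45 / 10,
                                         manager        = (124 / 3) * 32 / 10),
                                       course_trips = 8,
                                       followup_trips = 2,
                                       trip_cost = 2 * 5 * 0.30,
                                       followup_year1 = 143.95,
                                       participation_years = 5) {
  if (folder_cost < 0 || trip_cost < 0 || followup_year1 < 0 ||
      any(course_items < 0) || any(followup_items < 0))
    stop("intervention_cost_schedule: cost components must be non-negative")
  if (n_recruited <= 0) stop("intervention_cost_schedule: 'n_recruited' must be positive")
  screening <- folder_cost * n_folders / n_recruited
  course <- sum(course_items)
  followup <- sum(followup_items)
  course_total <- course + course_trips * trip_cost
  followup_total <- followup + followup_trips * trip_cost
  out <- list(
    screening = screening,
    course = course,
    course_total = course_total,
    followup = followup,
    followup_total = followup_total,
    followup_year1 = followup_year1,
    year1_total = screening + course_total + followup_year1,
    participation_years = participation_years,
    items = list(course = course_items, followup = followup_items,
                 folder_cost = folder_cost, n_folders = n_folders,
                 n_recruited = n_recruited, trip_cost = trip_cost,
                 course_trips = course_trips, followup_trips = followup_trips)
  )
  out$annualised <- (out$year1_total +
                       (participation_years - 1) * followup_total) / participation_years
  class(out) <- "cost_schedule"
  out
}

#' @export
print.cost_schedule <- function(x, ...) {
  cat("Intervention cost schedule (EUR per participant, 2007)\n")
  cat(sprintf("  screening                     %9.2f\n", x$screening))
  cat(sprintf("  course incl. transportation   %9.2f\n", x$course_total))
  cat(sprintf("  follow-up in year 1           %9.2f\n", x$followup_year1))
  cat(sprintf("  total, year 1                 %9.2f\n", x$year1_total))
  cat(sprintf("  total, each follow-up year    %9.2f\n", x$followup_total))
  cat(sprintf("  annualised over %d years       %9.2f\n",
              x$participation_years, x$annualised))
  invisible(x)
}

#' Default model parameter bundle
#'
#' Assembles the full base-case parameter set of the model: one-year
#' transition matrices for the no-intervention and intervention arms, the
#' intervention-effect profile (full effect in year 1, linear decay to zero
#' at the effect horizon), annual health-state costs, the itemised
#' intervention cost schedule, sex-specific utility weights, discount
#' rates, the initial cohort distribution, and the sampling distributions
#' used by probabilistic sensitivity analysis.
#'
#' Derived defaults follow the model's published conventions: the IGT cost
#' is 46\% of the T2D cost, the IGT utility is a 1\% decrement from the NGT
#' utility, cost distributions are Gamma with SE equal to the mean, and
#' probability/utility distributions are Beta fitted by the method of
#' moments.
#'
#' @return An object of class \code{"t2d_parameters"}.
#' @examples
#' p <- default_parameters()
#' p$transitions$control
#' @export
default_parameters <- function() {
  c_t2d <- 5861.92
  c_igt <- 0.46 * c_t2d          # 2696.48
  c_ngt <- 1744.21
  u <- list(
    male   = c(NGT = 0.772, IGT = derive_uigt(0.772), T2D = 0.724),
    female = c(NGT = 0.747, IGT = derive_uigt(0.747), T2D = 0.701)
  )
  sched <- intervention_cost_schedule()
  dists <- list(
    ngt2igt = dist_spec("beta", 0.163, 0.037),
    igt2ngt = dist_spec("beta", 0.162, 0.037),
    igt2t2d = dist_spec("beta", 0.062, 0.024),
    t2d2igt = dist_spec("beta", 0.005, 0.007),
    cNGT = dist_spec("gamma", c_ngt, c_ngt),
    cIGT = dist_spec("gamma", c_igt, c_igt),
    cT2D = dist_spec("gamma", c_t2d, c_t2d),
    intervention_cost = dist_spec("gamma", 230.03, 230.03),
    uNGT_male = dist_spec("beta", 0.772, 0.004),
    uNGT_female = dist_spec("beta", 0.747, 0.004),
    uIGT_male = dist_spec("beta", 0.764, 0.006),
    uIGT_female = dist_spec("beta", 0.740, 0.006),
    uT2D_male = dist_spec("beta", 0.724, 0.010),
    uT2D_female = dist_spec("beta", 0.701, 0.010)
  )
  params <- list(
    transitions = list(
      control = list(ngt2igt = 0.163, igt2ngt = 0.162, igt2t2d = 0.06, t2d2igt = 0.005),
      intervention = list(ngt2igt = 0.152, igt2ngt = 0.177, igt2t2d = 0.03, t2d2igt = 0.005)
    ),
    effect = list(horizon = 7, participation_years = 5, decay = "linear"),
    costs = c(NGT = c_ngt, IGT = c_igt, T2D = c_t2d),
    intervention_cost = sched,
    utilities = u,
    discount = c(costs = 0.03, qalys = 0.03),
    initial = c(NGT = 0.84, IGT = 0.16, T2D = 0, Dead = 0),
    distributions = dists,
    psa = list(intervention_sampling = "ratio")
  )
  class(params) <- "t2d_parameters"
  validate_parameters(params)
  params
}

#' Validate a parameter bundle
#'
#' Checks every structural invariant of the bundle and reports all
#' violations at once (rather than stopping at the first), which makes
#' configuration errors in a long file diagnosable in one pass.
#'
#' @param params A parameter bundle as returned by [default_parameters()]
#'   or [load_config()].
#' @return The bundle, invisibly, if valid; otherwise an error listing
#'   every violated invariant.
#' @export
validate_parameters <- function(params) {
  errs <- character(0)
  push <- function(msg) errs <<- c(errs, msg)

  for (arm in c("control", "intervention")) {
    tr <- params$transitions[[arm]]
    for (nm in c("ngt2igt", "igt2ngt", "igt2t2d", "t2d2igt")) {
      v <- tr[[nm]]
      if (is.null(v) || !is.finite(v) || v < 0 || v > 1)
        push(sprintf("transitions$%s$%s: probability outside [0, 1] (%s)",
                     arm, nm, format(v)))
    }
    s <- tr$igt2ngt + tr$igt2t2d
    if (is.finite(s) && s > 1)
      push(sprintf("transitions$%s: igt2ngt + igt2t2d = %g > 1 (negative IGT residual)",
                   arm, s))
  }
  if (!is.numeric(params$costs) || length(params$costs) != 3 || any(params$costs < 0))
    push("costs: must be three non-negative values (NGT, IGT, T2D)")
  for (sx in c("male", "female")) {
    uu <- params$utilities[[sx]]
    if (is.null(uu) || length(uu) != 3 || any(uu < 0) || any(uu > 1)) {
      push(sprintf("utilities$%s: must be three weights in [0, 1]", sx))
    } else if (!(uu["T2D"] <= uu["IGT"] && uu["IGT"] <= uu["NGT"]))
      push(sprintf("utilities$%s: ordering uT2D <= uIGT <= uNGT violated", sx))
  }
  dr <- params$discount
  if (!is.numeric(dr) || length(dr) != 2 || any(dr < 0) || any(dr > 0.2))
    push("discount: rates must lie in [0, 0.2]")
  init <- params$initial
  if (!is.numeric(init) || length(init) != 4 || any(init < 0) ||
      abs(sum(init) - 1) > 1e-12)
    push("initial: occupancy must be four non-negative shares summing to 1")
  ef <- params$effect
  if (is.null(ef$horizon) || ef$horizon < 1)
    push("effect$horizon: must be >= 1")
  if (identical(ef$decay, "linear") && ef$horizon < 2)
    push("effect: linear decay requires horizon >= 2")
  if (is.null(ef$participation_years) || ef$participation_years < 0)
    push("effect$participation_years: must be >= 0")
  if (!inherits(params$intervention_cost, "cost_schedule"))
    push("intervention_cost: not a cost_schedule object")

  if (length(errs))
    stop("invalid parameter bundle:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  invisible(params)
}

#' @export
print.t2d_parameters <- function(x, ...) {
  tc <- x$transitions$control; ti <- x$transitions$intervention
  cat("Four-state Markov model parameters (annual cycle)\n")
  cat(sprintf("  transitions (intervention / control): ngt2igt %.3f/%.3f, igt2ngt %.3f/%.3f,\n",
              ti$ngt2igt, tc$ngt2igt, ti$igt2ngt, tc$igt2ngt))
  cat(sprintf("    igt2t2d %.3f/%.3f, t2d2igt %.3f/%.3f\n",
              ti$igt2t2d, tc$igt2t2d, ti$t2d2igt, tc$t2d2igt))
  cat(sprintf("  effect: %s decay over horizon %d y, programme costs for %d y\n",
              x$effect$decay, x$effect$horizon, x$effect$participation_years))
  cat(sprintf("  state costs (EUR/y): NGT %.2f, IGT %.2f, T2D %.2f\n",
              x$costs["NGT"], x$costs["IGT"], x$costs["T2D"]))
  cat(sprintf("  utilities m/f: NGT %.3f/%.3f, IGT %.3f/%.3f, T2D %.3f/%.3f\n",
              x$utilities$male["NGT"], x$utilities$female["NGT"],
              x$utilities$male["IGT"], x$utilities$female["IGT"],
              x$utilities$male["T2D"], x$utilities$female["T2D"]))
  cat(sprintf("  discount: %.1f%% costs, %.1f%% QALYs; initial NGT/IGT/T2D: %.2f/%.2f/%.2f\n",
              100 * x$discount["costs"], 100 * x$discount["qalys"],
              x$initial[1], x$initial[2], x$initial[3]))
  invisible(x)
}

#' Arm transition matrices from a parameter bundle
#'
#' @param params Parameter bundle.
#' @param arm \code{"control"} or \code{"intervention"}.
#' @return A [transition_matrix()].
#' @export
arm_matrix <- function(params, arm = c("control", "intervention")) {
  arm <- match.arg(arm)
  tr <- params$transitions[[arm]]
  transition_matrix(tr$ngt2igt, tr$igt2ngt, tr$igt2t2d, tr$t2d2igt)
}
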