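# Probabilistic sensitivity analysis: Monte-Carlo parameter sampling and
# paired-arm evaluation producing the incremental draw set behind the CEAC.

# Fixed draw order so that a given seed always consumes random numbers
# identically: transitions, costs, utilities.
PSA_TRANSITIONS <- c("ngt2igt", "igt2ngt", "igt2t2d", "t2d2igt")
PSA_COSTS <- c("cNGT", "cIGT", "cT2D", "intervention_cost")

#' Draw one sampled parameter bundle
#'
#' Samples the no-intervention transition probabilities from their Beta
#' distributions, state and programme costs from their Gamma
#' distributions, and sex-specific utilities from their Beta
#' distributions; stay probabilities are recomputed as row residuals.
#' Draws that would make the IGT row residual negative are rejected and
#' redrawn (up to \code{max_tries}).
#'
#' Intervention-arm transitions carry no published distributions; by
#' default (\code{intervention_sampling = "ratio"}) each control draw is
#' multiplied by the deterministic intervention/control ratio, preserving
#' the relative effect while sampling baseline uncertainty. With
#' \code{"independent"} they are drawn from Betas centred on the
#' intervention means with the control standard errors.
#'
#' The programme cost draw scales the whole cost schedule by
#' \code{draw / annualised}, preserving its year-1/follow-up shape.
#' Degenerate specifications (\code{se = 0}) return their mean, so a fully
#' degenerate bundle reproduces the deterministic parameters exactly.
#'
#' @param params Parameter bundle with \code{distributions}.
#' @param max_tries Rejection-sampling bound for infeasible rows.
#' @return A list: \code{params} (the sampled bundle, usable anywhere a
#'   deterministic bundle is) and \code{draws} (named numeric vector of
#'   the sampled values).
#' @export
sample_parameters <- function(params, max_tries = 100L) {
  d <- params$distributions
  sampling <- params$psa$intervention_sampling %||% "ratio"
  ctrl_det <- params$transitions$control
  int_det <- params$transitions$intervention

  ok <- FALSE
  for (i in seq_len(max_tries)) {
    ctrl <- vapply(PSA_TRANSITIONS, function(nm) draw_dist(d[[nm]]), numeric(1))
    intv <- if (sampling == "ratio") {
      vapply(PSA_TRANSITIONS, function(nm) {
        det <- ctrl_det[[nm]]
        ratio <- if (det > 0) int_det[[nm]] / det else 0
        ctrl[[nm]] * ratio
      }, numeric(1))
    } else {
      vapply(PSA_TRANSITIONS, function(nm) {
        spec <- d[[nm]]
        if (spec$se == 0) return(int_det[[nm]])
        draw_dist(dist_spec("beta", int_det[[nm]], spec$se))
      }, numeric(1))
    }
    feasible <- all(ctrl >= 0 & ctrl <= 1) && all(intv >= 0 & intv <= 1) &&
      ctrl[["igt2ngt"]] + ctrl[["igt2t2d"]] <= 1 &&
      intv[["igt2ngt"]] + intv[["igt2t2d"]] <= 1
    if (feasible) { ok <- TRUE; break }
  }
  if (!ok)
    stop("sample_parameters: no feasible transition rows after ", max_tries, " draws")

  cost_draws <- vapply(PSA_COSTS, function(nm) draw_dist(d[[nm]]), numeric(1))
  udraw <- list()
  for (sx in SEXES) {
    udraw[[sx]] <- c(
      NGT = draw_dist(d[[paste0("uNGT_", sx)]]),
      IGT = draw_dist(d[[paste0("uIGT_", sx)]]),
      T2D = draw_dist(d[[paste0("uT2D_", sx)]]))
  }

  sampled <- params
  sampled$transitions$control[PSA_TRANSITIONS] <- as.list(ctrl)
  sampled$transitions$intervention[PSA_TRANSITIONS] <- as.list(intv)
  sampled$costs <- c(NGT = cost_draws[["cNGT"]], IGT = cost_draws[["cIGT"]],
                     T2D = cost_draws[["cT2D"]])
  sampled$utilities <- udraw
  scale <- cost_draws[["intervention_cost"]] / params$intervention_cost$annualised
  sched <- params$intervention_cost
  for (f in c("screening", "course", "course_total", "followup", "followup_total",
              "followup_year1", "year1_total", "annualised"))
    sched[[f]] <- sched[[f]] * scale
  sampled$intervention_cost <- sched

  draws <- c(ctrl, cost_draws,
             stats::setNames(udraw$male, paste0("u", names(udraw$male), "_male")),
             stats::setNames(udraw$female, paste0("u", names(udraw$female), "_female")))
  list(params = sampled, draws = draws)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a probabilistic sensitivity analysis
#'
#' Per draw, both arms are simulated with the same sampled parameter
#' record (common random parameters, as the CEAC interpretation requires)
#' and the incremental cost/QALY pair is stored together with every
#' sampled value.
#'
#' @param scenario A [t2d_scenario()].
#' @param params Parameter bundle.
#' @param mortality A [mortality_model()] (mortality is not sampled).
#' @param n_draws Number of Monte-Carlo draws (default 10,000).
#' @param seed Integer seed; recorded in the result. \code{NULL} leaves
#'   the RNG state untouched.
#' @return An object of class \code{"t2d_psa"}: \code{draws} (data frame,
#'   one row per draw with the sampled parameters, \code{delta_cost} and
#'   \code{delta_qalys}), \code{seed}, \code{n_draws}, \code{scenario}.
#' @export
run_psa <- function(scenario, params, mortality, n_draws = 10000L, seed = NULL) {
  stopifnot(n_draws >= 1)
  if (!is.null(seed)) set.seed(seed)
  rows <- vector("list", n_draws)
  for (i in seq_len(n_draws)) {
    s <- sample_parameters(params)
    ctl <- simulate_cohort(scenario, "control", s$params, mortality, keep_trace = FALSE)
    trt <- simulate_cohort(scenario, "intervention", s$params, mortality, keep_trace = FALSE)
    rows[[i]] <- c(s$draws,
                   delta_cost = trt$discounted_cost - ctl$discounted_cost,
                   delta_qalys = trt$discounted_qalys - ctl$discounted_qalys)
  }
  draws <- as.data.frame(do.call(rbind, rows))
  out <- list(draws = draws, seed = seed, n_draws = n_draws, scenario = scenario)
  class(out) <- "t2d_psa"
  out
}

#' @export
print.t2d_psa <- function(x, ...) {
  cat(sprintf("PSA: %d draws (%s, entry age %d)%s\n", x$n_draws,
              x$scenario$sex, x$scenario$start_age,
              if (is.null(x$seed)) "" else sprintf(", seed %d", x$seed)))
  cat(sprintf("  mean dCost %.2f EUR, mean dQALYs %.5f\n",
              mean(x$draws$delta_cost), mean(x$draws$delta_qalys)))
  cat(sprintf("  P(cost-saving) %.3f\n", mean(x$draws$delta_cost < 0)))
  invisible(x)
}

#' CEAC from a PSA result
#'
#' @param psa A \code{"t2d_psa"} object.
#' @param wtp Willingness-to-pay grid (see [ceac()]).
#' @return A \code{"ceac"} data frame.
#' @export
psa_ceac <- function(psa, wtp = seq(0, 50000, by = 1000)) {
  stopifnot(inherits(psa, "t2d_psa"))
  ceac(psa$draws$delta_cost, psa$draws$delta_qalys, wtp)
}

#' Write PSA draws to CSV
#'
#' One row per draw with all sampled parameters (probabilities
#' dimensionless, costs EUR/year, utilities per year) and the incremental
#' cost (EUR) and QALYs.
#'
#' @param psa A \code{"t2d_psa"} object.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_psa_csv <- function(psa, path) {
  stopifnot(inherits(psa, "t2d_psa"))
  utils::write.csv(psa$draws, path, row.names = FALSE)
  invisible(path)
}
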