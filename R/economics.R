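# Incremental cost-effectiveness statistics, acceptability curves, and
# deterministic one-way sensitivity analyses.

#' Incremental cost-effectiveness ratio with dominance classification
#'
#' Computes the incremental cost and QALYs of the intervention arm over the
#' control arm and their ratio. A bare negative ratio is ambiguous (it
#' arises both when the intervention saves money and gains health and in
#' the opposite corner), so the result always carries the quadrant of the
#' cost-effectiveness plane. When the QALY difference is zero the ratio is
#' undefined and reported as \code{NA}.
#'
#' @param control,intervention \code{"cohort_sim"} results for the two arms
#'   of the same scenario.
#' @return An object of class \code{"icer_result"} with
#'   \code{delta_cost}, \code{delta_qalys}, \code{icer} and
#'   \code{quadrant} (one of \code{"cost-saving-more-effective"},
#'   \code{"trade-off"}, \code{"dominated"},
#'   \code{"less-costly-less-effective"}).
#' @export
icer <- function(control, intervention) {
  stopifnot(inherits(control, "cohort_sim"), inherits(intervention, "cohort_sim"))
  if (control$arm != "control" || intervention$arm != "intervention")
    stop("icer: pass the control-arm result first, the intervention-arm result second")
  sc <- control$scenario; si <- intervention$scenario
  if (!identical(sc[c("sex", "start_age", "max_age")], si[c("sex", "start_age", "max_age")]))
    stop("icer: the two results come from different scenarios")
  dc <- intervention$discounted_cost - control$discounted_cost
  dq <- intervention$discounted_qalys - control$discounted_qalys
  quadrant <- if (dq > 0 && dc < 0) "cost-saving-more-effective"
  else if (dq > 0) "trade-off"
  else if (dq < 0 && dc > 0) "dominated"
  else if (dq < 0) "less-costly-less-effective"
  else if (dc > 0) "dominated"
  else if (dc < 0) "less-costly-less-effective"
  else "trade-off"
  out <- list(delta_cost = dc, delta_qalys = dq,
              icer = if (dq != 0) dc / dq else NA_real_,
              quadrant = quadrant)
  class(out) <- "icer_result"
  out
}

#' @export
print.icer_result <- function(x, ...) {
  cat(sprintf("Incremental result: dCost %.2f EUR, dQALYs %.5f (%s)\n",
              x$delta_cost, x$delta_qalys, x$quadrant))
  if (is.na(x$icer)) cat("  ICER undefined (zero QALY difference)\n")
  else cat(sprintf("  ICER %.0f EUR/QALY\n", x$icer))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value \eqn{\lambda} on the grid, the
#' probability that the intervention is cost-effective is the fraction of
#' draws with strictly positive incremental net monetary benefit
#' \eqn{\lambda \Delta Q - \Delta C > 0}; ties count as not cost-effective.
#'
#' @param delta_cost,delta_qalys Per-draw incremental costs and QALYs
#'   (equal length).
#' @param wtp Strictly increasing willingness-to-pay grid (EUR/QALY);
#'   default 0 to 50,000 in steps of 1,000.
#' @return A data frame of class \code{"ceac"} with columns \code{wtp} and
#'   \code{probability}; the number of draws is kept in attribute
#'   \code{"n_draws"}.
#' @export
ceac <- function(delta_cost, delta_qalys, wtp = seq(0, 50000, by = 1000)) {
  if (length(delta_cost) != length(delta_qalys))
    stop("ceac: 'delta_cost' and 'delta_qalys' must have equal length")
  if (length(delta_cost) < 1) stop("ceac: at least one draw is required")
  if (length(wtp) < 1) stop("ceac: empty willingness-to-pay grid")
  if (is.unsorted(wtp, strictly = TRUE))
    stop("ceac: 'wtp' must be strictly increasing")
  prob <- vapply(wtp, function(l) mean(l * delta_qalys - delta_cost > 0), numeric(1))
  out <- data.frame(wtp = wtp, probability = prob)
  class(out) <- c("ceac", "data.frame")
  attr(out, "n_draws") <- length(delta_cost)
  out
}

#' @export
plot.ceac <- function(x, ...) {
  graphics::plot(x$wtp, x$probability, type = "l", ylim = c(0, 1),
                 xlab = "Willingness to pay (EUR/QALY)",
                 ylab = "P(intervention cost-effective)", ...)
  graphics::abline(h = 0.5, lty = 3, col = "grey50")
  invisible(x)
}

#' Write a CEAC to CSV
#'
#' @param x A \code{"ceac"} data frame.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_ceac_csv <- function(x, path) {
  stopifnot(inherits(x, "ceac"))
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}

#' Deterministic one-way sensitivity analysis
#'
#' Re-runs the deterministic model per axis value for every age/sex
#' scenario, holding everything else at the base case. Two axes are
#' supported: the common discount rate (applied to both costs and QALYs)
#' and the intervention-effect horizon in years.
#'
#' @param params Parameter bundle (base case).
#' @param mortality A [mortality_model()].
#' @param axis \code{"discount_rate"} or \code{"effect_horizon"}.
#' @param values Axis values (e.g. \code{c(0, 0.03, 0.05)} or
#'   \code{c(3, 7, 20)}).
#' @param ages,sexes Scenario grid (defaults: ages 30/50/70, both sexes).
#' @param max_age Simulation horizon.
#' @return A data frame with one row per (value, age, sex): incremental
#'   cost, incremental QALYs, ICER and quadrant.
#' @export
one_way_sensitivity <- function(params, mortality,
                                axis = c("discount_rate", "effect_horizon"),
                                values,
                                ages = c(30, 50, 70),
                                sexes = c("male", "female"),
                                max_age = 100) {
  axis <- match.arg(axis)
  if (length(values) < 1) stop("one_way_sensitivity: no axis values supplied")
  if (axis == "discount_rate" && any(values < 0 | values > 0.2))
    stop("one_way_sensitivity: discount rates must lie in [0, 0.2]")
  if (axis == "effect_horizon" && any(values < 2))
    stop("one_way_sensitivity: effect horizons must be >= 2 for linear decay")
  rows <- list()
  for (v in values) {
    p <- params
    if (axis == "discount_rate") p$discount[] <- v else p$effect$horizon <- v
    for (sx in sexes) for (a in ages) {
      sc <- t2d_scenario(sx, a, initial = params$initial, max_age = max_age)
      res <- icer(simulate_cohort(sc, "control", p, mortality, keep_trace = FALSE),
                  simulate_cohort(sc, "intervention", p, mortality, keep_trace = FALSE))
      rows[[length(rows) + 1L]] <- data.frame(
        axis = axis, value = v, age = a, sex = sx,
        delta_cost = res$delta_cost, delta_qalys = res$delta_qalys,
        icer = res$icer, quadrant = res$quadrant, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
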