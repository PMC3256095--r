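# Main user-facing interface: evaluate the cost-effectiveness of the
# lifestyle intervention across entry ages and sexes, returning a classed
# object with print / summary / plot / simulate methods.

#' Lifetime cost-effectiveness of the lifestyle intervention
#'
#' Runs the deterministic four-state Markov cohort model for both arms
#' (no intervention vs. lifestyle intervention) over a grid of entry ages
#' and sexes and computes incremental cost-effectiveness ratios.
#'
#' @param params Parameter bundle ([default_parameters()] or
#'   [load_config()]).
#' @param mortality A [mortality_model()]; defaults to the
#'   \code{"german-like-2006"} synthetic life table with the
#'   attributable-share convention.
#' @param ages Entry ages (default 30, 50, 70).
#' @param sexes Sexes (default both).
#' @param max_age Simulation horizon (default 100).
#' @return An object of class \code{"t2d_cea"}: \code{summary} (one row
#'   per scenario with per-arm discounted costs and QALYs, incremental
#'   values, ICER and quadrant), \code{sims} (the per-arm
#'   \code{"cohort_sim"} objects), \code{params}, \code{mortality}.
#' @examples
#' \donttest{
#' fit <- t2d_cea()
#' summary(fit)
#' }
#' @export
t2d_cea <- function(params = default_parameters(),
                    mortality = NULL,
                    ages = c(30, 50, 70),
                    sexes = c("male", "female"),
                    max_age = 100) {
  validate_parameters(params)
  if (is.null(mortality)) {
    lt <- synthetic_life_table(synthetic_mortality_params("german-like-2006"))
    mortality <- mortality_from_life_table(lt, method = "attributable_share")
  }
  rows <- list(); sims <- list()
  for (sx in sexes) for (a in ages) {
    sc <- t2d_scenario(sx, a, initial = params$initial, max_age = max_age)
    ctl <- simulate_cohort(sc, "control", params, mortality)
    trt <- simulate_cohort(sc, "intervention", params, mortality)
    ic <- icer(ctl, trt)
    key <- paste(sx, a, sep = "_")
    sims[[key]] <- list(control = ctl, intervention = trt)
    rows[[key]] <- data.frame(
      age = a, sex = sx,
      cost_control = ctl$discounted_cost,
      cost_intervention = trt$discounted_cost,
      qalys_control = ctl$discounted_qalys,
      qalys_intervention = trt$discounted_qalys,
      delta_cost = ic$delta_cost, delta_qalys = ic$delta_qalys,
      icer = ic$icer, quadrant = ic$quadrant, stringsAsFactors = FALSE)
  }
  out <- list(summary = do.call(rbind, c(rows, make.row.names = FALSE)),
              sims = sims, params = params, mortality = mortality,
              max_age = max_age)
  class(out) <- "t2d_cea"
  out
}

#' @export
print.t2d_cea <- function(x, ...) {
  cat("Lifetime cost-effectiveness of lifestyle intervention vs. no intervention\n")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    ic <- if (is.na(s$icer[i])) "undefined" else sprintf("%.0f EUR/QALY", s$icer[i])
    cat(sprintf("  %-6s age %2d: dCost %8.0f EUR, dQALYs %7.4f, ICER %s (%s)\n",
                s$sex[i], s$age[i], s$delta_cost[i], s$delta_qalys[i], ic,
                s$quadrant[i]))
  }
  invisible(x)
}

#' @export
summary.t2d_cea <- function(object, ...) {
  s <- object$summary
  out <- data.frame(
    age = s$age, sex = s$sex,
    cost_control = round(s$cost_control, 2),
    cost_intervention = round(s$cost_intervention, 2),
    qalys_control = round(s$qalys_control, 2),
    qalys_intervention = round(s$qalys_intervention, 2),
    icer = round(s$icer),
    quadrant = s$quadrant, stringsAsFactors = FALSE)
  class(out) <- c("summary.t2d_cea", "data.frame")
  out
}

#' @export
print.summary.t2d_cea <- function(x, ...) {
  cat("Discounted lifetime results per person (EUR, QALYs) and ICER (EUR/QALY)\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' @export
plot.t2d_cea <- function(x, which = c("icer", "trace"), scenario = NULL, ...) {
  which <- match.arg(which)
  s <- x$summary
  if (which == "icer") {
    lab <- paste(substr(s$sex, 1, 1), s$age)
    graphics::barplot(s$icer, names.arg = lab, las = 1,
                      ylab = "ICER (EUR/QALY)",
                      main = "Incremental cost-effectiveness by entry age and sex")
    graphics::abline(h = 0)
  } else {
    key <- scenario %||% names(x$sims)[1]
    tr <- x$sims[[key]]$intervention$trace
    graphics::matplot(tr$age, tr[, c("share_ngt", "share_igt", "share_t2d", "share_dead")],
                      type = "l", lty = 1, lwd = 2,
                      xlab = "Age", ylab = "Cohort share",
                      main = paste("State occupancy,", key, "(intervention)"), ...)
    graphics::legend("right", legend = c("NGT", "IGT", "T2D", "Dead"),
                     col = 1:4, lty = 1, lwd = 2, bty = "n")
  }
  invisible(x)
}

#' Probabilistic sensitivity analysis for a fitted scenario grid
#'
#' \code{simulate()} on a \code{"t2d_cea"} object reruns one of its
#' scenarios under Monte-Carlo parameter uncertainty (see [run_psa()]).
#'
#' @param object A \code{"t2d_cea"} object.
#' @param nsim Number of draws.
#' @param seed Integer seed.
#' @param scenario Scenario key (e.g. \code{"male_50"}); defaults to the
#'   first.
#' @param ... Unused.
#' @return A \code{"t2d_psa"} object.
#' @export
simulate.t2d_cea <- function(object, nsim = 1000L, seed = NULL,
                             scenario = NULL, ...) {
  key <- scenario %||% names(object$sims)[1]
  if (!key %in% names(object$sims))
    stop("simulate.t2d_cea: unknown scenario '", key, "'")
  sc <- object$sims[[key]]$control$scenario
  run_psa(sc, object$params, object$mortality, n_draws = nsim, seed = seed)
}

#' Write the scenario summary table to CSV
#'
#' One row per age/sex scenario with per-arm discounted costs and QALYs,
#' incremental values, ICER and quadrant (full precision; round at
#' display time).
#'
#' @param x A \code{"t2d_cea"} object.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_summary_csv <- function(x, path) {
  stopifnot(inherits(x, "t2d_cea"))
  utils::write.csv(x$summary, path, row.names = FALSE)
  invisible(path)
}

#' Write a one-way sensitivity table to CSV
#'
#' @param x The data frame returned by [one_way_sensitivity()].
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_sensitivity_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Records what produced a set of output files: configuration source,
#' seed, package version, timestamp and the outputs themselves. Errors if
#' any listed output is missing.
#'
#' @param path Manifest path (JSON).
#' @param outputs Character vector of output file paths.
#' @param config Configuration file path or \code{"defaults"}.
#' @param seed Seed used, or \code{NULL}.
#' @return \code{path}, invisibly.
#' @export
write_run_manifest <- function(path, outputs, config = "defaults", seed = NULL) {
  missing_out <- outputs[!file.exists(outputs)]
  if (length(missing_out))
    stop("write_run_manifest: missing output file(s): ",
         paste(missing_out, collapse = ", "))
  manifest <- list(
    config = config,
    seed = seed,
    package = "t2dcea",
    version = as.character(utils::packageVersion("t2dcea")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = as.list(outputs))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
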