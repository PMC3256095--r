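# Configuration serialisation: one documented schema, YAML or JSON by file
# extension. Keys mirror the model's abbreviation list (ngt2igt, cNGT, uNGT,
# ...). Absent keys fall back to the base-case defaults.

as_plain <- function(x) as.list(stats::setNames(as.numeric(x), names(x)))

#' Serialise a parameter bundle to a configuration list
#'
#' @param params A validated parameter bundle.
#' @return A plain nested list following the documented config schema.
#' @seealso [load_config()], [write_config()]
#' @export
as_config_list <- function(params) {
  sched <- params$intervention_cost
  dists <- lapply(params$distributions, function(d) {
    out <- list(family = d$family, mean = d$mean, se = d$se)
    if (!is.null(d$alpha)) { out$alpha <- d$alpha; out$beta <- d$beta }
    if (!is.null(d$shape)) { out$shape <- d$shape; out$scale <- d$scale }
    out
  })
  list(
    transitions = list(control = params$transitions$control,
                       intervention = params$transitions$intervention),
    effect = params$effect,
    costs = list(cNGT = unname(params$costs["NGT"]),
                 cIGT = unname(params$costs["IGT"]),
                 cT2D = unname(params$costs["T2D"])),
    intervention_cost = list(
      folder_cost = sched$items$folder_cost,
      n_folders = sched$items$n_folders,
      n_recruited = sched$items$n_recruited,
      course_items = as_plain(sched$items$course),
      followup_items = as_plain(sched$items$followup),
      course_trips = sched$items$course_trips,
      followup_trips = sched$items$followup_trips,
      trip_cost = sched$items$trip_cost,
      followup_year1 = sched$followup_year1,
      participation_years = sched$participation_years),
    utilities = list(
      male = list(uNGT = unname(params$utilities$male["NGT"]),
                  uIGT = unname(params$utilities$male["IGT"]),
                  uT2D = unname(params$utilities$male["T2D"])),
      female = list(uNGT = unname(params$utilities$female["NGT"]),
                    uIGT = unname(params$utilities$female["IGT"]),
                    uT2D = unname(params$utilities$female["T2D"]))),
    discount = list(costs = unname(params$discount["costs"]),
                    qalys = unname(params$discount["qalys"])),
    initial = as_plain(params$initial),
    distributions = dists,
    psa = params$psa
  )
}

config_to_params <- function(cfg) {
  base <- as_config_list(default_parameters())
  merged <- utils::modifyList(base, cfg)

  named_vec <- function(lst, names_out, names_in = names_out) {
    v <- vapply(names_in, function(nm) as.numeric(lst[[nm]]), numeric(1))
    stats::setNames(v, names_out)
  }
  sched_cfg <- merged$intervention_cost
  sched <- intervention_cost_schedule(
    folder_cost = sched_cfg$folder_cost,
    n_folders = sched_cfg$n_folders,
    n_recruited = sched_cfg$n_recruited,
    course_items = unlist(sched_cfg$course_items),
    followup_items = unlist(sched_cfg$followup_items),
    course_trips = sched_cfg$course_trips,
    followup_trips = sched_cfg$followup_trips,
    trip_cost = sched_cfg$trip_cost,
    followup_year1 = sched_cfg$followup_year1,
    participation_years = sched_cfg$participation_years)
  dists <- lapply(merged$distributions, function(d)
    dist_spec(d$family, d$mean, d$se,
              alpha = d$alpha, beta = d$beta, shape = d$shape, scale = d$scale))
  params <- list(
    transitions = lapply(merged$transitions, function(tr)
      lapply(tr[c("ngt2igt", "igt2ngt", "igt2t2d", "t2d2igt")], as.numeric)),
    effect = list(horizon = as.numeric(merged$effect$horizon),
                  participation_years = as.numeric(merged$effect$participation_years),
                  decay = merged$effect$decay),
    costs = named_vec(merged$costs, c("NGT", "IGT", "T2D"), c("cNGT", "cIGT", "cT2D")),
    intervention_cost = sched,
    utilities = list(
      male = named_vec(merged$utilities$male, c("NGT", "IGT", "T2D"),
                       c("uNGT", "uIGT", "uT2D")),
      female = named_vec(merged$utilities$female, c("NGT", "IGT", "T2D"),
                         c("uNGT", "uIGT", "uT2D"))),
    discount = named_vec(merged$discount, c("costs", "qalys")),
    initial = named_vec(merged$initial, c("NGT", "IGT", "T2D", "Dead")),
    distributions = dists,
    psa = merged$psa
  )
  class(params) <- "t2d_parameters"
  validate_parameters(params)
  params
}

#' Load a model configuration
#'
#' Reads a YAML (\code{.yml}/\code{.yaml}) or JSON (\code{.json})
#' configuration file, fills every absent key with the base-case default,
#' and validates the resulting bundle. Validation reports all violated
#' invariants, naming the offending fields.
#'
#' An empty file (or empty mapping) therefore yields exactly the default
#' bundle of [default_parameters()].
#'
#' @param path Path to the configuration file.
#' @return A validated object of class \code{"t2d_parameters"}.
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop("load_config: configuration file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(cfg)) cfg <- list()
  config_to_params(cfg)
}

#' Write a model configuration
#'
#' Serialises a parameter bundle to YAML or JSON (chosen by file
#' extension) such that [load_config()] reproduces the bundle.
#'
#' @param params A validated parameter bundle.
#' @param path Output path ending in \code{.yaml}, \code{.yml} or
#'   \code{.json}.
#' @return \code{path}, invisibly.
#' @export
write_config <- function(params, path) {
  validate_parameters(params)
  cfg <- as_config_list(params)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(cfg, path, precision = 15)
  }
  invisible(path)
}
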