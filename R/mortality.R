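# Mortality module: life-table input, age-band aggregation, and the split of
# all-cause mortality into the non-diabetes probability mr[age] and the
# diabetes-attributable excess t2d2d.

BANDS <- c("<35", "35-64", "65-74", ">=75")
SEXES <- c("male", "female")

#' Age band for the mortality model
#'
#' The model stratifies mortality into four age bands: under 35, 35-64,
#' 65-74, and 75 and over. Band boundaries (35, 65, 75) belong to the upper
#' band.
#'
#' @param age Age(s) in years, 0 to 120.
#' @return Character vector of band labels
#'   (\code{"<35"}, \code{"35-64"}, \code{"65-74"}, \code{">=75"}).
#' @examples
#' band_for_age(c(34, 35, 80))
#' @export
band_for_age <- function(age) {
  if (any(!is.finite(age)) || any(age < 0) || any(age > 120))
    stop("band_for_age: ages must lie in [0, 120]")
  BANDS[band_index(age)]
}

band_index <- function(age) {
  findInterval(age, c(0, 35, 65, 75))
}

#' Construct and validate a life table
#'
#' A life table row gives, for one age and sex, the mid-year population,
#' total deaths over the year, and the subset of deaths attributable to
#' diabetes.
#'
#' @param age Integer ages (years).
#' @param sex \code{"male"}/\code{"female"} per row.
#' @param population Person counts, strictly positive.
#' @param deaths_total Total deaths, \code{0 <= deaths <= population}.
#' @param deaths_diabetes Diabetes-attributable deaths,
#'   \code{0 <= deaths_diabetes <= deaths_total}.
#' @return A \code{data.frame} of class \code{"life_table"}.
#' @export
life_table <- function(age, sex, population, deaths_total, deaths_diabetes) {
  lt <- data.frame(age = age, sex = sex, population = population,
                   deaths_total = deaths_total, deaths_diabetes = deaths_diabetes,
                   stringsAsFactors = FALSE)
  validate_life_table(lt)
}

validate_life_table <- function(lt) {
  req <- c("age", "sex", "population", "deaths_total", "deaths_diabetes")
  miss <- setdiff(req, names(lt))
  if (length(miss))
    stop("life table: missing columns: ", paste(miss, collapse = ", "))
  if (!all(lt$sex %in% SEXES))
    stop("life table: 'sex' must be 'male' or 'female'")
  if (any(lt$population <= 0))
    stop("life table: population must be strictly positive")
  if (any(lt$deaths_total < 0) || any(lt$deaths_total > lt$population))
    stop("life table: deaths_total must lie in [0, population]")
  if (any(lt$deaths_diabetes < 0) || any(lt$deaths_diabetes > lt$deaths_total))
    stop("life table: deaths_diabetes must lie in [0, deaths_total]")
  class(lt) <- unique(c("life_table", class(lt)))
  lt
}

#' Read a life table from CSV
#'
#' Expects a UTF-8 delimited text file with header columns \code{age},
#' \code{sex}, \code{population}, \code{deaths_total},
#' \code{deaths_diabetes}.
#'
#' @param path CSV file path.
#' @return A validated \code{"life_table"} data frame.
#' @export
read_life_table <- function(path) {
  if (!file.exists(path)) stop("read_life_table: file not found: ", path)
  lt <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  validate_life_table(lt)
}

#' Write a life table to CSV
#'
#' @param lt A \code{"life_table"} data frame.
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_life_table <- function(lt, path) {
  lt <- validate_life_table(lt)
  utils::write.csv(as.data.frame(lt), path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# Band-level rate column / population, per sex. Combinations with no rows
# are NA; completeness is enforced only where a full model is required.
band_aggregate <- function(lt, column) {
  out <- matrix(NA_real_, 2, 4, dimnames = list(SEXES, BANDS))
  b <- band_index(lt$age)
  for (sx in SEXES) {
    sel <- lt$sex == sx
    if (!any(sel)) next
    num <- tapply(lt[[column]][sel], BANDS[b[sel]], sum)
    den <- tapply(lt$population[sel], BANDS[b[sel]], sum)
    out[sx, names(num)] <- num / den
  }
  out
}

#' Non-diabetes death probability by age band
#'
#' Aggregates a life table into the four model age bands and computes, per
#' sex and band, the annual probability of dying from causes other than
#' diabetes: diabetes-attributable deaths are subtracted from total deaths
#' before dividing by the band population.
#'
#' @param lt A \code{"life_table"} data frame.
#' @return A 2x4 matrix (rows \code{male}/\code{female}, columns the age
#'   bands) of annual probabilities; sex/band combinations absent from the
#'   table are \code{NA}.
#' @export
mr_from_life_table <- function(lt) {
  lt <- validate_life_table(lt)
  lt$deaths_other <- lt$deaths_total - lt$deaths_diabetes
  band_aggregate(lt, "deaths_other")
}

#' Diabetes-attributable death probability from an attributable fraction
#'
#' Converts a population-level attributable fraction (the share of all
#' deaths attributable to diabetes) into an annual death probability for a
#' person in the T2D state, by allocating the attributable share of the
#' all-cause rate to the diabetic sub-population:
#' \code{t2d2d = fraction * all_cause_rate / prevalence}, capped at
#' \code{1 - mr} so that total state mortality never exceeds one.
#'
#' @param fraction Attributable fraction in \code{[0, 1)}.
#' @param all_cause_rate Annual all-cause death probability.
#' @param prevalence Diabetes prevalence in the band, strictly positive.
#' @param mr Non-diabetes death probability used for the cap (default 0).
#' @return Annual excess death probability for the T2D state.
#' @examples
#' t2d2d_from_fraction(0.1, 0.02, 0.1)  # 0.02
#' @export
t2d2d_from_fraction <- function(fraction, all_cause_rate, prevalence, mr = 0) {
  if (any(fraction < 0) || any(fraction >= 1))
    stop("t2d2d_from_fraction: 'fraction' must lie in [0, 1)")
  if (any(prevalence <= 0))
    stop("t2d2d_from_fraction: 'prevalence' must be strictly positive")
  if (any(all_cause_rate < 0) || any(all_cause_rate > 1))
    stop("t2d2d_from_fraction: 'all_cause_rate' must lie in [0, 1]")
  pmin(fraction * all_cause_rate / prevalence, 1 - mr)
}

#' Construct a mortality model
#'
#' Holds, per sex and age band, the annual non-diabetes death probability
#' \code{mr} (applied to the NGT and IGT states) and the
#' diabetes-attributable excess \code{t2d2d}; the T2D state dies with
#' probability \code{mr + t2d2d}.
#'
#' @param mr 2x4 matrix of non-diabetes death probabilities (rows
#'   \code{male}, \code{female}; columns the four age bands).
#' @param t2d2d 2x4 matrix of diabetes-attributable excess probabilities;
#'   defaults to zero.
#' @return An object of class \code{"mortality_model"}.
#' @export
mortality_model <- function(mr, t2d2d = matrix(0, 2, 4, dimnames = list(SEXES, BANDS))) {
  mr <- as.matrix(mr); t2d2d <- as.matrix(t2d2d)
  dimnames(mr) <- dimnames(t2d2d) <- list(SEXES, BANDS)
  if (anyNA(mr) || anyNA(t2d2d))
    stop("mortality_model: probabilities must be complete (no NA): supply all four bands for both sexes")
  if (any(mr < 0) || any(mr > 1) || any(t2d2d < 0) || any(t2d2d > 1))
    stop("mortality_model: probabilities must lie in [0, 1]")
  if (any(mr + t2d2d > 1 + 1e-12))
    stop("mortality_model: mr + t2d2d exceeds 1 in at least one band")
  out <- list(mr = mr, t2d2d = pmin(t2d2d, 1 - mr))
  class(out) <- "mortality_model"
  out
}

#' Mortality model with zero death probabilities
#'
#' Used for conservation and closed-form tests on immortal cohorts.
#'
#' @return A \code{"mortality_model"} with all probabilities zero.
#' @export
zero_mortality <- function() {
  z <- matrix(0, 2, 4, dimnames = list(SEXES, BANDS))
  mortality_model(z, z)
}

#' Build the mortality model from a life table
#'
#' Computes \code{mr} by subtracting diabetes-attributable deaths from
#' total deaths per band, and \code{t2d2d} by one of two conventions:
#' \describe{
#'   \item{\code{"attributable_share"}}{the diabetes-attributable share of
#'     the all-cause rate taken directly as the T2D excess,
#'     \code{t2d2d = deaths_diabetes / population} per band — the
#'     convention matching the source analysis this model reproduces;}
#'   \item{\code{"prevalence"}}{the attributable share divided by the
#'     band's diabetes prevalence (see [t2d2d_from_fraction()]), which
#'     reads the attributable deaths as concentrated in the diabetic
#'     sub-population.}
#' }
#'
#' @param lt A \code{"life_table"} data frame.
#' @param method \code{"attributable_share"} (default) or
#'   \code{"prevalence"}.
#' @param prevalence 2x4 matrix of diabetes prevalence by sex and band;
#'   required for \code{method = "prevalence"}.
#' @return A \code{"mortality_model"}.
#' @export
mortality_from_life_table <- function(lt,
                                      method = c("attributable_share", "prevalence"),
                                      prevalence = NULL) {
  method <- match.arg(method)
  lt <- validate_life_table(lt)
  rate <- band_aggregate(lt, "deaths_total")
  if (any(is.na(rate))) {
    empty <- which(is.na(rate), arr.ind = TRUE)
    stop("mortality_from_life_table: no population in band(s): ",
         paste(sprintf("%s/%s", SEXES[empty[, 1]], BANDS[empty[, 2]]), collapse = ", "))
  }
  lt$deaths_other <- lt$deaths_total - lt$deaths_diabetes
  mr <- band_aggregate(lt, "deaths_other")
  share <- rate - mr                     # attributable share of the all-cause rate
  t2d2d <- if (method == "attributable_share") {
    share
  } else {
    if (is.null(prevalence))
      stop("mortality_from_life_table: 'prevalence' is required for method = 'prevalence'")
    prevalence <- as.matrix(prevalence)
    dimnames(prevalence) <- list(SEXES, BANDS)
    frac <- ifelse(rate > 0, share / rate, 0)
    t2d2d_from_fraction(frac, rate, prevalence, mr)
  }
  mortality_model(mr, t2d2d)
}

#' Death probabilities by state for one age and sex
#'
#' @param mortality A \code{"mortality_model"}.
#' @param age Age in years.
#' @param sex \code{"male"} or \code{"female"}.
#' @return Numeric vector \code{c(NGT=, IGT=, T2D=)} of annual death
#'   probabilities. Ages beyond the last band reuse the \code{">=75"} band.
#' @export
state_death_probs <- function(mortality, age, sex) {
  stopifnot(inherits(mortality, "mortality_model"))
  sex <- match.arg(sex, SEXES)
  b <- band_index(min(age, 120))
  mr <- mortality$mr[sex, b]
  d_t2d <- min(mr + mortality$t2d2d[sex, b], 1)
  c(NGT = mr, IGT = mr, T2D = d_t2d)
}

#' @export
print.mortality_model <- function(x, ...) {
  cat("Mortality model (annual probabilities by sex and age band)\n")
  cat("mr (non-diabetes):\n")
  print(round(x$mr, 5))
  cat("t2d2d (diabetes-attributable excess):\n")
  print(round(x$t2d2d, 5))
  invisible(x)
}
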