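#' Fit a Beta distribution by the method of moments
#'
#' Inverts the mean/variance relations of the Beta distribution so that
#' \code{Beta(alpha, beta)} has exactly the requested mean and standard
#' error: with \eqn{\nu = m(1-m)/se^2 - 1}, \eqn{\alpha = m\nu} and
#' \eqn{\beta = (1-m)\nu}. This is the standard way of turning a published
#' (mean, SE) pair for a probability or a utility weight into a sampling
#' distribution for probabilistic sensitivity analysis.
#'
#' @param mean Mean on the parameter scale, strictly inside (0, 1).
#' @param se Standard error; must satisfy \code{se^2 < mean * (1 - mean)},
#'   otherwise no Beta distribution has these moments.
#' @return A list with components \code{alpha} and \code{beta}.
#' @examples
#' beta_from_moments(0.5, 0.1)   # alpha = beta = 12
#' beta_from_moments(0.062, 0.024)
#' @seealso [gamma_from_moments()], [dist_spec()]
#' @export
beta_from_moments <- function(mean, se) {
  stopifnot(is.numeric(mean), is.numeric(se), length(mean) == 1L, length(se) == 1L)
  if (!(mean > 0 && mean < 1))
    stop("beta_from_moments: 'mean' must lie strictly in (0, 1), got ", mean)
  if (se <= 0)
    stop("beta_from_moments: 'se' must be positive, got ", se)
  nu <- mean * (1 - mean) / se^2 - 1
  if (nu <= 0)
    stop("beta_from_moments: variance ", se^2, " is infeasible for a Beta with mean ",
         mean, " (requires se^2 < mean*(1-mean))")
  list(alpha = mean * nu, beta = (1 - mean) * nu)
}

#' Fit a Gamma distribution by the method of moments
#'
#' Returns shape and scale such that the Gamma distribution has the given
#' mean and standard error: \code{shape = (mean/se)^2},
#' \code{scale = se^2/mean}. Cost parameters in the model carry an SE equal
#' to their mean, which yields the unit-shape (exponential) special case
#' \code{shape = 1, scale = mean}.
#'
#' @param mean Mean, strictly positive (EUR for cost parameters).
#' @param se Standard error, strictly positive; defaults to \code{mean}.
#' @return A list with components \code{shape} and \code{scale}.
#' @examples
#' gamma_from_moments(1744.21)          # shape 1, scale 1744.21
#' gamma_from_moments(230.03, 230.03)
#' @export
gamma_from_moments <- function(mean, se = mean) {
  stopifnot(is.numeric(mean), is.numeric(se), length(mean) == 1L, length(se) == 1L)
  if (mean <= 0)
    stop("gamma_from_moments: 'mean' must be positive, got ", mean)
  if (se <= 0)
    stop("gamma_from_moments: 'se' must be positive, got ", se)
  list(shape = (mean / se)^2, scale = se^2 / mean)
}

#' Unit-shape Gamma for a cost parameter
#'
#' Convenience wrapper for the convention of assigning cost parameters a
#' Gamma distribution with the standard error set equal to the mean, which
#' fixes the shape at 1 and the scale at the mean.
#'
#' @param mean Mean cost in EUR, strictly positive.
#' @return A list with components \code{shape} (always 1) and \code{scale}.
#' @export
gamma_unit_shape <- function(mean) {
  gamma_from_moments(mean, mean)
}

#' Build a sampling-distribution specification
#'
#' A \code{dist_spec} couples a deterministic value with the distribution
#' used to sample it in probabilistic sensitivity analysis. Shape parameters
#' are derived from \code{(mean, se)} by the method of moments unless
#' explicit \code{alpha}/\code{beta} (Beta) or \code{shape}/\code{scale}
#' (Gamma) overrides are supplied. A zero \code{se} denotes a degenerate
#' (point-mass) distribution; draws then return the mean exactly.
#'
#' @param family Either \code{"beta"} or \code{"gamma"}.
#' @param mean Deterministic value / distribution mean.
#' @param se Standard error; 0 for a point mass.
#' @param alpha,beta Optional explicit Beta shapes, overriding the moment fit.
#' @param shape,scale Optional explicit Gamma parameters, overriding the
#'   moment fit.
#' @return An object of class \code{"dist_spec"}.
#' @export
dist_spec <- function(family = c("beta", "gamma"), mean, se,
                      alpha = NULL, beta = NULL, shape = NULL, scale = NULL) {
  family <- match.arg(family)
  stopifnot(is.numeric(mean), is.numeric(se), length(mean) == 1L, length(se) == 1L)
  if (se < 0) stop("dist_spec: 'se' must be non-negative")
  spec <- list(family = family, mean = mean, se = se)
  if (se > 0) {
    if (family == "beta") {
      if (is.null(alpha) != is.null(beta))
        stop("dist_spec: supply both 'alpha' and 'beta' or neither")
      if (is.null(alpha)) {
        mm <- beta_from_moments(mean, se)
        alpha <- mm$alpha; beta <- mm$beta
      } else {
        if (alpha <= 0 || beta <= 0) stop("dist_spec: Beta shapes must be positive")
        if (abs(alpha / (alpha + beta) - mean) > 0.01)
          stop("dist_spec: supplied alpha/beta imply mean ",
               signif(alpha / (alpha + beta), 4),
               ", more than 0.01 away from stated mean ", mean)
      }
      spec$alpha <- alpha; spec$beta <- beta
    } else {
      if (is.null(shape) != is.null(scale))
        stop("dist_spec: supply both 'shape' and 'scale' or neither")
      if (is.null(shape)) {
        mm <- gamma_from_moments(mean, se)
        shape <- mm$shape; scale <- mm$scale
      }
      if (shape <= 0 || scale <= 0) stop("dist_spec: Gamma parameters must be positive")
      spec$shape <- shape; spec$scale <- scale
    }
  }
  class(spec) <- "dist_spec"
  spec
}

#' Draw from a distribution specification
#'
#' @param spec A [dist_spec()] object.
#' @param n Number of draws.
#' @return Numeric vector of length \code{n}; for a degenerate spec
#'   (\code{se = 0}) the mean is returned exactly.
#' @export
draw_dist <- function(spec, n = 1L) {
  stopifnot(inherits(spec, "dist_spec"))
  if (spec$se == 0) return(rep(spec$mean, n))
  switch(spec$family,
         beta  = stats::rbeta(n, spec$alpha, spec$beta),
         gamma = stats::rgamma(n, shape = spec$shape, scale = spec$scale))
}

#' @export
print.dist_spec <- function(x, ...) {
  if (x$se == 0) {
    cat(sprintf("point mass at %g\n", x$mean))
  } else if (x$family == "beta") {
    cat(sprintf("Beta(%.4g, %.4g)  mean %.4g, se %.4g\n", x$alpha, x$beta, x$mean, x$se))
  } else {
    cat(sprintf("Gamma(shape %.4g, scale %.4g)  mean %.4g, se %.4g\n",
                x$shape, x$scale, x$mean, x$se))
  }
  invisible(x)
}
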