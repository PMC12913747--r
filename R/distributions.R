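# Moment-matched sampling distributions for probabilistic sensitivity
# analysis: beta for probabilities, gamma for costs, point mass for fixed
# parameters.

#' Moment-matched beta distribution for a probability parameter
#'
#' Solves for the beta shape parameters whose analytic mean and standard
#' deviation equal the supplied values: with
#' \eqn{\nu = m(1-m)/se^2 - 1}, \eqn{\alpha = m\nu}, \eqn{\beta = (1-m)\nu}.
#'
#' @param mean Mean in (0, 1).
#' @param se Standard error, with `0 < se^2 < mean * (1 - mean)`.
#' @return A `distribution_spec` with family `"beta"`.
#' @export
beta_from_moments <- function(mean, se) {
  stopifnot(length(mean) == 1, length(se) == 1)
  if (!(mean > 0 && mean < 1)) {
    stop("beta moments need 0 < mean < 1, got ", mean)
  }
  if (se <= 0) stop("beta moments need se > 0, got ", se)
  if (se^2 >= mean * (1 - mean)) {
    stop(sprintf(
      "infeasible moments: se^2 = %g is not below mean*(1-mean) = %g",
      se^2, mean * (1 - mean)))
  }
  nu <- mean * (1 - mean) / se^2 - 1
  spec <- list(family = "beta", shape1 = mean * nu, shape2 = (1 - mean) * nu,
               mean = mean, se = se)
  class(spec) <- "distribution_spec"
  spec
}

#' Moment-matched gamma distribution for a cost parameter
#'
#' Shape \eqn{(m/se)^2}, scale \eqn{se^2/m}; the analytic mean and
#' standard deviation then reproduce the inputs exactly.
#'
#' @param mean Positive mean cost.
#' @param se Positive standard error.
#' @return A `distribution_spec` with family `"gamma"`.
#' @export
gamma_from_moments <- function(mean, se) {
  stopifnot(length(mean) == 1, length(se) == 1)
  if (mean <= 0 || se <= 0) {
    stop("gamma moments need mean > 0 and se > 0, got mean = ",
         mean, ", se = ", se)
  }
  spec <- list(family = "gamma", shape = (mean / se)^2, scale = se^2 / mean,
               mean = mean, se = se)
  class(spec) <- "distribution_spec"
  spec
}

fixed_spec <- function(value) {
  spec <- list(family = "fixed", value = value, mean = value, se = 0)
  class(spec) <- "distribution_spec"
  spec
}

#' Analytic moments of a distribution spec
#'
#' @param spec A `distribution_spec`.
#' @return Named vector `c(mean, sd)`.
#' @export
spec_moments <- function(spec) {
  stopifnot(inherits(spec, "distribution_spec"))
  switch(spec$family,
    beta = {
      a <- spec$shape1; b <- spec$shape2
      m <- a / (a + b)
      c(mean = m, sd = sqrt(a * b / ((a + b)^2 * (a + b + 1))))
    },
    gamma = c(mean = spec$shape * spec$scale,
              sd = sqrt(spec$shape) * spec$scale),
    fixed = c(mean = spec$value, sd = 0),
    stop("unknown family: ", spec$family)
  )
}

#' Draw samples from a distribution spec
#'
#' Uses the current RNG state; seed management belongs to the caller.
#'
#' @param spec A `distribution_spec`.
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
sample_spec <- function(spec, n) {
  stopifnot(inherits(spec, "distribution_spec"), n >= 1)
  switch(spec$family,
    beta = stats::rbeta(n, spec$shape1, spec$shape2),
    gamma = stats::rgamma(n, shape = spec$shape, scale = spec$scale),
    fixed = rep(spec$value, n),
    stop("unknown family: ", spec$family)
  )
}

#' Build PSA distributions for a whole parameter set
#'
#' Probabilities with positive se get moment-matched beta distributions;
#' costs with positive se get moment-matched gamma distributions;
#' parameters with se = 0 are fixed at their mean. A cost whose se equals
#' its mean implies a gamma with shape 1 (an exponential) — a very
#' dispersed prior — and triggers a warning unless `warn_shape1 = FALSE`.
#'
#' @param params A `parameter_set`.
#' @param warn_shape1 Warn when a cost's se equals its mean.
#' @return Named list of `distribution_spec` objects, one per parameter.
#' @export
build_distributions <- function(params, warn_shape1 = TRUE) {
  stopifnot(inherits(params, "parameter_set"))
  specs <- vector("list", nrow(params))
  names(specs) <- params$name
  shape1 <- character(0)
  for (i in seq_len(nrow(params))) {
    m <- params$mean[i]; s <- params$se[i]
    specs[[i]] <- if (s == 0 || m == 0 || (params$kind[i] == "probability" && m == 1)) {
      fixed_spec(m)
    } else if (params$kind[i] == "probability") {
      beta_from_moments(m, s)
    } else {
      if (isTRUE(all.equal(m, s))) shape1 <- c(shape1, params$name[i])
      gamma_from_moments(m, s)
    }
  }
  if (warn_shape1 && length(shape1)) {
    warning("cost parameter(s) with se equal to mean imply gamma shape 1 ",
            "(high variance): ", paste(shape1, collapse = ", "),
            call. = FALSE)
  }
  specs
}

#' @export
print.distribution_spec <- function(x, ...) {
  hp <- switch(x$family,
    beta = sprintf("shape1 = %.4g, shape2 = %.4g", x$shape1, x$shape2),
    gamma = sprintf("shape = %.4g, scale = %.4g", x$shape, x$scale),
    fixed = sprintf("value = %.4g", x$value))
  cat(sprintf("<distribution_spec> %s (%s)\n", x$family, hp))
  invisible(x)
}
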