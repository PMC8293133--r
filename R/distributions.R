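#' Specify an uncertain model parameter
#'
#' A distribution specification carries the family, mean and standard error
#' of one uncertain input. The convention follows Canadian economic
#' evaluation practice: beta for probabilities and dis-utilities, gamma (or
#' lognormal) for costs, `fixed` for parameters excluded from the
#' probabilistic analysis.
#'
#' @param family One of `"beta"`, `"gamma"`, `"lognormal"`, `"fixed"`.
#' @param mean Parameter mean; beta requires mean in (0, 1), gamma and
#'   lognormal require mean > 0.
#' @param se Standard error, >= 0; must be 0 for `fixed`.
#' @return A `dist_spec` object.
#' @export
#' @examples
#' dist_spec("beta", 0.2, 0.05)
#' dist_spec("fixed", 1200)
dist_spec <- function(family = c("beta", "gamma", "lognormal", "fixed"),
                      mean, se = 0) {
  family <- match.arg(family)
  if (!is.numeric(mean) || length(mean) != 1L || !is.finite(mean))
    stop("`mean` must be a single finite number", call. = FALSE)
  if (!is.numeric(se) || length(se) != 1L || !is.finite(se) || se < 0)
    stop("`se` must be a single number >= 0", call. = FALSE)
  if (family == "beta" && (mean <= 0 || mean >= 1))
    stop("beta requires mean in (0, 1)", call. = FALSE)
  if (family %in% c("gamma", "lognormal") && mean <= 0)
    stop(family, " requires mean > 0", call. = FALSE)
  if (family == "fixed" && se != 0)
    stop("fixed requires se = 0", call. = FALSE)
  structure(list(family = family, mean = mean, se = se), class = "dist_spec")
}

#' @export
print.dist_spec <- function(x, ...) {
  cat(sprintf("<dist_spec> %s(mean = %g, se = %g)\n", x$family, x$mean, x$se))
  invisible(x)
}

.is_fixed <- function(spec) spec$se == 0 || spec$family == "fixed"

#' Build a sampler for a distribution specification
#'
#' Fits the family's parameters by the method of moments and returns a
#' function of `n` drawing that many values from the current RNG stream.
#' Beta: `alpha = m (m(1-m)/s^2 - 1)`, `beta = (1-m)(m(1-m)/s^2 - 1)`;
#' gamma: `shape = m^2/s^2`, `scale = s^2/m`; lognormal moment-matched on the
#' natural scale. A zero-`se` spec of any family samples the mean exactly.
#'
#' @param spec A [dist_spec()].
#' @return `function(n)` returning `n` draws.
#' @export
#' @examples
#' set.seed(1)
#' fit_distribution(dist_spec("beta", 0.2, 0.05))(3)
fit_distribution <- function(spec) {
  stopifnot(inherits(spec, "dist_spec"))
  m <- spec$mean
  s <- spec$se
  if (.is_fixed(spec)) return(function(n) rep.int(m, n))
  switch(spec$family,
    beta = {
      if (s^2 >= m * (1 - m))
        stop(sprintf(
          "beta moments infeasible: se^2 = %g >= mean(1-mean) = %g",
          s^2, m * (1 - m)), call. = FALSE)
      nu <- m * (1 - m) / s^2 - 1
      alpha <- m * nu
      beta <- (1 - m) * nu
      function(n) stats::rbeta(n, alpha, beta)
    },
    gamma = {
      shape <- m^2 / s^2
      scale <- s^2 / m
      function(n) stats::rgamma(n, shape = shape, scale = scale)
    },
    lognormal = {
      sdlog <- sqrt(log(1 + s^2 / m^2))
      meanlog <- log(m) - sdlog^2 / 2
      function(n) stats::rlnorm(n, meanlog, sdlog)
    }
  )
}

# One draw from each dist_spec in a flat named list.
.sample1 <- function(specs) {
  vapply(specs, function(sp) fit_distribution(sp)(1L), numeric(1))
}

.means_of <- function(specs) vapply(specs, `[[`, numeric(1), "mean")
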