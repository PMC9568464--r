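#' Prior specification on an effect-size parameter
#'
#' Constructs a `prior_spec`, the package's representation of a parametric
#' prior distribution on an effect size: the population correlation
#' \eqn{\rho} or Cohen's \eqn{\delta}.  Six families are supported:
#'
#' * `beta`: Beta(\eqn{\alpha}, \eqn{\beta}) on \eqn{\rho \in [0, 1]}
#'   (one-sided elicitation target; no rescaling to \eqn{(-1, 1)}).
#' * `t_truncated`: shifted-scaled Student-t with location `mu`, scale
#'   `sigma`, degrees of freedom `nu`, truncated to \eqn{\delta > 0} and
#'   renormalized by the untruncated mass above zero.
#' * `normal_truncated`: Normal(`mu`, `sigma`) truncated to \eqn{\delta > 0}.
#' * `cauchy_truncated`: central Cauchy with scale `scale`, truncated to
#'   \eqn{\delta > 0} (the positive-only default for t-tests).
#' * `uniform`: Uniform(`lower`, `upper`) (the default for \eqn{\rho}).
#' * `point`: all mass on a single `value` (the point null).
#'
#' @param family One of `"beta"`, `"t_truncated"`, `"normal_truncated"`,
#'   `"cauchy_truncated"`, `"uniform"`, `"point"`.
#' @param ... Named family parameters: `alpha`, `beta` (beta); `mu`,
#'   `sigma`, `nu` (t_truncated); `mu`, `sigma` (normal_truncated);
#'   `scale` (cauchy_truncated); `lower`, `upper` (uniform); `value`
#'   (point).
#' @param label Free-text label, e.g. `"Expert 4 (beta)"`.
#' @param parameter Which effect size the prior lives on: `"rho"`,
#'   `"delta"`, or `"other"`.
#' @return An object of class `prior_spec`: a list with elements
#'   `family`, `params`, `support` (length-2 numeric), `label`,
#'   `parameter`.
#' @examples
#' prior_spec("beta", alpha = 10.70, beta = 22.98, label = "Expert 4 (beta)")
#' prior_spec("cauchy_truncated", scale = sqrt(2) / 2, parameter = "delta")
#' @export
prior_spec <- function(family = c("beta", "t_truncated", "normal_truncated",
                                  "cauchy_truncated", "uniform", "point"),
                       ..., label = NULL, parameter = c("other", "rho", "delta")) {
  family <- match.arg(family)
  parameter <- match.arg(parameter)
  params <- list(...)
  required <- switch(family,
    beta = c("alpha", "beta"),
    t_truncated = c("mu", "sigma", "nu"),
    normal_truncated = c("mu", "sigma"),
    cauchy_truncated = "scale",
    uniform = c("lower", "upper"),
    point = "value"
  )
  missing <- setdiff(required, names(params))
  if (length(missing) > 0L) {
    stop(sprintf("prior family '%s' requires parameter(s): %s",
                 family, paste(missing, collapse = ", ")), call. = FALSE)
  }
  params <- params[required]
  p <- params
  switch(family,
    beta = {
      if (p$alpha <= 0 || p$beta <= 0)
        stop("beta prior requires alpha > 0 and beta > 0", call. = FALSE)
      support <- c(0, 1)
    },
    t_truncated = {
      if (p$sigma <= 0) stop("t prior requires sigma > 0", call. = FALSE)
      if (p$nu <= 0) stop("t prior requires nu > 0", call. = FALSE)
      support <- c(0, Inf)
    },
    normal_truncated = {
      if (p$sigma <= 0) stop("normal prior requires sigma > 0", call. = FALSE)
      support <- c(0, Inf)
    },
    cauchy_truncated = {
      if (p$scale <= 0) stop("Cauchy prior requires scale > 0", call. = FALSE)
      support <- c(0, Inf)
    },
    uniform = {
      if (p$lower >= p$upper)
        stop("uniform prior requires lower < upper", call. = FALSE)
      support <- c(p$lower, p$upper)
    },
    point = {
      support <- c(p$value, p$value)
    }
  )
  if (is.null(label)) label <- family
  structure(
    list(family = family, params = params, support = support,
         label = label, parameter = parameter),
    class = "prior_spec"
  )
}

#' @export
print.prior_spec <- function(x, ...) {
  pars <- paste(sprintf("%s = %g", names(x$params), unlist(x$params)),
                collapse = ", ")
  cat(sprintf("<prior_spec> %s: %s(%s) on [%g, %g] (%s)\n",
              x$label, x$family, pars, x$support[1], x$support[2],
              x$parameter))
  invisible(x)
}

#' Prior density
#'
#' Evaluates the prior density of a [prior_spec()] at `x`.  Truncated
#' families are renormalized by the untruncated mass on the support, so
#' every non-point prior integrates to one over its support.  Outside the
#' support the density is zero.  For a `point` prior the density is a
#' Dirac mass: `Inf` at the atom, `0` elsewhere (use [prior_mass_above()]
#' for probabilities).
#'
#' @param spec A [prior_spec()].
#' @param x Numeric vector of evaluation points (finite).
#' @param log If `TRUE`, return the log density.
#' @return Numeric vector of (log) densities.
#' @examples
#' u <- prior_spec("uniform", lower = 0, upper = 1)
#' prior_pdf(u, 0.5)  # 1
#' @export
prior_pdf <- function(spec, x, log = FALSE) {
  stopifnot(inherits(spec, "prior_spec"))
  if (any(!is.finite(x))) stop("x must be finite", call. = FALSE)
  p <- spec$params
  ld <- switch(spec$family,
    beta = stats::dbeta(x, p$alpha, p$beta, log = TRUE),
    t_truncated = {
      lz <- stats::pt(-p$mu / p$sigma, p$nu, lower.tail = FALSE, log.p = TRUE)
      stats::dt((x - p$mu) / p$sigma, p$nu, log = TRUE) - log(p$sigma) - lz
    },
    normal_truncated = {
      lz <- stats::pnorm(0, p$mu, p$sigma, lower.tail = FALSE, log.p = TRUE)
      stats::dnorm(x, p$mu, p$sigma, log = TRUE) - lz
    },
    cauchy_truncated = {
      # central Cauchy truncated to (0, Inf): exactly half the mass
      stats::dcauchy(x, 0, p$scale, log = TRUE) + log(2)
    },
    uniform = stats::dunif(x, p$lower, p$upper, log = TRUE),
    point = ifelse(x == p$value, Inf, -Inf)
  )
  ld[x < spec$support[1] | x > spec$support[2]] <- -Inf
  if (log) ld else exp(ld)
}

#' Prior cumulative distribution function
#'
#' \eqn{P(\theta \le q)} under a [prior_spec()], with truncation handled
#' by conditioning on the support.
#'
#' @inheritParams prior_pdf
#' @param q Numeric vector of quantiles.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
prior_cdf <- function(spec, q) {
  stopifnot(inherits(spec, "prior_spec"))
  p <- spec$params
  val <- switch(spec$family,
    beta = stats::pbeta(q, p$alpha, p$beta),
    t_truncated = {
      z0 <- stats::pt(-p$mu / p$sigma, p$nu)
      pmax(0, (stats::pt((q - p$mu) / p$sigma, p$nu) - z0) / (1 - z0))
    },
    normal_truncated = {
      z0 <- stats::pnorm(0, p$mu, p$sigma)
      pmax(0, (stats::pnorm(q, p$mu, p$sigma) - z0) / (1 - z0))
    },
    cauchy_truncated = pmax(0, 2 * (stats::pcauchy(q, 0, p$scale) - 0.5)),
    uniform = stats::punif(q, p$lower, p$upper),
    point = as.numeric(q >= p$value)
  )
  pmin(1, pmax(0, val))
}

#' Prior mass above a cutoff
#'
#' \eqn{P(\theta > \mathrm{cutoff})} under the prior.  Used, e.g., to
#' check how much prior mass an elicited t prior places on effect sizes
#' beyond a conventional benchmark such as \eqn{\delta = 0.5}.
#'
#' @inheritParams prior_pdf
#' @param cutoff Finite numeric scalar (or vector).
#' @return Probabilities in `[0, 1]`.
#' @examples
#' e2 <- prior_spec("t_truncated", mu = 0.55, sigma = 0.08, nu = 3)
#' prior_mass_above(e2, 0.5)  # > 0.70
#' @export
prior_mass_above <- function(spec, cutoff) {
  if (any(!is.finite(cutoff))) stop("cutoff must be finite", call. = FALSE)
  if (spec$family == "point") return(as.numeric(spec$params$value > cutoff))
  1 - prior_cdf(spec, cutoff)
}

#' Draw samples from a prior
#'
#' Inverse-CDF sampling for the truncated families (exact, no rejection).
#' The caller controls reproducibility through R's RNG state
#' (`set.seed()`).
#'
#' @inheritParams prior_pdf
#' @param n Number of draws.
#' @return Numeric vector of length `n`.
#' @export
prior_sample <- function(spec, n) {
  stopifnot(inherits(spec, "prior_spec"))
  p <- spec$params
  switch(spec$family,
    beta = stats::rbeta(n, p$alpha, p$beta),
    t_truncated = {
      z0 <- stats::pt(-p$mu / p$sigma, p$nu)
      u <- stats::runif(n, z0, 1)
      p$mu + p$sigma * stats::qt(u, p$nu)
    },
    normal_truncated = {
      z0 <- stats::pnorm(0, p$mu, p$sigma)
      stats::qnorm(stats::runif(n, z0, 1), p$mu, p$sigma)
    },
    cauchy_truncated = abs(stats::rcauchy(n, 0, p$scale)),
    uniform = stats::runif(n, p$lower, p$upper),
    point = rep(p$value, n)
  )
}

#' Registry of elicited and default priors
#'
#' The built-in set of priors used throughout the package: six elicited
#' beta priors on the correlation \eqn{\rho} and six elicited
#' shifted-scaled t priors on Cohen's \eqn{\delta} (one per expert), the
#' default uniform(0, 1) prior on \eqn{\rho}, the default positive-only
#' Cauchy prior on \eqn{\delta} with scale \eqn{\sqrt{2}/2}, and the two
#' point null priors (\eqn{\rho = 0}, \eqn{\delta = 0}).
#'
#' @return A named list of [prior_spec()] objects, keyed by label:
#'   `"Expert 1 (beta)"` ... `"Expert 6 (beta)"`, `"Expert 1 (t)"` ...
#'   `"Expert 6 (t)"`, `"default (rho)"`, `"default (delta)"`,
#'   `"null (rho)"`, `"null (delta)"`.
#' @examples
#' reg <- expert_registry()
#' reg[["Expert 4 (beta)"]]
#' @export
expert_registry <- function() {
  beta_par <- list(
    c(0.62, 2.44), c(5.32, 18.58), c(5.35, 15.69),
    c(10.70, 22.98), c(3.83, 8.76), c(8.65, 12.39)
  )
  t_par <- list(
    c(0.10, 0.12, 3), c(0.55, 0.08, 3), c(0.60, 0.11, 13),
    c(0.59, 0.11, 3), c(0.41, 0.12, 13), c(0.31, 0.08, 9)
  )
  reg <- list()
  for (i in 1:6) {
    lab <- sprintf("Expert %d (beta)", i)
    reg[[lab]] <- prior_spec("beta", alpha = beta_par[[i]][1],
                             beta = beta_par[[i]][2],
                             label = lab, parameter = "rho")
    lab <- sprintf("Expert %d (t)", i)
    reg[[lab]] <- prior_spec("t_truncated", mu = t_par[[i]][1],
                             sigma = t_par[[i]][2], nu = t_par[[i]][3],
                             label = lab, parameter = "delta")
  }
  reg[["default (rho)"]] <- prior_spec("uniform", lower = 0, upper = 1,
                                       label = "default (rho)",
                                       parameter = "rho")
  reg[["default (delta)"]] <- prior_spec("cauchy_truncated",
                                         scale = sqrt(2) / 2,
                                         label = "default (delta)",
                                         parameter = "delta")
  reg[["null (rho)"]] <- prior_spec("point", value = 0,
                                    label = "null (rho)", parameter = "rho")
  reg[["null (delta)"]] <- prior_spec("point", value = 0,
                                      label = "null (delta)",
                                      parameter = "delta")
  reg
}

#' Subset a prior registry by effect-size parameter
#'
#' @param registry A named list of [prior_spec()] objects.
#' @param parameter `"rho"` or `"delta"`.
#' @param include_null Keep the point null prior? Default `FALSE`.
#' @return The matching subset, in registry order.
#' @export
registry_subset <- function(registry, parameter = c("rho", "delta"),
                            include_null = FALSE) {
  parameter <- match.arg(parameter)
  keep <- vapply(registry, function(s) {
    s$parameter == parameter && (include_null || s$family != "point")
  }, logical(1))
  registry[keep]
}

#' Export and import prior registries as JSON
#'
#' `priors_to_json()` serializes a named list of priors to a JSON array of
#' `{label, family, params, support, parameter}` records;
#' `priors_from_json()` reads it back into `prior_spec` objects.
#'
#' @param registry Named list of [prior_spec()] objects.
#' @param path File path.
#' @return `priors_from_json()` returns a named list of priors;
#'   `priors_to_json()` returns `path` invisibly.
#' @export
priors_to_json <- function(registry, path) {
  recs <- lapply(registry, function(s) {
    list(label = s$label, family = s$family, params = s$params,
         support = s$support, parameter = s$parameter)
  })
  jsonlite::write_json(unname(recs), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname priors_to_json
#' @export
priors_from_json <- function(path) {
  recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  reg <- lapply(recs, function(r) {
    do.call(prior_spec, c(list(family = r$family), r$params,
                          list(label = r$label, parameter = r$parameter)))
  })
  names(reg) <- vapply(reg, `[[`, character(1), "label")
  reg
}
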