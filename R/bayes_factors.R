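# Gauss hypergeometric 2F1(1/2, 1/2; c; z) on the log scale, vectorized
# over z in [0, 1].  All series terms are positive (no cancellation) and
# for the c = n - 1/2 values arising here the ratio of consecutive terms
# is z (k + 1/2)^2 / ((k + c)(k + 1)) < z, so convergence is geometric
# even at z = 1 (where c - a - b = n - 3/2 > 0 guarantees a finite sum).
log_hyp2f1_half <- function(c, z) {
  stopifnot(all(z >= 0), all(z <= 1), c > 1)
  term <- rep(1, length(z))
  s <- rep(1, length(z))
  k <- 0
  repeat {
    term <- term * (k + 0.5)^2 / ((k + c) * (k + 1)) * z
    s <- s + term
    k <- k + 1
    if (max(term / s) < 1e-16) break
    if (k > 1e5) stop("2F1 series failed to converge", call. = FALSE)
  }
  log(s)
}

# Log likelihood-ratio kernel of the sample correlation, k(rho) =
# L(rho; r, n) / L(0; r, n), under the exact reduced likelihood of r for
# bivariate normal data (nuisance means and variances integrated out):
#   k(rho) = (1 - rho^2)^((n-1)/2) (1 - rho r)^{-(n - 3/2)}
#            2F1(1/2, 1/2; n - 1/2; (1 + rho r)/2) / 2F1(...; 1/2)
log_corr_kernel <- function(rho, r, n, lH0 = NULL) {
  if (is.null(lH0)) lH0 <- log_hyp2f1_half(n - 0.5, 0.5)
  (n - 1) / 2 * log1p(-rho^2) - (n - 1.5) * log1p(-rho * r) +
    log_hyp2f1_half(n - 0.5, (1 + rho * r) / 2) - lH0
}

# Log likelihood-ratio kernel for the t statistic: noncentral-t density
# with noncentrality delta * sqrt(n_eff) over the central density.
# stats::dt()'s noncentral branch emits "full precision" warnings for
# large ncp; its accuracy is ample here, so they are muted.
log_t_kernel <- function(delta, t, df, n_eff) {
  suppressWarnings(
    stats::dt(t, df, ncp = delta * sqrt(n_eff), log = TRUE) -
      stats::dt(t, df, ncp = 0, log = TRUE)
  )
}

# Integrate exp(log_f) over [lo, hi] with a max-shift for numerical
# stability: m = max over a scan grid, integrate exp(log_f - m)
# adaptively, return the log of the integral plus diagnostics.
log_integral <- function(log_f, lo, hi, rel_tol = 1e-8, scan_n = 401L) {
  grid <- seq(lo, hi, length.out = scan_n)
  lf <- log_f(grid)
  m <- max(lf[is.finite(lf)])
  if (!is.finite(m)) stop("integrand is zero everywhere", call. = FALSE)
  res <- tryCatch(
    stats::integrate(function(x) exp(log_f(x) - m), lo, hi,
                     rel.tol = rel_tol, abs.tol = 0,
                     subdivisions = 400L, stop.on.error = TRUE),
    error = function(e) {
      stop(sprintf("quadrature failed on [%g, %g]: %s", lo, hi,
                   conditionMessage(e)), call. = FALSE)
    }
  )
  list(log_value = m + log(res$value),
       rel_error = res$abs.error / res$value,
       subdivisions = res$subdivisions)
}

bf_result <- function(study_id, prior_label, log_bf10,
                      rel_error = 0, subdivisions = 0L,
                      method = "quadrature") {
  structure(
    list(study_id = study_id, prior_label = prior_label,
         log_bf10 = log_bf10, bf10 = exp(log_bf10),
         rel_error = rel_error, subdivisions = subdivisions,
         method = method),
    class = "bf_result"
  )
}

#' @export
print.bf_result <- function(x, ...) {
  cat(sprintf("<bf_result> %s | %s: log BF10 = %.4f (BF10 = %.6g)\n",
              x$study_id, x$prior_label, x$log_bf10, x$bf10))
  invisible(x)
}

#' One study's sufficient statistics
#'
#' A validated record of one hypothesis test: a correlation test carries
#' the sample correlation `r` and sample size `n`; a t-test carries the
#' design (one-sample, paired, or independent), the t statistic, and the
#' per-group sample sizes.
#'
#' @param study_id Identifier.
#' @param kind `"correlation"` or `"ttest"`.
#' @param r Sample correlation, `|r| < 1` (correlation only).
#' @param n Sample size, `n >= 4` (correlation only).
#' @param design `"one_sample"`, `"paired"`, or `"independent"` (t-test
#'   only).
#' @param t Observed t statistic.
#' @param n1,n2 Group sample sizes; `n2` only for independent designs.
#' @return An object of class `study_record`.
#' @export
study_record <- function(study_id, kind = c("correlation", "ttest"),
                         r = NULL, n = NULL, design = NULL, t = NULL,
                         n1 = NULL, n2 = NULL) {
  kind <- match.arg(kind)
  if (kind == "correlation") {
    if (is.null(r) || is.null(n)) stop("correlation record needs r and n",
                                       call. = FALSE)
    if (!is.finite(r) || abs(r) >= 1)
      stop("invalid record: |r| must be < 1", call. = FALSE)
    if (n < 4 || n %% 1 != 0)
      stop("invalid record: correlation requires integer n >= 4",
           call. = FALSE)
    rec <- list(study_id = study_id, kind = kind, r = r, n = as.integer(n))
  } else {
    design <- match.arg(design, c("one_sample", "paired", "independent"))
    if (is.null(t) || is.null(n1)) stop("t-test record needs t and n1",
                                        call. = FALSE)
    if (!is.finite(t)) stop("invalid record: t must be finite", call. = FALSE)
    if (n1 < 2) stop("invalid record: n1 must be >= 2", call. = FALSE)
    if (design == "independent") {
      if (is.null(n2) || is.na(n2) || n2 < 2)
        stop("invalid record: independent design requires n2 >= 2",
             call. = FALSE)
    } else {
      n2 <- NA_integer_
    }
    rec <- list(study_id = study_id, kind = kind, design = design, t = t,
                n1 = as.integer(n1),
                n2 = if (is.na(n2)) NA_integer_ else as.integer(n2))
  }
  structure(rec, class = "study_record")
}

# df and effective n conventions: one-sample/paired work on (difference)
# scores, df = n1 - 1, n_eff = n1; independent pools, df = n1 + n2 - 2,
# n_eff = n1 n2 / (n1 + n2).
ttest_df_neff <- function(record) {
  if (record$design == "independent") {
    list(df = record$n1 + record$n2 - 2,
         n_eff = record$n1 * record$n2 / (record$n1 + record$n2))
  } else {
    list(df = record$n1 - 1, n_eff = record$n1)
  }
}

#' One-sided Bayes factor for a correlation test
#'
#' Computes \eqn{\mathrm{BF}_{10}} for a Pearson correlation test: the
#' marginal likelihood of the sample correlation under a prior on
#' \eqn{\rho \in [0, 1]} divided by the likelihood under the point null
#' \eqn{\rho = 0}.  The likelihood is the exact reduced sampling density
#' of \eqn{r} under bivariate normality (hypergeometric form, with
#' nuisance parameters integrated out); constant factors cancel in the
#' ratio.  Integration is adaptive quadrature accumulated on the log
#' scale, so very large Bayes factors are handled without overflow.
#'
#' @param r Sample correlation, `|r| < 1`.
#' @param n Sample size, `n >= 4`.
#' @param prior A [prior_spec()] supported on `[0, 1]` (or a point mass).
#' @param study_id Optional identifier carried into the result.
#' @param rel_tol Relative quadrature tolerance.
#' @return A `bf_result` with `log_bf10` (natural log), `bf10`, and
#'   integration diagnostics (`rel_error`, `subdivisions`).
#' @examples
#' reg <- expert_registry()
#' corr_bf10(0.3, 260, reg[["Expert 4 (beta)"]])  # approx 1.1e5
#' @export
corr_bf10 <- function(r, n, prior, study_id = NA_character_,
                      rel_tol = 1e-8) {
  stopifnot(inherits(prior, "prior_spec"))
  rec <- study_record(study_id, "correlation", r = r, n = n)  # validates
  if (prior$support[1] < 0 || prior$support[2] > 1)
    stop("correlation prior must be supported on [0, 1]", call. = FALSE)
  lH0 <- log_hyp2f1_half(n - 0.5, 0.5)
  if (prior$family == "point") {
    lb <- log_corr_kernel(prior$params$value, r, n, lH0)
    return(bf_result(study_id, prior$label, lb, method = "closed_form"))
  }
  lo <- prior$support[1]; hi <- prior$support[2]
  res <- log_integral(
    function(rho) log_corr_kernel(rho, r, n, lH0) +
      prior_pdf(prior, rho, log = TRUE),
    lo, hi, rel_tol = rel_tol
  )
  bf_result(study_id, prior$label, res$log_value,
            rel_error = res$rel_error, subdivisions = res$subdivisions)
}

#' One-sided Bayes factor for a t-test
#'
#' Computes \eqn{\mathrm{BF}_{10}} for a t-test: the noncentral-t
#' marginal likelihood of the observed t statistic under a prior on
#' Cohen's \eqn{\delta \ge 0}, divided by the central-t likelihood under
#' the point null \eqn{\delta = 0}.  The noncentrality parameter is
#' \eqn{\delta\sqrt{n_\mathrm{eff}}} with \eqn{n_\mathrm{eff} = n_1} and
#' \eqn{df = n_1 - 1} for one-sample and paired designs (paired tests
#' operate on difference scores), and
#' \eqn{n_\mathrm{eff} = n_1 n_2/(n_1 + n_2)}, \eqn{df = n_1 + n_2 - 2}
#' for independent samples.  The half-line integral is mapped to (0, 1)
#' by \eqn{u = \delta/(1 + \delta)} and accumulated on the log scale.
#'
#' @param record A [study_record()] with `kind = "ttest"`.
#' @param prior A [prior_spec()] supported on \eqn{\delta \ge 0} (or a
#'   point mass).
#' @param rel_tol Relative quadrature tolerance.
#' @return A `bf_result`.
#' @examples
#' rec <- study_record("s1", "ttest", design = "one_sample", t = 2.5, n1 = 24)
#' ttest_bf10(rec, expert_registry()[["default (delta)"]])
#' @export
ttest_bf10 <- function(record, prior, rel_tol = 1e-8) {
  stopifnot(inherits(record, "study_record"), inherits(prior, "prior_spec"))
  if (record$kind != "ttest") stop("record must be a t-test record",
                                   call. = FALSE)
  if (prior$support[1] < 0)
    stop("t-test prior must be supported on delta >= 0", call. = FALSE)
  conv <- ttest_df_neff(record)
  if (conv$df < 1) stop("invalid record: df < 1", call. = FALSE)
  if (prior$family == "point") {
    lb <- log_t_kernel(prior$params$value, record$t, conv$df, conv$n_eff)
    return(bf_result(record$study_id, prior$label, lb,
                     method = "closed_form"))
  }
  # u = delta / (1 + delta): delta = u/(1-u), Jacobian 1/(1-u)^2
  res <- log_integral(
    function(u) {
      d <- u / (1 - u)
      log_t_kernel(d, record$t, conv$df, conv$n_eff) +
        prior_pdf(prior, d, log = TRUE) - 2 * log1p(-u)
    },
    1e-12, 1 - 1e-12, rel_tol = rel_tol
  )
  bf_result(record$study_id, prior$label, res$log_value,
            rel_error = res$rel_error, subdivisions = res$subdivisions)
}

#' Posterior probability of the alternative hypothesis
#'
#' Converts a Bayes factor and prior model odds into
#' \eqn{p(H_1 \mid D) = \mathrm{BF}_{10}\,\omega / (1 +
#' \mathrm{BF}_{10}\,\omega)} with \eqn{\omega} the prior odds (1 for
#' equal prior model probabilities).  Computed as
#' \eqn{1/(1 + 1/(\mathrm{BF}\,\omega))} so very large Bayes factors do
#' not lose precision.
#'
#' @param bf10 Positive Bayes factor(s).
#' @param prior_odds Positive prior odds for H1 over H0 (default 1).
#' @return Probabilities in `(0, 1)`.
#' @examples
#' posterior_prob_h1(110157)  # 0.999991
#' @export
posterior_prob_h1 <- function(bf10, prior_odds = 1) {
  if (any(bf10 <= 0) || any(prior_odds <= 0))
    stop("bf10 and prior_odds must be positive", call. = FALSE)
  1 / (1 + 1 / (bf10 * prior_odds))
}

#' Ratio of two Bayes factors
#'
#' For two Bayes factors sharing the same null model, the ratio
#' \eqn{\mathrm{BF}_{10}/\mathrm{BF}_{20}} is itself a Bayes factor
#' comparing the two alternative models (transitivity).  Computed on the
#' log scale from the stored `log_bf10` values.
#'
#' @param bf_a,bf_b `bf_result` objects for the same study.
#' @return A positive scalar, \eqn{\mathrm{BF}_{ab}}.
#' @export
bf_ratio <- function(bf_a, bf_b) {
  stopifnot(inherits(bf_a, "bf_result"), inherits(bf_b, "bf_result"))
  if (!identical(bf_a$study_id, bf_b$study_id))
    stop("Bayes factors belong to different studies: ",
         bf_a$study_id, " vs ", bf_b$study_id, call. = FALSE)
  exp(bf_a$log_bf10 - bf_b$log_bf10)
}

#' Monte Carlo marginal-likelihood oracle
#'
#' An independent check on the quadrature engines: draws effect sizes
#' from the prior and averages the likelihood-ratio kernel, giving a
#' simple Monte Carlo estimate of \eqn{\mathrm{BF}_{10}} with a standard
#' error.  Shares the kernel with the quadrature path but not the
#' integration strategy, so systematic quadrature errors would surface as
#' estimates separated by more than a few standard errors.
#'
#' @param record A [study_record()].
#' @param prior A [prior_spec()]; a point prior returns the closed form
#'   with zero standard error.
#' @param draws Number of Monte Carlo draws (at least 1000).
#' @param seed Integer seed; the estimate is reproducible per seed.
#' @return A list with `bf10`, `se`, `log_bf10`, `draws`.
#' @export
mc_marginal_oracle <- function(record, prior, draws = 1e5, seed = 1L) {
  stopifnot(inherits(record, "study_record"), inherits(prior, "prior_spec"))
  if (draws < 1000) stop("draws must be at least 1000", call. = FALSE)
  if (prior$family == "point") {
    bf <- if (record$kind == "correlation") {
      exp(log_corr_kernel(prior$params$value, record$r, record$n))
    } else {
      conv <- ttest_df_neff(record)
      exp(log_t_kernel(prior$params$value, record$t, conv$df, conv$n_eff))
    }
    return(list(bf10 = bf, se = 0, log_bf10 = log(bf), draws = 0L))
  }
  set.seed(seed)
  theta <- prior_sample(prior, draws)
  lk <- if (record$kind == "correlation") {
    log_corr_kernel(theta, record$r, record$n)
  } else {
    conv <- ttest_df_neff(record)
    log_t_kernel(theta, record$t, conv$df, conv$n_eff)
  }
  m <- max(lk)
  w <- exp(lk - m)
  est <- exp(m) * mean(w)
  se <- exp(m) * stats::sd(w) / sqrt(draws)
  list(bf10 = est, se = se, log_bf10 = log(est), draws = as.integer(draws))
}

#' Bayes factors for a whole study database
#'
#' Applies every prior in `priors` to every study in `db` and returns a
#' long-format table.  Studies whose records fail the engine's
#' preconditions are skipped with a recorded reason (attribute
#' `skipped`), not dropped silently.
#'
#' @param db A `correlation_table` or `ttest_table` (see
#'   [read_study_table()], [gen_correlation_db()], [gen_ttest_db()]).
#'   Correlation tables may carry either a single `n` column or equal
#'   `n1`/`n2` columns.
#' @param priors Named list of [prior_spec()] objects, all on the
#'   matching effect-size parameter.
#' @param rel_tol Relative quadrature tolerance passed to the engines.
#' @return A data.frame with columns `study_id`, `prior_label`,
#'   `log_bf10`, `bf10`; attribute `skipped` is a data.frame of skipped
#'   studies and reasons.
#' @export
compute_bf_table <- function(db, priors, rel_tol = 1e-8) {
  stopifnot(is.list(priors), length(priors) >= 1)
  if (is.null(names(priors)) || any(names(priors) == ""))
    names(priors) <- vapply(priors, `[[`, character(1), "label")
  is_corr <- inherits(db, "correlation_table") ||
    (!inherits(db, "ttest_table") && "r" %in% names(db))
  out <- vector("list", nrow(db))
  skipped <- list()
  for (i in seq_len(nrow(db))) {
    row <- db[i, ]
    rec <- tryCatch({
      if (is_corr) {
        n <- if ("n" %in% names(db)) row$n else row$n1
        study_record(as.character(row$study_id), "correlation",
                     r = row$r, n = n)
      } else {
        study_record(as.character(row$study_id), "ttest",
                     design = as.character(row$design), t = row$t,
                     n1 = row$n1,
                     n2 = if (is.na(row$n2)) NULL else row$n2)
      }
    }, error = function(e) e)
    if (inherits(rec, "error")) {
      skipped[[length(skipped) + 1L]] <-
        data.frame(study_id = as.character(row$study_id),
                   reason = conditionMessage(rec))
      next
    }
    res <- lapply(priors, function(pr) {
      b <- if (is_corr) corr_bf10(rec$r, rec$n, pr, study_id = rec$study_id,
                                  rel_tol = rel_tol)
           else ttest_bf10(rec, pr, rel_tol = rel_tol)
      data.frame(study_id = rec$study_id, prior_label = pr$label,
                 log_bf10 = b$log_bf10, bf10 = b$bf10)
    })
    out[[i]] <- do.call(rbind, res)
  }
  tab <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  if (is.null(tab)) {
    tab <- data.frame(study_id = character(), prior_label = character(),
                      log_bf10 = numeric(), bf10 = numeric())
  }
  attr(tab, "skipped") <- if (length(skipped)) do.call(rbind, skipped)
                          else data.frame(study_id = character(),
                                          reason = character())
  tab
}
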