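#' Configuration for the synthetic database generators
#'
#' Describes how to generate a synthetic study database with the
#' statistical structure of the large meta-analytic correlation and
#' t-test databases: the number of studies, an effect-size model, a
#' sample-size model, and (for t-tests) the design mix.
#'
#' Effect models:
#' * `"fixed"`: every study has the same true effect `effect_value`.
#' * `"from_prior"`: true effects drawn from `effect_prior`.
#' * `"two_component"`: a proportion `null_prop` of studies are exact
#'   nulls, the rest draw their effect from `effect_prior`.
#'
#' The sample-size model draws log-uniform integers on
#' `[n_min, n_max]`; when `n_median` is given the log-scale position is
#' power-transformed so the model median equals it (the published
#' databases report only range and median of n).
#'
#' Defaults emulate the published descriptives: correlations —
#' 855 studies, n in \[10, 500\], two-component effects with 50% nulls
#' and the non-null component drawn from a Beta(3.5, 6) prior on
#' \eqn{\rho} (a moderately diffuse small-to-medium-effect
#' distribution, calibrated so the synthetic median r sits near the
#' reported 0.15); t-tests — 855 studies, per-group n in \[2, 212\]
#' with median 24, design mix 85 one-sample / 604 paired /
#' 166 independent, non-null effects from Expert 2's t prior.
#'
#' @param kind `"correlation"` or `"ttest"`.
#' @param n_studies Number of studies.
#' @param effect_model `"two_component"`, `"from_prior"`, or `"fixed"`.
#' @param effect_prior A [prior_spec()] for the non-null component;
#'   defaults by `kind` as above.
#' @param effect_value True effect for `effect_model = "fixed"`.
#' @param null_prop Null proportion for the two-component model.
#' @param n_min,n_max Sample-size bounds (per group for t-tests).
#' @param n_median Optional target median for the sample-size model.
#' @param fixed_n Optional fixed sample size overriding the size model.
#' @param design_mix Named proportions for t-test designs; must sum
#'   to 1.
#' @param seed Integer seed (mandatory; the generators are fully
#'   seeded).
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(kind = c("correlation", "ttest"),
                             n_studies = 855,
                             effect_model = c("two_component",
                                              "from_prior", "fixed"),
                             effect_prior = NULL,
                             effect_value = NULL,
                             null_prop = 0.5,
                             n_min = NULL, n_max = NULL, n_median = NULL,
                             fixed_n = NULL,
                             design_mix = c(one_sample = 85 / 855,
                                            paired = 604 / 855,
                                            independent = 166 / 855),
                             seed) {
  kind <- match.arg(kind)
  effect_model <- match.arg(effect_model)
  if (missing(seed) || !is.finite(seed))
    stop("seed is mandatory in a generator config", call. = FALSE)
  if (is.null(n_min)) n_min <- if (kind == "correlation") 10 else 2
  if (is.null(n_max)) n_max <- if (kind == "correlation") 500 else 212
  if (is.null(n_median) && kind == "ttest") n_median <- 24
  if (n_min < 2) stop("n_min must be >= 2", call. = FALSE)
  if (n_min >= n_max) stop("n_min must be < n_max", call. = FALSE)
  if (effect_model == "fixed" && is.null(effect_value))
    stop("effect_model = 'fixed' requires effect_value", call. = FALSE)
  if (effect_model != "fixed" && is.null(effect_prior)) {
    effect_prior <- if (kind == "correlation") {
      prior_spec("beta", alpha = 3.5, beta = 6,
                 label = "synthetic effects (beta)", parameter = "rho")
    } else {
      expert_registry()[["Expert 2 (t)"]]
    }
  }
  if (!is.null(effect_prior)) stopifnot(inherits(effect_prior,
                                                 "prior_spec"))
  if (null_prop < 0 || null_prop > 1)
    stop("null_prop must be in [0, 1]", call. = FALSE)
  if (kind == "ttest") {
    if (abs(sum(design_mix) - 1) > 1e-8)
      stop("design_mix proportions must sum to 1", call. = FALSE)
    design_mix <- design_mix[c("one_sample", "paired", "independent")]
    if (any(is.na(design_mix)))
      stop("design_mix must name one_sample, paired, independent",
           call. = FALSE)
  }
  structure(
    list(kind = kind, n_studies = as.integer(n_studies),
         effect_model = effect_model, effect_prior = effect_prior,
         effect_value = effect_value, null_prop = null_prop,
         n_min = n_min, n_max = n_max, n_median = n_median,
         fixed_n = fixed_n, design_mix = design_mix,
         seed = as.integer(seed)),
    class = "generator_config"
  )
}

# Log-uniform integer sample sizes; a power transform of the log-scale
# position pins the model median at n_median when requested.
draw_sizes <- function(n, n_min, n_max, n_median = NULL) {
  gamma <- 1
  if (!is.null(n_median)) {
    stopifnot(n_median > n_min, n_median < n_max)
    gamma <- log(log(n_median / n_min) / log(n_max / n_min)) / log(0.5)
  }
  u <- stats::runif(n)
  sizes <- round(n_min * (n_max / n_min)^(u^gamma))
  pmin(pmax(sizes, n_min), n_max)
}

draw_effects <- function(config, n) {
  switch(config$effect_model,
    fixed = list(effect = rep(config$effect_value, n),
                 is_null = rep(config$effect_value == 0, n)),
    from_prior = list(effect = prior_sample(config$effect_prior, n),
                      is_null = rep(FALSE, n)),
    two_component = {
      is_null <- stats::runif(n) < config$null_prop
      eff <- numeric(n)
      eff[!is_null] <- prior_sample(config$effect_prior, sum(!is_null))
      list(effect = eff, is_null = is_null)
    }
  )
}

#' Generate a synthetic correlation database
#'
#' For each study, draws a true correlation \eqn{\rho} from the effect
#' model and a sample size from the size model, then simulates `n`
#' bivariate-normal pairs and records their sample correlation.  The
#' observed `r` thus follows the exact sampling distribution of the
#' correlation coefficient by construction, without reusing the analytic
#' likelihood of the Bayes factor engine — the generator stays an
#' independent check on it.
#'
#' @param config A [generator_config()] with `kind = "correlation"`.
#' @return A `correlation_table` (`study_id`, `r`, `n1 = n2 = n`) with
#'   attribute `truth`: a data.frame of `study_id`, `rho_true`,
#'   `is_null`.
#' @examples
#' cfg <- generator_config("correlation", n_studies = 20, seed = 1)
#' gen_correlation_db(cfg)
#' @export
gen_correlation_db <- function(config) {
  stopifnot(inherits(config, "generator_config"),
            config$kind == "correlation")
  set.seed(config$seed)
  n_st <- config$n_studies
  eff <- draw_effects(config, n_st)
  sizes <- if (!is.null(config$fixed_n)) rep(config$fixed_n, n_st)
           else draw_sizes(n_st, config$n_min, config$n_max,
                           config$n_median)
  r <- vapply(seq_len(n_st), function(i) {
    rho <- eff$effect[i]; n <- sizes[i]
    x <- stats::rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * stats::rnorm(n)
    stats::cor(x, y)
  }, numeric(1))
  ids <- sprintf("synth-c%04d", seq_len(n_st))
  tab <- correlation_table(data.frame(study_id = ids, r = r,
                                      n1 = sizes, n2 = sizes))
  attr(tab, "truth") <- data.frame(study_id = ids,
                                   rho_true = eff$effect,
                                   is_null = eff$is_null)
  tab
}

#' Generate a synthetic t-test database
#'
#' Draws a true Cohen's \eqn{\delta} from the effect model, per-group
#' sample sizes from the size model, and a design from the mix (exact
#' largest-remainder counts, shuffled across studies — so the default
#' 855-study run contains exactly 85 one-sample, 604 paired and 166
#' independent tests).  The t statistic is then drawn from the
#' noncentral-t distribution with the engine's df / effective-n
#' conventions.
#'
#' @param config A [generator_config()] with `kind = "ttest"`.
#' @return A `ttest_table` with attribute `truth` (`study_id`,
#'   `delta_true`, `is_null`).
#' @export
gen_ttest_db <- function(config) {
  stopifnot(inherits(config, "generator_config"), config$kind == "ttest")
  set.seed(config$seed)
  n_st <- config$n_studies
  eff <- draw_effects(config, n_st)

  mix <- config$design_mix
  base <- floor(mix * n_st)
  rem <- n_st - sum(base)
  frac_order <- order(mix * n_st - base, decreasing = TRUE)
  base[frac_order[seq_len(rem)]] <- base[frac_order[seq_len(rem)]] + 1L
  designs <- sample(rep(names(base), times = base))

  n1 <- if (!is.null(config$fixed_n)) rep(config$fixed_n, n_st)
        else draw_sizes(n_st, config$n_min, config$n_max, config$n_median)
  n2 <- ifelse(designs == "independent",
               if (!is.null(config$fixed_n)) config$fixed_n
               else draw_sizes(n_st, config$n_min, config$n_max,
                               config$n_median),
               NA_real_)
  df <- ifelse(designs == "independent", n1 + n2 - 2, n1 - 1)
  n_eff <- ifelse(designs == "independent", n1 * n2 / (n1 + n2), n1)
  t_obs <- suppressWarnings(
    stats::rt(n_st, df = df, ncp = eff$effect * sqrt(n_eff))
  )
  ids <- sprintf("synth-t%04d", seq_len(n_st))
  tab <- ttest_table(data.frame(study_id = ids, design = designs,
                                t = t_obs, n1 = n1, n2 = n2))
  attr(tab, "truth") <- data.frame(study_id = ids,
                                   delta_true = eff$effect,
                                   is_null = eff$is_null)
  tab
}

#' Generate an elicitation grid from a prior
#'
#' Produces histogram-method fixtures: the prior's renormalized bin
#' masses over a ten-bin grid, either as exact expected chip counts
#' (`mode = "deterministic"`, fractional counts allowed — the noiseless
#' input for parameter-recovery checks) or as a seeded multinomial draw
#' (`mode = "multinomial"`).
#'
#' @param prior A [prior_spec()].
#' @param total_chips Total chips to distribute (at least 1).
#' @param mode `"deterministic"` or `"multinomial"`.
#' @param bin_edges 11 ascending bin edges (default `seq(0, 1, 0.1)`).
#' @param seed Seed for the multinomial mode.
#' @return An [elicitation_grid()].
#' @export
gen_elicitation_grid <- function(prior, total_chips = 100,
                                 mode = c("deterministic", "multinomial"),
                                 bin_edges = seq(0, 1, by = 0.1),
                                 seed = 1L) {
  stopifnot(inherits(prior, "prior_spec"))
  mode <- match.arg(mode)
  if (total_chips < 1) stop("total_chips must be >= 1", call. = FALSE)
  probs <- grid_bin_probs(prior, bin_edges)
  if (any(!is.finite(probs)))
    stop("prior places no mass on the elicitation grid", call. = FALSE)
  chips <- if (mode == "deterministic") {
    total_chips * probs
  } else {
    set.seed(seed)
    as.numeric(stats::rmultinom(1, total_chips, probs))
  }
  suppressWarnings(elicitation_grid(bin_edges, chips))
}
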