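#' Elicitation grid (histogram / roulette method)
#'
#' In histogram-method elicitation an expert distributes chips over bins
#' of effect-size values; the chip proportions approximate their
#' subjective distribution.  The grid used here has ten bins spanning the
#' elicitation range (effect sizes 0 to 1 by default) and, in the
#' interview setting, at most ten integer chips per bin.  The constructor
#' accepts non-negative real chip counts so that noiseless expected-count
#' grids can be represented exactly; counts that are non-integer or
#' exceed ten are flagged with a warning as outside the interview
#' convention, but are valid for fitting.
#'
#' @param bin_edges 11 strictly increasing numerics (10 bins).
#' @param chips 10 non-negative chip counts; total must be positive for
#'   fitting.
#' @return An object of class `elicitation_grid`.
#' @examples
#' elicitation_grid(seq(0, 1, 0.1), c(0, 2, 5, 8, 6, 3, 1, 0, 0, 0))
#' @export
elicitation_grid <- function(bin_edges = seq(0, 1, by = 0.1), chips) {
  bin_edges <- as.numeric(bin_edges)
  chips <- as.numeric(chips)
  if (length(bin_edges) != 11L || any(diff(bin_edges) <= 0))
    stop("bin_edges must be 11 strictly increasing values (10 bins)",
         call. = FALSE)
  if (length(chips) != 10L || any(chips < 0) || any(!is.finite(chips)))
    stop("chips must be 10 finite non-negative counts", call. = FALSE)
  if (any(chips > 10) || any(chips %% 1 != 0))
    warning("chip counts outside the interview convention ",
            "(integers, at most 10 per bin)", call. = FALSE)
  structure(list(bin_edges = bin_edges, chips = chips),
            class = "elicitation_grid")
}

#' @export
print.elicitation_grid <- function(x, ...) {
  cat("<elicitation_grid> 10 bins on [", x$bin_edges[1], ", ",
      x$bin_edges[11], "], ", sum(x$chips), " chips\n", sep = "")
  invisible(x)
}

#' Read / write elicitation grids
#'
#' CSV layout: two columns `bin_lower, chips`, ten rows; the upper edge
#' of the last bin is taken as `bin_lower[10] + bin width`.  JSON layout:
#' an object with `bin_edges` (11 values) and `chips` (10 values).
#'
#' @param path File path; format chosen by extension (`.csv` or `.json`).
#' @return An [elicitation_grid()].
#' @export
read_elicitation_grid <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    return(elicitation_grid(obj$bin_edges, obj$chips))
  }
  df <- utils::read.csv(path)
  need <- c("bin_lower", "chips")
  if (!all(need %in% names(df)))
    stop("elicitation grid CSV must have columns: bin_lower, chips",
         call. = FALSE)
  lo <- df$bin_lower
  edges <- c(lo, lo[length(lo)] + (lo[2] - lo[1]))
  elicitation_grid(edges, df$chips)
}

#' @rdname read_elicitation_grid
#' @param grid An [elicitation_grid()].
#' @export
write_elicitation_grid <- function(grid, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(list(bin_edges = grid$bin_edges,
                              chips = grid$chips),
                         path, auto_unbox = FALSE, digits = NA)
  } else {
    utils::write.csv(data.frame(bin_lower = grid$bin_edges[1:10],
                                chips = grid$chips),
                     path, row.names = FALSE)
  }
  invisible(path)
}

# Model bin probabilities: CDF differences across the bin edges,
# renormalized to the mass the prior places on the grid range.
grid_bin_probs <- function(spec, edges) {
  cdf <- prior_cdf(spec, edges)
  total <- cdf[length(cdf)] - cdf[1]
  if (total <= 0) return(rep(NA_real_, length(edges) - 1L))
  diff(cdf) / total
}

#' Fit a parametric prior to an elicitation grid
#'
#' Finds the member of the requested family whose bin probabilities (CDF
#' differences across the grid's bin edges, renormalized to the grid
#' range) are closest, in sum of squared differences, to the observed
#' chip proportions.  This mirrors the least-squares fitting used by
#' roulette-method elicitation tools.  Optimization is bounded
#' quasi-Newton (`L-BFGS-B`) from moment-based start values, so the fit
#' is deterministic given the grid.
#'
#' Degrees of freedom are fitted as a positive real; round for display
#' only.
#'
#' @param grid An [elicitation_grid()] with a positive chip total.
#' @param family `"beta"`, `"t_truncated"`, or `"normal_truncated"`.
#' @return A [prior_spec()] of the requested family, with attributes
#'   `sse` (objective at the optimum) and `convergence` (optim code).
#' @examples
#' g <- gen_elicitation_grid(prior_spec("beta", alpha = 5, beta = 15),
#'                           total_chips = 100, mode = "deterministic")
#' fit_prior_to_grid(g, "beta")
#' @export
fit_prior_to_grid <- function(grid,
                              family = c("beta", "t_truncated",
                                         "normal_truncated")) {
  stopifnot(inherits(grid, "elicitation_grid"))
  family <- match.arg(family)
  chips <- grid$chips
  if (sum(chips) <= 0)
    stop("cannot fit a prior to an empty grid (no chips placed)",
         call. = FALSE)
  props <- chips / sum(chips)
  edges <- grid$bin_edges
  n_par <- switch(family, beta = 2L, normal_truncated = 2L,
                  t_truncated = 3L)
  if (sum(chips > 0) < n_par)
    warning("under-determined fit: fewer occupied bins than free ",
            "parameters; returning best effort", call. = FALSE)

  mids <- (edges[-1] + edges[-11]) / 2
  m <- sum(props * mids)
  v <- max(sum(props * (mids - m)^2), (edges[2] - edges[1])^2 / 12)

  make_spec <- function(par) {
    switch(family,
      beta = prior_spec("beta", alpha = par[1], beta = par[2]),
      t_truncated = prior_spec("t_truncated", mu = par[1], sigma = par[2],
                               nu = par[3]),
      normal_truncated = prior_spec("normal_truncated", mu = par[1],
                                    sigma = par[2])
    )
  }
  objective <- function(par) {
    spec <- make_spec(par)
    pr <- grid_bin_probs(spec, edges)
    if (any(!is.finite(pr))) return(1e6)
    sum((pr - props)^2)
  }

  if (family == "beta") {
    # method-of-moments start on the unit interval
    m01 <- min(max((m - edges[1]) / (edges[11] - edges[1]), 0.02), 0.98)
    v01 <- v / (edges[11] - edges[1])^2
    k <- max(m01 * (1 - m01) / v01 - 1, 0.1)
    start <- c(m01 * k, (1 - m01) * k)
    lower <- c(1e-3, 1e-3); upper <- c(1e3, 1e3)
  } else if (family == "normal_truncated") {
    start <- c(m, sqrt(v))
    lower <- c(edges[1] - diff(range(edges)), 1e-4)
    upper <- c(edges[11] + diff(range(edges)), 10 * diff(range(edges)))
  } else {
    start <- c(m, sqrt(v), 5)
    lower <- c(edges[1] - diff(range(edges)), 1e-4, 0.5)
    upper <- c(edges[11] + diff(range(edges)), 10 * diff(range(edges)), 500)
  }

  opt <- stats::optim(start, objective, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = 500, factr = 1e4))
  fit <- make_spec(opt$par)
  fit$label <- sprintf("fitted %s", family)
  attr(fit, "sse") <- opt$value
  attr(fit, "convergence") <- opt$convergence
  fit
}
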