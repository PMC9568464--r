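#' Evidence categorization schemes
#'
#' Two discretizations of the Bayes factor:
#'
#' * `"strong_bounds"`: three categories — strong evidence for H0
#'   (\eqn{\mathrm{BF}_{10} < 1/10}), inconclusive, strong evidence for
#'   H1 (\eqn{\mathrm{BF}_{10} > 10}).  Inequalities are strict, so a
#'   Bayes factor exactly at a bound counts as inconclusive.
#' * `"jeffreys"`: six categories with edges 1/10, 1/3, 1, 3, 10 —
#'   strong/moderate/anecdotal evidence for H0, then anecdotal/moderate/
#'   strong evidence for H1.  A Bayes factor exactly on an edge is
#'   assigned to the adjacent category closer to 1 (the less extreme
#'   reading); a Bayes factor of exactly 1 is read as anecdotal H0.
#'
#' These boundary conventions concern measure-zero events and are fixed
#' only so results are deterministic.
#'
#' @param scheme `"strong_bounds"` (default) or `"jeffreys"`.
#' @return An object of class `evidence_scheme` with `scheme`, `edges`,
#'   `labels`.
#' @export
evidence_scheme <- function(scheme = c("strong_bounds", "jeffreys")) {
  scheme <- match.arg(scheme)
  if (scheme == "strong_bounds") {
    out <- list(scheme = scheme, edges = c(1 / 10, 10),
                labels = c("strong_H0", "inconclusive", "strong_H1"))
  } else {
    out <- list(scheme = scheme, edges = c(1 / 10, 1 / 3, 1, 3, 10),
                labels = c("strong_H0", "moderate_H0", "anecdotal_H0",
                           "anecdotal_H1", "moderate_H1", "strong_H1"))
  }
  stopifnot(all(diff(out$edges) > 0))
  structure(out, class = "evidence_scheme")
}

#' Categorize Bayes factors into evidence labels
#'
#' @param bf10 Positive Bayes factor(s).
#' @param scheme An [evidence_scheme()] (default `"strong_bounds"`).
#' @return A factor with the scheme's labels as levels.
#' @examples
#' categorize_bf(c(110157, 1, 10, 0.05))
#' @export
categorize_bf <- function(bf10, scheme = evidence_scheme()) {
  stopifnot(inherits(scheme, "evidence_scheme"))
  if (any(!is.finite(bf10) & !is.infinite(bf10)) || any(bf10 <= 0))
    stop("bf10 must be positive", call. = FALSE)
  if (scheme$scheme == "strong_bounds") {
    lab <- ifelse(bf10 > 10, "strong_H1",
                  ifelse(bf10 < 1 / 10, "strong_H0", "inconclusive"))
  } else {
    idx <- findInterval(bf10, scheme$edges) + 1L
    # an exact hit on an edge >= 1 falls in the right-hand interval by
    # findInterval; pull it back to the interval closer to 1
    on_upper_edge <- bf10 %in% scheme$edges[scheme$edges >= 1]
    idx[on_upper_edge] <- idx[on_upper_edge] - 1L
    lab <- scheme$labels[idx]
  }
  factor(lab, levels = scheme$labels)
}

# Align two BF inputs: numeric vectors, lists of bf_result, or
# data.frames with study_id + bf10. Returns a list(a, b) of bf10 vectors.
align_bf_pair <- function(bfs_a, bfs_b) {
  as_bf <- function(x) {
    if (is.numeric(x)) return(list(id = NULL, bf = x))
    if (is.data.frame(x)) return(list(id = as.character(x$study_id),
                                      bf = x$bf10))
    if (is.list(x) && all(vapply(x, inherits, logical(1), "bf_result"))) {
      return(list(id = vapply(x, function(b) as.character(b$study_id),
                              character(1)),
                  bf = vapply(x, `[[`, numeric(1), "bf10")))
    }
    stop("expected numeric bf10 values, bf_result lists, or a data.frame",
         call. = FALSE)
  }
  a <- as_bf(bfs_a); b <- as_bf(bfs_b)
  if (length(a$bf) != length(b$bf))
    stop("misaligned inputs: lengths differ", call. = FALSE)
  if (!is.null(a$id) && !is.null(b$id) && !identical(a$id, b$id))
    stop("misaligned inputs: study ids differ", call. = FALSE)
  list(a = a$bf, b = b$bf)
}

#' Direction agreement between two sets of Bayes factors
#'
#' The proportion of studies in which both Bayes factors fall strictly on
#' the same side of 1 (both favor H1 or both favor H0).  A Bayes factor
#' exactly equal to 1 has no direction and counts as disagreement.
#'
#' @param bfs_a,bfs_b Aligned inputs: numeric `bf10` vectors, lists of
#'   `bf_result`, or data.frames with `study_id` and `bf10`.
#' @return Agreement rate in `[0, 1]`.
#' @examples
#' direction_agreement(c(2, 0.5, 3, 0.2), c(4, 2, 5, 0.9))  # 0.75
#' @export
direction_agreement <- function(bfs_a, bfs_b) {
  p <- align_bf_pair(bfs_a, bfs_b)
  mean((p$a - 1) * (p$b - 1) > 0)
}

#' Evidence-category agreement between two sets of Bayes factors
#'
#' The proportion of studies whose Bayes factors receive the same
#' evidence label under the scheme.  Under the default strong-bounds
#' scheme this is the rate at which neither Bayes factor crosses a
#' strong-evidence threshold that the other does not.
#'
#' @inheritParams direction_agreement
#' @param scheme An [evidence_scheme()].
#' @return Agreement rate in `[0, 1]`.
#' @export
category_agreement <- function(bfs_a, bfs_b, scheme = evidence_scheme()) {
  p <- align_bf_pair(bfs_a, bfs_b)
  mean(categorize_bf(p$a, scheme) == categorize_bf(p$b, scheme))
}

# Long BF table -> wide matrix (studies x priors), checking completeness.
bf_table_wide <- function(bf_table, value = "bf10") {
  priors <- unique(bf_table$prior_label)
  studies <- unique(bf_table$study_id)
  wide <- matrix(NA_real_, length(studies), length(priors),
                 dimnames = list(studies, priors))
  idx <- cbind(match(bf_table$study_id, studies),
               match(bf_table$prior_label, priors))
  wide[idx] <- bf_table[[value]]
  if (any(is.na(wide)))
    stop("missing cells: every prior needs a Bayes factor for every study",
         call. = FALSE)
  wide
}

#' Pairwise agreement matrix across priors
#'
#' For every pair of priors in a long-format Bayes factor table, the
#' agreement rate over all studies, either on the direction of evidence
#' or on the evidence category.
#'
#' @param bf_table Long data.frame with columns `study_id`,
#'   `prior_label`, `bf10` (as from [compute_bf_table()]); every prior
#'   must have a Bayes factor for every study.
#' @param metric `"direction"` or `"category"`.
#' @param scheme An [evidence_scheme()] (category metric only).
#' @return An `agreement_matrix`: a symmetric k x k matrix with unit
#'   diagonal, prior labels as dimnames, and attribute `metric`.
#' @export
pairwise_matrix <- function(bf_table, metric = c("direction", "category"),
                            scheme = evidence_scheme()) {
  metric <- match.arg(metric)
  wide <- bf_table_wide(bf_table)
  k <- ncol(wide)
  m <- diag(1, k)
  dimnames(m) <- list(colnames(wide), colnames(wide))
  if (k > 1) {
    for (i in 1:(k - 1)) {
      for (j in (i + 1):k) {
        rate <- if (metric == "direction") {
          direction_agreement(wide[, i], wide[, j])
        } else {
          category_agreement(wide[, i], wide[, j], scheme)
        }
        m[i, j] <- m[j, i] <- rate
      }
    }
  }
  structure(m, metric = metric, class = c("agreement_matrix", "matrix",
                                          "array"))
}

#' Bayes factor ratio summaries for all prior pairs
#'
#' For each ordered pair of priors (a, b), the per-study ratios
#' \eqn{\mathrm{BF}_{10}^{(a)} / \mathrm{BF}_{10}^{(b)}} — themselves
#' Bayes factors comparing the two alternative models — and quantile
#' summaries, including the fraction of ratios between 1/3 and 3.
#' Ratios satisfy ratio(a, b) = 1 / ratio(b, a) elementwise.
#'
#' @inheritParams pairwise_matrix
#' @param probs Quantiles to report.
#' @return A list with `ratios` (long data.frame: `prior_a`, `prior_b`,
#'   `study_id`, `ratio`, `log_ratio`) and `summary` (one row per ordered
#'   pair with quantiles and `prop_within_3`).
#' @export
ratio_summary <- function(bf_table,
                          probs = c(0.025, 0.25, 0.5, 0.75, 0.975)) {
  wide <- bf_table_wide(bf_table, value = "log_bf10")
  labs <- colnames(wide)
  k <- ncol(wide)
  ratios <- list()
  summ <- list()
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j) next
      lr <- wide[, i] - wide[, j]
      ratios[[length(ratios) + 1L]] <- data.frame(
        prior_a = labs[i], prior_b = labs[j],
        study_id = rownames(wide), ratio = exp(lr), log_ratio = lr,
        row.names = NULL)
      q <- stats::quantile(exp(lr), probs = probs, names = FALSE)
      summ[[length(summ) + 1L]] <- data.frame(
        prior_a = labs[i], prior_b = labs[j],
        t(stats::setNames(q, paste0("q", probs * 100))),
        min = min(exp(lr)), max = max(exp(lr)),
        prop_within_3 = mean(exp(lr) >= 1 / 3 & exp(lr) <= 3),
        row.names = NULL)
    }
  }
  list(ratios = do.call(rbind, ratios), summary = do.call(rbind, summ))
}

#' Flag studies with opposite strong evidence under different priors
#'
#' Scans a long Bayes factor table for studies where one prior yields
#' strong evidence for H1 while another yields strong evidence for H0 —
#' an event that, empirically, does not occur for reasonably overlapping
#' priors, but which is data-dependent and therefore flagged (with a
#' warning) rather than treated as an error.
#'
#' @inheritParams pairwise_matrix
#' @param scheme An [evidence_scheme()] with strong categories.
#' @return A data.frame of offending `study_id`s with the priors giving
#'   strong H1 and strong H0 (zero rows if none); warns when non-empty.
#' @export
strong_conflicts <- function(bf_table, scheme = evidence_scheme()) {
  wide <- bf_table_wide(bf_table)
  cats <- apply(wide, 2, function(col) as.character(categorize_bf(col,
                                                                  scheme)))
  if (is.null(dim(cats))) cats <- matrix(cats, nrow = 1,
                                         dimnames = list(rownames(wide),
                                                         colnames(wide)))
  has_h1 <- apply(cats == "strong_H1", 1, any)
  has_h0 <- apply(cats == "strong_H0", 1, any)
  bad <- which(has_h1 & has_h0)
  out <- do.call(rbind, lapply(bad, function(i) {
    data.frame(study_id = rownames(wide)[i],
               strong_h1_priors = paste(colnames(wide)[cats[i, ] ==
                                                        "strong_H1"],
                                        collapse = ";"),
               strong_h0_priors = paste(colnames(wide)[cats[i, ] ==
                                                        "strong_H0"],
                                        collapse = ";"))
  }))
  if (is.null(out)) out <- data.frame(study_id = character(),
                                      strong_h1_priors = character(),
                                      strong_h0_priors = character())
  if (nrow(out) > 0)
    warning(sprintf("%d study(ies) show strong evidence in opposite %s",
                    nrow(out), "directions under different priors"),
            call. = FALSE)
  out
}
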