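#' Typed study tables
#'
#' `correlation_table()` validates and classes a data.frame of
#' correlation records: `study_id`, `r`, and the two per-variable sample
#' sizes `n1`, `n2` as reported in correlational effect-size databases
#' (a single `n` column is accepted and duplicated into `n1 = n2 = n`).
#' `ttest_table()` does the same for t-test records: `study_id`,
#' `design` (one_sample / paired / independent), `t`, `n1`, `n2` (`n2`
#' may be `NA` except for independent designs).
#'
#' Validation problems are collected row-wise into a `validation`
#' attribute rather than silently dropped; structurally malformed input
#' (missing columns, unparseable numerics) is an error.  Paired designs
#' reporting unequal per-group sizes are flagged in the validation
#' report and analysed with `n = n1` (difference scores).
#'
#' @param df A data.frame.
#' @return The classed table with attribute `validation` (a data.frame
#'   of row indices and messages; zero rows when clean).
#' @export
correlation_table <- function(df) {
  need <- c("study_id", "r")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("schema error: missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!("n1" %in% names(df))) {
    if (!("n" %in% names(df)))
      stop("schema error: missing column(s): n1 (or n)", call. = FALSE)
    df$n1 <- df$n; df$n2 <- df$n
  }
  if (!("n2" %in% names(df))) df$n2 <- df$n1
  for (col in c("r", "n1", "n2")) {
    vals <- df[[col]]
    if (!is.numeric(vals)) {
      parsed <- suppressWarnings(as.numeric(vals))
      bad <- which(is.na(parsed) & !is.na(vals))
      if (length(bad))
        stop(sprintf("parse error in column '%s' at row(s) %s", col,
                     paste(utils::head(bad, 5), collapse = ", ")),
             call. = FALSE)
      df[[col]] <- parsed
    }
  }
  report <- list()
  flag <- function(rows, msg) {
    if (length(rows))
      report[[length(report) + 1L]] <<- data.frame(row = rows, message = msg)
  }
  flag(which(abs(df$r) > 1), "correlation outside [-1, 1]")
  flag(which(df$n1 <= 0 | df$n2 <= 0), "non-positive sample size")
  out <- df[, c("study_id", "r", "n1", "n2")]
  attr(out, "validation") <- if (length(report)) do.call(rbind, report)
                             else data.frame(row = integer(),
                                             message = character())
  class(out) <- c("correlation_table", "data.frame")
  out
}

#' @rdname correlation_table
#' @export
ttest_table <- function(df) {
  need <- c("study_id", "design", "t", "n1")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("schema error: missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!("n2" %in% names(df))) df$n2 <- NA_real_
  for (col in c("t", "n1", "n2")) {
    vals <- df[[col]]
    if (!is.numeric(vals)) {
      parsed <- suppressWarnings(as.numeric(vals))
      bad <- which(is.na(parsed) & !is.na(vals))
      if (length(bad))
        stop(sprintf("parse error in column '%s' at row(s) %s", col,
                     paste(utils::head(bad, 5), collapse = ", ")),
             call. = FALSE)
      df[[col]] <- parsed
    }
  }
  designs <- c("one_sample", "paired", "independent")
  if (!all(df$design %in% designs))
    stop("design must be one of: ", paste(designs, collapse = ", "),
         call. = FALSE)
  report <- list()
  flag <- function(rows, msg) {
    if (length(rows))
      report[[length(report) + 1L]] <<- data.frame(row = rows, message = msg)
  }
  flag(which(df$n1 < 2), "n1 < 2")
  flag(which(df$design == "independent" & (is.na(df$n2) | df$n2 < 2)),
       "independent design with missing or invalid n2")
  flag(which(df$design == "paired" & !is.na(df$n2) & df$n2 != df$n1),
       "paired design with unequal per-group sizes (n = n1 assumed)")
  out <- df[, c("study_id", "design", "t", "n1", "n2")]
  attr(out, "validation") <- if (length(report)) do.call(rbind, report)
                             else data.frame(row = integer(),
                                             message = character())
  class(out) <- c("ttest_table", "data.frame")
  out
}

#' Read a study database from CSV
#'
#' Reads a CSV in either schema and returns the validated typed table.
#' Databases published with other column headers can be adapted with a
#' column mapping — a named character vector (`c(r = "corr", ...)`,
#' names are this package's canonical columns, values the file's
#' headers) or the path to a YAML file holding the same mapping.
#'
#' @param path CSV file path.
#' @param schema `"correlation"` or `"ttest"`.
#' @param mapping Optional column mapping (named character vector or
#'   YAML file path).
#' @return A `correlation_table` or `ttest_table` with a `validation`
#'   attribute.
#' @export
read_study_table <- function(path, schema = c("correlation", "ttest"),
                             mapping = NULL) {
  schema <- match.arg(schema)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(mapping)) {
    if (is.character(mapping) && length(mapping) == 1 &&
        file.exists(mapping) && is.null(names(mapping))) {
      mapping <- unlist(yaml::read_yaml(mapping))
    }
    for (canon in names(mapping)) {
      src <- mapping[[canon]]
      if (!src %in% names(df))
        stop("schema error: mapped column '", src, "' not in file",
             call. = FALSE)
      names(df)[names(df) == src] <- canon
    }
  }
  if (schema == "correlation") correlation_table(df) else ttest_table(df)
}

#' @rdname read_study_table
#' @param table A typed study table to write.
#' @export
write_study_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Filter a correlation database by the published extraction rules
#'
#' Applies, in order: (1) remove perfect correlations (`|r| = 1`);
#' (2) remove rows whose two per-variable sample sizes are unequal or
#' non-integer; (3) remove rows with sample sizes below 10 or above 500.
#' Integerness is checked exactly on the parsed values (tolerance zero).
#' Per-rule removal counts are recorded sequentially, so they sum to
#' rows in minus rows out, and the filter is idempotent.
#'
#' @param table A `correlation_table`.
#' @param n_range Inclusive sample-size bounds, default `c(10, 500)`.
#' @return The filtered `correlation_table` with attribute
#'   `removal_counts` (named: `perfect_r`, `unequal_or_noninteger_n`,
#'   `n_out_of_range`).
#' @export
filter_bosco <- function(table, n_range = c(10, 500)) {
  stopifnot(inherits(table, "correlation_table"))
  counts <- c(perfect_r = 0L, unequal_or_noninteger_n = 0L,
              n_out_of_range = 0L)
  keep <- abs(table$r) < 1
  counts["perfect_r"] <- sum(!keep)
  t1 <- table[keep, , drop = FALSE]

  keep <- t1$n1 == t1$n2 & t1$n1 %% 1 == 0 & t1$n2 %% 1 == 0
  counts["unequal_or_noninteger_n"] <- sum(!keep)
  t2 <- t1[keep, , drop = FALSE]

  keep <- t2$n1 >= n_range[1] & t2$n1 <= n_range[2]
  counts["n_out_of_range"] <- sum(!keep)
  out <- t2[keep, , drop = FALSE]

  rownames(out) <- NULL
  attr(out, "validation") <- attr(table, "validation")
  attr(out, "removal_counts") <- counts
  class(out) <- c("correlation_table", "data.frame")
  out
}

#' Sample one record per study
#'
#' Draws `k` records, at most one per `study_id`, uniformly without
#' replacement: first one record is chosen uniformly within each study,
#' then `k` studies are chosen uniformly among the distinct studies.
#' This enforces independence between the sampled effect sizes when a
#' database reports several correlations per article.  Reproducible per
#' seed.
#'
#' @param table A `correlation_table` (or any study table with
#'   `study_id`).
#' @param k Number of records; must not exceed the number of distinct
#'   studies.
#' @param seed Integer seed.
#' @return A table of `k` rows with distinct `study_id`s.
#' @export
sample_one_per_study <- function(table, k, seed) {
  ids <- unique(as.character(table$study_id))
  if (k > length(ids))
    stop(sprintf("k = %d exceeds the %d distinct studies", k,
                 length(ids)), call. = FALSE)
  set.seed(seed)
  # one uniform row per study, then k studies without replacement
  per_study <- vapply(split(seq_len(nrow(table)),
                            as.character(table$study_id)),
                      function(rows) {
                        if (length(rows) == 1) rows else sample(rows, 1)
                      }, integer(1))
  chosen <- sample(names(per_study), k, replace = FALSE)
  out <- table[per_study[chosen], , drop = FALSE]
  rownames(out) <- NULL
  out
}
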