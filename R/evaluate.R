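#' Evaluation statistics for predicted breeding values
#'
#' The five statistics used to compare prediction methods against the
#' simulated truth:
#'
#' * `accuracy()` -- Pearson correlation between GEBV and TBV.
#' * `bias_slope()` -- OLS regression coefficient of TBV on GEBV; 1 means
#'   correctly dispersed predictions, below 1 means inflated GEBV.
#' * `top_rank_correlation()` -- Spearman correlation between GEBV and TBV
#'   within the top `fraction` of individuals ranked by TBV (average ranks
#'   for ties; the cutoff tie is broken by individual id).
#' * `msep_centered()` -- mean squared prediction error after both vectors
#'   are centered on zero.
#' * `variance_of_estimates()` -- sample variance of the GEBV and its ratio
#'   to the TBV variance (n-1 denominators).
#'
#' @param gebv,tbv Numeric vectors over the same individuals.
#' @return `accuracy()`, `bias_slope()`, `msep_centered()` a single number;
#'   `top_rank_correlation()` a single number; `variance_of_estimates()` a
#'   named list `var`, `ratio`.
#' @examples
#' accuracy(c(1, 2, 3), c(1.1, 1.9, 3.2))
#' bias_slope(gebv = 2 * c(1, 2, 3), tbv = c(1, 2, 3))
#' @export
accuracy <- function(gebv, tbv) {
  check_pair(gebv, tbv, min_n = 3L)
  if (var(gebv) == 0 || var(tbv) == 0) {
    abort("correlation undefined for zero-variance input")
  }
  cor(gebv, tbv)
}

#' @rdname accuracy
#' @export
bias_slope <- function(gebv, tbv) {
  check_pair(gebv, tbv, min_n = 2L)
  v <- var(gebv)
  if (v == 0) abort("bias slope undefined for zero-variance GEBV")
  stats::cov(tbv, gebv) / v
}

#' @rdname accuracy
#' @param fraction Fraction of individuals (by TBV) forming the top set.
#' @param ids Optional ids used to break ties at the cutoff (defaults to
#'   position).
#' @export
top_rank_correlation <- function(gebv, tbv, fraction = 0.10, ids = NULL) {
  check_pair(gebv, tbv, min_n = 2L)
  n <- length(tbv)
  k <- ceiling(fraction * n)
  if (k < 2L) abort("top set must contain at least 2 individuals")
  ids <- ids %||% seq_len(n)
  ord <- order(-tbv, ids)
  top <- ord[seq_len(k)]
  cor(gebv[top], tbv[top], method = "spearman")
}

#' @rdname accuracy
#' @export
msep_centered <- function(gebv, tbv) {
  check_pair(gebv, tbv, min_n = 2L)
  d <- (gebv - mean(gebv)) - (tbv - mean(tbv))
  mean(d^2)
}

#' @rdname accuracy
#' @export
variance_of_estimates <- function(gebv, tbv) {
  check_pair(gebv, tbv, min_n = 2L)
  v <- var(gebv)
  list(var = v, ratio = v / var(tbv))
}

check_pair <- function(gebv, tbv, min_n = 2L) {
  if (length(gebv) != length(tbv)) abort("gebv and tbv lengths differ")
  if (length(gebv) < min_n) abort(sprintf("need at least %d individuals", min_n))
  if (any(!is.finite(gebv)) || any(!is.finite(tbv))) abort("non-finite values")
  invisible(NULL)
}

#' One evaluation row for a prediction method
#'
#' Joins a GEBV table to a TBV table on `individual_id` and computes the
#' comparison-table columns `Var`, `Acc`, `MSEP`, `Rank`, `Regr`.
#'
#' @param gebv A `gs_gebv` tibble (`individual_id`, `gebv`).
#' @param tbv A tibble (`individual_id`, `tbv`), e.g. from
#'   [true_breeding_values()].
#' @param method Method label; defaults to the GEBV table's method
#'   attribute.
#' @param fraction Top fraction for the rank correlation.
#' @return A one-row tibble `Method`, `Var`, `Acc`, `MSEP`, `Rank`, `Regr`.
#' @export
evaluate_gebv <- function(gebv, tbv, method = NULL, fraction = 0.10) {
  method <- method %||% attr(gebv, "method") %||% "method"
  j <- dplyr::inner_join(tibble::as_tibble(gebv), tibble::as_tibble(tbv),
                         by = "individual_id")
  if (nrow(j) == 0L) abort("gebv and tbv share no individuals")
  tibble::tibble(
    Method = method,
    Var = variance_of_estimates(j$gebv, j$tbv)$var,
    Acc = accuracy(j$gebv, j$tbv),
    MSEP = msep_centered(j$gebv, j$tbv),
    Rank = top_rank_correlation(j$gebv, j$tbv, fraction = fraction,
                                ids = j$individual_id),
    Regr = bias_slope(j$gebv, j$tbv))
}

#' Build the method-comparison table
#'
#' Stacks evaluation rows under a TBV reference row (`Var = var(TBV)`,
#' `Acc = 1`, `MSEP = 0`, `Rank = 1`, `Regr = 1`).
#'
#' @param rows A tibble of evaluation rows ([evaluate_gebv()] output), or a
#'   list of them.
#' @param tbv TBV tibble (`individual_id`, `tbv`) for the reference row.
#' @param sort_by_acc Sort method rows by decreasing accuracy?
#' @return A tibble of class `gs_report`.
#' @export
build_comparison_table <- function(rows, tbv, sort_by_acc = FALSE) {
  if (is.list(rows) && !is.data.frame(rows)) rows <- dplyr::bind_rows(rows)
  ref <- tibble::tibble(Method = "TBV", Var = var(tbv$tbv), Acc = 1,
                        MSEP = 0, Rank = 1, Regr = 1)
  if (!is.null(rows) && nrow(rows) > 0) {
    if (anyDuplicated(rows$Method)) abort("method labels must be unique")
    if (sort_by_acc) rows <- dplyr::arrange(rows, dplyr::desc(.data$Acc))
    out <- dplyr::bind_rows(ref, rows)
  } else {
    out <- ref
  }
  structure(out, class = c("gs_report", class(out)))
}

#' @export
print.gs_report <- function(x, ...) {
  cat("Comparison to true breeding values\n")
  df <- as.data.frame(x)
  df[-1] <- lapply(df[-1], function(v) sprintf("%8.3f", v))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write a comparison table as TSV
#'
#' @param report A `gs_report`.
#' @param path Output path.
#' @export
write_report_tsv <- function(report, path) {
  readr::write_tsv(tibble::as_tibble(report), path)
  invisible(path)
}
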