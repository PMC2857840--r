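#' Tidy methods for fitted objects
#'
#' `tidy()` returns the per-unit estimates of a fit as a tibble; `glance()`
#' returns a one-row model summary.
#'
#' @param x A fitted object (`gs_mme`, `gs_posterior`, `gs_rr`,
#'   `gs_curvefit`, `gs_benchmark`).
#' @param ... Unused.
#' @return A tibble.
#' @name gsbench-tidiers
NULL

#' @rdname gsbench-tidiers
#' @export
tidy.gs_mme <- function(x, ...) {
  u <- tibble::as_tibble(x$u, .name_repair = "minimal")
  if (ncol(u) == 1L) names(u) <- "ebv" else names(u) <- paste0("ebv_", seq_len(ncol(u)))
  dplyr::bind_cols(tibble::tibble(individual_id = rownames(x$u)), u)
}

#' @rdname gsbench-tidiers
#' @export
glance.gs_mme <- function(x, ...) {
  tibble::tibble(n_individuals = nrow(x$u), n_records = length(x$record_ids),
                 n_traits = ncol(x$u), lambda = x$lambda,
                 residual_norm = sum(x$residual_norm))
}

#' @rdname gsbench-tidiers
#' @export
tidy.gs_posterior <- function(x, ...) x$markers

#' @rdname gsbench-tidiers
#' @export
glance.gs_posterior <- function(x, ...) {
  tibble::tibble(variant = x$config$variant, n_markers = nrow(x$markers),
                 kept_samples = x$kept, mu = x$mu, sigma2e = x$sigma2e,
                 pi = x$pi, lambda2 = x$lambda2)
}

#' @rdname gsbench-tidiers
#' @export
tidy.gs_rr <- function(x, ...) x$effects

#' @rdname gsbench-tidiers
#' @export
glance.gs_rr <- function(x, ...) {
  tibble::tibble(n_markers = nrow(x$effects), intercept = x$b,
                 lambda_m = x$lambda_m, polygenic = x$polygenic)
}

#' @rdname gsbench-tidiers
#' @export
tidy.gs_curvefit <- function(x, ...) {
  tibble::tibble(term = c("a", "b", "c"),
                 estimate = c(x$a, x$b, x$c))
}

#' @rdname gsbench-tidiers
#' @export
glance.gs_curvefit <- function(x, ...) {
  tibble::tibble(family = x$family, rss = x$rss, converged = x$converged)
}

#' @rdname gsbench-tidiers
#' @export
tidy.gs_benchmark <- function(x, ...) tibble::as_tibble(x$report)
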