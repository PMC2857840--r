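#' Simulate cumulative-yield phenotypes
#'
#' Each phenotyped individual's curve parameters are
#' `theta = curve_mean + g + e`, with environmental deviations drawn
#' independently per parameter from `N(0, sigma2_g (1 - h2) / h2)` so each
#' parameter has heritability `h2`. `sigma2_g` is taken as the realized
#' variance of the genetic deviations among the phenotyped individuals --
#' not the nominal configured variance -- so the delivered dataset carries
#' the stated heritability even though drift, QTL linkage and the small
#' parent pool make the realized genetic variance wobble between
#' replicates. The five cumulative yields are that
#' phenotypic curve evaluated at the configured time points; with the
#' logistic family and positive parameters they are automatically
#' non-decreasing in time. A rate parameter driven non-positive by an
#' extreme draw is clipped to a small positive value with a warning.
#' Optional per-time-point measurement noise (`measurement_sd > 0`) is added
#' and then monotonized with a running maximum, preserving the cumulative
#' reading of the series.
#'
#' @param truth `gs_truth` from [compute_true_values()].
#' @param pedigree Pedigree (supplies the phenotyped flags).
#' @param config A [sim_config()].
#' @param seed Optional RNG seed.
#' @return A tibble (class `gs_phenotypes`) with `individual_id` and one
#'   `y_<time>` column per time point, rows restricted to offspring of
#'   phenotyped families; the phenotypic curve parameters are kept in the
#'   `parameters` attribute (truth side, never written to participant files).
#' @export
simulate_phenotypes <- function(truth, pedigree, config = sim_config(),
                                seed = NULL) {
  with_seed(seed, {
    keep <- pedigree$individual_id[pedigree$phenotyped]
    idx <- match(keep, truth$individual_id)
    if (anyNA(idx)) abort("phenotyped individuals missing from truth table")
    n <- length(keep)
    h2 <- config$h2
    theta <- vapply(param_names(), function(par) {
      g <- truth[[paste0("g_", par)]][idx]
      sig_e <- sqrt(var(g) * (1 - h2) / h2)
      config$curve_mean[[par]] + g + rnorm(n, 0, sig_e)
    }, numeric(n))
    bad_c <- theta[, "c"] <= 0
    if (any(bad_c)) {
      warn(sprintf("clipped %d non-positive rate parameter(s) to positive support",
                   sum(bad_c)))
      theta[bad_c, "c"] <- 1e-4 * config$curve_mean[["c"]]
    }
    tp <- config$time_points
    Y <- vapply(tp, function(t) {
      logistic_curve(t, theta[, "a"], theta[, "b"], theta[, "c"])
    }, numeric(n))
    if (config$measurement_sd > 0) {
      Y <- Y + matrix(rnorm(length(Y), 0, config$measurement_sd), nrow = n)
      Y <- t(apply(Y, 1, cummax))
    }
    colnames(Y) <- paste0("y_", tp)
    out <- dplyr::bind_cols(tibble::tibble(individual_id = keep),
                            tibble::as_tibble(Y))
    attr(out, "time_points") <- tp
    attr(out, "parameters") <- tibble::tibble(
      individual_id = keep, p_a = theta[, "a"], p_b = theta[, "b"],
      p_c = theta[, "c"])
    structure(out, class = c("gs_phenotypes", class(out)))
  })
}
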