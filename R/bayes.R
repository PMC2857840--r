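#' Bayesian whole-genome regression by Gibbs sampling
#'
#' Fits `y = mu + W g + e` over column-centered marker dosages `W` with one
#' of four marker-effect priors:
#'
#' * **BayesA** -- every marker has its own variance drawn from a common
#'   scaled-inverse-chi-squared prior; all markers stay in the model.
#' * **BayesB** -- with prior probability `pi` a marker has a BayesA-type
#'   effect, otherwise its effect is exactly zero; class indicators are
#'   sampled each cycle and their posterior mean is the inclusion
#'   probability.
#' * **BayesC** -- every effect comes from one of two normal distributions,
#'   a large-variance class (markers presumed linked to a QTL) and a
#'   small-variance class, with both class variances sampled; the inclusion
#'   probability is the posterior probability of the large class.
#' * **Bayesian Lasso** -- double-exponential prior via the
#'   normal-exponential scale mixture, with the rate parameter sampled under
#'   a Gamma prior (or fixed).
#'
#' The intercept is sampled; the residual variance gets a flat
#' scaled-inverse-chi-squared prior. Effects are updated by single-site
#' Gibbs in fixed marker order, and all randomness flows through R's RNG so
#' a seed makes the chain fully reproducible.
#'
#' @param y Numeric response vector (no missing values).
#' @param markers Dosage matrix (records x markers), column names = locus
#'   ids. Columns are centered internally.
#' @param config A [bayes_config()]; `run_bayes_a()` etc. force the variant.
#' @return A list of class `gs_posterior`: `markers` (tibble `locus_id`,
#'   `post_mean`, `inclusion_prob`), `mu`, `sigma2e`, `pi`,
#'   `sigma2_large`, `sigma2_small`, `lambda2`, `kept`, `center`
#'   (column means used for centering) and `config`.
#' @export
run_bayes <- function(y, markers, config = bayes_config()) {
  stopifnot(inherits(config, "gs_bayes_config"))
  if (config$polygenic) {
    abort("a polygenic term is not implemented in the Gibbs samplers")
  }
  y <- as.numeric(y)
  if (any(!is.finite(y))) abort("non-finite phenotype")
  M <- as.matrix(markers)
  if (nrow(M) != length(y)) abort("y and markers are incompatible")
  ctr <- colMeans(M)
  W <- sweep(M, 2, ctr)
  p_freq <- ctr / 2
  het <- 2 * sum(pmax(p_freq * (1 - p_freq), 0))
  variant <- match(config$variant, c("A", "B", "C", "lasso")) - 1L

  # prior scale: prior mean marker variance nu*S/(nu-2) matches the
  # equal-split marker variance h2*var(y) / (2 sum p(1-p)); BayesB divides
  # by pi because only the included fraction carries variance
  s2 <- config$s2
  if (is.null(s2)) {
    sigma2g <- config$h2 * var(y)
    sigma2m <- sigma2g / max(het, 1e-12)
    if (config$variant == "B") sigma2m <- sigma2m / config$pi
    s2 <- sigma2m * (config$nu - 2) / config$nu
  }
  lambda2 <- config$lasso_lambda2 %||% -1
  sample_l2 <- is.null(config$lasso_lambda2)
  if (sample_l2) {
    # moment-matched start: prior var of a DE(lambda) effect is 2/lambda^2
    sigma2m0 <- config$h2 * var(y) / max(het, 1e-12)
    lambda2 <- 2 / max(sigma2m0, 1e-12)
  }

  res <- with_seed(config$seed,
    .gibbs_wgr(y, W, variant,
               config$pi, config$sample_pi, config$pi_beta[1], config$pi_beta[2],
               config$nu, s2,
               lambda2, sample_l2, config$lasso_shape, config$lasso_rate,
               isTRUE(config$tie_variances),
               config$n_iter, config$burn_in, config$thin))
  structure(list(
    markers = tibble::tibble(
      locus_id = colnames(M) %||% paste0("m", seq_len(ncol(M))),
      post_mean = res$g_mean,
      inclusion_prob = res$inclusion_prob),
    mu = res$mu_mean, sigma2e = res$sigma2e_mean, pi = res$pi_mean,
    sigma2_large = res$sigma2_large_mean, sigma2_small = res$sigma2_small_mean,
    lambda2 = res$lambda2_mean, kept = res$kept,
    center = ctr, config = config
  ), class = "gs_posterior")
}

#' @rdname run_bayes
#' @param ... Arguments forwarded to [bayes_config()].
#' @export
run_bayes_a <- function(y, markers, ...) {
  run_bayes(y, markers, bayes_config(variant = "A", ...))
}

#' @rdname run_bayes
#' @export
run_bayes_b <- function(y, markers, ...) {
  run_bayes(y, markers, bayes_config(variant = "B", ...))
}

#' @rdname run_bayes
#' @export
run_bayes_c <- function(y, markers, ...) {
  run_bayes(y, markers, bayes_config(variant = "C", ...))
}

#' @rdname run_bayes
#' @export
run_bayes_lasso <- function(y, markers, ...) {
  run_bayes(y, markers, bayes_config(variant = "lasso", ...))
}

#' @export
print.gs_posterior <- function(x, ...) {
  cat(sprintf("<gs_posterior> Bayes%s: %d markers, %d kept samples, sigma2e = %.4g\n",
              x$config$variant, nrow(x$markers), x$kept, x$sigma2e))
  invisible(x)
}

#' Genomic breeding values from posterior marker effects
#'
#' `GEBV_i = sum_k w_ik * post_mean_k` with the same column centering used
#' when the chain was fitted.
#'
#' @param summary A `gs_posterior`.
#' @param genotypes Dosage matrix, `gs_genotypes` or `gs_dataset`; columns
#'   must cover the fitted loci.
#' @return A `gs_gebv` tibble (`individual_id`, `gebv`).
#' @export
predict_from_markers <- function(summary, genotypes) {
  stopifnot(inherits(summary, "gs_posterior"))
  M <- if (is.matrix(genotypes)) genotypes else marker_dosages(genotypes)
  loci <- summary$markers$locus_id
  if (!all(loci %in% colnames(M))) abort("genotypes lack some fitted loci")
  W <- sweep(M[, loci, drop = FALSE], 2, summary$center[loci])
  ids <- rownames(M) %||% seq_len(nrow(M))
  if (!is.matrix(genotypes)) {
    g <- if (inherits(genotypes, "gs_dataset")) genotypes$genotypes else genotypes
    ids <- g$individual_ids
  }
  as_gebv(ids, drop(W %*% summary$markers$post_mean),
          paste0("bayes_", summary$config$variant))
}
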