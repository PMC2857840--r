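#' Assign additive effects to the QTL
#'
#' The QTL on the map are split at random into three groups of six, one per
#' growth-curve parameter. Raw effects are drawn, the QTL with the largest
#' raw variance contribution in each group is designated the large QTL, and
#' all effects are rescaled so that -- at base-population allele frequencies
#' `p` under Hardy-Weinberg, where a QTL with effect `alpha` contributes
#' `2 p (1 - p) alpha^2` -- the large QTL carries exactly `large_qtl_share`
#' (default one half) of that parameter's configured genetic variance and
#' the remaining QTL share the rest equally.
#'
#' @param map Genetic map containing `kind == "qtl"` rows.
#' @param pool Base-population pool (source of base allele frequencies).
#' @param config A [sim_config()].
#' @param seed Optional RNG seed.
#' @return A tibble of class `gs_qtl_model`: `locus_id`, `parameter`
#'   (`"a"|"b"|"c"`), `effect` (per-parameter units, signed), `base_freq`,
#'   `variance_share`.
#' @export
assign_qtl_effects <- function(map, pool, config = sim_config(), seed = NULL) {
  qtl_ids <- map$locus_id[map$kind == "qtl"]
  n_per <- config$n_qtl_per_parameter
  if (length(qtl_ids) != 3L * n_per) {
    abort("map must carry 3 * n_qtl_per_parameter QTL")
  }
  p <- pool$freq[qtl_ids]
  if (any(p <= 0 | p >= 1)) abort("QTL with allele frequency 0 or 1 cannot carry variance")
  with_seed(seed, {
    groups <- split(sample(qtl_ids), rep(param_names(), each = n_per))
    rows <- purrr::imap(groups, function(ids, par) {
      pj <- p[ids]
      raw <- rnorm(length(ids))
      contrib <- 2 * pj * (1 - pj) * raw^2
      big <- which.max(contrib)
      share <- rep((1 - config$large_qtl_share) / (length(ids) - 1L), length(ids))
      share[big] <- config$large_qtl_share
      sg2 <- config$genetic_var[[par]]
      alpha <- unname(sign(raw) * sqrt(share * sg2 / (2 * pj * (1 - pj))))
      tibble::tibble(locus_id = ids, parameter = par, effect = alpha,
                     base_freq = unname(pj), variance_share = share)
    })
    out <- dplyr::bind_rows(rows) |> dplyr::arrange(.data$locus_id)
    structure(out, class = c("gs_qtl_model", class(out)))
  })
}

#' Compute true genetic values and breeding values
#'
#' Per-parameter genetic deviations are the centered QTL sums
#' `g = sum_k alpha_k (dosage_k - 2 p_k)`, so an individual whose dosages sit
#' at twice the base frequency has deviation zero. The true breeding value
#' for yield at time `t` is the curve displacement
#' `f(t; theta_mean + g) - f(t; theta_mean)` with `f` the logistic curve, so
#' zero genetic deviations give TBV 0 at every `t`.
#'
#' @param genotypes `gs_genotypes` carrying QTL columns.
#' @param qtl_model Output of [assign_qtl_effects()].
#' @param config A [sim_config()].
#' @return A tibble of class `gs_truth`: `individual_id`, `g_a`, `g_b`,
#'   `g_c`, `tbv_<eval_time>`; the configured mean curve is kept in the
#'   `curve_mean` attribute and [true_breeding_values()] evaluates TBV at
#'   any time.
#' @export
compute_true_values <- function(genotypes, qtl_model, config = sim_config()) {
  D <- qtl_dosages(genotypes)
  g <- vapply(param_names(), function(par) {
    q <- qtl_model[qtl_model$parameter == par, ]
    W <- sweep(D[, q$locus_id, drop = FALSE], 2, 2 * q$base_freq)
    unname(drop(W %*% q$effect))
  }, numeric(nrow(D)))
  out <- tibble::tibble(
    individual_id = genotypes$individual_ids,
    g_a = g[, "a"], g_b = g[, "b"], g_c = g[, "c"])
  attr(out, "curve_mean") <- config$curve_mean
  attr(out, "eval_time") <- config$eval_time
  out[[paste0("tbv_", format(config$eval_time))]] <-
    tbv_at(out, config$eval_time)
  structure(out, class = c("gs_truth", class(out)))
}

tbv_at <- function(truth, t) {
  m <- attr(truth, "curve_mean")
  logistic_curve(t, m[["a"]] + truth$g_a, m[["b"]] + truth$g_b,
                 m[["c"]] + truth$g_c) -
    logistic_curve(t, m[["a"]], m[["b"]], m[["c"]])
}

#' True breeding values at a chosen time
#'
#' @param x A `gs_truth` table or a `gs_dataset`.
#' @param t Evaluation time (default: the configured evaluation time).
#' @return A tibble `individual_id`, `tbv`.
#' @export
true_breeding_values <- function(x, t = NULL) {
  truth <- if (inherits(x, "gs_dataset")) x$truth else x
  stopifnot(inherits(truth, "gs_truth"))
  t <- t %||% attr(truth, "eval_time")
  tibble::tibble(individual_id = truth$individual_id, tbv = tbv_at(truth, t))
}
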