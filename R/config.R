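#' Simulation configuration
#'
#' Bundles every knob of the synthetic population generator. The defaults
#' reproduce the benchmark design: 25 parents (factorial mating of 20 dams by
#' 5 sires), 100 full-sib families of 20 offspring, 453 biallelic markers on
#' five 1-Morgan chromosomes, 18 QTL (6 per growth-curve parameter, the
#' largest carrying half of that parameter's genetic variance), heritability
#' 0.50 per parameter, cumulative-yield phenotypes at five time points ending
#' at 530 for the offspring of 50 families, and true breeding values evaluated
#' at time 600.
#'
#' @param n_sires,n_dams Number of male and female parents; every sire is
#'   mated to every dam (factorial design), giving `n_sires * n_dams`
#'   full-sib families.
#' @param n_offspring Offspring per full-sib family.
#' @param n_phenotyped_families Families whose offspring receive phenotypes.
#'   Families are phenotyped in full or not at all, balanced across sires.
#' @param markers_per_chromosome Integer vector, markers on each chromosome.
#'   Each chromosome is 1 Morgan long and markers are equally spaced.
#' @param n_qtl_per_parameter QTL controlling each growth-curve parameter.
#' @param large_qtl_share Fraction of a parameter's genetic variance carried
#'   by its largest QTL (at base-population allele frequencies under HWE);
#'   the remaining QTL split the rest equally.
#' @param h2 Narrow-sense heritability of each growth-curve parameter.
#' @param time_points Five strictly increasing phenotyping times.
#' @param eval_time Time at which true breeding values are evaluated; must
#'   exceed the last phenotyping time.
#' @param curve_mean Named vector `c(a=, b=, c=)` of population-mean logistic
#'   parameters for `a / (1 + b * exp(-c * t))`. The default places the
#'   curve's inflection near the evaluation time so that growth is close to
#'   linear over the extrapolation window and the asymptote lies well beyond.
#' @param genetic_var Named vector of additive-genetic variances of the three
#'   parameters. The default makes the three parameters contribute about
#'   equally to the genetic variance of yield at the evaluation time (the
#'   design treats the parameters symmetrically: same QTL count, same
#'   heritability), while keeping the rate parameter's share small enough
#'   that the map from parameter deviations to yield deviations stays close
#'   to linear -- breeding values are additive by definition, so the
#'   simulated truth must behave additively (parent-average resemblance).
#' @param pool_haplotypes Size of the base-population haplotype pool.
#' @param burnin_generations Generations of random mating (population size
#'   `pool_haplotypes / 2`) used to build linkage disequilibrium in the pool.
#' @param founder_freq_range Range of the uniform distribution from which
#'   initial allele frequencies are drawn, per locus.
#' @param maf_min Minimum minor allele frequency a locus must retain in the
#'   burned-in pool; failing loci are re-assigned founder alleles.
#' @param qtl_min_marker_dist Minimum map distance (Morgan) between a QTL and
#'   the nearest marker.
#' @param measurement_sd Optional per-time-point measurement noise (yield
#'   units) added to the cumulative yields; 0 disables it.
#'
#' @return A list of class `gs_config`.
#' @examples
#' cfg <- sim_config()
#' cfg$h2
#' @export
sim_config <- function(n_sires = 5L,
                       n_dams = 20L,
                       n_offspring = 20L,
                       n_phenotyped_families = 50L,
                       markers_per_chromosome = c(91L, 91L, 91L, 90L, 90L),
                       n_qtl_per_parameter = 6L,
                       large_qtl_share = 0.5,
                       h2 = 0.5,
                       time_points = c(106, 212, 318, 424, 530),
                       eval_time = 600,
                       curve_mean = c(a = 100, b = 20, c = 0.005),
                       genetic_var = c(a = 36, b = 5.76, c = 3.6e-8),
                       pool_haplotypes = 100L,
                       burnin_generations = 100L,
                       founder_freq_range = c(0.2, 0.8),
                       maf_min = 0.05,
                       qtl_min_marker_dist = 0.005,
                       measurement_sd = 0) {
  check_number(h2, "h2", lower = 1e-12, upper = 1)
  check_number(large_qtl_share, "large_qtl_share", lower = 0, upper = 1)
  check_number(maf_min, "maf_min", lower = 0, upper = 0.5)
  if (any(diff(time_points) <= 0)) abort("`time_points` must be strictly increasing")
  if (eval_time <= max(time_points)) abort("`eval_time` must exceed the last phenotyping time")
  if (pool_haplotypes %% 2L != 0L || pool_haplotypes < 4L) {
    abort("`pool_haplotypes` must be an even number >= 4")
  }
  cfg <- list(
    n_sires = as.integer(n_sires),
    n_dams = as.integer(n_dams),
    n_offspring = as.integer(n_offspring),
    n_phenotyped_families = as.integer(n_phenotyped_families),
    markers_per_chromosome = as.integer(markers_per_chromosome),
    n_qtl_per_parameter = as.integer(n_qtl_per_parameter),
    large_qtl_share = large_qtl_share,
    h2 = h2,
    time_points = as.numeric(time_points),
    eval_time = as.numeric(eval_time),
    curve_mean = as_param_vec(curve_mean, "curve_mean"),
    genetic_var = as_param_vec(genetic_var, "genetic_var"),
    pool_haplotypes = as.integer(pool_haplotypes),
    burnin_generations = as.integer(burnin_generations),
    founder_freq_range = as.numeric(founder_freq_range),
    maf_min = maf_min,
    qtl_min_marker_dist = qtl_min_marker_dist,
    measurement_sd = measurement_sd
  )
  if (cfg$n_phenotyped_families > cfg$n_sires * cfg$n_dams) {
    abort("more phenotyped families requested than families exist")
  }
  structure(cfg, class = "gs_config")
}

#' @export
print.gs_config <- function(x, ...) {
  cat("<gs_config>\n")
  cat(sprintf("  families: %d sires x %d dams, %d offspring each (%d phenotyped families)\n",
              x$n_sires, x$n_dams, x$n_offspring, x$n_phenotyped_families))
  cat(sprintf("  markers: %d on %d chromosomes; QTL: %d per parameter\n",
              sum(x$markers_per_chromosome), length(x$markers_per_chromosome),
              x$n_qtl_per_parameter))
  cat(sprintf("  h2 = %.2f, phenotypes at {%s}, evaluation at t = %g\n",
              x$h2, paste(x$time_points, collapse = ", "), x$eval_time))
  invisible(x)
}

#' Bayesian whole-genome regression configuration
#'
#' Settings for the Gibbs samplers behind [run_bayes_a()], [run_bayes_b()],
#' [run_bayes_c()] and [run_bayes_lasso()].
#'
#' @param variant One of `"A"`, `"B"`, `"C"`, `"lasso"`.
#' @param pi Prior proportion of markers in the non-zero (BayesB) or
#'   large-effect (BayesC) class. Ignored by BayesA and the Lasso.
#' @param sample_pi For BayesC, sample `pi` from its Beta full conditional
#'   (prior `Beta(pi_beta[1], pi_beta[2])`) instead of fixing it.
#' @param pi_beta Beta prior hyperparameters used when `sample_pi = TRUE`.
#' @param nu Prior degrees of freedom of the scaled-inverse-chi-squared marker
#'   variance prior.
#' @param s2 Prior scale; `NULL` picks it so the prior mean marker variance
#'   equals `h2 * var(y) / (2 * sum(p * (1 - p)))` (divided by `pi` for
#'   BayesB, whose included markers must carry all the variance).
#' @param h2 Heritability used to translate phenotypic variance into the
#'   default prior scale.
#' @param n_iter,burn_in,thin Chain length, burn-in, and thinning interval.
#' @param lasso_lambda2 Fixed squared Lasso rate; `NULL` samples it under a
#'   `Gamma(lasso_shape, lasso_rate)` prior.
#' @param lasso_shape,lasso_rate Gamma hyperparameters for the sampled rate.
#' @param seed Optional RNG seed applied when the sampler runs.
#' @param tie_variances For BayesC: constrain the two class variances to a
#'   single pooled draw (a degenerate one-distribution check).
#' @param polygenic Accepted for interface completeness; the samplers do not
#'   implement an additional pedigree-structured term and stop if it is set.
#'
#' @return A list of class `gs_bayes_config`.
#' @export
bayes_config <- function(variant = c("A", "B", "C", "lasso"),
                         pi = 0.05,
                         sample_pi = (variant == "C"),
                         pi_beta = c(1, 9),
                         nu = 4.2,
                         s2 = NULL,
                         h2 = 0.5,
                         n_iter = 20000L,
                         burn_in = 5000L,
                         thin = 10L,
                         lasso_lambda2 = NULL,
                         lasso_shape = 1,
                         lasso_rate = 1,
                         seed = NULL,
                         tie_variances = FALSE,
                         polygenic = FALSE) {
  variant <- match.arg(variant)
  check_number(pi, "pi", lower = 1e-12, upper = 1)
  check_number(h2, "h2", lower = 1e-12, upper = 1)
  if (n_iter <= burn_in) abort("`n_iter` must exceed `burn_in`")
  if (thin < 1L) abort("`thin` must be >= 1")
  structure(list(
    variant = variant, pi = pi, sample_pi = isTRUE(sample_pi),
    pi_beta = as.numeric(pi_beta), nu = nu, s2 = s2, h2 = h2,
    n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
    thin = as.integer(thin),
    lasso_lambda2 = lasso_lambda2, lasso_shape = lasso_shape,
    lasso_rate = lasso_rate, seed = seed,
    tie_variances = isTRUE(tie_variances), polygenic = isTRUE(polygenic)
  ), class = "gs_bayes_config")
}
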