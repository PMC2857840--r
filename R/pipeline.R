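#' Specify a prediction strategy
#'
#' A strategy wires a prediction method to one of the routes from phenotypes
#' at five time points to breeding values at the target time:
#'
#' * `phenotype_first` -- fit a growth curve per phenotyped individual,
#'   predict the phenotype at the target time, then run the predictor once
#'   on those predicted phenotypes.
#' * `ebv_first` -- run the predictor once per time point and extrapolate
#'   each individual's EBV series to the target time (`linear3` on the last
#'   three points or `quadratic5` on all five).
#' * `curve_params` -- fit curves, run the predictor on each of the three
#'   estimated parameters as traits, and push the predicted parameter
#'   deviations through the curve at the target time.
#' * `best_case` -- regress fitted curve parameters on the true QTL
#'   genotypes (truth side; an upper bound, not a participant method).
#' * `pedigree_only` -- alias for `ebv_first` with the pedigree predictor.
#'
#' @param strategy One of the strategies above.
#' @param predictor `"pedigree_blup"`, `"gblup"`, `"rr_blup"`, `"bayes_a"`,
#'   `"bayes_b"`, `"bayes_c"`, `"bayes_lasso"`. Ignored by `best_case`.
#' @param curve_family `"logistic"` or `"gompertz"` (curve-based routes).
#' @param extrapolation `"linear3"` or `"quadratic5"` (`ebv_first` only).
#' @param target_time Time at which breeding values are reported.
#' @param h2 Heritability handed to the predictor.
#' @param label Unique method label for reports.
#' @param marker_subset Optional marker restriction (locus ids or
#'   chromosome numbers) for marker-based predictors.
#' @param predictor_args Extra arguments for the predictor (e.g.
#'   [bayes_config()] fields such as `pi`, `n_iter`; or `polygenic` for
#'   `rr_blup`).
#' @return A list of class `gs_strategy`.
#' @export
strategy_spec <- function(strategy = c("phenotype_first", "ebv_first",
                                       "curve_params", "best_case",
                                       "pedigree_only"),
                          predictor = "rr_blup",
                          curve_family = "logistic",
                          extrapolation = c("linear3", "quadratic5"),
                          target_time = 600,
                          h2 = 0.5,
                          label = NULL,
                          marker_subset = NULL,
                          predictor_args = list()) {
  strategy <- match.arg(strategy)
  extrapolation <- match.arg(extrapolation)
  if (strategy == "pedigree_only") {
    strategy <- "ebv_first"
    predictor <- "pedigree_blup"
  }
  preds <- c("pedigree_blup", "gblup", "rr_blup",
             "bayes_a", "bayes_b", "bayes_c", "bayes_lasso")
  if (strategy != "best_case" && !predictor %in% preds) {
    abort(sprintf("unknown predictor `%s`", predictor))
  }
  if (strategy == "phenotype_first" && predictor == "pedigree_blup" &&
      !is.null(curve_family)) {
    # allowed: pedigree BLUP on curve-predicted phenotypes is well defined,
    # though the benchmark wirings use it ebv-first
  }
  label <- label %||% paste(strategy,
                            if (strategy == "best_case") "qtl_regression" else predictor,
                            sep = ":")
  structure(list(strategy = strategy, predictor = predictor,
                 curve_family = curve_family, extrapolation = extrapolation,
                 target_time = target_time, h2 = h2, label = label,
                 marker_subset = marker_subset,
                 predictor_args = predictor_args),
            class = "gs_strategy")
}

# Offspring of unphenotyped families: the validation set.
validation_ids <- function(dataset) {
  ped <- dataset$pedigree
  ped$individual_id[!ped$phenotyped & ped$sire_id != 0L]
}

# Run one predictor on a single response, returning GEBV for all individuals
# the method covers. `seed` feeds the Bayes chains.
fit_predictor <- function(dataset, y, predictor, h2, marker_subset = NULL,
                          predictor_args = list(), seed = NULL,
                          cache = new.env(parent = emptyenv())) {
  switch(predictor,
    pedigree_blup = {
      if (is.null(cache$A)) cache$A <- a_matrix(dataset$pedigree)
      pedigree_blup(dataset, h2 = h2, y = y, A = cache$A)
    },
    gblup = {
      if (is.null(cache$G)) {
        cache$G <- g_matrix(dataset, marker_subset = marker_subset)
      }
      gblup(dataset, h2 = h2, y = y, G = cache$G)
    },
    rr_blup = {
      args <- c(list(dataset = dataset, h2 = h2, y = y,
                     marker_subset = marker_subset), predictor_args)
      do.call(rr_blup, args)$gebv
    },
    {
      variant <- c(bayes_a = "A", bayes_b = "B", bayes_c = "C",
                   bayes_lasso = "lasso")[[predictor]]
      args <- c(list(variant = variant, h2 = h2, seed = seed), predictor_args)
      cfg <- do.call(bayes_config, args)
      M <- marker_dosages(dataset, subset = marker_subset)
      tr <- match(y$individual_id, dataset$genotypes$individual_ids)
      post <- run_bayes(y$value, M[tr, , drop = FALSE], cfg)
      predict_from_markers(post, dataset)
    })
}

# Growth-curve fits per phenotyped individual, memoized on the dataset's
# cache environment (fits depend only on the phenotype table and family).
cached_growth_curves <- function(dataset, family) {
  key <- paste0("curve_fits_", family)
  cache <- dataset$cache
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  fits <- fit_growth_curves(dataset$phenotypes, family = family)
  if (!is.null(cache)) cache[[key]] <- fits
  fits
}

# Predicted phenotype at `t_target` per phenotyped individual: curve fit,
# with linear extrapolation of the last three observations as the fallback
# for non-converged fits.
predicted_phenotype <- function(dataset, family, t_target) {
  fits <- cached_growth_curves(dataset, family)
  times <- phenotype_times(dataset$phenotypes)
  y600 <- predict_yield(fits, t_target, family = family)
  bad <- !fits$converged
  if (any(bad)) {
    inform(sprintf("%d curve fit(s) did not converge; falling back to linear extrapolation",
                   sum(bad)))
    last3 <- utils::tail(times, 3)
    ymat <- as.matrix(dataset$phenotypes[bad, paste0("y_", last3), drop = FALSE])
    y600[bad] <- extrapolate_matrix(last3, ymat, t_target, degree = 1L)
  }
  tibble::tibble(individual_id = dataset$phenotypes$individual_id,
                 value = y600)
}

#' Run the phenotype-first strategy
#'
#' Fit the strategy's curve family to each phenotyped individual's yield
#' series, predict the phenotype at the target time, run the predictor on
#' those values, and return GEBV for the unphenotyped offspring.
#'
#' @param dataset A `gs_dataset`.
#' @param spec A [strategy_spec()] with `strategy = "phenotype_first"`.
#' @param seed Optional seed for stochastic predictors.
#' @return A `gs_gebv` tibble restricted to the validation individuals.
#' @export
run_phenotype_first <- function(dataset, spec, seed = NULL) {
  stopifnot(spec$strategy == "phenotype_first")
  y <- predicted_phenotype(dataset, spec$curve_family, spec$target_time)
  gebv <- fit_predictor(dataset, y, spec$predictor, spec$h2,
                        spec$marker_subset, spec$predictor_args, seed)
  restrict_gebv(gebv, validation_ids(dataset), spec$label)
}

#' Run the EBV-first strategy
#'
#' Run the predictor independently at each phenotyping time point and
#' extrapolate each validation individual's EBV series to the target time,
#' either linearly through the last three points or quadratically through
#' all five. BLUP-family predictors reuse one relationship-matrix
#' factorization across the time points.
#'
#' @inheritParams run_phenotype_first
#' @export
run_ebv_first <- function(dataset, spec, seed = NULL) {
  stopifnot(spec$strategy == "ebv_first")
  times <- phenotype_times(dataset$phenotypes)
  ids_val <- validation_ids(dataset)
  if (spec$predictor %in% c("pedigree_blup", "gblup")) {
    K <- if (spec$predictor == "pedigree_blup") {
      a_matrix(dataset$pedigree)
    } else {
      g_matrix(dataset, marker_subset = spec$marker_subset)
    }
    Y <- as.matrix(dataset$phenotypes[, paste0("y_", times)])
    fit <- solve_animal_model(Y, dataset$phenotypes$individual_id, K, spec$h2)
    E <- fit$u[match(as.character(ids_val), rownames(K)), , drop = FALSE]
  } else {
    cache <- new.env(parent = emptyenv())
    cols <- purrr::imap(times, function(t, k) {
      y <- tibble::tibble(individual_id = dataset$phenotypes$individual_id,
                          value = dataset$phenotypes[[paste0("y_", t)]])
      g <- fit_predictor(dataset, y, spec$predictor, spec$h2,
                         spec$marker_subset, spec$predictor_args,
                         seed = if (is.null(seed)) NULL else fan_seed(seed, k),
                         cache = cache)
      g$gebv[match(ids_val, g$individual_id)]
    })
    E <- do.call(cbind, cols)
  }
  ext <- if (spec$extrapolation == "linear3") {
    extrapolate_matrix(utils::tail(times, 3),
                       E[, utils::tail(seq_along(times), 3), drop = FALSE],
                       spec$target_time, degree = 1L)
  } else {
    extrapolate_matrix(times, E, spec$target_time, degree = 2L)
  }
  restrict_gebv(as_gebv(ids_val, ext, spec$predictor), ids_val, spec$label)
}

#' Run the curve-parameter strategy
#'
#' Fit curves per phenotyped individual, run the predictor on each of the
#' three estimated parameters as traits, and reconstruct GEBV at the target
#' time as `f(t; theta_mean + g_hat) - f(t; theta_mean)`, where `theta_mean`
#' is the mean of the estimated parameters over phenotyped individuals (the
#' truth-side mean is not visible to strategies).
#'
#' @inheritParams run_phenotype_first
#' @export
run_curve_params <- function(dataset, spec, seed = NULL) {
  stopifnot(spec$strategy == "curve_params")
  fits <- cached_growth_curves(dataset, spec$curve_family)
  if (any(!fits$converged)) {
    inform(sprintf("dropping %d non-converged curve fit(s) from training",
                   sum(!fits$converged)))
    fits <- fits[fits$converged, ]
  }
  ids_val <- validation_ids(dataset)
  cache <- new.env(parent = emptyenv())
  theta_mean <- c(a = mean(fits$a), b = mean(fits$b), c = mean(fits$c))
  ghat <- purrr::imap(c(a = "a", b = "b", c = "c"), function(par, k) {
    y <- tibble::tibble(individual_id = fits$individual_id,
                        value = fits[[par]])
    g <- fit_predictor(dataset, y, spec$predictor, spec$h2,
                       spec$marker_subset, spec$predictor_args,
                       seed = if (is.null(seed)) NULL else fan_seed(seed, match(par, c("a", "b", "c"))),
                       cache = cache)
    v <- g$gebv[match(ids_val, g$individual_id)]
    v - mean(v)
  })
  f <- curve_fun(spec$curve_family)
  gebv <- f(spec$target_time, theta_mean[["a"]] + ghat$a,
            theta_mean[["b"]] + ghat$b, theta_mean[["c"]] + ghat$c) -
    f(spec$target_time, theta_mean[["a"]], theta_mean[["b"]], theta_mean[["c"]])
  restrict_gebv(as_gebv(ids_val, gebv, "curve_params"), ids_val, spec$label)
}

#' Run the best-case analysis
#'
#' The organizers' upper bound: fit a logistic curve to each phenotyped
#' individual's five yields, regress the three estimated parameters on the
#' 18 true QTL dosages by least squares (one OLS fit per parameter --
#' identical covariates make a joint fit equivalent for the point
#' estimates), predict the parameter genetic deviations of the unphenotyped
#' offspring, and convert them to breeding values at the target time
#' through the logistic curve.
#'
#' @param dataset A `gs_dataset` with truth-side QTL genotypes.
#' @param target_time Evaluation time.
#' @param h2 Unused (kept for a uniform strategy interface).
#' @param curve_family Curve family for the per-individual fits.
#' @param label Method label.
#' @return A `gs_gebv` tibble over the validation individuals.
#' @export
run_best_case <- function(dataset, target_time = 600, h2 = 0.5,
                          curve_family = "logistic", label = "best_case") {
  if (is.null(dataset$qtl) && !("qtl" %in% dataset$map$kind)) {
    abort("best-case analysis needs truth-side QTL genotypes")
  }
  D <- qtl_dosages(dataset)
  fits <- cached_growth_curves(dataset, curve_family)
  fits <- fits[fits$converged, ]
  ids <- dataset$genotypes$individual_ids
  tr <- match(fits$individual_id, ids)
  ids_val <- validation_ids(dataset)
  vi <- match(ids_val, ids)
  Dtr <- D[tr, , drop = FALSE]
  theta_mean <- c(a = mean(fits$a), b = mean(fits$b), c = mean(fits$c))
  ghat <- purrr::map(c(a = "a", b = "b", c = "c"), function(par) {
    fit <- lm(fits[[par]] ~ Dtr)
    beta <- coef(fit)[-1]
    beta[is.na(beta)] <- 0
    sc <- drop(D %*% beta)
    (sc - mean(sc[tr]))[vi]
  })
  f <- curve_fun(curve_family)
  gebv <- f(target_time, theta_mean[["a"]] + ghat$a,
            theta_mean[["b"]] + ghat$b, theta_mean[["c"]] + ghat$c) -
    f(target_time, theta_mean[["a"]], theta_mean[["b"]], theta_mean[["c"]])
  restrict_gebv(as_gebv(ids_val, gebv, "best_case"), ids_val, label)
}

restrict_gebv <- function(gebv, ids, label) {
  out <- gebv[match(ids, gebv$individual_id), ]
  if (anyNA(out$gebv)) abort("predictor did not cover all validation individuals")
  attr(out, "method") <- label
  structure(out, class = unique(c("gs_gebv", class(out))))
}

#' Run one strategy
#'
#' Dispatches a [strategy_spec()] to its runner.
#'
#' @inheritParams run_phenotype_first
#' @export
run_strategy <- function(dataset, spec, seed = NULL) {
  switch(spec$strategy,
    phenotype_first = run_phenotype_first(dataset, spec, seed),
    ebv_first = run_ebv_first(dataset, spec, seed),
    curve_params = run_curve_params(dataset, spec, seed),
    best_case = run_best_case(dataset, target_time = spec$target_time,
                              curve_family = spec$curve_family,
                              label = spec$label))
}

#' The benchmark's standard method set
#'
#' Pedigree BLUP (EBV-first, linear extrapolation of the last three time
#' points), full-marker ridge-regression BLUP and the four Bayesian
#' variants (phenotype-first through a logistic curve), and the best-case
#' QTL regression.
#'
#' @param h2 Heritability handed to every predictor.
#' @param n_iter,burn_in Chain settings for the Bayesian variants.
#' @return A named list of [strategy_spec()]s.
#' @export
default_benchmark_specs <- function(h2 = 0.5, n_iter = 20000L, burn_in = 5000L) {
  bayes <- function(pred) {
    strategy_spec("phenotype_first", pred, curve_family = "logistic", h2 = h2,
                  label = pred,
                  predictor_args = list(n_iter = n_iter, burn_in = burn_in))
  }
  list(
    pedigree_blup = strategy_spec("ebv_first", "pedigree_blup",
                                  extrapolation = "linear3", h2 = h2,
                                  label = "pedigree_blup"),
    rr_blup = strategy_spec("phenotype_first", "rr_blup",
                            curve_family = "logistic", h2 = h2,
                            label = "rr_blup"),
    bayes_a = bayes("bayes_a"),
    bayes_b = bayes("bayes_b"),
    bayes_c = bayes("bayes_c"),
    bayes_lasso = bayes("bayes_lasso"),
    best_case = strategy_spec("best_case", label = "best_case")
  )
}

#' Run the full benchmark
#'
#' Simulates (or accepts) one dataset, executes every strategy, evaluates
#' each GEBV set against the true breeding values at the target time over
#' the unphenotyped offspring, and assembles the comparison table. The
#' master seed fans out to per-method seeds by fixed offsets, so adding a
#' method never perturbs the randomness another method sees. A failing
#' strategy is recorded and skipped; the report is still produced for the
#' rest.
#'
#' @param specs List of [strategy_spec()]s (unique labels).
#' @param dataset A `gs_dataset`, or `NULL` to simulate one.
#' @param config [sim_config()] used when simulating.
#' @param seed Master seed.
#' @param out_dir Optional directory for `report.tsv`, per-method
#'   `gebv_<label>.csv` files and `run.log`.
#' @return A list of class `gs_benchmark`: `report` (`gs_report`), `gebv`
#'   (named list of `gs_gebv`), `tbv`, `errors` (named list of failure
#'   messages), `seed`, `timings` (seconds per method).
#' @export
run_benchmark <- function(specs = default_benchmark_specs(), dataset = NULL,
                          config = sim_config(), seed = 1L, out_dir = NULL) {
  labels <- vapply(specs, function(s) s$label, "")
  if (anyDuplicated(labels)) abort("method labels must be unique")
  if (is.null(dataset)) dataset <- simulate_dataset(config, seed = seed)
  t_target <- specs[[1]]$target_time
  tbv <- true_breeding_values(dataset, t = t_target)
  tbv <- tbv[tbv$individual_id %in% validation_ids(dataset), ]

  gebv_list <- list(); errors <- list(); rows <- list(); timings <- numeric()
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(run_strategy(dataset, sp, seed = fan_seed(seed, 100L + i)),
                    error = function(e) e)
    timings[[sp$label]] <- proc.time()[["elapsed"]] - t0
    if (inherits(res, "error")) {
      errors[[sp$label]] <- conditionMessage(res)
      warn(sprintf("strategy `%s` failed: %s", sp$label, errors[[sp$label]]))
      next
    }
    gebv_list[[sp$label]] <- res
    rows[[sp$label]] <- evaluate_gebv(res, tbv, method = sp$label)
  }
  report <- build_comparison_table(dplyr::bind_rows(rows), tbv)
  out <- structure(list(report = report, gebv = gebv_list, tbv = tbv,
                        errors = errors, seed = seed, timings = timings,
                        dataset = dataset),
                   class = "gs_benchmark")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report_tsv(report, file.path(out_dir, "report.tsv"))
    for (lab in names(gebv_list)) {
      readr::write_csv(tibble::as_tibble(gebv_list[[lab]]),
                       file.path(out_dir, sprintf("gebv_%s.csv", lab)))
    }
    log_lines <- c(sprintf("master seed: %d", seed),
                   sprintf("%s: %.2fs%s", names(timings), timings,
                           ifelse(names(timings) %in% names(errors),
                                  " [FAILED]", "")))
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  out
}

#' @export
print.gs_benchmark <- function(x, ...) {
  print(x$report)
  if (length(x$errors)) {
    cat("failed:", paste(names(x$errors), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Strategy wiring for the published method table
#'
#' Returns the [strategy_spec()] reproducing the wiring of one of the 20
#' numbered methods in the workshop comparison (Gompertz/logistic
#' extrapolation, predictor family, EBV-first linear/quadratic
#' extrapolation, the three-step curve-parameter route, and the best-case
#' regression). Haplotype-covariance methods (9-11) and the
#' three-distribution mixture (14) are outside this package's scope and are
#' rejected with a clear message; the Student-t prior of method 3 is mapped
#' to BayesA (its marginal effect prior is the same scaled-t family), and
#' unspecified "Bayes" entries map to BayesC.
#'
#' @param n Method number, 1-20.
#' @param h2 Heritability handed to the predictor.
#' @return A `gs_strategy`.
#' @export
table1_method <- function(n, h2 = 0.5) {
  if (n %in% c(9, 10, 11)) {
    abort(sprintf("method %d uses haplotype-based covariance models, which are not supported", n))
  }
  if (n == 14) {
    abort("method 14 uses a three-distribution mixture, which is not supported")
  }
  ph <- function(pred, fam) strategy_spec("phenotype_first", pred,
                                          curve_family = fam, h2 = h2,
                                          label = sprintf("method_%02d", n))
  eb <- function(pred, ext, subset = NULL) {
    strategy_spec("ebv_first", pred, extrapolation = ext, h2 = h2,
                  marker_subset = subset, label = sprintf("method_%02d", n))
  }
  switch(as.character(n),
    "1" = ph("bayes_a", "gompertz"),
    "2" = ph("bayes_lasso", "gompertz"),
    "3" = ph("bayes_a", "gompertz"),
    "4" = ph("bayes_b", "gompertz"),
    "5" = strategy_spec("phenotype_first", "rr_blup", curve_family = "logistic",
                        h2 = h2, predictor_args = list(polygenic = TRUE),
                        label = sprintf("method_%02d", n)),
    "6" = eb("gblup", "quadratic5", subset = 1L),
    "7" = eb("bayes_c", "linear3"),
    "8" = eb("pedigree_blup", "linear3"),
    "12" = eb("bayes_a", "linear3"),
    "13" = eb("bayes_c", "linear3"),
    "15" = eb("bayes_c", "linear3"),
    "16" = eb("bayes_a", "linear3"),
    "17" = eb("bayes_b", "linear3"),
    "18" = eb("bayes_c", "linear3"),
    "19" = strategy_spec("curve_params", "bayes_b", curve_family = "gompertz",
                         h2 = h2, label = sprintf("method_%02d", n)),
    "20" = strategy_spec("best_case", label = sprintf("method_%02d", n)),
    abort(sprintf("unknown method number %s", n)))
}
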