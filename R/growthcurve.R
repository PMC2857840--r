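#' Sigmoidal growth-curve families
#'
#' Closed-form evaluation of the two three-parameter curve families used
#' throughout the package: logistic `a / (1 + b * exp(-c * t))` and Gompertz
#' `a * exp(-b * exp(-c * t))`. `a` is the asymptote in yield units, `b` a
#' dimensionless shape parameter and `c` a rate per time unit.
#'
#' @param t Time (vectorized).
#' @param a,b,c Curve parameters (vectorized, recycled against `t`).
#' @return Yield at `t`.
#' @examples
#' logistic_curve(600, a = 100, b = 50, c = 0.01)
#' @export
logistic_curve <- function(t, a, b, c) a / (1 + b * exp(-c * t))

#' @rdname logistic_curve
#' @export
gompertz_curve <- function(t, a, b, c) a * exp(-b * exp(-c * t))

curve_fun <- function(family = c("logistic", "gompertz")) {
  switch(match.arg(family), logistic = logistic_curve, gompertz = gompertz_curve)
}

#' Fit a growth curve to one individual's yield series
#'
#' Nonlinear least squares (Levenberg-Marquardt) of the chosen family to a
#' short cumulative-yield series. Starting values are built from the data
#' (`a0 = 1.2 * max(yields)`, `c0` from the log-linearized series, `b0`
#' solved from the first observation) and a handful of jittered restarts are
#' tried; the best converged fit by residual sum of squares wins.
#'
#' @param times Observation times (>= 3 distinct values).
#' @param yields Observed cumulative yields, same length as `times`.
#' @param family `"logistic"` or `"gompertz"`.
#' @param n_starts Number of jittered restarts after the data-driven start.
#' @return A list of class `gs_curvefit` with elements `a`, `b`, `c`, `rss`,
#'   `converged` and `family`. Degenerate inputs (e.g. constant yields, for
#'   which the asymptote is unidentifiable) return `converged = FALSE` and
#'   `NA` parameters; callers are expected to fall back to linear
#'   extrapolation of the observations.
#' @examples
#' y <- logistic_curve(c(106, 212, 318, 424, 530), 100, 50, 0.01)
#' fit_curve(c(106, 212, 318, 424, 530), y)
#' @export
fit_curve <- function(times, yields, family = c("logistic", "gompertz"),
                      n_starts = 5L) {
  family <- match.arg(family)
  if (length(times) != length(yields)) abort("`times` and `yields` lengths differ")
  if (length(unique(times)) < 3L) abort("need at least 3 distinct time points")
  out <- structure(
    list(a = NA_real_, b = NA_real_, c = NA_real_, rss = Inf,
         converged = FALSE, family = family),
    class = "gs_curvefit")
  if (any(!is.finite(yields)) || stats::sd(yields) < 1e-10 * (abs(mean(yields)) + 1)) {
    return(out)
  }
  starts <- curve_starts(times, yields, family, n_starts)
  f <- curve_fun(family)
  df <- data.frame(t = times, y = yields)
  for (st in starts) {
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        y ~ f(t, a, b, c), data = df, start = st,
        lower = c(a = 1e-8, b = 1e-8, c = 1e-10),
        control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (rss < out$rss) {
      p <- coef(fit)
      out$a <- p[["a"]]; out$b <- p[["b"]]; out$c <- p[["c"]]
      out$rss <- rss; out$converged <- TRUE
    }
  }
  out
}

# Data-driven then jittered starting values.
curve_starts <- function(times, yields, family, n_starts) {
  a0 <- 1.2 * max(yields)
  yy <- pmin(pmax(yields / a0, 1e-6), 1 - 1e-6)
  z <- if (family == "logistic") log(1 / yy - 1) else log(-log(yy))
  sl <- coef(lm(z ~ times))
  c0 <- max(-sl[[2]], 1e-6)
  b0 <- if (family == "logistic") {
    max((a0 / yields[1] - 1) * exp(c0 * times[1]), 1e-6)
  } else {
    max(-log(max(yields[1] / a0, 1e-6)) * exp(c0 * times[1]), 1e-6)
  }
  base <- list(a = a0, b = b0, c = c0)
  jit <- purrr::map(seq_len(n_starts), function(i) {
    # deterministic multiplicative jitter, so fits do not consume RNG state
    fac <- 0.5 + (i - 1) * 0.35
    list(a = a0 * fac^0.25, b = b0 * fac, c = c0 / fac^0.5)
  })
  c(list(base), jit)
}

#' Evaluate a fitted growth curve
#'
#' @param params A `gs_curvefit`, or any list/one-row data frame with
#'   elements `a`, `b`, `c` and (optionally) `family`.
#' @param t Time(s) at which to predict.
#' @param family Curve family, overriding `params$family` when given.
#' @return Predicted yield(s).
#' @export
predict_yield <- function(params, t, family = NULL) {
  fam <- family %||% params$family %||% "logistic"
  curve_fun(fam)(t, params$a, params$b, params$c)
}

#' Fit growth curves to every phenotyped individual
#'
#' @param phenotypes Phenotype table as produced by [simulate_phenotypes()]:
#'   a tibble with `individual_id` and one `y_<time>` column per time point
#'   (times recoverable from the column names or a `time_points` attribute).
#' @inheritParams fit_curve
#' @return A tibble with columns `individual_id`, `a`, `b`, `c`, `rss`,
#'   `converged`.
#' @export
fit_growth_curves <- function(phenotypes, family = c("logistic", "gompertz"),
                              n_starts = 5L) {
  family <- match.arg(family)
  times <- phenotype_times(phenotypes)
  ymat <- as.matrix(phenotypes[, paste0("y_", times)])
  fits <- purrr::map(seq_len(nrow(ymat)), function(i) {
    ft <- fit_curve(times, ymat[i, ], family = family, n_starts = n_starts)
    tibble::tibble(a = ft$a, b = ft$b, c = ft$c, rss = ft$rss,
                   converged = ft$converged)
  })
  dplyr::bind_cols(
    tibble::tibble(individual_id = phenotypes$individual_id),
    dplyr::bind_rows(fits))
}

phenotype_times <- function(phenotypes) {
  tp <- attr(phenotypes, "time_points")
  if (!is.null(tp)) return(tp)
  nm <- grep("^y_", names(phenotypes), value = TRUE)
  if (length(nm) == 0L) abort("no `y_<time>` columns found in phenotype table")
  as.numeric(sub("^y_", "", nm))
}

#' Linear extrapolation through the last observations
#'
#' Ordinary least-squares line through the supplied points, evaluated at
#' `t_target`. The benchmark convention is to pass the last three time
#' points of an EBV or phenotype series.
#'
#' @param times,values Coordinates of the points (same length, >= 2).
#' @param t_target Time at which the line is evaluated.
#' @return Extrapolated value.
#' @examples
#' extrapolate_linear(c(318, 424, 530), c(3, 4, 5), 636)
#' @export
extrapolate_linear <- function(times, values, t_target) {
  if (length(times) < 2L) abort("need at least 2 points for a line")
  drop(extrapolate_matrix(times, matrix(values, nrow = 1), t_target, degree = 1L))
}

#' Quadratic extrapolation through a series
#'
#' Least-squares quadratic through the supplied points (>= 3), evaluated at
#' `t_target`.
#'
#' @inheritParams extrapolate_linear
#' @return Extrapolated value.
#' @export
extrapolate_quadratic <- function(times, values, t_target) {
  if (length(times) < 3L) abort("need at least 3 points for a quadratic")
  drop(extrapolate_matrix(times, matrix(values, nrow = 1), t_target, degree = 2L))
}

# Vectorized polynomial extrapolation: rows of `Y` are individual series
# observed at `times`; returns the degree-`degree` LS polynomial through each
# row evaluated at `t_target`. Times are centered before building the
# Vandermonde matrix for conditioning.
extrapolate_matrix <- function(times, Y, t_target, degree) {
  tc <- times - mean(times)
  TT <- outer(tc, 0:degree, `^`)
  proj <- solve(crossprod(TT), t(TT))            # (degree+1) x k
  coefs <- Y %*% t(proj)                         # n x (degree+1)
  tv <- (t_target - mean(times))^(0:degree)
  drop(coefs %*% tv)
}
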