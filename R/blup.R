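#' Solve the animal model
#'
#' Mixed model `y = X b + Z u + e` with `u ~ (0, K sigma2_g)`,
#' `e ~ (0, I sigma2_e)` and known variance ratio
#' `lambda = sigma2_e / sigma2_g = (1 - h2) / h2`. One record per phenotyped
#' individual and an intercept-only fixed part by default. The solution of
#' Henderson's equations is computed through the algebraically identical
#' GLS/BLUP form
#' `b = (X' V^-1 X)^-1 X' V^-1 y`, `u = K[, p] V^-1 (y - X b)` with
#' `V = K[p, p] + lambda I` over the phenotyped block `p`: this needs no
#' inverse of `K`, so it is exact even for a singular genomic `K`, and
#' predictions are returned for every individual in the relationship
#' structure, phenotyped or not. `y` may be a matrix (one column per trait);
#' the factorization of `V` is reused across columns.
#'
#' @param y Numeric vector (or matrix, traits in columns) of records.
#' @param record_ids Ids of the individuals the rows of `y` belong to.
#' @param K Relationship matrix with id dimnames covering `record_ids`.
#' @param h2 Heritability, in (0, 1).
#' @return A list of class `gs_mme`: `b` (fixed-effect estimates),
#'   `u` (matrix of predictions, all individuals x traits), `lambda`,
#'   `record_ids`, and `residual_norm` (per trait, `||y - Xb - Zu||`).
#' @export
solve_animal_model <- function(y, record_ids, K, h2) {
  check_number(h2, "h2", lower = 1e-12, upper = 1 - 1e-12)
  Y <- as.matrix(y)
  ids <- rownames(K)
  if (is.null(ids)) abort("K must carry individual ids as dimnames")
  p <- match(as.character(record_ids), ids)
  if (anyNA(p)) abort("record ids missing from the relationship matrix")
  if (nrow(Y) != length(p)) abort("y and record_ids lengths differ")
  lambda <- (1 - h2) / h2
  V <- K[p, p, drop = FALSE] + diag(lambda, length(p))
  R <- tryCatch(chol(V), error = function(e) {
    abort(sprintf("animal-model system is singular (chol failed: %s)",
                  conditionMessage(e)))
  })
  Vinv_y <- backsolve(R, forwardsolve(t(R), Y))
  one <- matrix(1, length(p), 1)
  Vinv_1 <- backsolve(R, forwardsolve(t(R), one))
  b <- drop(crossprod(one, Vinv_y)) / drop(crossprod(one, Vinv_1))
  resid <- sweep(Y, 2, b)
  Vinv_r <- backsolve(R, forwardsolve(t(R), resid))
  U <- K[, p, drop = FALSE] %*% Vinv_r
  colnames(U) <- colnames(Y)
  e_hat <- resid - U[p, , drop = FALSE]
  structure(list(b = b, u = U, lambda = lambda,
                 record_ids = as.character(record_ids),
                 residual_norm = sqrt(colSums(e_hat^2))),
            class = "gs_mme")
}

#' @export
print.gs_mme <- function(x, ...) {
  cat(sprintf("<gs_mme> %d individuals, %d trait(s), lambda = %.4g\n",
              nrow(x$u), ncol(x$u), x$lambda))
  invisible(x)
}

# Default single-trait response: phenotype at the last observed time point,
# unless the caller provides `y` as a tibble (individual_id, value).
default_response <- function(dataset, y) {
  if (is.null(y)) {
    tp <- phenotype_times(dataset$phenotypes)
    tibble::tibble(individual_id = dataset$phenotypes$individual_id,
                   value = dataset$phenotypes[[paste0("y_", max(tp))]])
  } else {
    stopifnot(all(c("individual_id", "value") %in% names(y)))
    y
  }
}

as_gebv <- function(ids, gebv, method, dataset = NULL) {
  out <- tibble::tibble(individual_id = ids, gebv = as.numeric(gebv))
  attr(out, "method") <- method
  structure(out, class = c("gs_gebv", class(out)))
}

#' Pedigree BLUP
#'
#' Animal model with the pedigree numerator relationship matrix; marker data
#' are ignored entirely. Unphenotyped full sibs of phenotyped families
#' receive parent-average predictions.
#'
#' @param dataset A `gs_dataset`.
#' @param h2 Heritability used for the shrinkage ratio.
#' @param y Optional response tibble (`individual_id`, `value`); defaults to
#'   the phenotype at the last observed time point.
#' @param A Optional precomputed [a_matrix()].
#' @return A `gs_gebv` tibble (`individual_id`, `gebv`) for all pedigree
#'   members.
#' @export
pedigree_blup <- function(dataset, h2 = 0.5, y = NULL, A = NULL) {
  y <- default_response(dataset, y)
  A <- A %||% a_matrix(dataset$pedigree)
  fit <- solve_animal_model(y$value, y$individual_id, A, h2)
  as_gebv(dataset$pedigree$individual_id, fit$u[, 1], "pedigree_blup")
}

#' GBLUP
#'
#' Animal model with a genomic relationship matrix built from the markers
#' (optionally a subset, e.g. a single chromosome).
#'
#' @inheritParams pedigree_blup
#' @param marker_subset Optional subset (locus ids or chromosome numbers).
#' @param G Optional precomputed [g_matrix()].
#' @return A `gs_gebv` tibble for all genotyped individuals.
#' @export
gblup <- function(dataset, h2 = 0.5, marker_subset = NULL, y = NULL, G = NULL) {
  y <- default_response(dataset, y)
  G <- G %||% g_matrix(dataset, marker_subset = marker_subset)
  fit <- solve_animal_model(y$value, y$individual_id, G, h2)
  as_gebv(dataset$genotypes$individual_ids, fit$u[, 1], "gblup")
}

#' Ridge-regression BLUP
#'
#' Regression of the phenotype on all column-centered marker dosages with a
#' common per-marker shrinkage `lambda_m = sigma2_e / sigma2_m`, where
#' `sigma2_m = sigma2_g / (2 sum_k p_k (1 - p_k))`; with matching centering
#' and scaling the resulting GEBV `W g_hat` are algebraically identical to
#' [gblup()]. With `polygenic = TRUE` half the genetic variance is assigned
#' to the markers and half to an additional pedigree-structured random term
#' (two-random-term mixed-model equations), mirroring ridge implementations
#' that retain a polygene.
#'
#' @inheritParams gblup
#' @param polygenic Add the A-structured polygenic term?
#' @return A list of class `gs_rr`: `effects` (tibble `locus_id`,
#'   `effect`), `gebv` (a `gs_gebv` for all genotyped individuals,
#'   marker part plus polygene when present), `b` (intercept), `lambda_m`.
#' @export
rr_blup <- function(dataset, h2 = 0.5, y = NULL, marker_subset = NULL,
                    polygenic = FALSE) {
  check_number(h2, "h2", lower = 1e-12, upper = 1 - 1e-12)
  y <- default_response(dataset, y)
  M <- marker_dosages(dataset, subset = marker_subset)
  ids <- dataset$genotypes$individual_ids
  p <- colMeans(M) / 2
  keep <- p > 0 & p < 1
  M <- M[, keep, drop = FALSE]; p <- p[keep]
  W <- sweep(M, 2, 2 * p)
  tr <- match(y$individual_id, ids)
  if (anyNA(tr)) abort("response ids missing from genotypes")
  Wp <- W[tr, , drop = FALSE]
  m <- ncol(Wp)
  denom <- 2 * sum(p * (1 - p))
  lam_ratio <- (1 - h2) / h2             # sigma2_e / sigma2_g
  if (!polygenic) {
    lambda_m <- lam_ratio * denom        # sigma2_e / sigma2_m
    C <- rbind(
      cbind(length(tr), t(colSums(Wp))),
      cbind(colSums(Wp), crossprod(Wp) + diag(lambda_m, m)))
    rhs <- c(sum(y$value), crossprod(Wp, y$value))
    sol <- solve(C, rhs)
    b <- sol[1]; g_hat <- sol[-1]
    gebv <- drop(W %*% g_hat)
  } else {
    # markers and polygene each carry half of sigma2_g
    lambda_m <- 2 * lam_ratio * denom
    lambda_a <- 2 * lam_ratio
    A <- a_matrix(dataset$pedigree)
    aid <- rownames(A)
    Zp <- matrix(0, length(tr), nrow(A))
    Zp[cbind(seq_along(tr), match(as.character(y$individual_id), aid))] <- 1
    Ainv <- solve(A)
    C <- rbind(
      cbind(length(tr), t(colSums(Wp)), t(colSums(Zp))),
      cbind(colSums(Wp), crossprod(Wp) + diag(lambda_m, m), crossprod(Wp, Zp)),
      cbind(colSums(Zp), crossprod(Zp, Wp), crossprod(Zp) + lambda_a * Ainv))
    rhs <- c(sum(y$value), crossprod(Wp, y$value), crossprod(Zp, y$value))
    sol <- solve(C, rhs)
    b <- sol[1]
    g_hat <- sol[1 + seq_len(m)]
    u_poly <- sol[-(seq_len(m + 1))]
    gebv <- drop(W %*% g_hat) + u_poly[match(as.character(ids), aid)]
  }
  structure(list(
    effects = tibble::tibble(locus_id = colnames(M), effect = unname(g_hat)),
    gebv = as_gebv(ids, gebv, "rr_blup"),
    b = unname(b), lambda_m = lambda_m, polygenic = polygenic
  ), class = "gs_rr")
}
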