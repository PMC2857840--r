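#' Numerator relationship matrix (A)
#'
#' Tabular method on a parents-first pedigree: for individual `i` with
#' parents `s` and `d`, `A[i, i] = 1 + A[s, d] / 2` and
#' `A[i, j] = (A[j, s] + A[j, d]) / 2` for earlier `j`; an unknown parent
#' contributes 0. Inbreeding is accommodated (diagonal may exceed 1) even
#' though the default simulation produces essentially none.
#'
#' @param pedigree Tibble with `individual_id`, `sire_id`, `dam_id`
#'   (0 = unknown/founder), parents before offspring.
#' @return Symmetric matrix with individual ids as dimnames, class
#'   `gs_relmat`, attribute `kind = "pedigree"`.
#' @export
a_matrix <- function(pedigree) {
  validate_pedigree(pedigree)
  ids <- pedigree$individual_id
  n <- length(ids)
  si <- match(pedigree$sire_id, ids)  # NA for founders
  di <- match(pedigree$dam_id, ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    a_sd <- if (!is.na(s) && !is.na(d)) A[s, d] else 0
    A[i, i] <- 1 + a_sd / 2
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row_s <- if (!is.na(s)) A[j, s] else 0
      row_d <- if (!is.na(d)) A[j, d] else 0
      A[j, i] <- (row_s + row_d) / 2
      A[i, j] <- A[j, i]
    }
  }
  structure(A, kind = "pedigree", class = c("gs_relmat", class(A)))
}

#' Genomic relationship matrix (G)
#'
#' VanRaden-style scaling: `G = W W' / (2 sum_k p_k (1 - p_k))` with `W` the
#' column-centered dosage matrix (`w = dosage - 2 p`) and allele frequencies
#' `p` estimated from the provided genotypes (the full genotyped sample).
#' Monomorphic markers are excluded with a warning. The matrix is invariant
#' to swapping allele labels at any locus.
#'
#' @param genotypes `gs_genotypes`, `gs_dataset`, or a plain dosage matrix
#'   (individuals x markers).
#' @param marker_subset Optional subset passed to [marker_dosages()] (locus
#'   ids or chromosome numbers); ignored for plain matrices.
#' @param ridge Value added to the diagonal to stabilize the matrix when a
#'   downstream user needs an inverse (n individuals typically exceed the
#'   marker count, so G itself is singular). The default leaves G untouched;
#'   the package's own solver never inverts G.
#' @return Symmetric PSD matrix, class `gs_relmat`, `kind = "genomic"`.
#' @export
g_matrix <- function(genotypes, marker_subset = NULL, ridge = 0) {
  M <- if (is.matrix(genotypes)) genotypes else marker_dosages(genotypes, marker_subset)
  if (nrow(M) < 2L || ncol(M) < 1L) abort("need >= 2 individuals and >= 1 marker")
  p <- colMeans(M) / 2
  mono <- p <= 0 | p >= 1
  if (any(mono)) {
    warn(sprintf("excluding %d monomorphic marker(s) from G", sum(mono)))
    M <- M[, !mono, drop = FALSE]
    p <- p[!mono]
    if (ncol(M) == 0L) abort("all markers monomorphic")
  }
  W <- sweep(M, 2, 2 * p)
  G <- tcrossprod(W) / (2 * sum(p * (1 - p)))
  if (ridge > 0) G <- G + diag(ridge, nrow(G))
  dimnames(G) <- list(rownames(M), rownames(M))
  structure(G, kind = "genomic", class = c("gs_relmat", class(G)))
}

#' Dump a relationship matrix as TSV
#'
#' @param K A relationship matrix with id dimnames.
#' @param path Output file.
#' @export
write_relationship_tsv <- function(K, path) {
  df <- dplyr::bind_cols(tibble::tibble(individual_id = rownames(K)),
                         tibble::as_tibble(unclass(K)))
  readr::write_tsv(df, path)
  invisible(path)
}
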