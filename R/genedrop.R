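#' Drop genes down a pedigree
#'
#' Founders draw phased haplotypes from the base-population pool without
#' replacement; every offspring receives one recombinant gamete from each
#' parent, with crossovers per chromosome Poisson-distributed in the map
#' length and uniformly placed (Haldane model, no interference; female and
#' male maps equal).
#'
#' @param pedigree Pedigree from [simulate_pedigree()] (parents first).
#' @param pool Haplotype pool from [simulate_base_population()].
#' @param map Genetic map (defaults to the pool's map).
#' @param seed Optional RNG seed.
#' @return A list of class `gs_genotypes`: `individual_ids`, `map`,
#'   `dosages` (individuals x loci integer matrix counting the reference
#'   allele, all loci including QTL), and phased haplotypes `h1`, `h2`
#'   (`h1` = paternal gamete for offspring).
#' @export
gene_drop <- function(pedigree, pool, map = pool$map, seed = NULL) {
  validate_pedigree(pedigree)
  validate_map(map)
  if (!identical(colnames(pool$haplotypes), map$locus_id)) {
    abort("pool and map disagree on loci")
  }
  with_seed(seed, {
    ids <- pedigree$individual_id
    n <- length(ids)
    L <- nrow(map)
    founder_rows <- which(pedigree$sire_id == 0L & pedigree$dam_id == 0L)
    if (2L * length(founder_rows) > nrow(pool$haplotypes)) {
      abort("haplotype pool too small for the number of founders")
    }
    chr <- map$chromosome
    pos <- map$position_morgan
    chr_lens <- chromosome_lengths(map)

    h1 <- matrix(0L, n, L, dimnames = list(ids, map$locus_id))
    h2 <- h1
    draw <- sample.int(nrow(pool$haplotypes), 2L * length(founder_rows))
    h1[founder_rows, ] <- pool$haplotypes[draw[seq_along(founder_rows) * 2L - 1L], , drop = FALSE]
    h2[founder_rows, ] <- pool$haplotypes[draw[seq_along(founder_rows) * 2L], , drop = FALSE]

    row_of <- match(ids, ids)  # identity; offspring reference parents by id
    for (i in seq_len(n)) {
      s <- pedigree$sire_id[i]
      if (s == 0L) next
      d <- pedigree$dam_id[i]
      si <- match(s, ids); di <- match(d, ids)
      h1[i, ] <- meiosis_origin(h1[si, ], h2[si, ], chr, pos, chr_lens)
      h2[i, ] <- meiosis_origin(h1[di, ], h2[di, ], chr, pos, chr_lens)
    }
    structure(list(individual_ids = ids, map = map,
                   dosages = h1 + h2, h1 = h1, h2 = h2),
              class = "gs_genotypes")
  })
}

#' Marker-only dosage matrix
#'
#' The view prediction methods are allowed to see: reference-allele dosages
#' at marker loci only. QTL columns stay on the truth side.
#'
#' @param genotypes A `gs_genotypes` or a `gs_dataset`.
#' @param subset Optional marker subset: a character vector of locus ids or
#'   an integer vector of chromosome numbers.
#' @return Numeric matrix (individuals x markers) with locus-id column names
#'   and individual-id row names.
#' @export
marker_dosages <- function(genotypes, subset = NULL) {
  g <- if (inherits(genotypes, "gs_dataset")) genotypes$genotypes else genotypes
  stopifnot(inherits(g, "gs_genotypes"))
  keep <- g$map$kind == "marker"
  if (!is.null(subset)) {
    keep <- keep & if (is.character(subset)) {
      g$map$locus_id %in% subset
    } else {
      g$map$chromosome %in% as.integer(subset)
    }
  }
  if (!any(keep)) abort("marker subset selects no loci")
  g$dosages[, keep, drop = FALSE]
}

#' QTL dosage matrix (truth side)
#'
#' @param genotypes A `gs_genotypes` or `gs_dataset`.
#' @return Integer matrix of reference-allele dosages at the QTL.
#' @export
qtl_dosages <- function(genotypes) {
  g <- if (inherits(genotypes, "gs_dataset")) genotypes$genotypes else genotypes
  stopifnot(inherits(g, "gs_genotypes"))
  g$dosages[, g$map$kind == "qtl", drop = FALSE]
}
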