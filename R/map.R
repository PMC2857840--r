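#' Build the genetic map
#'
#' Places the configured markers equally spaced on each 1-Morgan chromosome
#' (marker `j` of `m` sits at `(j - 0.5) / m` Morgan) and drops the QTL at
#' the midpoints of randomly chosen, distinct marker intervals, which keeps
#' every QTL at least half a marker spacing away from the nearest marker.
#'
#' @param config A [sim_config()].
#' @param seed Optional RNG seed for the QTL placement.
#' @return A tibble with columns `locus_id`, `chromosome`, `position_morgan`,
#'   `kind` (`"marker"` or `"qtl"`), ordered by genome position.
#' @export
build_map <- function(config = sim_config(), seed = NULL) {
  with_seed(seed, {
    mpc <- config$markers_per_chromosome
    n_chr <- length(mpc)
    markers <- purrr::map2_dfr(seq_len(n_chr), mpc, function(chr, m) {
      tibble::tibble(
        chromosome = chr,
        position_morgan = (seq_len(m) - 0.5) / m,
        kind = "marker")
    })
    n_qtl <- 3L * config$n_qtl_per_parameter
    # candidate interior interval midpoints (between consecutive markers)
    cand <- purrr::map2_dfr(seq_len(n_chr), mpc, function(chr, m) {
      if (m < 2L) return(tibble::tibble())
      pos <- (seq_len(m) - 0.5) / m
      tibble::tibble(chromosome = chr,
                     position_morgan = (pos[-m] + pos[-1]) / 2)
    })
    if (nrow(cand) < n_qtl) abort("not enough marker intervals to place the QTL")
    pick <- cand[sample.int(nrow(cand), n_qtl), ]
    spacing <- 1 / max(mpc)
    if (spacing / 2 < config$qtl_min_marker_dist) {
      abort("marker spacing too tight for the configured QTL-marker distance")
    }
    pick$kind <- "qtl"
    map <- dplyr::bind_rows(markers, pick) |>
      dplyr::arrange(.data$chromosome, .data$position_morgan)
    # ids in genome order, markers and QTL numbered separately
    map$locus_id <- NA_character_
    map$locus_id[map$kind == "marker"] <-
      sprintf("M%03d", seq_len(sum(map$kind == "marker")))
    map$locus_id[map$kind == "qtl"] <-
      sprintf("Q%02d", seq_len(sum(map$kind == "qtl")))
    dplyr::select(map, "locus_id", "chromosome", "position_morgan", "kind")
  })
}

validate_map <- function(map) {
  stopifnot(all(c("locus_id", "chromosome", "position_morgan", "kind") %in% names(map)))
  by_chr <- split(map$position_morgan, map$chromosome)
  if (!all(vapply(by_chr, function(p) all(diff(p) > 0), TRUE))) {
    abort("positions within a chromosome must be strictly increasing")
  }
  if (any(map$position_morgan > 1 | map$position_morgan < 0)) {
    abort("positions must lie within [0, 1] Morgan")
  }
  invisible(map)
}

# Chromosome lengths used for meiosis: each chromosome spans 1 Morgan.
chromosome_lengths <- function(map) {
  chrs <- sort(unique(map$chromosome))
  setNames(rep(1, length(chrs)), chrs)
}
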