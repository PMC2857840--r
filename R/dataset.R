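#' Simulate a complete benchmark dataset
#'
#' Runs the full generator: map, base-population pool with LD, factorial
#' pedigree, gene drop, QTL effect assignment, true values and phenotypes.
#' The master seed fans out deterministically to the individual stages, so
#' the same `(config, seed)` pair always yields a byte-identical dataset.
#'
#' @param config A [sim_config()].
#' @param seed Master seed (integer).
#' @return A list of class `gs_dataset` with elements `map`, `pedigree`,
#'   `genotypes` (`gs_genotypes`), `phenotypes`, `qtl` (`gs_qtl_model`),
#'   `truth` (`gs_truth`), `pool` and `config`.
#' @examples
#' \donttest{
#' ds <- simulate_dataset(sim_config(), seed = 1)
#' ds
#' }
#' @export
simulate_dataset <- function(config = sim_config(), seed = 1L) {
  map <- build_map(config, seed = fan_seed(seed, 1L))
  pool <- simulate_base_population(map, config, seed = fan_seed(seed, 2L))
  ped <- simulate_pedigree(config, seed = fan_seed(seed, 3L))
  geno <- gene_drop(ped, pool, map, seed = fan_seed(seed, 4L))
  qtl <- assign_qtl_effects(map, pool, config, seed = fan_seed(seed, 5L))
  truth <- compute_true_values(geno, qtl, config)
  phen <- simulate_phenotypes(truth, ped, config, seed = fan_seed(seed, 6L))
  structure(list(map = map, pedigree = ped, genotypes = geno,
                 phenotypes = phen, qtl = qtl, truth = truth,
                 pool = pool, config = config, seed = seed,
                 cache = new.env(parent = emptyenv())),
            class = "gs_dataset")
}

#' @export
print.gs_dataset <- function(x, ...) {
  cat("<gs_dataset>\n")
  cat(sprintf("  %d individuals (%d phenotyped), %d markers + %d QTL on %d chromosomes\n",
              nrow(x$pedigree), sum(x$pedigree$phenotyped),
              sum(x$map$kind == "marker"), sum(x$map$kind == "qtl"),
              length(unique(x$map$chromosome))))
  if (!is.null(x$config)) {
    cat(sprintf("  phenotypes at {%s}, TBV at t = %g\n",
                paste(x$config$time_points, collapse = ", "),
                x$config$eval_time))
  }
  invisible(x)
}

#' Participant-visible view of a dataset
#'
#' Strips everything a benchmark participant must not see: the QTL columns
#' of the genotype matrix, the QTL model, the phased haplotypes and the true
#' breeding values. Prediction methods run identically on this view and on
#' the full dataset.
#'
#' @param dataset A `gs_dataset`.
#' @return A `gs_dataset` without truth-side components.
#' @export
participant_view <- function(dataset) {
  stopifnot(inherits(dataset, "gs_dataset"))
  g <- dataset$genotypes
  keep <- g$map$kind == "marker"
  gv <- structure(list(individual_ids = g$individual_ids,
                       map = g$map[keep, ],
                       dosages = g$dosages[, keep, drop = FALSE],
                       h1 = NULL, h2 = NULL),
                  class = "gs_genotypes")
  structure(list(map = dataset$map[dataset$map$kind == "marker", ],
                 pedigree = dataset$pedigree, genotypes = gv,
                 phenotypes = dataset$phenotypes, qtl = NULL, truth = NULL,
                 pool = NULL, config = dataset$config, seed = dataset$seed,
                 cache = new.env(parent = emptyenv())),
            class = "gs_dataset")
}

#' Write / read a dataset as plain delimited files
#'
#' `write_dataset()` writes the participant-visible files (`pedigree.csv`,
#' `genotypes.csv` with marker dosages only, `map.csv`, `phenotypes.csv`)
#' and, separately, the truth-side files (`qtl_genotypes.csv`,
#' `qtl_effects.csv`, `tbv.csv`). `read_dataset()` restores a `gs_dataset`
#' from such a directory; numeric values round-trip to full precision.
#' Missing participant files raise an explicit error.
#'
#' @param dataset A `gs_dataset`.
#' @param dir Target/source directory.
#' @param truth Write (require) the truth-side files too?
#' @return `write_dataset()` the directory, invisibly; `read_dataset()` a
#'   `gs_dataset` (without pool/haplotypes, which live only in memory).
#' @export
write_dataset <- function(dataset, dir, truth = TRUE) {
  stopifnot(inherits(dataset, "gs_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  readr::write_csv(dataset$pedigree, p("pedigree.csv"))
  readr::write_csv(dataset$map, p("map.csv"))
  mk <- marker_dosages(dataset)
  geno <- dplyr::bind_cols(
    tibble::tibble(individual_id = dataset$genotypes$individual_ids),
    tibble::as_tibble(mk))
  readr::write_csv(geno, p("genotypes.csv"))
  readr::write_csv(tibble::as_tibble(dataset$phenotypes), p("phenotypes.csv"))
  if (truth && !is.null(dataset$truth)) {
    qg <- dplyr::bind_cols(
      tibble::tibble(individual_id = dataset$genotypes$individual_ids),
      tibble::as_tibble(qtl_dosages(dataset)))
    readr::write_csv(qg, p("qtl_genotypes.csv"))
    readr::write_csv(tibble::as_tibble(dataset$qtl), p("qtl_effects.csv"))
    readr::write_csv(tibble::as_tibble(dataset$truth), p("tbv.csv"))
  }
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir, truth = TRUE) {
  p <- function(f) {
    path <- file.path(dir, f)
    if (!file.exists(path)) abort(sprintf("expected file `%s` not found in %s", f, dir))
    path
  }
  rd <- function(f, ...) {
    spec <- readr::cols(.default = readr::col_double(), ...)
    readr::read_csv(p(f), col_types = spec, progress = FALSE)
  }
  ped <- rd("pedigree.csv", phenotyped = readr::col_logical())
  ped$individual_id <- as.integer(ped$individual_id)
  ped$sire_id <- as.integer(ped$sire_id)
  ped$dam_id <- as.integer(ped$dam_id)
  ped$family_id <- as.integer(ped$family_id)
  ped$phenotyped <- as.logical(ped$phenotyped)
  map <- rd("map.csv", locus_id = readr::col_character(),
            kind = readr::col_character())
  map$chromosome <- as.integer(map$chromosome)
  geno_tab <- rd("genotypes.csv")
  phen <- rd("phenotypes.csv")
  tp <- as.numeric(sub("^y_", "", grep("^y_", names(phen), value = TRUE)))
  attr(phen, "time_points") <- tp
  phen$individual_id <- as.integer(phen$individual_id)
  class(phen) <- c("gs_phenotypes", class(phen))

  ids <- as.integer(geno_tab$individual_id)
  marker_map <- map[map$kind == "marker", ]
  dos <- as.matrix(geno_tab[, marker_map$locus_id, drop = FALSE])
  storage.mode(dos) <- "integer"
  rownames(dos) <- ids

  qtl <- NULL; truth_tab <- NULL
  if (truth) {
    qg <- rd("qtl_genotypes.csv")
    qd <- as.matrix(qg[, setdiff(names(qg), "individual_id"), drop = FALSE])
    storage.mode(qd) <- "integer"
    qtl <- rd("qtl_effects.csv", locus_id = readr::col_character(),
              parameter = readr::col_character())
    class(qtl) <- c("gs_qtl_model", class(qtl))
    full_map <- map
    dos_all <- cbind(dos, qd)[, full_map$locus_id, drop = FALSE]
    geno <- structure(list(individual_ids = ids, map = full_map,
                           dosages = dos_all, h1 = NULL, h2 = NULL),
                      class = "gs_genotypes")
    truth_tab <- rd("tbv.csv")
    truth_tab$individual_id <- as.integer(truth_tab$individual_id)
    tbv_col <- grep("^tbv_", names(truth_tab), value = TRUE)
    attr(truth_tab, "eval_time") <- as.numeric(sub("^tbv_", "", tbv_col[1]))
    class(truth_tab) <- c("gs_truth", class(truth_tab))
  } else {
    geno <- structure(list(individual_ids = ids, map = marker_map,
                           dosages = dos, h1 = NULL, h2 = NULL),
                      class = "gs_genotypes")
    map <- marker_map
  }
  structure(list(map = map, pedigree = ped, genotypes = geno,
                 phenotypes = phen, qtl = qtl, truth = truth_tab,
                 pool = NULL, config = NULL, seed = NULL,
                 cache = new.env(parent = emptyenv())),
            class = "gs_dataset")
}
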