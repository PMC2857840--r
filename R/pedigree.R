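#' Simulate the factorial-mating pedigree
#'
#' Every sire is mated to every dam, so the default 5 sires x 20 dams give
#' 100 full-sib families of `n_offspring` each. Families are flagged
#' phenotyped as whole units (no family is split) and the phenotyped
#' families are balanced across sires.
#'
#' @param config A [sim_config()].
#' @param seed Optional RNG seed (which families are phenotyped).
#' @return A tibble with columns `individual_id`, `sire_id`, `dam_id`
#'   (0 marks a founder parent field), `family_id` (`NA` for parents) and
#'   `phenotyped`. Parents precede all offspring.
#' @export
simulate_pedigree <- function(config = sim_config(), seed = NULL) {
  with_seed(seed, {
    ns <- config$n_sires; nd <- config$n_dams; no <- config$n_offspring
    sires <- seq_len(ns)
    dams <- ns + seq_len(nd)
    parents <- tibble::tibble(
      individual_id = c(sires, dams),
      sire_id = 0L, dam_id = 0L,
      family_id = NA_integer_, phenotyped = FALSE)

    fams <- tidyr::expand_grid(sire_id = sires, dam_id = dams)
    fams$family_id <- seq_len(nrow(fams))
    # balanced phenotyping across sires: an equal share of each sire's
    # families is flagged (remainder families allocated at random)
    per_sire <- split(fams$family_id, fams$sire_id)
    n_ph <- config$n_phenotyped_families
    base_k <- n_ph %/% ns
    extra <- n_ph - base_k * ns
    extra_sires <- if (extra > 0) sample(seq_len(ns), extra) else integer()
    ph_fams <- unlist(purrr::imap(per_sire, function(ids, s) {
      k <- base_k + as.integer(as.integer(s) %in% extra_sires)
      if (k > length(ids)) abort("cannot balance phenotyped families across sires")
      sample(ids, k)
    }), use.names = FALSE)
    fams$phenotyped <- fams$family_id %in% ph_fams

    offspring <- fams[rep(seq_len(nrow(fams)), each = no), ]
    offspring$individual_id <- ns + nd + seq_len(nrow(offspring))
    offspring <- dplyr::select(offspring, "individual_id", "sire_id",
                               "dam_id", "family_id", "phenotyped")
    dplyr::bind_rows(parents, offspring)
  })
}

validate_pedigree <- function(pedigree) {
  ids <- pedigree$individual_id
  if (anyDuplicated(ids)) abort("duplicated individual ids in pedigree")
  pos <- match(ids, ids)
  for (col in c("sire_id", "dam_id")) {
    par <- pedigree[[col]]
    known <- par != 0L
    idx <- match(par[known], ids)
    if (anyNA(idx)) abort(sprintf("%s refers to unknown individuals", col))
    if (any(idx >= which(known))) abort("parents must precede their offspring")
  }
  invisible(pedigree)
}
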