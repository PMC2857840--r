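# Shared fixtures, memoized per test run. Everything is generated in code;
# the small configuration keeps unit tests fast while the default replicate
# backs the benchmark-level checks.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# Reduced population: 8 families of 8, 60 markers on 2 chromosomes.
toy_config <- function(...) {
  sim_config(n_sires = 2L, n_dams = 4L, n_offspring = 8L,
             n_phenotyped_families = 4L,
             markers_per_chromosome = c(30L, 30L),
             pool_haplotypes = 60L, burnin_generations = 30L, ...)
}

toy_dataset <- function() memo("toy", simulate_dataset(toy_config(), seed = 11L))

# The full benchmark-scale replicate used by the acceptance-level tests.
default_dataset <- function() memo("default", simulate_dataset(sim_config(), seed = 1L))

validation_tbv <- function(ds, t = 600) {
  tb <- true_breeding_values(ds, t)
  val <- ds$pedigree$individual_id[!ds$pedigree$phenotyped & ds$pedigree$sire_id != 0L]
  tb[match(val, tb$individual_id), ]
}

acc_against <- function(gebv, tbv_tab) {
  j <- merge(as.data.frame(gebv), as.data.frame(tbv_tab), by = "individual_id")
  accuracy(j$gebv, j$tbv)
}

# Hand-built pedigree: 2 founders, their 2 full-sib offspring, one
# grand-offspring from a sib x founder backcross-like mating.
textbook_pedigree <- function() {
  tibble::tibble(
    individual_id = 1:5,
    sire_id = c(0L, 0L, 1L, 1L, 3L),
    dam_id = c(0L, 0L, 2L, 2L, 4L),
    family_id = c(NA, NA, 1L, 1L, 2L),
    phenotyped = c(FALSE, FALSE, TRUE, TRUE, FALSE))
}
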