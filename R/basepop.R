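#' Simulate the base-population haplotype pool
#'
#' Builds linkage disequilibrium by random mating: a closed population of
#' `pool_haplotypes / 2` diploids is mated at random for
#' `burnin_generations` generations with Haldane meiosis, tracking for every
#' final haplotype which founder haplotype each locus descends from. Founder
#' alleles are then drawn i.i.d. per locus at a frequency sampled from
#' `founder_freq_range` and propagated through the recorded ancestry, so LD
#' reflects shared descent. Loci whose minor allele frequency falls below
#' `maf_min` in the final pool (drift loss) have their founder alleles
#' redrawn -- ancestry, and hence LD with neighbours, is untouched -- until
#' they segregate or the attempt budget is exhausted. A locus whose
#' ancestry has coalesced so far that no founder assignment can reach the
#' MAF floor (with this much drift a minority of loci fully coalesce) is
#' instead replaced by an independent single-locus Wright-Fisher redraw of
#' the same depth: correct marginal allele-frequency distribution, but no
#' linkage disequilibrium with its neighbours.
#'
#' With `burnin_generations = 0` the pool is simply i.i.d. alleles at the
#' configured frequencies: no drift and no LD.
#'
#' @param map Genetic map from [build_map()].
#' @param config A [sim_config()].
#' @param seed Optional RNG seed.
#' @param max_resample Attempts allowed per low-MAF locus before erroring.
#' @return A list of class `gs_pool`: `haplotypes` (pool x loci 0/1 integer
#'   matrix, columns named by locus), `freq` (pool allele-1 frequencies) and
#'   `map`.
#' @export
simulate_base_population <- function(map, config = sim_config(), seed = NULL,
                                     max_resample = 100L) {
  validate_map(map)
  with_seed(seed, {
    n_hap <- config$pool_haplotypes
    n_ind <- n_hap %/% 2L
    L <- nrow(map)
    chr <- map$chromosome
    pos <- map$position_morgan
    chr_lens <- chromosome_lengths(map)

    # ancestry: origins[h, j] = founder haplotype that locus j of pool
    # haplotype h descends from
    origins <- matrix(rep(seq_len(n_hap), L), nrow = n_hap)
    G <- config$burnin_generations
    if (G > 0L) {
      for (g in seq_len(G)) {
        nxt <- matrix(0L, nrow = n_hap, ncol = L)
        for (i in seq_len(n_ind)) {
          par <- sample.int(n_ind, 2L, replace = FALSE)
          nxt[2L * i - 1L, ] <- meiosis_origin(origins[2L * par[1] - 1L, ],
                                               origins[2L * par[1], ], chr, pos, chr_lens)
          nxt[2L * i, ] <- meiosis_origin(origins[2L * par[2] - 1L, ],
                                          origins[2L * par[2], ], chr, pos, chr_lens)
        }
        origins <- nxt
      }
    }

    f <- config$founder_freq_range
    p0 <- runif(L, f[1], f[2])
    founder <- matrix(rbinom(n_hap * L, 1L, rep(p0, each = n_hap)), nrow = n_hap)
    haps <- matrix(founder[cbind(as.vector(origins), rep(seq_len(L), each = n_hap))],
                   nrow = n_hap)

    freq <- colMeans(haps)
    low <- which(pmin(freq, 1 - freq) < config$maf_min)
    for (j in low) {
      ok <- FALSE
      # an assignment can only segregate if >= 2 founder lineages survive
      # with enough copies on each side of the split
      n_origins <- length(unique(origins[, j]))
      if (n_origins >= 2L) {
        for (att in seq_len(max_resample)) {
          pj <- runif(1, f[1], f[2])
          col <- rbinom(n_hap, 1L, pj)[origins[, j]]
          fj <- mean(col)
          if (min(fj, 1 - fj) >= config$maf_min) {
            haps[, j] <- col
            ok <- TRUE
            break
          }
        }
      }
      if (!ok) {
        col <- wf_column(n_hap, G, f, config$maf_min, max_resample)
        if (is.null(col)) {
          abort(sprintf(
            "locus %s stayed below the minimum MAF after %d resampling attempts",
            map$locus_id[j], max_resample))
        }
        haps[, j] <- col
      }
    }
    colnames(haps) <- map$locus_id
    structure(list(haplotypes = haps, freq = colMeans(haps), map = map),
              class = "gs_pool")
  })
}

# Independent single-locus Wright-Fisher redraw of depth G on 2N = n_hap
# gene copies; returns a 0/1 column meeting the MAF floor, or NULL if the
# attempt budget runs out.
wf_column <- function(n_hap, G, freq_range, maf_min, max_attempts) {
  for (att in seq_len(max_attempts)) {
    p <- runif(1, freq_range[1], freq_range[2])
    for (g in seq_len(G)) {
      p <- rbinom(1L, n_hap, p) / n_hap
      if (p == 0 || p == 1) break
    }
    if (min(p, 1 - p) >= maf_min) {
      return(sample(c(rep(1L, round(p * n_hap)),
                      rep(0L, n_hap - round(p * n_hap)))))
    }
  }
  NULL
}

# One meiosis on ancestry (or allele) vectors: per chromosome, crossovers are
# Poisson(length) with uniform positions (Haldane, no interference) and the
# starting strand is chosen at random. Works for any integer payload.
meiosis_origin <- function(h1, h2, chr, pos, chr_lens) {
  gamete <- h1
  for (cc in seq_along(chr_lens)) {
    idx <- which(chr == as.integer(names(chr_lens)[cc]))
    n_xo <- rpois(1L, chr_lens[cc])
    start <- sample.int(2L, 1L)
    if (n_xo == 0L) {
      if (start == 2L) gamete[idx] <- h2[idx]
      next
    }
    xo <- sort(runif(n_xo, 0, chr_lens[cc]))
    seg <- findInterval(pos[idx], xo)  # 0-based segment index
    use2 <- (seg + start) %% 2L == 1L
    take <- idx[use2]
    gamete[take] <- h2[take]
    gamete[idx[!use2]] <- h1[idx[!use2]]
  }
  gamete
}
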