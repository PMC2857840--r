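test_that("default map carries 453 equally spaced markers and 18 off-marker QTL", {
  map <- build_map(sim_config(), seed = 5)
  expect_equal(sum(map$kind == "marker"), 453L)
  expect_equal(sum(map$kind == "qtl"), 18L)
  counts <- table(map$chromosome[map$kind == "marker"])
  expect_equal(as.integer(counts), c(91L, 91L, 91L, 90L, 90L))
  for (chr in split(map, map$chromosome)) {
    expect_true(all(diff(chr$position_morgan) > 0))
    expect_lte(max(chr$position_morgan), 1.0)
  }
  # every QTL is at least the configured distance from the nearest marker
  mk <- map[map$kind == "marker", ]
  for (i in which(map$kind == "qtl")) {
    same <- mk[mk$chromosome == map$chromosome[i], ]
    expect_gte(min(abs(same$position_morgan - map$position_morgan[i])), 0.005)
  }
})

test_that("minimal one-chromosome map keeps ordering", {
  cfg <- sim_config(markers_per_chromosome = 5L, n_qtl_per_parameter = 1L)
  map <- build_map(cfg, seed = 1)
  expect_equal(sum(map$kind == "marker"), 5L)
  expect_equal(sum(map$kind == "qtl"), 3L)
  expect_true(all(diff(map$position_morgan[map$kind == "marker"]) > 0))
  expect_true(all(diff(map$position_morgan) > 0))
})

test_that("burn-in free pool has independent alleles at configured frequencies", {
  cfg <- sim_config(n_sires = 2L, n_dams = 4L, n_offspring = 8L,
                    n_phenotyped_families = 4L,
                    markers_per_chromosome = c(30L, 30L),
                    burnin_generations = 0L, pool_haplotypes = 1000L,
                    founder_freq_range = c(0.3, 0.7))
  map <- build_map(cfg, seed = 2)
  pool <- simulate_base_population(map, cfg, seed = 3)
  expect_true(all(pool$freq >= 0.2 & pool$freq <= 0.8))
  # pairwise LD across a spread of locus pairs is at sampling-noise level
  set.seed(4)
  pairs <- cbind(sample(nrow(map), 40), sample(nrow(map), 40))
  pairs <- pairs[pairs[, 1] != pairs[, 2], ]
  r2 <- apply(pairs, 1, function(ix) {
    cor(pool$haplotypes[, ix[1]], pool$haplotypes[, ix[2]])^2
  })
  expect_lt(mean(r2), 0.01)
})

test_that("burned-in pool respects the MAF floor and is seed-deterministic", {
  cfg <- toy_config()
  map <- build_map(cfg, seed = 2)
  p1 <- simulate_base_population(map, cfg, seed = 9)
  p2 <- simulate_base_population(map, cfg, seed = 9)
  expect_identical(p1$haplotypes, p2$haplotypes)
  expect_true(all(pmin(p1$freq, 1 - p1$freq) >= cfg$maf_min))
  # drift-built LD between close neighbours clearly exceeds the G = 0 level
  mk <- which(map$kind == "marker")
  r2_adj <- sapply(mk[1:20], function(j) {
    cor(p1$haplotypes[, j], p1$haplotypes[, j + 1])^2
  })
  expect_gt(mean(r2_adj), 0.05)
})

test_that("factorial pedigree has the stated family structure", {
  ped <- simulate_pedigree(sim_config(), seed = 3)
  expect_equal(nrow(ped), 2025L)
  off <- ped[ped$sire_id != 0L, ]
  expect_equal(nrow(off), 2000L)
  expect_equal(sum(off$phenotyped), 1000L)
  # every sire x dam pair used exactly once
  fams <- unique(off[, c("sire_id", "dam_id", "family_id", "phenotyped")])
  expect_equal(nrow(fams), 100L)
  expect_equal(anyDuplicated(fams[, c("sire_id", "dam_id")]), 0L)
  # no family split; balance across sires
  split_check <- tapply(off$phenotyped, off$family_id, function(x) length(unique(x)))
  expect_true(all(split_check == 1L))
  per_sire <- tapply(fams$phenotyped, fams$sire_id, sum)
  expect_true(all(per_sire == 10L))
  # parents precede offspring
  expect_silent(gsbench:::validate_pedigree(ped))
})

test_that("a one-mating pedigree is just a trio", {
  ped <- simulate_pedigree(sim_config(n_sires = 1, n_dams = 1, n_offspring = 1,
                                      n_phenotyped_families = 1), seed = 1)
  expect_equal(nrow(ped), 3L)
})

test_that("meiosis produces one expected crossover per Morgan", {
  cfg <- sim_config(markers_per_chromosome = 90L, n_qtl_per_parameter = 1L)
  map <- build_map(cfg, seed = 1)
  chr <- map$chromosome; pos <- map$position_morgan
  lens <- gsbench:::chromosome_lengths(map)
  h1 <- rep(1L, nrow(map)); h2 <- rep(2L, nrow(map))
  set.seed(42)
  switches <- replicate(10000, {
    g <- gsbench:::meiosis_origin(h1, h2, chr, pos, lens)
    sum(diff(g) != 0)
  })
  # observed strand switches estimate crossovers inside the marker span
  span <- max(pos) - min(pos)
  expect_equal(mean(switches), span, tolerance = 0.05)
})

test_that("gene drop is Mendelian and transmits heterozygous alleles 50:50", {
  ds <- toy_dataset()
  g <- ds$genotypes
  ped <- ds$pedigree
  for (i in which(ped$sire_id != 0L)) {
    si <- match(ped$sire_id[i], g$individual_ids)
    di <- match(ped$dam_id[i], g$individual_ids)
    expect_true(all(g$h1[i, ] == g$h1[si, ] | g$h1[i, ] == g$h2[si, ]))
    expect_true(all(g$h2[i, ] == g$h1[di, ] | g$h2[i, ] == g$h2[di, ]))
  }
  # large half-sib family from one heterozygous parent
  cfg <- sim_config(n_sires = 1, n_dams = 1, n_offspring = 10000,
                    n_phenotyped_families = 1,
                    markers_per_chromosome = c(5L, 5L),
                    n_qtl_per_parameter = 1L,
                    pool_haplotypes = 10L, burnin_generations = 0L)
  map <- build_map(cfg, seed = 2)
  pool <- simulate_base_population(map, cfg, seed = 3)
  ped2 <- simulate_pedigree(cfg, seed = 4)
  gd <- gene_drop(ped2, pool, map, seed = 5)
  sire_het <- which(gd$h1[1, ] != gd$h2[1, ])
  expect_gt(length(sire_het), 0)
  freq <- colMeans(gd$h1[ped2$sire_id != 0L, sire_het, drop = FALSE])
  expect_true(all(abs(freq - 0.5) < 0.015))
})

test_that("gene drop rejects a pool that cannot cover the founders", {
  cfg <- toy_config()
  map <- build_map(cfg, seed = 2)
  pool <- simulate_base_population(map, cfg, seed = 3)
  ped <- simulate_pedigree(sim_config(), seed = 1)  # 25 founders > 60 haplotypes / 2
  pool_small <- pool
  pool_small$haplotypes <- pool$haplotypes[1:10, ]
  expect_error(gene_drop(ped, pool_small, map, seed = 1), "pool too small")
})

test_that("QTL effects give the large QTL exactly half the variance at base frequencies", {
  ds <- toy_dataset()
  q <- ds$qtl
  expect_equal(nrow(q), 18L)
  for (par in c("a", "b", "c")) {
    qq <- q[q$parameter == par, ]
    expect_equal(nrow(qq), 6L)
    contrib <- 2 * qq$base_freq * (1 - qq$base_freq) * qq$effect^2
    share <- contrib / sum(contrib)
    expect_equal(max(share), 0.5, tolerance = 1e-12)
    expect_equal(sum(qq$variance_share), 1, tolerance = 1e-12)
    expect_equal(sum(contrib), ds$config$genetic_var[[par]], tolerance = 1e-9)
  }
})

test_that("a single QTL with full share has the closed-form effect size", {
  cfg <- toy_config(n_qtl_per_parameter = 1L, large_qtl_share = 1.0)
  map <- build_map(cfg, seed = 6)
  pool <- simulate_base_population(map, cfg, seed = 7)
  q <- assign_qtl_effects(map, pool, cfg, seed = 8)
  for (i in seq_len(nrow(q))) {
    p <- q$base_freq[i]
    sg2 <- cfg$genetic_var[[q$parameter[i]]]
    expect_equal(abs(q$effect[i]), sqrt(sg2 / (2 * p * (1 - p))), tolerance = 1e-12)
  }
})

test_that("QTL with fixed alleles are rejected", {
  ds <- toy_dataset()
  pool <- ds$pool
  pool$freq[ds$map$locus_id[ds$map$kind == "qtl"][1]] <- 0
  expect_error(assign_qtl_effects(ds$map, pool, ds$config, seed = 1),
               "frequency 0 or 1")
})

test_that("realized variance share of the large QTL is near one half", {
  ds <- default_dataset()
  q <- ds$qtl
  D <- qtl_dosages(ds)
  off <- as.character(ds$pedigree$individual_id[ds$pedigree$sire_id != 0L])
  Drow <- D[match(off, rownames(D)), , drop = FALSE]
  for (par in c("a", "b", "c")) {
    qq <- q[q$parameter == par, ]
    p_hat <- colMeans(Drow[, qq$locus_id, drop = FALSE]) / 2
    contrib <- 2 * p_hat * (1 - p_hat) * qq$effect^2
    expect_equal(max(contrib) / sum(contrib), 0.5, tolerance = 0.05)
  }
})

test_that("true values vanish for frequency-centered genotypes and obey the curve", {
  ds <- toy_dataset()
  cm <- attr(ds$truth, "curve_mean")
  # hand-built two-QTL individual checked against direct curve evaluation
  q <- ds$qtl[ds$qtl$parameter == "a", ][1:2, ]
  dos <- c(2, 0)
  g_a <- sum(q$effect * (dos - 2 * q$base_freq))
  tbv_hand <- logistic_curve(600, cm[["a"]] + g_a, cm[["b"]], cm[["c"]]) -
    logistic_curve(600, cm[["a"]], cm[["b"]], cm[["c"]])
  i <- match(ds$phenotypes$individual_id[1], ds$truth$individual_id)
  row <- ds$truth[i, ]
  tbv_pkg <- gsbench:::tbv_at(
    {r <- row; r$g_a <- g_a; r$g_b <- 0; r$g_c <- 0
     attr(r, "curve_mean") <- cm; r}, 600)
  expect_equal(tbv_pkg, tbv_hand, tolerance = 1e-12)
  # zero genetic deviations give TBV 0 at any time
  z <- ds$truth[1, ]
  z$g_a <- 0; z$g_b <- 0; z$g_c <- 0
  attr(z, "curve_mean") <- cm
  expect_equal(gsbench:::tbv_at(z, 250), 0)
  expect_equal(gsbench:::tbv_at(z, 600), 0)
  # deviations are centered: a Hardy-Weinberg population at base
  # frequencies has mean genetic deviation zero
  q <- ds$qtl[ds$qtl$parameter == "a", ]
  set.seed(101)
  Dhw <- sapply(q$base_freq, function(p) rbinom(5000, 2, p))
  g_hw <- sweep(Dhw, 2, 2 * q$base_freq) %*% q$effect
  expect_lt(abs(mean(g_hw)), 4 * stats::sd(g_hw) / sqrt(5000))
  # t -> infinity approaches the asymptote difference
  far <- gsbench:::tbv_at(ds$truth[3, ], 1e6)
  expect_equal(far, ds$truth$g_a[3], tolerance = 1e-6)
})

test_that("phenotypes carry the configured heritability and are cumulative", {
  ds <- default_dataset()
  pp <- attr(ds$phenotypes, "parameters")
  tr <- ds$truth[match(pp$individual_id, ds$truth$individual_id), ]
  for (par in c("a", "b", "c")) {
    g <- tr[[paste0("g_", par)]]
    h2 <- var(g) / var(pp[[paste0("p_", par)]])
    expect_gte(h2, 0.45); expect_lte(h2, 0.55)
  }
  Y <- as.matrix(ds$phenotypes[, paste0("y_", ds$config$time_points)])
  expect_true(all(apply(Y, 1, function(r) all(diff(r) >= 0))))
  # only offspring of phenotyped families appear
  ped <- ds$pedigree
  expect_setequal(ds$phenotypes$individual_id,
                  ped$individual_id[ped$phenotyped])
})

test_that("noise-free heritability makes yield track the genetic curve exactly", {
  cfg <- toy_config(h2 = 1)
  ds <- simulate_dataset(cfg, seed = 21)
  tb <- true_breeding_values(ds, 530)
  j <- merge(ds$phenotypes, tb, by = "individual_id")
  slope <- coef(lm(j$y_530 ~ j$tbv))[[2]]
  expect_equal(slope, 1, tolerance = 0.02)
})

test_that("datasets round-trip through delimited files", {
  ds <- toy_dataset()
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  ds2 <- read_dataset(dir)
  expect_equal(as.data.frame(ds2$pedigree), as.data.frame(ds$pedigree))
  expect_equal(as.data.frame(ds2$map), as.data.frame(ds$map))
  expect_identical(ds2$genotypes$dosages[, ds2$map$locus_id],
                   ds$genotypes$dosages[, ds2$map$locus_id])
  expect_equal(as.data.frame(ds2$phenotypes), as.data.frame(ds$phenotypes),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(ds2$truth$g_a, ds$truth$g_a, tolerance = 1e-12)
  expect_equal(ds2$qtl$effect, ds$qtl$effect, tolerance = 1e-12)
})

test_that("participant view hides every truth-side column", {
  ds <- toy_dataset()
  pv <- participant_view(ds)
  expect_null(pv$truth)
  expect_null(pv$qtl)
  expect_false(any(pv$map$kind == "qtl"))
  expect_false(any(grepl("^Q", colnames(pv$genotypes$dosages))))
  dir <- withr::local_tempdir()
  write_dataset(pv, dir, truth = FALSE)
  geno_cols <- names(readr::read_csv(file.path(dir, "genotypes.csv"),
                                     n_max = 1, show_col_types = FALSE))
  expect_false(any(grepl("^Q", geno_cols)))
  expect_false(file.exists(file.path(dir, "tbv.csv")))
})

test_that("a missing phenotype file is an explicit error", {
  ds <- toy_dataset()
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  file.remove(file.path(dir, "phenotypes.csv"))
  expect_error(read_dataset(dir), "phenotypes.csv")
})

test_that("identical config and seed give byte-identical datasets", {
  cfg <- toy_config()
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_dataset(simulate_dataset(cfg, seed = 33), d1)
  write_dataset(simulate_dataset(cfg, seed = 33), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})
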