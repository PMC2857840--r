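test_that("animal model approaches simple centering when shrinkage vanishes", {
  y <- c(3, 5, 9, 1)
  K <- diag(4); dimnames(K) <- list(1:4, 1:4)
  fit <- solve_animal_model(y, 1:4, K, h2 = 1 - 1e-10)
  expect_equal(unname(drop(fit$u[, 1])), y - mean(y), tolerance = 1e-6)
})

test_that("constant records give zero breeding values", {
  K <- diag(5); dimnames(K) <- list(1:5, 1:5)
  fit <- solve_animal_model(rep(4.2, 5), 1:5, K, h2 = 0.5)
  expect_equal(unname(drop(fit$u[, 1])), rep(0, 5), tolerance = 1e-12)
})

test_that("animal model agrees with a dense GLS oracle on a pedigree toy", {
  ped <- textbook_pedigree()
  A <- a_matrix(ped)
  y <- c(10.2, 8.1)          # records on the two phenotyped sibs
  rid <- c(3L, 4L)
  h2 <- 0.4
  fit <- solve_animal_model(y, rid, A, h2)
  # oracle: u = Cov(u, y) Var(y)^-1 (y - X b), independent dense arithmetic
  sg2 <- h2; se2 <- 1 - h2
  p <- match(as.character(rid), rownames(A))
  V <- sg2 * A[p, p] + se2 * diag(2)
  X <- matrix(1, 2, 1)
  b <- solve(t(X) %*% solve(V) %*% X, t(X) %*% solve(V) %*% y)
  u <- sg2 * A[, p] %*% solve(V, y - X %*% b)
  expect_equal(drop(fit$u[, 1]), drop(u), tolerance = 1e-8)
  expect_equal(fit$b[1], drop(b), tolerance = 1e-8)
})

test_that("unphenotyped full sibs get the parent-average prediction", {
  ped <- tibble::tibble(
    individual_id = 1:7,
    sire_id = c(0L, 0L, 1L, 1L, 1L, 1L, 1L),
    dam_id = c(0L, 0L, 2L, 2L, 2L, 2L, 2L),
    family_id = c(NA, NA, rep(1L, 5)),
    phenotyped = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE))
  A <- a_matrix(ped)
  y <- c(4, 6, 5, 7)
  fit <- solve_animal_model(y, 3:6, A, h2 = 0.5)
  u <- unname(drop(fit$u[, 1]))
  expect_equal(u[7], (u[1] + u[2]) / 2, tolerance = 1e-10)
})

test_that("breeding values vanish as heritability goes to zero", {
  ds <- toy_dataset()
  g <- pedigree_blup(ds, h2 = 1e-9)
  expect_lt(max(abs(g$gebv)), 1e-5)
})

test_that("pedigree BLUP shrinks relative to the true breeding values", {
  ds <- toy_dataset()
  g <- pedigree_blup(ds, h2 = 0.5)
  tb <- validation_tbv(ds, 530)
  gv <- g$gebv[match(tb$individual_id, g$individual_id)]
  expect_lt(var(gv), var(tb$tbv))
})

test_that("ridge regression reproduces the OLS slope without shrinkage", {
  set.seed(31)
  ds <- toy_dataset()
  # single-marker dataset view
  M <- marker_dosages(ds)[, 5, drop = FALSE]
  ids <- ds$genotypes$individual_ids
  keep <- ds$phenotypes$individual_id
  w <- M[match(keep, ids), 1] - mean(M[, 1])
  y <- ds$phenotypes$y_530
  ds1 <- ds
  ds1$genotypes <- structure(list(individual_ids = ids,
                                  map = ds$map[ds$map$locus_id == colnames(M), ],
                                  dosages = M, h1 = NULL, h2 = NULL),
                             class = "gs_genotypes")
  fit <- rr_blup(ds1, h2 = 1 - 1e-9)
  ols <- coef(lm(y ~ w))[[2]]
  expect_equal(fit$effects$effect[1], ols, tolerance = 1e-4)
})

test_that("ridge-regression GEBV equal GBLUP GEBV and ignore marker order", {
  ds <- toy_dataset()
  rr <- rr_blup(ds, h2 = 0.5)
  gb <- suppressWarnings(gblup(ds, h2 = 0.5))
  expect_lt(max(abs(rr$gebv$gebv - gb$gebv)), 1e-6)

  ds2 <- ds
  perm <- sample(ncol(ds$genotypes$dosages))
  ds2$genotypes$dosages <- ds$genotypes$dosages[, perm]
  ds2$genotypes$map <- ds$genotypes$map[perm, ]
  rr2 <- rr_blup(ds2, h2 = 0.5)
  expect_equal(rr$gebv$gebv, rr2$gebv$gebv, tolerance = 1e-9)
})

test_that("identical genotype rows receive identical GEBV", {
  ds <- toy_dataset()
  g <- ds$genotypes
  twin_of <- 30L
  g$dosages[31L, ] <- g$dosages[twin_of, ]
  ds$genotypes <- g
  fit <- suppressWarnings(gblup(ds, h2 = 0.5))
  expect_equal(fit$gebv[31L], fit$gebv[twin_of], tolerance = 1e-10)
})

test_that("a polygenic term changes but does not break ridge predictions", {
  ds <- toy_dataset()
  rr <- rr_blup(ds, h2 = 0.5, polygenic = TRUE)
  expect_equal(nrow(rr$gebv), nrow(ds$pedigree))
  expect_true(all(is.finite(rr$gebv$gebv)))
  rr0 <- rr_blup(ds, h2 = 0.5)
  expect_gt(cor(rr$gebv$gebv, rr0$gebv$gebv), 0.6)
})

test_that("EBV of unphenotyped individuals are linear in the records", {
  ped <- textbook_pedigree()
  A <- a_matrix(ped)
  y1 <- c(1, 2); y2 <- c(0.5, -1)
  u <- function(y) drop(solve_animal_model(y, c(3L, 4L), A, 0.5)$u[, 1])
  expect_equal(u(y1 + y2), u(y1) + u(y2), tolerance = 1e-9)
})
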