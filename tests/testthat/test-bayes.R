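# Small planted-signal design shared by several sampler checks: 100 null
# markers, 3 of which carry real effects, 600 records.
planted <- function(seed = 17, n = 600, p = 100, beta = c(1, -0.8, 0.6)) {
  memo(sprintf("planted_%d", seed), {
    set.seed(seed)
    M <- sapply(runif(p, 0.2, 0.8), function(pk) rbinom(n, 2, pk))
    colnames(M) <- sprintf("m%03d", seq_len(p))
    signal <- c(10, 50, 90)
    g <- sweep(M[, signal], 2, colMeans(M[, signal])) %*% beta
    y <- drop(g) + rnorm(n, 0, sd(g))
    list(M = M, y = y, signal = signal, beta = beta)
  })
}

test_that("chains are reproducible under a fixed seed", {
  d <- planted()
  for (fn in list(run_bayes_a, run_bayes_lasso)) {
    f1 <- fn(d$y, d$M, n_iter = 600, burn_in = 100, thin = 5, seed = 5)
    f2 <- fn(d$y, d$M, n_iter = 600, burn_in = 100, thin = 5, seed = 5)
    expect_identical(f1$markers$post_mean, f2$markers$post_mean)
    expect_identical(f1$sigma2e, f2$sigma2e)
  }
})

test_that("a flat phenotype yields near-zero effects", {
  d <- planted()
  y0 <- rep(3, length(d$y))
  fit <- run_bayes_a(y0 + rnorm(length(y0), 0, 1e-6), d$M,
                     n_iter = 1000, burn_in = 200, seed = 2)
  expect_lt(max(abs(fit$markers$post_mean)), 1e-3)
})

test_that("one strong marker is estimated at its OLS value", {
  set.seed(8)
  n <- 500
  w <- rbinom(n, 2, 0.5)
  y <- w * 1.0 + rnorm(n, 0, 0.05)
  M <- matrix(w, ncol = 1, dimnames = list(NULL, "m1"))
  fit <- run_bayes_a(y, M, n_iter = 3000, burn_in = 500, seed = 3)
  ols <- coef(lm(y ~ w))[[2]]
  expect_equal(fit$markers$post_mean[1], ols, tolerance = 0.1)
})

test_that("BayesB with full inclusion collapses onto BayesA", {
  d <- planted()
  fa <- run_bayes_a(d$y, d$M, n_iter = 6000, burn_in = 1000, seed = 4)
  fb <- run_bayes_b(d$y, d$M, pi = 1 - 1e-9, n_iter = 6000, burn_in = 1000, seed = 4)
  expect_true(all(fb$markers$inclusion_prob > 0.999))
  expect_equal(fb$markers$post_mean, fa$markers$post_mean, tolerance = 0.08)
  gap <- cor(fa$markers$post_mean, fb$markers$post_mean)
  expect_gt(gap, 0.98)
})

test_that("BayesB ranks the planted markers highest", {
  d <- planted()
  fit <- run_bayes_b(d$y, d$M, pi = 0.05, n_iter = 4000, burn_in = 1000, seed = 6)
  top3 <- order(-fit$markers$inclusion_prob)[1:3]
  expect_setequal(top3, d$signal)
})

test_that("BayesB stays sparse on pure noise", {
  set.seed(12)
  M <- sapply(runif(100, 0.2, 0.8), function(pk) rbinom(400, 2, pk))
  colnames(M) <- sprintf("m%03d", 1:100)
  y <- rnorm(400)
  fit <- run_bayes_b(y, M, pi = 0.01, n_iter = 3000, burn_in = 500, seed = 13)
  expect_lte(mean(fit$markers$inclusion_prob), 0.05)
})

test_that("BayesC recovers planted markers and tolerates tied variances", {
  d <- planted()
  fit <- run_bayes_c(d$y, d$M, n_iter = 5000, burn_in = 1000, seed = 14)
  expect_true(all(fit$markers$inclusion_prob[d$signal] > 0.5))
  # tied class variances reduce to one shared-variance distribution
  tied <- run_bayes_c(d$y, d$M, tie_variances = TRUE,
                      n_iter = 5000, burn_in = 1000, seed = 15)
  fa <- run_bayes_a(d$y, d$M, n_iter = 5000, burn_in = 1000, seed = 15)
  W <- sweep(d$M, 2, colMeans(d$M))
  g_tied <- drop(W %*% tied$markers$post_mean)
  g_a <- drop(W %*% fa$markers$post_mean)
  expect_gt(cor(g_tied, g_a), 0.98)
})

test_that("BayesC predictions are stable across chain initializations", {
  d <- planted()
  W <- sweep(d$M, 2, colMeans(d$M))
  g1 <- drop(W %*% run_bayes_c(d$y, d$M, n_iter = 4000, burn_in = 1000,
                               seed = 21)$markers$post_mean)
  g2 <- drop(W %*% run_bayes_c(d$y, d$M, n_iter = 4000, burn_in = 1000,
                               seed = 22)$markers$post_mean)
  expect_gt(cor(g1, g2), 0.98)
})

test_that("the Bayesian Lasso shrinks under a huge fixed rate and signs the signal", {
  d <- planted()
  ols <- apply(d$M, 2, function(w) coef(lm(d$y ~ w))[[2]])
  hard <- run_bayes_lasso(d$y, d$M, lasso_lambda2 = 1e8,
                          n_iter = 2000, burn_in = 500, seed = 16)
  expect_lt(max(abs(hard$markers$post_mean)), 0.1 * max(abs(ols)))
  fit <- run_bayes_lasso(d$y, d$M, n_iter = 4000, burn_in = 1000, seed = 17)
  expect_equal(sign(fit$markers$post_mean[d$signal]), sign(d$beta))
})

test_that("a marker carrying half the genetic variance is confidently included", {
  set.seed(23)
  n <- 1000
  p_large <- 0.5
  w_large <- rbinom(n, 2, p_large)
  M_small <- sapply(runif(40, 0.2, 0.8), function(pk) rbinom(n, 2, pk))
  beta_small <- rnorm(40, 0, sqrt(1 / (40 * 2 * 0.25)))
  alpha <- sqrt(1 / (2 * p_large * (1 - p_large)))  # 50% of sigma2_g = 2
  g <- w_large * alpha + drop(M_small %*% beta_small)
  y <- g + rnorm(n, 0, sd(g))                        # h2 = 0.5
  M <- cbind(big = w_large, M_small)
  colnames(M) <- c("big", sprintf("s%02d", 1:40))
  fit <- run_bayes_b(y, M, pi = 0.05, n_iter = 4000, burn_in = 1000, seed = 24)
  expect_gt(fit$markers$inclusion_prob[1], 0.9)
})

test_that("posterior predictions are linear dot products with stored centering", {
  d <- planted()
  fit <- run_bayes_b(d$y, d$M, n_iter = 800, burn_in = 200, seed = 25)
  newM <- d$M[1:7, ]
  rownames(newM) <- 1:7
  pred <- predict_from_markers(fit, newM)
  W <- sweep(newM, 2, fit$center)
  expect_equal(pred$gebv, unname(drop(W %*% fit$markers$post_mean)),
               tolerance = 1e-12)
  # zero effects -> zero GEBV; doubled effects -> doubled GEBV
  fit0 <- fit; fit0$markers$post_mean <- rep(0, nrow(fit$markers))
  expect_equal(predict_from_markers(fit0, newM)$gebv, rep(0, 7))
  fit2 <- fit; fit2$markers$post_mean <- 2 * fit$markers$post_mean
  expect_equal(predict_from_markers(fit2, newM)$gebv, 2 * pred$gebv)
  # two-marker dot-product oracle
  mini <- fit
  mini$markers <- fit$markers[1:2, ]
  mini$center <- fit$center[1:2]
  m2 <- newM[, 1:2]
  expect_equal(predict_from_markers(mini, m2)$gebv[1],
               sum((m2[1, ] - mini$center) * mini$markers$post_mean))
})

test_that("invalid inputs are rejected", {
  d <- planted()
  expect_error(run_bayes_a(c(d$y[-1], NA), d$M), "non-finite")
  expect_error(run_bayes(d$y, d$M, bayes_config(polygenic = TRUE)),
               "polygenic")
  expect_error(bayes_config(n_iter = 100, burn_in = 200), "exceed")
})
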