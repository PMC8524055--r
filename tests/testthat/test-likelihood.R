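# Bivariate longitudinal likelihood: density evaluation, null and
# genotype-specific fits, EM behavior.

test_that("multivariate normal log-density agrees with the explicit-inverse form", {
  set.seed(5)
  A <- matrix(rnorm(36), 6)
  sigma <- crossprod(A) + diag(6)
  mu <- rnorm(6)
  y <- rnorm(6)
  direct <- -0.5 * (6 * log(2 * pi) + determinant(sigma)$modulus[1] +
                    t(y - mu) %*% solve(sigma) %*% (y - mu))
  expect_equal(mvn_loglik(y, mu, sigma), as.numeric(direct),
               tolerance = 1e-10)
  # quadratic form vanishes at the mean
  expect_equal(mvn_loglik(mu, mu, sigma),
               as.numeric(-0.5 * (6 * log(2 * pi) +
                                  determinant(sigma)$modulus[1])),
               tolerance = 1e-12)
  # diagonal case factorizes into univariate densities
  expect_equal(mvn_loglik(c(1, 2), c(0, 0), diag(c(4, 9))),
               dnorm(1, 0, 2, log = TRUE) + dnorm(2, 0, 3, log = TRUE),
               tolerance = 1e-12)
  expect_error(mvn_loglik(y, mu, -sigma))
})

test_that("compiled Nelder-Mead matches optim on standard objectives", {
  rosen <- function(x) 100 * (x[2] - x[1]^2)^2 + (1 - x[1])^2
  r1 <- mpqtl:::cpp_nelder_mead(c(-1.2, 1), rosen, init_step = 0.1,
                                reltol = 1e-10, maxit = 5000)
  r2 <- optim(c(-1.2, 1), rosen, method = "Nelder-Mead",
              control = list(maxit = 5000, reltol = 1e-10))
  expect_lt(r1$value, r2$value + 1e-4)
  expect_equal(r1$par, c(1, 1), tolerance = 1e-2)
  quad <- function(x) sum((x - c(3, -2, 7))^2)
  r3 <- mpqtl:::cpp_nelder_mead(c(0, 0, 0), quad, init_step = 0.5,
                                reltol = 1e-12, maxit = 4000)
  expect_equal(r3$par, c(3, -2, 7), tolerance = 1e-4)
})

test_that("null fit beats the generating parameters in likelihood", {
  sim <- small_sim(n = 40, H2 = 0.3, seed = 31)
  # single-curve data: every sample follows the frequency-weighted curve
  cfg0 <- sim$config; cfg0$causal <- NA
  ph <- simulate_phenotypes(cfg0, sim$markers, sad = sim$sad, seed = 77)
  nf <- fit_null(ph, cfg0$grid)
  avg <- mpqtl:::validate_nge_params(
    (as.numeric(sim$config$params$AA) +
     as.numeric(sim$config$params$Aa)) / 2)
  ll_truth <- eval_loglik(ph, avg, sim$sad, cfg0$grid)
  expect_gte(nf$loglik, ll_truth)
  # coordinate ascent is monotone up to M-step tolerance
  expect_true(all(diff(nf$trace) > -1e-6 * (abs(nf$loglik) + 1)))
})

test_that("log-likelihood is additive over duplicated samples", {
  sim <- small_sim(n = 20, seed = 33)
  ph2 <- trait_matrix(rbind(unclass(sim$pheno), unclass(sim$pheno)),
                      sample_ids = c(rownames(sim$pheno),
                                     paste0("d_", rownames(sim$pheno))))
  p <- sim$config$params$AA
  ll1 <- eval_loglik(sim$pheno, p, sim$sad, sim$config$grid)
  expect_equal(eval_loglik(ph2, p, sim$sad, sim$config$grid), 2 * ll1,
               tolerance = 1e-10)
})

test_that("responsibilities are one-hot, prior-weighted, or Bayes-exact", {
  sim <- small_sim(n = 30, H2 = 0.4, seed = 35)
  gc_obs <- genotype_column(sim$codes)
  fit <- fit_alternative(sim$pheno, gc_obs, sim$config$grid,
                         control = fit_control(max_iter = 20))
  W <- genotype_posteriors(sim$pheno, gc_obs, fit)
  ind <- 1 * outer(sim$codes, gc_obs$labels, "==")
  expect_equal(unname(W), unname(ind))
  # missing genotypes with identical parameter sets: prior weights
  codes_na <- sim$codes; codes_na[1:5] <- NA
  gc_na <- genotype_column(codes_na, priors = c(0.3, 0.7))
  fit_same <- fit
  fit_same$params <- list(AA = fit$params$AA, Aa = fit$params$AA)
  W2 <- genotype_posteriors(sim$pheno, gc_na, fit_same)
  expect_equal(unname(W2[1:5, ]), matrix(c(0.3, 0.7), 5, 2, byrow = TRUE))
  # missing genotypes, distinct fits: direct Bayes computation
  W3 <- genotype_posteriors(sim$pheno, gc_na, fit)
  sigma <- build_covariance(fit$sad, 24)
  for (i in 1:3) {
    lf <- sapply(fit$params, function(p)
      mvn_loglik(unclass(sim$pheno)[i, ],
                 mpqtl:::nge_mu_vec(p, sim$config$grid), sigma))
    post <- exp(lf + log(gc_na$priors))
    expect_equal(unname(W3[i, ]), unname(post / sum(post)),
                 tolerance = 1e-10)
  }
  expect_true(all(abs(rowSums(W3) - 1) < 1e-12))
})

test_that("a single genotype class reduces the QTL model to the null", {
  sim <- small_sim(n = 20, seed = 37)
  nf <- fit_null(sim$pheno, sim$config$grid)
  alt <- fit_alternative(sim$pheno, rep("AA", 20), sim$config$grid,
                         null_fit = nf)
  expect_identical(alt$loglik, nf$loglik)
  expect_equal(lr_test(nf, alt)$LR, 0)
})

test_that("genotype-specific fit is invariant to sample order", {
  sim <- small_sim(n = 24, seed = 39)
  nf <- fit_null(sim$pheno, sim$config$grid)
  alt <- fit_alternative(sim$pheno, sim$codes, sim$config$grid,
                         null_fit = nf, covariance = "fixed")
  set.seed(8)
  perm <- sample(24)
  ph_p <- trait_matrix(unclass(sim$pheno)[perm, ],
                       sample_ids = rownames(sim$pheno)[perm])
  alt_p <- fit_alternative(ph_p, sim$codes[perm], sim$config$grid,
                           null_fit = nf, covariance = "fixed")
  expect_equal(alt_p$loglik, alt$loglik, tolerance = 1e-8)
})

test_that("EM increases the observed-data likelihood with missing genotypes", {
  sim <- small_sim(n = 40, H2 = 0.5, seed = 41)
  codes <- sim$codes
  codes[1:10] <- NA
  nf <- fit_null(sim$pheno, sim$config$grid)
  alt <- fit_alternative(sim$pheno, codes, sim$config$grid, null_fit = nf)
  expect_true(all(diff(alt$trace) > -1e-6 * (abs(alt$loglik) + 1)))
  expect_gte(alt$loglik, nf$loglik - 1e-6)
})

test_that("well-separated genotype groups are recovered at low noise", {
  sad <- sad_params(0.5, 0.5, 0.05, 0.05, 0.2)
  sim <- small_sim(n = 30, seed = 43, sad = sad)
  deep <- fit_control(nm_maxit_warm = 3000, max_iter = 300)
  nf <- fit_null(sim$pheno, sim$config$grid, deep)
  alt <- fit_alternative(sim$pheno, sim$codes, sim$config$grid,
                         control = deep, null_fit = nf)
  grid <- sim$config$grid
  for (g in c("AA", "Aa")) {
    mu_true <- mpqtl:::nge_mu_vec(sim$config$params[[g]], grid)
    mu_fit <- mpqtl:::nge_mu_vec(alt$params[[g]], grid)
    expect_lt(max(abs(mu_fit - mu_true) / pmax(mu_true, 0.5)), 0.05)
  }
  expect_error(fit_alternative(sim$pheno, c("AA", rep("Aa", 29)),
                               sim$config$grid, null_fit = nf),
               "degenerate")
})

test_that("trait matrices and genotype columns validate their inputs", {
  expect_error(trait_matrix(matrix(c(1, NA, 3, 4), 2)), "non-finite")
  expect_error(trait_matrix(matrix(1:6, 2, 3)), "even number")
  expect_error(trait_matrix(matrix(1:8, 2), sample_ids = c("a", "a")),
               "duplicate")
  expect_error(genotype_column(rep(NA_character_, 4)), "no observed")
  expect_error(genotype_column(c("a", "b", "c", "d")), "more than 3")
})
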