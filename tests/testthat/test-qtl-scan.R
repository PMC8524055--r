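# Marker scan, likelihood-ratio tests, multiple-testing adjustment and
# phase-specific sub-hypotheses.

test_that("LR test handles equal fits, degrees of freedom and clamping", {
  f0 <- structure(list(loglik = -100, n_params = 17, J = 1L),
                  class = "model_fit")
  f1 <- structure(list(loglik = -100, n_params = 29, J = 2L),
                  class = "model_fit")
  r <- lr_test(f0, f1)
  expect_equal(r$LR, 0)
  expect_equal(r$df, 12)
  expect_equal(r$p, 1)
  f3 <- structure(list(loglik = -90, n_params = 41, J = 3L),
                  class = "model_fit")
  expect_equal(lr_test(f0, f3)$df, 24)
  f1$loglik <- -100 - 1e-8
  expect_warning(r2 <- lr_test(f0, f1), "clamped")
  expect_equal(r2$LR, 0)
  f1$loglik <- -101
  expect_error(lr_test(f0, f1), "refit")
})

test_that("Bonferroni and BH adjustments match hand computations", {
  a <- adjust_pvalues(c(0.01, 0.02, 0.03, 0.5), M = 1000, alpha = 0.05)
  expect_equal(a$bonferroni_threshold, 5e-5)
  # BH step-up by hand at M = 4
  b <- adjust_pvalues(c(0.01, 0.02, 0.03, 0.5), alpha = 0.05)
  expect_equal(b$p_fdr, c(0.04, 0.04, 0.04, 0.5))
  expect_identical(adjust_pvalues(0.03)$p_fdr, 0.03)
  expect_error(adjust_pvalues(numeric(0)), "empty")
  # BH flags are a superset of Bonferroni flags at equal alpha
  set.seed(2)
  p <- c(runif(40), runif(10, 0, 1e-4))
  adj <- adjust_pvalues(p, alpha = 0.05)
  expect_true(all(adj$significant_fdr[adj$significant_bonferroni]))
})

test_that("scan ranks a strong causal marker first and skips degenerates", {
  sad <- sad_params(0.5, 0.5, 0.4, 0.4, 0.2)
  sim <- small_sim(n = 40, seed = 51, sad = sad)
  cfg <- sim$config; cfg$M <- 10
  mk <- simulate_markers(cfg, seed = 51)
  mk[1, rownames(sim$pheno)] <- sim$codes          # causal marker
  mk[2, ] <- mk[1, ]                                # exact duplicate
  mk$marker_id[2] <- "M2dup"
  mk[3, rownames(sim$pheno)] <- "AA"                # single class
  res <- qtl_scan(sim$pheno, mk, cfg$grid, covariance = "fixed")
  expect_s3_class(res, "scan_result")
  expect_true(res$skipped[res$marker_id == "M3"])
  expect_match(res$reason[res$marker_id == "M3"], "single_genotype_class")
  tested <- res[!res$skipped, ]
  expect_equal(tested$marker_id[which.min(tested$p_raw)], "M1")
  expect_equal(res$LR[res$marker_id == "M1"],
               res$LR[res$marker_id == "M2dup"], tolerance = 1e-10)
  expect_true(all(res$p_fdr[!res$skipped] >= res$p_raw[!res$skipped] - 1e-12))
})

test_that("full-block sub-hypothesis equals the overall test", {
  sim <- small_sim(n = 30, H2 = 0.4, seed = 53)
  nf <- fit_null(sim$pheno, sim$config$grid)
  alt <- fit_alternative(sim$pheno, sim$codes, sim$config$grid,
                         null_fit = nf, covariance = "fixed")
  st <- sub_hypothesis_test(sim$pheno, sim$codes, "full", sim$config$grid,
                            null_fit = nf, alt_fit = alt)
  overall <- lr_test(nf, alt)
  expect_equal(st$df, 12)
  expect_equal(st$LR, overall$LR, tolerance = 0.05)
  # single-parameter block with two genotypes
  st1 <- sub_hypothesis_test(sim$pheno, sim$codes, "beta_H_from_D",
                             sim$config$grid, null_fit = nf, alt_fit = alt)
  expect_equal(st1$df, 1)
  expect_lte(st1$LR, overall$LR + 0.05)   # nesting
  expect_error(sub_hypothesis_test(sim$pheno, sim$codes, "not_a_block",
                                   sim$config$grid, null_fit = nf,
                                   alt_fit = alt),
               "valid blocks")
})

test_that("phase-specific tests localize a phase-2 height effect", {
  # genotypes differ only in the adult-phase height parameters
  pAA <- sim_true_params()$AA
  pAa <- pAA
  pAa["K_H2"] <- pAA["K_H2"] * 1.25
  pAa["q_H"] <- 0.21
  pAa["K_D2"] <- pAA["K_D2"] * 1.1   # phase-2 diameter shift keeps the
                                     # per-trait noise calibration feasible
  params <- list(AA = mpqtl:::validate_nge_params(pAA),
                 Aa = mpqtl:::validate_nge_params(pAa))
  hits1 <- hits2 <- 0
  reps <- 8
  for (r in seq_len(reps)) {
    sim <- small_sim(n = 44, H2 = 0.35, seed = 600 + r, params = params)
    nf <- fit_null(sim$pheno, sim$config$grid)
    alt <- fit_alternative(sim$pheno, sim$codes, sim$config$grid,
                           null_fit = nf, covariance = "fixed")
    s1 <- sub_hypothesis_test(sim$pheno, sim$codes, "phase1",
                              sim$config$grid, null_fit = nf,
                              alt_fit = alt)
    s2 <- sub_hypothesis_test(sim$pheno, sim$codes, "phase2_H",
                              sim$config$grid, null_fit = nf,
                              alt_fit = alt)
    expect_equal(s1$df, 6)
    expect_equal(s2$df, 3)
    hits1 <- hits1 + (s1$p < 0.05)
    hits2 <- hits2 + (s2$p < 0.05)
  }
  expect_gt(hits2, reps / 2)     # the true signal is detected
  expect_lt(hits1, hits2)        # and localized to the right block
})
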