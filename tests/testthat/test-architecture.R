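# Genetic effect decomposition, PVE curves, phase clustering, and
# curve features.

test_that("effect curves decompose additively and vanish for equal genotypes", {
  tp <- sim_true_params()
  grid <- time_grid(T = 24)
  ec <- effect_curves(tp, grid)
  w <- function(comp) ec$effect[ec$trait == "height" & ec$component == comp]
  expect_equal(w("net"), w("phase1") + w("phase2"), tolerance = 1e-9)
  expect_equal(w("phase1"), w("phase1_independent") + w("phase1_interaction"),
               tolerance = 1e-9)
  # equal parameter sets: all effects identically zero
  ec0 <- effect_curves(list(A = tp$AA, B = tp$AA), grid)
  expect_true(all(abs(ec0$effect) < 1e-12))
  # direct-subtraction oracle for the net height effect at t = 24
  muAA <- nge_mean(tp$AA, grid)$H_total[24]
  muAa <- nge_mean(tp$Aa, grid)$H_total[24]
  expect_equal(w("net")[24], (muAA - muAa) / 2, tolerance = 1e-10)
})

test_that("interaction effect is zero when both genotypes are uncoupled", {
  a <- nge_params(0.5, 12, 0, 0.4, 18, 0, 10, 2, 0.2, 12, 2.5, 0.15)
  b <- nge_params(0.6, 13, 0, 0.5, 17, 0, 11, 2, 0.25, 13, 2.4, 0.16)
  ec <- effect_curves(list(g1 = a, g2 = b), time_grid(T = 12))
  expect_true(all(abs(ec$effect[ec$component == "phase1_interaction"])
                  < 1e-9))
})

test_that("three-genotype effects split into additive and dominance parts", {
  tp <- sim_true_params()
  mid <- mpqtl:::validate_nge_params(
    (as.numeric(tp$AA) + as.numeric(tp$Aa)) / 2)
  ec <- effect_curves(list(AA = tp$AA, Aa = mid, aa = tp$Aa),
                      time_grid(T = 10))
  expect_setequal(unique(ec$type), c("additive", "dominance"))
  # heterozygote exactly midway: dominance of the net curve is the
  # deviation of the mid-curve from the homozygote curve average
  dnet <- ec$effect[ec$type == "dominance" & ec$component == "net" &
                    ec$trait == "height"]
  grid <- time_grid(T = 10)
  direct <- nge_mean(mid, grid)$H_total -
    (nge_mean(tp$AA, grid)$H_total + nge_mean(tp$Aa, grid)$H_total) / 2
  expect_equal(dnet, direct, tolerance = 1e-10)
})

test_that("PVE matches the closed-form two-genotype decomposition", {
  tp <- sim_true_params()
  grid <- time_grid(T = 24)
  v <- matrix(4, 24, 2)
  pv <- suppressWarnings(pve_curves(tp, c(0.5, 0.5), v, grid))
  muAA <- nge_mean(tp$AA, grid)$H_total
  muAa <- nge_mean(tp$Aa, grid)$H_total
  d <- muAA - muAa
  expect_equal(pv$pve[pv$trait == "height"], pmin((d^2 / 4) / 4, 1),
               tolerance = 1e-8)
  # equal means give zero PVE; label exchange leaves PVE unchanged
  pv0 <- pve_curves(list(tp$AA, tp$AA), c(0.5, 0.5), v, grid)
  expect_true(all(pv0$pve == 0))
  pv_sw <- suppressWarnings(
    pve_curves(list(tp$Aa, tp$AA), c(0.5, 0.5), v, grid))
  expect_equal(pv_sw$pve, pv$pve, tolerance = 1e-10)
  # genetic variance above the phenotypic estimate clips with a warning
  expect_warning(pvc <- pve_curves(tp, c(0.5, 0.5),
                                   matrix(1e-4, 24, 2), grid), "clipped")
  expect_true(all(pvc$pve <= 1))
  expect_error(pve_curves(tp, c(0.6, 0.6), v, grid), "sum to 1")
})

test_that("two-phase clustering recovers a block structure exactly", {
  set.seed(3)
  pve <- cbind(matrix(runif(10 * 6, 0.30, 0.40), 10),   # years 1-6 high
               matrix(runif(10 * 18, 0.01, 0.06), 10))  # years 7-24 low
  lab <- cluster_phases(pve)
  expect_equal(lab, rep(c(1L, 2L), c(6, 18)))
  # SNP order is irrelevant
  expect_equal(cluster_phases(pve[sample(10), ]), lab)
  # degenerate constant matrix
  expect_warning(lab0 <- cluster_phases(matrix(0.2, 5, 8)), "constant")
  expect_equal(lab0, rep(1L, 8))
})

test_that("phase features match closed forms and a dense-scan oracle", {
  # uncoupled juvenile phase: logistic inverse gives the 95% time
  p <- nge_params(0.5, 12, 0, 0.4, 18, 0, 10, 2, 0.2, 12, 2.5, 0.15)
  grid <- time_grid(T = 40, step = 0.01)
  pf <- phase_features(p, grid)
  t95 <- log(((12 - 0.01) / 0.01) * 19) / 0.5   # reach 0.95 K from eps
  expect_equal(pf$phase1_offset[pf$trait == "height"], t95,
               tolerance = 0.02)
  expect_equal(pf$max_rate_phase2[pf$trait == "height"], 0.2 * 10 / exp(1),
               tolerance = 1e-10)
  expect_equal(pf$max_rate_phase2_time[pf$trait == "height"], 2 / 0.2)
  # dense-scan oracle for the coupled AA truth
  pAA <- sim_true_params()$AA
  pfA <- phase_features(pAA, time_grid(T = 40, step = 0.001))
  dense <- solve_phase1(pAA, time_grid(times = seq(0.001, 40, by = 0.001),
                                       step = 0.001))
  aH <- pAA["K_H1"]; aD <- pAA["K_D1"]
  bH <- pAA["beta_H_from_D"]; bD <- pAA["beta_D_from_H"]
  Hstar <- aH * (1 + bH * aD) / (1 - aH * aD * bH * bD)
  t_off <- dense$time[which(dense$H1 >= 0.95 * Hstar)[1]]
  expect_equal(pfA$phase1_offset[pfA$trait == "height"], t_off,
               tolerance = 1e-3)
  rate <- pAA["alpha_H"] * (1 - dense$H1 / aH) * dense$H1 +
    pAA["alpha_H"] * bH * dense$H1 * dense$D1
  expect_equal(pfA$max_rate_phase1[pfA$trait == "height"], max(rate),
               tolerance = 1e-6)
  expect_true(all(pfA$overlap >= 0))
  expect_true(all(pfA$phase2_offset >= pfA$phase2_onset))
})
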