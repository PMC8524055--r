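# Juvenile-phase solver, adult-phase curves, biphasic means, logistic
# alternatives, curve fitting and fit metrics.

test_that("decoupled juvenile system matches the logistic closed form", {
  p <- nge_params(0.5, 12, 0, 0.4, 18, 0, 10, 2, 0.2, 12, 2.5, 0.15)
  grid <- time_grid(T = 24, step = 0.05)
  sol <- solve_phase1(p, grid, init = c(0.3, 0.5))
  expect_equal(sol$H1, logistic_closed(grid$times, 12, 0.3, 0.5),
               tolerance = 1e-6)
  expect_equal(sol$D1, logistic_closed(grid$times, 18, 0.5, 0.4),
               tolerance = 1e-6)
  # step 0.1 must stay within the same tolerance
  sol2 <- solve_phase1(p, time_grid(T = 24, step = 0.1), init = c(0.3, 0.5))
  expect_equal(sol2$H1, logistic_closed(grid$times, 12, 0.3, 0.5),
               tolerance = 1e-6)
})

test_that("carrying-capacity start is an equilibrium when decoupled", {
  p <- nge_params(0.5, 12, 0, 0.4, 18, 0, 10, 2, 0.2, 12, 2.5, 0.15)
  sol <- solve_phase1(p, time_grid(T = 10), init = c(12, 18))
  expect_equal(sol$H1, rep(12, 10), tolerance = 1e-10)
  expect_equal(sol$D1, rep(18, 10), tolerance = 1e-10)
})

test_that("coupled solution matches the fine-step reference integrator", {
  # frozen reference: fourth-order fixed-step integration at step 1e-4
  # (deSolve::rk4), juvenile parameters of the AA genotype truth,
  # init (0.01, 0.01), evaluated at t = 12
  p <- sim_true_params()$AA
  sol <- solve_phase1(p, time_grid(times = c(6, 12), step = 0.05),
                      init = c(0.01, 0.01))
  expect_equal(sol$H1[2], 2.632465120492, tolerance = 1e-5)
  expect_equal(sol$D1[2], 3.547821334729, tolerance = 1e-5)
})

test_that("RK4 error shrinks about sixteen-fold when the step is halved", {
  skip_if_not_installed("deSolve")
  p <- sim_true_params()$AA
  rhs <- function(t, y, pp) {
    H <- y[1]; D <- y[2]
    list(c(pp[1] * (1 - H / pp[2]) * H + pp[1] * pp[3] * H * D,
           pp[4] * (1 - D / pp[5]) * D + pp[4] * pp[6] * D * H))
  }
  ref <- deSolve::rk4(c(0.01, 0.01), seq(0, 8, by = 0.005), rhs,
                      as.numeric(p)[1:6])
  ref_H <- ref[nrow(ref), 2]
  err <- sapply(c(0.4, 0.2), function(h) {
    s <- solve_phase1(p, time_grid(times = 8, step = h),
                      init = c(0.01, 0.01))
    abs(s$H1 - ref_H)
  })
  expect_gt(err[1] / err[2], 8)   # fourth-order: ratio ~ 16
})

test_that("solver reports divergence with the failure time", {
  # beta large and positive blows the coupled system up in finite time
  p <- nge_params(2, 5, 8, 2, 5, 8, 10, 2, 0.2, 12, 2.5, 0.15)
  expect_error(solve_phase1(p, time_grid(T = 30), init = c(5, 5)),
               "diverged near t")
})

test_that("adult-phase Gompertz identities hold", {
  p <- ref_joint_params()
  g <- phase2_curve(p, time_grid(times = p["p_H"] / p["q_H"]))
  expect_equal(g$H2, as.numeric(p["K_H2"] * exp(-1)), tolerance = 1e-12)
  # strictly increasing with supremum K2 for q > 0
  g24 <- phase2_curve(p, time_grid(T = 24))
  expect_true(all(diff(g24$H2) > 0))
  expect_true(all(g24$H2 < p["K_H2"]))
  # direct high-precision evaluation at t = 24
  expect_equal(g24$H2[24],
               as.numeric(16.1135 * exp(-exp(1.7521 - 0.1755 * 24))),
               tolerance = 1e-12)
})

test_that("biphasic total is exactly the sum of its phases", {
  tr <- nge_mean(ref_joint_params(), time_grid(T = 24))
  expect_equal(tr$H_total, tr$H1 + tr$H2, tolerance = 1e-12)
  expect_equal(tr$D_total, tr$D1 + tr$D2, tolerance = 1e-12)
})

test_that("interaction sign orders total against independent growth", {
  # height is inhibited by diameter (beta < 0): coupled growth below the
  # independent curve; diameter is promoted by height (beta > 0): above
  tr <- nge_mean(ref_joint_params(), time_grid(T = 24))
  expect_true(all(tr$H1 <= tr$H1_ind + 1e-9))
  expect_true(all(tr$D1 >= tr$D1_ind - 1e-9))
})

test_that("multiphasic logistic curves satisfy the basic identities", {
  grid <- time_grid(T = 30)
  one <- data.frame(p = 2, q = 0.4, K = 11)
  y1 <- kphasic_logistic(one, grid)
  expect_equal(y1[30], 11, tolerance = 1e-3)            # q > 0 limit
  expect_equal(kphasic_logistic(rbind(one, one), grid), 2 * y1)
  # first-phase contribution at its own midpoint is K/2
  di <- data.frame(p = c(2.5808, 0.8054), q = c(0.1925, 0.3326),
                   K = c(9.8744, 15.7204))
  tmid <- di$p[1] / di$q[1]
  second <- di$K[2] / (1 + exp(di$p[2] - di$q[2] * tmid))
  ymid <- kphasic_logistic(di, time_grid(times = tmid))
  expect_equal(ymid - second, di$K[1] / 2, tolerance = 1e-10)
})

test_that("fit metrics match a hand-computed five-point example", {
  obs <- c(1, 2, 3, 4, 6)
  fit <- c(1.1, 1.9, 3.2, 3.9, 5.8)
  m <- fit_metrics(obs, fit, n_params = 2)
  sse <- 0.01 + 0.01 + 0.04 + 0.01 + 0.04          # = 0.11
  sst <- sum((obs - 3.2)^2)                         # = 14.8
  r2 <- 1 - sse / sst
  expect_equal(m$RSD, sqrt(sse / 3), tolerance = 1e-12)
  expect_equal(m$adj_R2, 1 - (1 - r2) * 4 / 2, tolerance = 1e-12)
  logL <- -5 / 2 * (log(2 * pi * sse / 5) + 1)
  expect_equal(m$AIC, 4 - 2 * logL, tolerance = 1e-12)
  expect_equal(m$BIC, 2 * log(5) - 2 * logL, tolerance = 1e-12)
  # boundary behavior
  expect_equal(fit_metrics(obs, obs, 2)$RSD, 0)
  expect_equal(fit_metrics(obs, obs, 2)$adj_R2, 1)
  expect_equal(fit_metrics(obs, rep(3.2, 5), 2)$R2, 0, tolerance = 1e-12)
  expect_error(fit_metrics(obs, fit, 5), "more observations")
})

test_that("noise-free biphasic data are recovered to numerical accuracy", {
  p <- ref_joint_params()
  grid <- time_grid(T = 24)
  tr <- nge_mean(p, grid)
  f <- fit_growth_curve(grid$times, tr$H_total, tr$D_total, model = "nge",
                        restarts = 5, seed = 2)
  expect_lt(f$metrics$RSD, 1e-3)
})

test_that("richer logistic families never fit worse than nested ones", {
  grid <- time_grid(T = 24)
  y <- kphasic_logistic(data.frame(p = 1.5, q = 0.3, K = 20), grid)
  f1 <- fit_growth_curve(grid$times, y, model = "logistic1", restarts = 5,
                         seed = 3)
  f2 <- fit_growth_curve(grid$times, y, model = "logistic2", restarts = 5,
                         seed = 3)
  expect_lte(f2$metrics$RSD, f1$metrics$RSD + 1e-8)
})

test_that("noisy trajectories are recovered up to the asymptote tradeoff", {
  # the juvenile and adult asymptotes trade off along a near-flat SSE
  # direction, so the curve is recovered to the noise level while K_H2
  # itself carries the spread seen in repeated-simulation estimates
  p <- sim_true_params()$AA
  grid <- time_grid(T = 24)
  tr <- nge_mean(p, grid)
  set.seed(7)
  f <- fit_growth_curve(grid$times, tr$H_total + rnorm(24, 0, 0.1),
                        tr$D_total + rnorm(24, 0, 0.1), model = "nge",
                        restarts = 10, seed = 4)
  mu_true <- c(tr$H_total, tr$D_total)
  mu_fit <- c(f$fitted$height, f$fitted$diameter)
  expect_lt(sqrt(mean((mu_fit - mu_true)^2)), 0.1)
  expect_lt(abs(f$params["K_H2"] - p["K_H2"]) / p["K_H2"], 0.35)
})
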