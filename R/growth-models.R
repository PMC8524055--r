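#' Biphasic growth-model parameters
#'
#' The mean trajectory of each genotype is the sum of two developmental
#' phases per trait.  During the juvenile phase, stem height `H1` and stem
#' diameter `D1` grow as a pair of logistic curves coupled Lotka-Volterra
#' style:
#' \deqn{dH_1/dt = \alpha_H (1 - H_1/K_{H1}) H_1 + \alpha_H \beta_{H \leftarrow D} H_1 D_1}
#' and symmetrically for `D1`.  A negative \eqn{\beta} means the partner
#' trait inhibits growth (competition); a positive one means promotion
#' (cooperation).  The adult phase follows a Gompertz curve per trait,
#' \eqn{H_2(t) = K_{H2} \exp(-\exp(p_H - q_H t))}, and the observed trait is
#' the sum of the two phases.
#'
#' @param alpha_H,alpha_D juvenile intrinsic growth rates (1/year), > 0.
#' @param K_H1,K_D1 juvenile independent-growth asymptotes (trait units), > 0.
#' @param beta_H_from_D,beta_D_from_H dimensionless interaction coefficients
#'   (effect of the partner trait on this trait's juvenile growth).
#' @param K_H2,K_D2 adult-phase asymptotes (trait units), > 0.
#' @param p_H,p_D dimensionless Gompertz location parameters (related to the
#'   adult-phase initial value).
#' @param q_H,q_D adult-phase rate parameters (1/year).
#'
#' @return An object of class `nge_params`: a named numeric vector of
#'   length 12 in the canonical order `alpha_H, K_H1, beta_H_from_D,
#'   alpha_D, K_D1, beta_D_from_H, K_H2, p_H, q_H, K_D2, p_D, q_D`.
#' @examples
#' p <- nge_params(0.56, 14.9, -0.0092, 0.54, 20.0, 0.0059,
#'                 16.1, 1.75, 0.176, 18.6, 2.56, 0.129)
#' nge_mean(p, time_grid(24))
#' @export
nge_params <- function(alpha_H, K_H1, beta_H_from_D,
                       alpha_D, K_D1, beta_D_from_H,
                       K_H2, p_H, q_H, K_D2, p_D, q_D) {
  x <- c(alpha_H = alpha_H, K_H1 = K_H1, beta_H_from_D = beta_H_from_D,
         alpha_D = alpha_D, K_D1 = K_D1, beta_D_from_H = beta_D_from_H,
         K_H2 = K_H2, p_H = p_H, q_H = q_H,
         K_D2 = K_D2, p_D = p_D, q_D = q_D)
  validate_nge_params(x)
}

.nge_names <- c("alpha_H", "K_H1", "beta_H_from_D",
                "alpha_D", "K_D1", "beta_D_from_H",
                "K_H2", "p_H", "q_H", "K_D2", "p_D", "q_D")

validate_nge_params <- function(x) {
  x <- as.numeric(x)[seq_len(12)]
  names(x) <- .nge_names
  if (any(!is.finite(x)))
    stop("nge_params: all 12 parameters must be finite")
  pos <- c("alpha_H", "K_H1", "alpha_D", "K_D1", "K_H2", "K_D2")
  if (any(x[pos] <= 0))
    stop("nge_params: ", paste(pos[x[pos] <= 0], collapse = ", "),
         " must be > 0")
  class(x) <- "nge_params"
  x
}

#' @export
print.nge_params <- function(x, ...) {
  cat("Biphasic growth parameters (juvenile LV + adult Gompertz):\n")
  print(setNames(as.numeric(x), names(x)), ...)
  invisible(x)
}

as_nge_params <- function(x) {
  if (inherits(x, "nge_params")) return(x)
  validate_nge_params(x)
}

#' Measurement time grid
#'
#' Annual measurements at integer years `1..T`; the juvenile-phase system is
#' integrated from `t = 0` with a fixed Runge-Kutta step.
#'
#' @param T number of annual measurements (default 24).
#' @param step fixed RK4 solver step in years (default 0.05).
#' @param times optional explicit output times (strictly increasing,
#'   non-negative); overrides `T`.
#' @return An object of class `time_grid` with elements `times` and `step`.
#' @export
time_grid <- function(T = 24, step = 0.05, times = NULL) {
  if (is.null(times)) {
    if (T < 1) stop("time_grid: T must be >= 1")
    times <- seq_len(T)
  }
  times <- as.numeric(times)
  if (any(diff(times) <= 0) || any(times < 0))
    stop("time_grid: times must be strictly increasing and non-negative")
  if (step <= 0) stop("time_grid: step must be > 0")
  structure(list(times = times, step = step), class = "time_grid")
}

as_time_grid <- function(grid) {
  if (inherits(grid, "time_grid")) return(grid)
  if (is.numeric(grid) && length(grid) == 1) return(time_grid(T = grid))
  stop("expected a time_grid object")
}

#' Solve the juvenile-phase coupled system
#'
#' Integrates the Lotka-Volterra-coupled logistic pair with classical
#' fourth-order Runge-Kutta at the grid's fixed step, starting from `t = 0`,
#' and samples the solution at the grid's output times.
#'
#' @param params an [nge_params] object (only the six juvenile-phase entries
#'   are used).
#' @param grid a [time_grid].
#' @param init length-2 positive initial state `c(H1(0), D1(0))`
#'   (default `c(0.01, 0.01)`).
#' @param independent if `TRUE`, both interaction coefficients are treated
#'   as zero so each trait follows its independent logistic curve.
#' @return A data frame with columns `time`, `H1`, `D1`.
#' @export
solve_phase1 <- function(params, grid, init = c(0.01, 0.01),
                         independent = FALSE) {
  params <- as_nge_params(params)
  grid <- as_time_grid(grid)
  if (length(init) != 2 || any(init <= 0))
    stop("solve_phase1: init must be two positive values")
  p <- as.numeric(params)
  if (independent) p[c(3, 6)] <- 0
  sol <- cpp_solve_phase1(p[1:6], grid$times, grid$step, init[1], init[2])
  if (sol$t_fail >= 0)
    stop(sprintf("solve_phase1: solution diverged near t = %.4f", sol$t_fail))
  data.frame(time = grid$times, H1 = sol$H1, D1 = sol$D1)
}

#' Adult-phase Gompertz curves
#'
#' Pointwise evaluation of \eqn{K_2 \exp(-\exp(p - q t))} for each trait.
#'
#' @inheritParams solve_phase1
#' @return A data frame with columns `time`, `H2`, `D2`.
#' @export
phase2_curve <- function(params, grid) {
  params <- as_nge_params(params)
  grid <- as_time_grid(grid)
  t <- grid$times
  data.frame(
    time = t,
    H2 = params["K_H2"] * exp(-exp(params["p_H"] - params["q_H"] * t)),
    D2 = params["K_D2"] * exp(-exp(params["p_D"] - params["q_D"] * t))
  )
}

#' Biphasic mean trajectory
#'
#' Total growth per trait is the sum of the juvenile-phase solution and the
#' adult-phase Gompertz curve.  The juvenile phase is also reported with the
#' interaction switched off (`H1_ind`, `D1_ind`), which separates
#' independent from interaction-driven growth.
#'
#' @inheritParams solve_phase1
#' @return An object of class `nge_trajectory`: a data frame with columns
#'   `time`, `H_total`, `D_total`, `H1`, `D1`, `H1_ind`, `D1_ind`,
#'   `H2`, `D2`.
#' @export
nge_mean <- function(params, grid, init = c(0.01, 0.01)) {
  params <- as_nge_params(params)
  grid <- as_time_grid(grid)
  ph1 <- solve_phase1(params, grid, init = init)
  ph1i <- solve_phase1(params, grid, init = init, independent = TRUE)
  ph2 <- phase2_curve(params, grid)
  out <- data.frame(
    time = grid$times,
    H_total = ph1$H1 + ph2$H2, D_total = ph1$D1 + ph2$D2,
    H1 = ph1$H1, D1 = ph1$D1,
    H1_ind = ph1i$H1, D1_ind = ph1i$D1,
    H2 = ph2$H2, D2 = ph2$D2
  )
  class(out) <- c("nge_trajectory", "data.frame")
  out
}

# stacked 2T mean vector (height years then diameter years); compiled path
nge_mu_vec <- function(params, grid, init_eps = 0.01) {
  mu <- as.numeric(cpp_nge_mu(as.numeric(params)[1:12], grid$times,
                              grid$step, init_eps))
  if (any(!is.finite(mu)))
    stop("nge_mu_vec: solution diverged for the supplied parameters")
  mu
}

#' Multiphasic logistic curves
#'
#' Sum of 1-3 logistic phases \eqn{K_i / (1 + e^{p_i - q_i t})}, the
#' single-trait alternatives against which the biphasic coupled model is
#' compared.
#'
#' @param phases a data frame (or matrix) with columns `p`, `q`, `K`
#'   and 1-3 rows, one per phase.
#' @param grid a [time_grid].
#' @return Numeric vector of the summed curve at the grid times.
#' @export
kphasic_logistic <- function(phases, grid) {
  grid <- as_time_grid(grid)
  phases <- as.data.frame(phases)
  if (!all(c("p", "q", "K") %in% names(phases)))
    stop("kphasic_logistic: phases needs columns p, q, K")
  if (nrow(phases) < 1 || nrow(phases) > 3)
    stop("kphasic_logistic: 1 to 3 phases supported")
  if (any(phases$K <= 0)) stop("kphasic_logistic: K must be > 0")
  y <- rep(0, length(grid$times))
  for (i in seq_len(nrow(phases)))
    y <- y + phases$K[i] / (1 + exp(phases$p[i] - phases$q[i] * grid$times))
  y
}

#' Least-squares fit quality metrics
#'
#' @param observed,fitted numeric vectors of equal length.
#' @param n_params number of fitted parameters.
#' @return A list of class `fit_metrics`: `adj_R2`, `RSD`
#'   (`sqrt(SSE/(n-k))`), `AIC`/`BIC` under a Gaussian residual likelihood
#'   (totals), `AIC_per_obs`/`BIC_per_obs`, `n_params`, `n_obs`.
#' @export
fit_metrics <- function(observed, fitted, n_params) {
  if (length(observed) != length(fitted))
    stop("fit_metrics: observed and fitted lengths differ")
  n <- length(observed)
  k <- n_params
  if (n <= k) stop("fit_metrics: need more observations than parameters")
  sse <- sum((observed - fitted)^2)
  sst <- sum((observed - mean(observed))^2)
  r2 <- if (sst > 0) 1 - sse / sst else 1
  adj <- if (n - k - 1 > 0) 1 - (1 - r2) * (n - 1) / (n - k - 1) else NA_real_
  # Gaussian profile likelihood: logL = -n/2 (log(2 pi sse/n) + 1)
  logL <- -n / 2 * (log(2 * pi * max(sse, .Machine$double.xmin) / n) + 1)
  aic <- 2 * k - 2 * logL
  bic <- k * log(n) - 2 * logL
  structure(list(adj_R2 = adj, R2 = r2, RSD = sqrt(sse / (n - k)),
                 AIC = aic, BIC = bic,
                 AIC_per_obs = aic / n, BIC_per_obs = bic / n,
                 n_params = k, n_obs = n, SSE = sse),
            class = "fit_metrics")
}

# data-driven starting values for a biphasic fit
nge_guess <- function(times, H, D) {
  nge_params(
    alpha_H = 0.5, K_H1 = 0.55 * max(H), beta_H_from_D = 0,
    alpha_D = 0.5, K_D1 = 0.55 * max(D), beta_D_from_H = 0,
    K_H2 = 0.6 * max(H), p_H = 2, q_H = 2.5 / max(times),
    K_D2 = 0.6 * max(D), p_D = 2, q_D = 2.5 / max(times)
  )
}

# Generous biological box for the 12 parameters, scaled to the observed
# trajectories (asymptotes within 3x the observed maxima, rates and
# interactions in plausible ranges).  Keeps Nelder-Mead off the
# unidentified ridges where asymptote and interaction terms trade off at
# wildly unphysical values while the curve barely changes.
nge_box <- function(ybar) {
  Tn <- nrow(ybar) %/% 2
  Hmax <- max(ybar[seq_len(Tn), ])
  Dmax <- max(ybar[Tn + seq_len(Tn), ])
  # lower bounds are absolute constants so a fit started from a slightly
  # different trajectory set (pooled vs per-genotype means) never begins
  # outside its box
  list(
    lo = c(0.02, 1e-3, -0.3, 0.02, 1e-3, -0.3,
           1e-3, -15, 1e-3, 1e-3, -15, 1e-3),
    hi = c(5, 3 * Hmax, 0.3, 5, 3 * Dmax, 0.3,
           3 * Hmax, 15, 2, 3 * Dmax, 15, 2)
  )
}

# pull a transformed flat parameter vector strictly inside a box
clamp_tpar <- function(tpar, idx, box) {
  eps <- 1e-8 * (box$hi - box$lo)
  for (j in seq_len(ncol(idx))) {
    th <- cpp_nge_untransform(tpar[idx[, j]])
    th <- pmin(pmax(th, box$lo + eps), box$hi - eps)
    tpar[idx[, j]] <- cpp_nge_transform(th)
  }
  tpar
}

# multi-start wrapper around the compiled weighted-LS curve optimizer.
# ybar: 2T x J matrix; idx: 12 x J 1-based index map into the flat vector;
# start: flat vector on the natural scale (via start_tpar on the
# unconstrained scale).  Returns list(par (transformed flat), value).
fit_curves_ms <- function(start_tpar, idx, ybar, w, L, grid, eps,
                          restarts = 0, maxit = 2000, reltol = 1e-8,
                          rng_seed = NULL, init_step = 0.1, polish = 2,
                          box = nge_box(ybar)) {
  Lm <- if (is.null(L)) NULL else L
  run <- function(tp, istep) {
    f <- cpp_fit_curves(tp, idx - 1L, ybar, w, Lm, grid$times,
                        grid$step, eps, maxit, reltol, istep,
                        box$lo, box$hi)
    # polish: fresh simplices around the solution (alternating small and
    # large spans) escape prematurely collapsed simplices
    for (k in seq_len(polish)) {
      g <- cpp_fit_curves(f$par, idx - 1L, ybar, w, Lm, grid$times,
                          grid$step, eps, maxit, reltol,
                          if (k %% 2 == 1) istep / 5 else istep * 2,
                          box$lo, box$hi)
      if (g$value < f$value) f <- g
      else if (k %% 2 == 0) break
    }
    f
  }
  best <- run(start_tpar, init_step)
  if (restarts > 0) {
    if (!is.null(rng_seed)) set.seed(rng_seed)
    for (r in seq_len(restarts)) {
      jit <- start_tpar + rnorm(length(start_tpar), 0, 0.25)
      cand <- run(jit, init_step)
      if (cand$value < best$value) best <- cand
    }
  }
  best
}

#' Fit a growth model to a mean trajectory
#'
#' Least-squares fitting of either the biphasic coupled model (both traits
#' jointly, 12 parameters) or a K-phasic logistic model (each trait
#' separately, 3 parameters per phase) by derivative-free Nelder-Mead
#' simplex search with multi-start.
#'
#' @param times measurement times.
#' @param height,diameter observed mean series; `diameter` may be `NULL`
#'   for single-trait logistic fits.
#' @param model one of `"nge"`, `"logistic1"`, `"logistic2"`, `"logistic3"`.
#' @param init_guess optional starting parameters ([nge_params] for
#'   `"nge"`; a phases data frame for logistic models).
#' @param restarts number of perturbed restarts (starting values jittered
#'   about +/-50 percent, log-uniform for positive parameters).
#' @param seed RNG seed for the restart perturbations.
#' @param grid_step RK4 step used during fitting.
#' @param init_eps juvenile-phase initial value.
#' @return A list of class `growth_fit`: `model`, `params` (and for
#'   logistic fits `params_height`/`params_diameter`), `fitted`, `metrics`
#'   (overall [fit_metrics]), `rsd`.
#' @export
fit_growth_curve <- function(times, height, diameter = NULL,
                             model = c("nge", "logistic1", "logistic2",
                                       "logistic3"),
                             init_guess = NULL, restarts = 20, seed = 1,
                             grid_step = 0.05, init_eps = 0.01) {
  model <- match.arg(model)
  grid <- time_grid(times = times, step = grid_step)
  if (model == "nge") {
    if (is.null(diameter))
      stop("fit_growth_curve: the biphasic model is fitted jointly; ",
           "diameter is required")
    if (length(height) < 12)
      stop("fit_growth_curve: need at least as many observations as ",
           "parameters")
    start <- if (is.null(init_guess)) nge_guess(times, height, diameter)
             else as_nge_params(init_guess)
    ybar <- matrix(c(height, diameter), ncol = 1)
    fit <- fit_curves_ms(cpp_nge_transform(as.numeric(start)),
                         idx = matrix(1:12, ncol = 1), ybar = ybar,
                         w = 1, L = NULL, grid = grid, eps = init_eps,
                         restarts = restarts, rng_seed = seed,
                         maxit = 5000, reltol = 1e-10, polish = 8)
    par <- validate_nge_params(cpp_nge_untransform(fit$par))
    mu <- nge_mu_vec(par, grid, init_eps)
    T <- length(times)
    obs <- c(height, diameter)
    out <- list(model = model, params = par,
                fitted = data.frame(time = times, height = mu[1:T],
                                    diameter = mu[T + 1:T]),
                metrics = fit_metrics(obs, mu, 12),
                objective = fit$value)
    class(out) <- "growth_fit"
    return(out)
  }
  n_phase <- as.integer(substring(model, 9))
  fit1 <- fit_logistic_trait(times, height, n_phase, init_guess, restarts,
                             seed)
  out <- list(model = model, params_height = fit1$phases,
              fitted = data.frame(time = times, height = fit1$fitted))
  obs <- height
  fitv <- fit1$fitted
  k <- 3 * n_phase
  if (!is.null(diameter)) {
    fit2 <- fit_logistic_trait(times, diameter, n_phase, init_guess,
                               restarts, seed + 1)
    out$params_diameter <- fit2$phases
    out$fitted$diameter <- fit2$fitted
    obs <- c(obs, diameter)
    fitv <- c(fitv, fit2$fitted)
    k <- 2 * k
  }
  out$metrics <- fit_metrics(obs, fitv, k)
  class(out) <- "growth_fit"
  out
}

fit_logistic_trait <- function(times, y, n_phase, init_guess, restarts,
                               seed) {
  if (length(y) < 3 * n_phase)
    stop("fit_growth_curve: series shorter than the parameter count")
  grid <- time_grid(times = times)
  if (is.null(init_guess)) {
    Ks <- rep(max(y) / n_phase, n_phase)
    ps <- seq(1, 2.5, length.out = n_phase)
    qs <- rep(3 / max(times), n_phase) * seq_len(n_phase)
    start <- data.frame(p = ps, q = qs, K = Ks)
  } else start <- as.data.frame(init_guess)
  pack <- function(ph) as.numeric(rbind(ph$p, ph$q, log(ph$K)))
  unpack <- function(v) {
    m <- matrix(v, nrow = 3)
    data.frame(p = m[1, ], q = m[2, ], K = exp(m[3, ]))
  }
  obj <- function(v) {
    f <- kphasic_logistic(unpack(v), grid)
    sum((y - f)^2)
  }
  polish <- function(v) {
    o <- optim(v, obj, method = "Nelder-Mead",
               control = list(maxit = 4000, reltol = 1e-12))
    for (k in 1:3) {
      o2 <- optim(o$par, obj, method = "Nelder-Mead",
                  control = list(maxit = 4000, reltol = 1e-12))
      if (o2$value > o$value - 1e-12) { o <- o2; break }
      o <- o2
    }
    o
  }
  set.seed(seed)
  starts <- list(pack(start))
  if (is.null(init_guess) && n_phase > 1) {
    # nested start: the (k-1)-phase solution plus one small extra phase,
    # so a richer family never fits worse than the nested one
    sub <- fit_logistic_trait(times, y, n_phase - 1, NULL,
                              max(restarts %/% 2, 2), seed + 17)
    extra <- data.frame(p = 3, q = 0.5, K = max(y) * 1e-3)
    starts <- c(starts, list(pack(rbind(sub$phases, extra))))
  }
  best <- NULL
  for (v0 in starts) {
    for (r in 0:restarts) {
      v <- if (r == 0) v0 else v0 + runif(length(v0), -0.5, 0.5)
      o <- polish(v)
      if (is.null(best) || o$value < best$value) best <- o
    }
  }
  phases <- unpack(best$par)
  list(phases = phases, fitted = kphasic_logistic(phases, grid),
       sse = best$value)
}
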