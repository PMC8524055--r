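#' Reference two-genotype parameter set for the poplar height-diameter
#' system
#'
#' The generating truth used by the simulation studies: genotype-specific
#' biphasic parameters for a testcross QTL segregating two genotypes
#' (`AA`, `Aa`) in a full-sib poplar family, height in meters and diameter
#' in centimeters over 24 annual measurements.  `corrected = TRUE`
#' replaces the implausible adult-phase location value `p_H = 0.0034` of
#' genotype `Aa` (which duplicates an interaction coefficient and sits
#' three orders of magnitude below its homozygote counterpart, most likely
#' a typesetting artifact) with a value in the plausible class of the
#' other genotype; the default keeps the printed value.
#'
#' @param corrected logical; see Details.
#' @return A named list of two [nge_params] objects (`AA`, `Aa`).
#' @export
sim_true_params <- function(corrected = FALSE) {
  AA <- nge_params(
    alpha_H = 0.4816, K_H1 = 16.6452, beta_H_from_D = -0.0085,
    alpha_D = 0.5057, K_D1 = 18.8163, beta_D_from_H = 0.0034,
    K_H2 = 14.7208, p_H = 1.9779, q_H = 0.1751,
    K_D2 = 14.1880, p_D = 3.1031, q_D = 0.1639)
  Aa <- nge_params(
    alpha_H = 0.5880, K_H1 = 16.3061, beta_H_from_D = -0.0082,
    alpha_D = 0.5387, K_D1 = 18.9900, beta_D_from_H = 0.0120,
    K_H2 = 15.0220, p_H = if (corrected) 2.0 else 0.0034, q_H = 0.1699,
    K_D2 = 14.9758, p_D = 2.7916, q_D = 0.1538)
  list(AA = AA, Aa = Aa)
}

#' Simulation study configuration
#'
#' Describes one cell of the simulation design: sample size, marker count,
#' time grid, target heritability, replicate count and the generating
#' genotype parameters.
#'
#' @param n number of samples.
#' @param H2 target heritability, the mean-over-time proportion of
#'   phenotypic variance that is genetic, in (0, 1).
#' @param M number of simulated markers (default 1000).
#' @param T number of annual measurements (default 24).
#' @param reps replicate count (default 100).
#' @param seed base RNG seed.
#' @param params named list of genotype [nge_params] (default
#'   [sim_true_params()]).
#' @param sad_shape an [sad_params] giving the antedependence shape
#'   (`phi_1`, `phi_2`, `rho`); its `gamma` entries are the base innovation
#'   SDs rescaled by the heritability calibration.  Default
#'   `sad_params(0.8, 0.8, 1, 1, 0.3)`.
#' @param causal index of the phenotype-linked marker, or `NA` for a
#'   no-QTL (null) configuration.
#' @param segregation `"testcross"` (1:1) or `"intercross"` (1:2:1).
#' @param step RK4 solver step.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n, H2, M = 1000, T = 24, reps = 100,
                              seed = 1, params = sim_true_params(),
                              sad_shape = sad_params(0.8, 0.8, 1, 1, 0.3),
                              causal = 1,
                              segregation = c("testcross", "intercross"),
                              step = 0.05) {
  segregation <- match.arg(segregation)
  if (H2 <= 0 || H2 >= 1) stop("simulation_config: H2 must be in (0, 1)")
  if (reps < 1) stop("simulation_config: reps must be >= 1")
  if (M < 1) stop("simulation_config: M must be >= 1")
  J <- length(params)
  freqs <- if (segregation == "testcross") rep(0.5, 2) else
    c(0.25, 0.5, 0.25)
  if (J != length(freqs))
    stop("simulation_config: parameter list length must match the ",
         "segregation genotype count")
  structure(list(n = n, M = M, T = T, H2 = H2, reps = reps, seed = seed,
                 params = params, sad_shape = as_sad_params(sad_shape),
                 causal = causal, segregation = segregation,
                 freqs = freqs, grid = time_grid(T = T, step = step)),
            class = "simulation_config")
}

derive_seed <- function(seed, k) {
  as.integer((as.double(seed) + 104729 * as.double(k)) %% 2147483629)
}

#' Simulate a marker table
#'
#' Markers are drawn i.i.d. across samples: testcross markers segregate
#' 1:1 into codes `AA`/`Aa`, intercross markers 1:2:1 into
#' `AA`/`Aa`/`aa`.  No linkage disequilibrium is imposed.  The causal
#' marker (when configured) is the row at `config$causal`.
#'
#' @param config a [simulation_config].
#' @param seed RNG seed (defaults to the config seed).
#' @return A marker data frame: `marker_id`, `chrom`, `pos_bp`,
#'   `seg_type`, then one genotype column per sample.
#' @export
simulate_markers <- function(config, seed = config$seed) {
  set.seed(seed)
  M <- config$M; n <- config$n
  if (config$segregation == "testcross") {
    codes <- c("AA", "Aa"); prob <- c(0.5, 0.5)
  } else {
    codes <- c("AA", "Aa", "aa"); prob <- c(0.25, 0.5, 0.25)
  }
  G <- matrix(sample(codes, M * n, replace = TRUE, prob = prob), M, n)
  ids <- paste0("S", seq_len(n))
  out <- data.frame(marker_id = paste0("M", seq_len(M)),
                    chrom = ((seq_len(M) - 1) %% 19) + 1,
                    pos_bp = ((seq_len(M) - 1) %/% 19 + 1) * 10000,
                    seg_type = config$segregation,
                    stringsAsFactors = FALSE)
  G <- as.data.frame(G, stringsAsFactors = FALSE)
  names(G) <- ids
  cbind(out, G)
}

# solve for the noise scale c with mean_t g(t) / (g(t) + c v(t)) = H2
solve_noise_scale <- function(g, v, H2) {
  if (all(g <= 0)) stop("calibrate_noise: zero genetic variance with H2 > 0")
  f <- function(logc) mean(g / (g + exp(logc) * v)) - H2
  lo <- -40; hi <- 40
  if (f(lo) < 0 || f(hi) > 0)
    stop("calibrate_noise: target heritability infeasible")
  exp(uniroot(f, c(lo, hi), tol = 1e-12)$root)
}

#' Calibrate the innovation variances to a target heritability
#'
#' The genetic variance per trait and time,
#' `sigma2_g,k(t) = sum_j f_j (mu_jk(t) - mubar_k(t))^2`, is fixed by the
#' genotype curves; a scalar `c_k` per trait is found by 1-D root-finding
#' so that the mean over time of
#' `sigma2_g,k(t) / (sigma2_g,k(t) + c_k v_k(t))` equals `H2`, where
#' `v_k(t)` is the SAD(1) marginal variance at the base innovation SD.
#' The returned parameters carry `gamma_k` scaled by `sqrt(c_k)`.
#'
#' @param params_list genotype parameter sets.
#' @param freqs genotype frequencies.
#' @param sad_shape base [sad_params].
#' @param H2 target heritability in (0, 1).
#' @param grid a [time_grid].
#' @param init_eps juvenile-phase initial value.
#' @return An [sad_params] with calibrated `gamma_1`, `gamma_2`.
#' @export
calibrate_noise <- function(params_list, freqs, sad_shape, H2, grid,
                            init_eps = 0.01) {
  grid <- as_time_grid(grid)
  sad_shape <- as_sad_params(sad_shape)
  if (H2 <= 0 || H2 >= 1) stop("calibrate_noise: H2 must be in (0, 1)")
  Tn <- length(grid$times)
  mus <- vapply(params_list, function(p)
    nge_mu_vec(as_nge_params(p), grid, init_eps), numeric(2 * Tn))
  gv <- genetic_variance(mus, freqs)
  base_var <- function(phi, gam)
    gam^2 * (1 - phi^(2 * seq_len(Tn))) / (1 - phi^2)
  v1 <- base_var(sad_shape["phi_1"], sad_shape["gamma_1"])
  v2 <- base_var(sad_shape["phi_2"], sad_shape["gamma_2"])
  c1 <- solve_noise_scale(gv[seq_len(Tn)], v1, H2)
  c2 <- solve_noise_scale(gv[Tn + seq_len(Tn)], v2, H2)
  sad_params(sad_shape["phi_1"], sad_shape["phi_2"],
             sad_shape["gamma_1"] * sqrt(c1),
             sad_shape["gamma_2"] * sqrt(c2),
             sad_shape["rho"])
}

#' Simulate phenotypes under the biphasic model
#'
#' Each sample's `2T` mean vector comes from the biphasic curve of its
#' genotype at the causal marker (or, for a no-QTL configuration, from the
#' frequency-weighted average parameter set); residuals are drawn from the
#' multivariate normal with the calibrated SAD(1) covariance.
#'
#' @param config a [simulation_config].
#' @param markers a marker table from [simulate_markers].
#' @param sad calibrated [sad_params]; computed by [calibrate_noise] when
#'   absent.
#' @param seed RNG seed.
#' @return A [trait_matrix].
#' @export
simulate_phenotypes <- function(config, markers, sad = NULL,
                                seed = config$seed) {
  grid <- config$grid
  Tn <- config$T
  if (is.null(sad))
    sad <- calibrate_noise(config$params, config$freqs, config$sad_shape,
                           config$H2, grid)
  sigma <- build_covariance(sad, Tn)
  if (!isTRUE(attr(sigma, "positive_definite")))
    stop("simulate_phenotypes: covariance is not positive definite")
  ids <- setdiff(names(markers),
                 c("marker_id", "chrom", "pos_bp", "seg_type"))
  n <- length(ids)
  mu <- matrix(0, n, 2 * Tn)
  if (!is.na(config$causal)) {
    codes <- as.character(markers[config$causal, ids])
    labs <- names(config$params)
    jidx <- match(codes, labs)
    if (anyNA(jidx))
      stop("simulate_phenotypes: causal-marker codes do not match the ",
           "genotype parameter labels")
    mus <- vapply(config$params, function(p)
      nge_mu_vec(p, grid), numeric(2 * Tn))
    mu <- t(mus[, jidx])
  } else {
    avg <- validate_nge_params(
      as.numeric(vapply(config$params, as.numeric, numeric(12)) %*%
                   config$freqs))
    mu <- matrix(nge_mu_vec(avg, grid), n, 2 * Tn, byrow = TRUE)
  }
  set.seed(seed)
  U <- chol(sigma)
  E <- matrix(rnorm(n * 2 * Tn), n, 2 * Tn) %*% U
  trait_matrix(mu + E, sample_ids = ids)
}

# empirical mean-over-time heritability of a simulated data set, using the
# known causal genotype assignment
emp_heritability <- function(pheno, codes) {
  Y <- unclass(pheno)
  Tn <- tm_T(pheno)
  f <- factor(codes)
  gm <- apply(Y, 2, function(col) tapply(col, f, mean))
  fr <- as.numeric(table(f)) / length(f)
  gv <- genetic_variance(t(gm), fr)
  pv <- apply(Y, 2, var)
  c(height = mean((gv / pv)[seq_len(Tn)]),
    diameter = mean((gv / pv)[Tn + seq_len(Tn)]))
}

threshold_for <- function(alpha, M, df) {
  qchisq(alpha / M, df = df, lower.tail = FALSE)
}

# Batched per-marker LR with the covariance fixed at the null estimate:
# LR = B + 2 V0 - 2 sum_j V_j (between-group Mahalanobis plus warm-started
# per-group curve-fit objectives), the compiled equivalent of
# fit_alternative(covariance = "fixed") per marker.  codes: M x n matrix of
# genotype codes aligned with rownames(pheno).
scan_lrs_fixed <- function(pheno, codes, null_fit, control = fit_control(),
                           refine_above = Inf, maxit_refine = 2500,
                           solver_step = NULL) {
  Y <- unclass(pheno)
  Tn <- tm_T(pheno)
  grid <- null_fit$grid
  if (!is.null(solver_step)) grid$step <- solver_step
  sigma <- build_covariance(null_fit$sad, Tn)
  L <- t(chol(sigma))
  tpar0 <- cpp_nge_transform(as.numeric(null_fit$params[[1]]))
  V0 <- cpp_curve_objective(tpar0, matrix(0:11, ncol = 1),
                            matrix(colMeans(Y), ncol = 1), nrow(Y), L,
                            grid$times, grid$step, control$init_eps)
  codes <- matrix(as.character(codes), ncol = nrow(Y))
  G <- matrix(0L, nrow(codes), ncol(codes))
  for (m in seq_len(nrow(codes))) {
    cm <- codes[m, ]
    labs <- sort(unique(cm[!is.na(cm)]), method = "radix")
    gi <- match(cm, labs)
    gi[is.na(gi)] <- 0L
    G[m, ] <- gi
  }
  box <- nge_box(matrix(colMeans(Y), ncol = 1))
  tpar0 <- clamp_tpar(tpar0, matrix(1:12, ncol = 1), box)
  as.numeric(cpp_scan_lrs(Y, G, L, tpar0, V0, grid$times, grid$step,
                          control$init_eps, control$nm_maxit_warm,
                          control$nm_reltol, 0.02, refine_above,
                          maxit_refine, box$lo, box$hi))
}

#' Statistical power study
#'
#' Per replicate, phenotypes are simulated from the causal marker's
#' genotype curves with heritability-calibrated SAD(1) noise, the null and
#' genotype-specific models are fitted at the causal marker, and a
#' detection is declared when the LR statistic exceeds the chi-square
#' threshold at the Bonferroni-corrected level `alpha / M`.  The default
#' fast mode evaluates the causal marker only (the detection rule is
#' unchanged); `mode = "scan"` scans all `M` simulated markers and
#' declares detection when the causal marker passes.
#'
#' @param config a [simulation_config] with a causal marker.
#' @param alpha family-wise significance level (default 0.05).
#' @param mode `"fast"` or `"scan"`.
#' @param control a [fit_control].
#' @param threshold optional LR threshold override.
#' @return A list of class `power_result`: `power`, `detected`, `lr`
#'   (per-replicate LR at the causal marker), `threshold`, `df`, `reps`,
#'   `failed`.
#' @export
power_study <- function(config, alpha = 0.05, mode = c("fast", "scan"),
                        control = fit_control(nm_maxit_warm = 2000),
                        threshold = NULL) {
  mode <- match.arg(mode)
  if (is.na(config$causal)) stop("power_study: config has no causal marker")
  J <- length(config$params)
  df <- 12 * (J - 1)
  if (is.null(threshold)) threshold <- threshold_for(alpha, config$M, df)
  sad <- calibrate_noise(config$params, config$freqs, config$sad_shape,
                         config$H2, config$grid)
  lrs <- rep(NA_real_, config$reps)
  failed <- 0L
  for (r in seq_len(config$reps)) {
    sr <- derive_seed(config$seed, r)
    cfg_r <- config
    if (mode == "fast") cfg_r$M <- 1  # only the causal marker is needed
    cfg_r$causal <- 1
    mk <- simulate_markers(cfg_r, seed = sr)
    ph <- simulate_phenotypes(cfg_r, mk, sad = sad,
                              seed = derive_seed(sr, 1))
    lr <- tryCatch({
      nf <- fit_null(ph, config$grid, control)
      gc <- genotype_column(as.character(mk[1, rownames(ph)]),
                            segregation = config$segregation)
      alt <- fit_genotype_model(ph, gc, config$grid, control, nf,
                                covariance = "refit")
      max(2 * (alt$loglik - nf$loglik), 0)
    }, error = function(e) NA_real_)
    if (is.na(lr)) failed <- failed + 1L
    lrs[r] <- lr
  }
  ok <- !is.na(lrs)
  structure(list(power = mean(lrs[ok] >= threshold),
                 detected = lrs >= threshold, lr = lrs,
                 threshold = threshold, df = df, reps = config$reps,
                 failed = failed, H2 = config$H2, n = config$n),
            class = "power_result")
}

#' False-positive rate study
#'
#' Per replicate, phenotypes are simulated with no QTL anywhere (all
#' samples share the frequency-weighted average curve) and all `M`
#' simulated null markers are tested; the replicate counts as a false
#' positive when any marker's LR exceeds the `alpha / M` Bonferroni
#' chi-square threshold.
#'
#' @param config a [simulation_config]; its causal marker is ignored.
#' @inheritParams power_study
#' @return A list of class `power_result` with `fpr`, `max_lr`
#'   (per-replicate maximum LR across markers), `threshold`, `reps`.
#' @export
fpr_study <- function(config, alpha = 0.05, control = fit_control(),
                      threshold = NULL) {
  J <- length(config$params)
  df <- 12 * (J - 1)
  if (is.null(threshold)) threshold <- threshold_for(alpha, config$M, df)
  sad <- calibrate_noise(config$params, config$freqs, config$sad_shape,
                         config$H2, config$grid)
  cfg0 <- config
  cfg0$causal <- NA
  max_lr <- rep(NA_real_, config$reps)
  n_pos <- rep(NA_real_, config$reps)
  failed <- 0L
  for (r in seq_len(config$reps)) {
    sr <- derive_seed(config$seed, 3000000 + r)
    mk <- simulate_markers(cfg0, seed = sr)
    ph <- simulate_phenotypes(cfg0, mk, sad = sad,
                              seed = derive_seed(sr, 1))
    # two-stage evaluation: a cheap fixed-covariance pass over all markers,
    # then the full shared-covariance refit (the scan statistic) for any
    # marker within reach of the threshold.  The refit only increases the
    # alternative likelihood and its gain on null markers is a few units,
    # so markers far below the threshold cannot flip to detections.
    ctl_quick <- control
    ctl_quick$nm_maxit_warm <- min(control$nm_maxit_warm, 200)
    res <- tryCatch({
      nf <- fit_null(ph, config$grid, control)
      lr <- scan_lrs_fixed(ph, as.matrix(mk[, rownames(ph), drop = FALSE]),
                           nf, ctl_quick, refine_above = threshold - 14,
                           maxit_refine = 1200)
      near <- which(!is.na(lr) & lr > threshold - 12)
      for (m in near) {
        gcm <- genotype_column(as.character(mk[m, rownames(ph)]),
                               segregation = config$segregation)
        alt <- fit_genotype_model(ph, gcm, config$grid, control, nf,
                                  covariance = "refit")
        lr[m] <- max(2 * (alt$loglik - nf$loglik), lr[m], 0)
      }
      lr
    }, error = function(e) NULL)
    if (is.null(res)) { failed <- failed + 1L; next }
    max_lr[r] <- max(res, na.rm = TRUE)
    n_pos[r] <- sum(res >= threshold, na.rm = TRUE)
  }
  ok <- !is.na(max_lr)
  structure(list(fpr = mean(max_lr[ok] >= threshold), max_lr = max_lr,
                 n_pos = n_pos, threshold = threshold, df = df,
                 reps = config$reps, failed = failed, H2 = config$H2,
                 n = config$n),
            class = "power_result")
}

#' ROC curve and AUC from paired LR records
#'
#' Sweeps the detection threshold over the pooled LR values of a causal
#' study (true-positive side) and a null study (false-positive side) and
#' integrates the resulting (FPR, power) points by the trapezoidal rule,
#' anchored at (0, 0) and (1, 1).
#'
#' @param causal_lr LR statistics at the causal marker across replicates.
#' @param null_lr per-replicate null detection statistics (e.g. maximum LR
#'   across markers from [fpr_study]).
#' @return A list with `roc` (data frame `threshold`, `fpr`, `power`) and
#'   `auc`.
#' @export
roc_auc <- function(causal_lr, null_lr) {
  causal_lr <- causal_lr[!is.na(causal_lr)]
  null_lr <- null_lr[!is.na(null_lr)]
  if (length(causal_lr) == 0 || length(null_lr) == 0)
    stop("roc_auc: empty LR records")
  thr <- sort(unique(c(causal_lr, null_lr)))
  pts <- data.frame(
    threshold = thr,
    fpr = vapply(thr, function(c) mean(null_lr >= c), numeric(1)),
    power = vapply(thr, function(c) mean(causal_lr >= c), numeric(1)))
  x <- c(1, pts$fpr, 0)
  y <- c(1, pts$power, 0)
  o <- order(x, y)
  x <- x[o]; y <- y[o]
  auc <- sum(diff(x) * (head(y, -1) + y[-1]) / 2)
  list(roc = pts, auc = auc)
}

#' Parameter-recovery study
#'
#' Per replicate, data are simulated at the causal marker and the
#' genotype-specific model is refitted (with the shared covariance
#' re-estimated); the study reports the mean and SD of each parameter
#' estimate per genotype, matched to the truth by genotype label.
#'
#' @param config a [simulation_config] with a causal marker.
#' @param control a [fit_control].
#' @return A list of class `recovery_result`: `estimates` (reps x 12 x J
#'   array), `mean`, `sd`, `truth` (12 x J matrices), `failed`.
#' @export
recovery_study <- function(config, control = fit_control()) {
  if (is.na(config$causal)) stop("recovery_study: config has no causal marker")
  J <- length(config$params)
  labs <- names(config$params)
  sad <- calibrate_noise(config$params, config$freqs, config$sad_shape,
                         config$H2, config$grid)
  est <- array(NA_real_, c(config$reps, 12, J),
               dimnames = list(NULL, .nge_names, labs))
  failed <- 0L
  for (r in seq_len(config$reps)) {
    sr <- derive_seed(config$seed, 6000000 + r)
    cfg_r <- config
    cfg_r$M <- 1
    cfg_r$causal <- 1
    mk <- simulate_markers(cfg_r, seed = sr)
    ok <- tryCatch({
      ph <- simulate_phenotypes(cfg_r, mk, sad = sad,
                                seed = derive_seed(sr, 1))
      gc <- genotype_column(as.character(mk[1, rownames(ph)]),
                            segregation = config$segregation)
      nf <- fit_null(ph, config$grid, control)
      alt <- fit_genotype_model(ph, gc, config$grid, control, nf,
                                covariance = "refit")
      for (j in seq_len(J)) {
        lab <- match(labs[j], alt$labels)
        if (!is.na(lab)) est[r, , j] <- as.numeric(alt$params[[lab]])
      }
      TRUE
    }, error = function(e) FALSE)
    if (!ok) failed <- failed + 1L
  }
  truth <- vapply(config$params, as.numeric, numeric(12))
  rownames(truth) <- .nge_names
  structure(list(estimates = est,
                 mean = apply(est, c(2, 3), mean, na.rm = TRUE),
                 sd = apply(est, c(2, 3), sd, na.rm = TRUE),
                 truth = truth, failed = failed),
            class = "recovery_result")
}
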