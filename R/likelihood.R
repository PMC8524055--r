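#' Bivariate longitudinal trait matrix
#'
#' Stacked phenotype layout used throughout: each row is one sample, the
#' first `T` columns are trait 1 (height) at years `1..T`, the last `T`
#' columns are trait 2 (diameter) at years `1..T`.
#'
#' @param values numeric `n x 2T` matrix.
#' @param sample_ids character vector of length `n` (unique).
#' @return An object of class `trait_matrix` (a matrix with `sample_ids`
#'   rownames and attribute `T`).
#' @export
trait_matrix <- function(values, sample_ids = NULL) {
  values <- as.matrix(values)
  if (ncol(values) %% 2 != 0)
    stop("trait_matrix: need an even number of columns (2 traits x T)")
  if (nrow(values) < 2) stop("trait_matrix: need at least 2 samples")
  if (any(!is.finite(values)))
    stop("trait_matrix: non-finite entries are not allowed")
  if (is.null(sample_ids)) sample_ids <- rownames(values)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  if (anyDuplicated(sample_ids)) stop("trait_matrix: duplicate sample ids")
  rownames(values) <- as.character(sample_ids)
  Tn <- ncol(values) %/% 2
  colnames(values) <- c(paste0("height_", seq_len(Tn)),
                        paste0("diameter_", seq_len(Tn)))
  attr(values, "T") <- Tn
  class(values) <- c("trait_matrix", class(values))
  values
}

tm_T <- function(pheno) {
  Tn <- attr(pheno, "T")
  if (is.null(Tn)) ncol(pheno) %/% 2 else Tn
}

#' Marker genotype column
#'
#' @param codes genotype codes per sample (character/factor; `NA` =
#'   missing).  Testcross markers segregate into two classes (1:1),
#'   intercross markers into three (1:2:1).
#' @param segregation `"testcross"` or `"intercross"`.
#' @param priors optional prior class probabilities used for samples with
#'   missing genotypes; defaults to the segregation ratio.
#' @return An object of class `genotype_column`.
#' @export
genotype_column <- function(codes, segregation = c("testcross", "intercross"),
                            priors = NULL) {
  segregation <- match.arg(segregation)
  codes <- as.character(codes)
  labels <- sort(unique(codes[!is.na(codes)]), method = "radix")
  J <- length(labels)
  if (J < 1) stop("genotype_column: no observed genotypes")
  if (J > 3) stop("genotype_column: more than 3 genotype classes")
  if (is.null(priors)) {
    priors <- if (segregation == "testcross") rep(1 / J, J)
              else if (J == 3) c(0.25, 0.5, 0.25) else rep(1 / J, J)
  }
  priors <- priors / sum(priors)
  if (length(priors) != J)
    stop("genotype_column: priors length must match class count")
  structure(list(codes = codes, labels = labels, J = J,
                 segregation = segregation, priors = priors),
            class = "genotype_column")
}

as_genotype_column <- function(x, segregation = "testcross") {
  if (inherits(x, "genotype_column")) return(x)
  genotype_column(x, segregation = segregation)
}

#' Multivariate normal log-density
#'
#' Exact Gaussian log-density via the lower Cholesky factor of the
#' covariance (no explicit inverse).
#'
#' @param y numeric vector of length `d`, or an `n x d` matrix of rows.
#' @param mu mean vector of length `d`.
#' @param sigma `d x d` positive-definite covariance.
#' @return Scalar log-density, or a vector of per-row log-densities.
#' @export
mvn_loglik <- function(y, mu, sigma) {
  L <- t(chol(sigma))   # stops with a factorization error if not PD
  d <- length(mu)
  logdet <- 2 * sum(log(diag(L)))
  if (is.matrix(y)) {
    r <- t(y) - mu
    z <- forwardsolve(L, r)
    -0.5 * (d * log(2 * pi) + logdet + colSums(z^2))
  } else {
    z <- forwardsolve(L, y - mu)
    -0.5 * (d * log(2 * pi) + logdet + sum(z^2))
  }
}

#' Fitting controls for the likelihood machinery
#'
#' @param step RK4 solver step (years).
#' @param init_eps juvenile-phase initial value for both traits.
#' @param max_iter maximum EM / coordinate-ascent iterations.
#' @param tol relative log-likelihood convergence tolerance.
#' @param nm_maxit Nelder-Mead evaluation budget for cold curve fits.
#' @param nm_maxit_warm budget for warm-started refinements.
#' @param nm_reltol Nelder-Mead relative tolerance.
#' @param sad_maxit Nelder-Mead budget for the 5-parameter SAD step.
#' @param restarts perturbed restarts for the initial curve fit.
#' @param seed RNG seed for restart perturbations.
#' @return A list of class `fit_control`.
#' @export
fit_control <- function(step = 0.05, init_eps = 0.01, max_iter = 200,
                        tol = 1e-6, nm_maxit = 2000, nm_maxit_warm = 600,
                        nm_reltol = 1e-8, sad_maxit = 500, restarts = 2,
                        seed = 1) {
  structure(list(step = step, init_eps = init_eps, max_iter = max_iter,
                 tol = tol, nm_maxit = nm_maxit,
                 nm_maxit_warm = nm_maxit_warm, nm_reltol = nm_reltol,
                 sad_maxit = sad_maxit, restarts = restarts, seed = seed),
            class = "fit_control")
}

# moment-based SAD starting values from a residual matrix (n x 2T)
sad_init_from_residuals <- function(R, T) {
  R1 <- R[, seq_len(T), drop = FALSE]
  R2 <- R[, T + seq_len(T), drop = FALSE]
  lag1 <- function(M) {
    a <- as.numeric(M[, -ncol(M)])
    b <- as.numeric(M[, -1])
    s <- suppressWarnings(cor(a, b))
    if (!is.finite(s)) 0 else max(min(s, 0.95), -0.95)
  }
  phi1 <- lag1(R1); phi2 <- lag1(R2)
  innov <- function(M, phi) {
    e <- M[, -1, drop = FALSE] - phi * M[, -ncol(M), drop = FALSE]
    cbind(M[, 1], e)
  }
  e1 <- innov(R1, phi1); e2 <- innov(R2, phi2)
  g1 <- max(sd(as.numeric(e1)), 1e-4)
  g2 <- max(sd(as.numeric(e2)), 1e-4)
  rho <- suppressWarnings(cor(as.numeric(e1), as.numeric(e2)))
  if (!is.finite(rho)) rho <- 0
  sad_params(phi1, phi2, g1, g2, max(min(rho, 0.95), -0.95))
}

# observed-data log-likelihood from a residual scatter matrix
loglik_from_scatter <- function(sad, S, n, T) {
  -cpp_sad_objective(sad_transform(sad), S, n, as.integer(T))
}

#' Evaluate the model log-likelihood at given parameters
#'
#' Sums the bivariate longitudinal Gaussian log-density over samples, with
#' per-sample means taken from the genotype-specific biphasic curves (or a
#' single shared curve when `geno` is `NULL`).
#'
#' @param pheno a [trait_matrix].
#' @param params an [nge_params] object, or a named list of them (one per
#'   genotype label).
#' @param sad an [sad_params] object.
#' @param grid a [time_grid].
#' @param geno optional [genotype_column]; samples with missing codes
#'   contribute a prior-weighted mixture density.
#' @param init_eps juvenile-phase initial value.
#' @return Scalar log-likelihood.
#' @export
eval_loglik <- function(pheno, params, sad, grid, geno = NULL,
                        init_eps = 0.01) {
  grid <- as_time_grid(grid)
  Tn <- tm_T(pheno)
  sigma <- build_covariance(sad, Tn)
  if (is.null(geno)) {
    p <- if (is.list(params)) params[[1]] else params
    mu <- nge_mu_vec(as_nge_params(p), grid, init_eps)
    return(sum(mvn_loglik(unclass(pheno), mu, sigma)))
  }
  geno <- as_genotype_column(geno)
  if (!is.list(params)) params <- list(params)
  logf <- sample_logdens(pheno, params, sigma, grid, geno, init_eps)
  obs <- !is.na(geno$codes)
  ll <- 0
  if (any(obs)) {
    jidx <- match(geno$codes[obs], geno$labels)
    ll <- ll + sum(logf[cbind(which(obs), jidx)])
  }
  if (any(!obs)) {
    lp <- sweep(logf[!obs, , drop = FALSE], 2, log(geno$priors), "+")
    ll <- ll + sum(apply(lp, 1, logsumexp))
  }
  ll
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# n x J matrix of per-sample per-genotype log-densities
sample_logdens <- function(pheno, params_list, sigma, grid, geno,
                           init_eps) {
  Y <- unclass(pheno)
  J <- length(params_list)
  out <- matrix(NA_real_, nrow(Y), J)
  for (j in seq_len(J)) {
    mu <- nge_mu_vec(as_nge_params(params_list[[j]]), grid, init_eps)
    out[, j] <- mvn_loglik(Y, mu, sigma)
  }
  out
}

new_model_fit <- function(params, sad, loglik, J, trace, iterations,
                          converged, grid, counts = NULL, posteriors = NULL,
                          labels = NULL) {
  structure(list(params = params, sad = sad, loglik = loglik, J = J,
                 n_params = 12 * J + 5, trace = trace,
                 iterations = iterations, converged = converged,
                 grid = grid, counts = counts, posteriors = posteriors,
                 labels = labels),
            class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("Biphasic growth model fit: J = %d genotype class(es), %d parameters\n",
              x$J, x$n_params))
  cat(sprintf("log-likelihood: %.4f  (%d iterations, converged: %s)\n",
              x$loglik, x$iterations, x$converged))
  invisible(x)
}

#' Fit the no-QTL (null) model
#'
#' One shared biphasic mean curve (12 parameters) plus the shared SAD(1)
#' covariance (5 parameters), maximized by coordinate ascent: the curve
#' parameters are refined by Nelder-Mead against the sample mean trajectory
#' weighted by the current covariance, then the SAD parameters are refined
#' by Nelder-Mead on the profiled Gaussian likelihood of the residual
#' scatter, until the log-likelihood stabilizes.
#'
#' @param pheno a [trait_matrix].
#' @param grid a [time_grid].
#' @param control a [fit_control].
#' @param start optional [nge_params] starting values.
#' @return A `model_fit` with a single parameter set.
#' @export
fit_null <- function(pheno, grid = time_grid(tm_T(pheno)),
                     control = fit_control(), start = NULL) {
  grid <- as_time_grid(grid)
  Y <- unclass(pheno)
  n <- nrow(Y); Tn <- tm_T(pheno)
  ybar <- colMeans(Y)
  idx <- matrix(1:12, ncol = 1)
  th0 <- if (is.null(start))
    nge_guess(grid$times, ybar[seq_len(Tn)], ybar[Tn + seq_len(Tn)])
  else as_nge_params(start)
  # stage 1: unweighted curve fit to the mean trajectory (multi-start)
  f0 <- fit_curves_ms(cpp_nge_transform(as.numeric(th0)), idx,
                      matrix(ybar, ncol = 1), w = 1, L = NULL, grid = grid,
                      eps = control$init_eps, restarts = control$restarts,
                      maxit = control$nm_maxit, reltol = control$nm_reltol,
                      rng_seed = control$seed, polish = 1)
  tpar <- f0$par
  mu <- cpp_nge_mu(cpp_nge_untransform(tpar), grid$times, grid$step,
                   control$init_eps)
  Rm <- sweep(Y, 2, mu)
  sad <- sad_init_from_residuals(Rm, Tn)
  S <- crossprod(Rm)
  sadfit <- cpp_fit_sad(sad_transform(sad), S, n, Tn, control$sad_maxit,
                        control$nm_reltol)
  ll <- -sadfit$value
  trace <- ll
  conv <- FALSE
  it <- 0
  while (it < control$max_iter) {
    it <- it + 1
    sad <- sad_untransform(sadfit$par)
    sigma <- build_covariance(sad, Tn)
    Lc <- t(chol(sigma))
    cf <- fit_curves_ms(tpar, idx, matrix(ybar, ncol = 1), w = n, L = Lc,
                        grid = grid, eps = control$init_eps, restarts = 0,
                        maxit = control$nm_maxit_warm,
                        reltol = control$nm_reltol,
                        init_step = if (it == 1) 0.1 else 0.03)
    tpar <- cf$par
    mu <- cpp_nge_mu(cpp_nge_untransform(tpar), grid$times, grid$step,
                     control$init_eps)
    Rm <- sweep(Y, 2, mu)
    S <- crossprod(Rm)
    sadfit <- cpp_fit_sad(sadfit$par, S, n, Tn, control$sad_maxit,
                          control$nm_reltol)
    ll_new <- -sadfit$value
    trace <- c(trace, ll_new)
    if (abs(ll_new - ll) < control$tol * (abs(ll) + 1)) {
      conv <- TRUE
      ll <- ll_new
      break
    }
    ll <- ll_new
  }
  sad <- sad_untransform(sadfit$par)
  params <- list(null = validate_nge_params(cpp_nge_untransform(tpar)))
  new_model_fit(params, sad, ll, J = 1L, trace = trace, iterations = it,
                converged = conv, grid = grid, counts = n,
                labels = "null")
}

#' Genotype responsibilities
#'
#' E-step of the mixture model: samples with observed genotypes get one-hot
#' rows; samples with missing genotypes get prior-weighted normalized
#' densities under the current genotype-specific fits (computed with
#' log-sum-exp for numerical safety).
#'
#' @param pheno a [trait_matrix].
#' @param geno a [genotype_column].
#' @param fit a `model_fit` with `J` genotype parameter sets.
#' @return An `n x J` responsibility matrix whose rows sum to 1.
#' @export
genotype_posteriors <- function(pheno, geno, fit) {
  geno <- as_genotype_column(geno)
  if (fit$J != geno$J)
    stop("genotype_posteriors: fit has ", fit$J,
         " parameter sets but the marker has ", geno$J, " classes")
  n <- nrow(pheno)
  W <- matrix(0, n, geno$J)
  obs <- !is.na(geno$codes)
  W[cbind(which(obs), match(geno$codes[obs], geno$labels))] <- 1
  if (any(!obs)) {
    sigma <- build_covariance(fit$sad, tm_T(pheno))
    logf <- sample_logdens(pheno, fit$params, sigma, fit$grid, geno,
                           init_eps = 0.01)
    lp <- sweep(logf[!obs, , drop = FALSE], 2, log(geno$priors), "+")
    m <- apply(lp, 1, max)
    if (any(!is.finite(m)))
      stop("genotype_posteriors: numerical underflow in all densities")
    wm <- exp(lp - m)
    W[!obs, ] <- wm / rowSums(wm)
  }
  colnames(W) <- geno$labels
  W
}

# shared machinery for genotype-specific fits, optionally with parameter
# blocks constrained equal across genotypes (see sub_hypothesis_test).
# Returns a model_fit.
fit_genotype_model <- function(pheno, geno, grid, control, null_fit,
                               covariance = c("refit", "fixed"),
                               shared_idx = integer(0)) {
  covariance <- match.arg(covariance)
  grid <- as_time_grid(grid)
  geno <- as_genotype_column(geno)
  Y <- unclass(pheno)
  n <- nrow(Y); Tn <- tm_T(pheno)
  if (length(geno$codes) != n)
    stop("genotype codes and phenotype rows do not align")
  J <- geno$J
  if (J == 1) return(null_fit)
  cnt <- table(factor(geno$codes, levels = geno$labels))
  if (any(cnt < 2))
    stop("degenerate genotype class (fewer than 2 members): ",
         paste(geno$labels[cnt < 2], collapse = ", "))
  # flat parameter vector: 12 entries for genotype 1; free (non-shared)
  # entries appended for genotypes 2..J
  free <- setdiff(1:12, shared_idx)
  idx <- matrix(0L, 12, J)
  idx[, 1] <- 1:12
  nxt <- 13L
  for (j in seq_len(J)[-1]) {
    idx[shared_idx, j] <- shared_idx
    if (length(free)) {
      idx[free, j] <- seq.int(nxt, nxt + length(free) - 1L)
      nxt <- nxt + length(free)
    }
  }
  th_null <- as.numeric(null_fit$params[[1]])
  tnull <- cpp_nge_transform(th_null)
  tpar <- c(tnull, rep(tnull[free], J - 1))
  sad_t <- sad_transform(null_fit$sad)
  mixture <- anyNA(geno$codes)
  W <- matrix(0, n, J)
  obs <- !is.na(geno$codes)
  W[cbind(which(obs), match(geno$codes[obs], geno$labels))] <- 1
  if (mixture) W[!obs, ] <- matrix(geno$priors, sum(!obs), J, byrow = TRUE)
  ll <- -Inf
  trace <- numeric(0)
  conv <- FALSE
  it <- 0
  sep <- length(shared_idx) == 0   # genotypes decouple given Sigma
  repeat {
    it <- it + 1
    sad <- sad_untransform(sad_t)
    sigma <- build_covariance(sad, Tn)
    Lc <- t(chol(sigma))
    nj <- colSums(W)
    ybar <- sweep(crossprod(Y, W), 2, nj, "/")   # 2T x J
    # M-step, curve parameters
    warm_step <- if (it == 1) 0.1 else 0.03
    box <- nge_box(ybar)
    tpar <- clamp_tpar(tpar, idx, box)
    if (sep) {
      for (j in seq_len(J)) {
        cf <- cpp_fit_curves(tpar[idx[, j]], matrix(0:11, ncol = 1),
                             ybar[, j, drop = FALSE], nj[j], Lc,
                             grid$times, grid$step, control$init_eps,
                             control$nm_maxit_warm, control$nm_reltol,
                             warm_step, box$lo, box$hi)
        tpar[idx[, j]] <- cf$par
      }
    } else {
      cf <- cpp_fit_curves(tpar, idx - 1L, ybar, nj, Lc, grid$times,
                           grid$step, control$init_eps,
                           control$nm_maxit_warm, control$nm_reltol,
                           warm_step, box$lo, box$hi)
      tpar <- cf$par
    }
    mus <- vapply(seq_len(J), function(j)
      cpp_nge_mu(cpp_nge_untransform(tpar[idx[, j]]), grid$times,
                 grid$step, control$init_eps), numeric(2 * Tn))
    S <- matrix(0, 2 * Tn, 2 * Tn)
    for (j in seq_len(J)) {
      Rj <- sweep(Y, 2, mus[, j])
      S <- S + crossprod(Rj, W[, j] * Rj)
    }
    # M-step, shared covariance
    if (covariance == "refit") {
      sadfit <- cpp_fit_sad(sad_t, S, n, Tn, control$sad_maxit,
                            control$nm_reltol)
      sad_t <- sadfit$par
      sad <- sad_untransform(sad_t)
      sigma <- build_covariance(sad, Tn)
    }
    # observed-data log-likelihood
    if (!mixture) {
      ll_new <- loglik_from_scatter(sad, S, n, Tn)
    } else {
      logf <- vapply(seq_len(J), function(j)
        mvn_loglik(Y, mus[, j], sigma), numeric(n))
      lobs <- numeric(n)
      jidx <- match(geno$codes[obs], geno$labels)
      lobs[obs] <- logf[cbind(which(obs), jidx)]
      if (any(!obs)) {
        lp <- sweep(logf[!obs, , drop = FALSE], 2, log(geno$priors), "+")
        lobs[!obs] <- apply(lp, 1, logsumexp)
      }
      ll_new <- sum(lobs)
    }
    trace <- c(trace, ll_new)
    done <- is.finite(ll) &&
      abs(ll_new - ll) < control$tol * (abs(ll) + 1)
    # without mixture and with fixed covariance a single pass maximizes
    no_more <- !mixture && covariance == "fixed"
    ll <- ll_new
    if (done || no_more || it >= control$max_iter) {
      conv <- done || no_more
      break
    }
    # E-step for the next round
    if (mixture) {
      lp <- vapply(seq_len(J), function(j)
        mvn_loglik(Y, mus[, j], sigma), numeric(n))
      lpm <- sweep(lp[!obs, , drop = FALSE], 2, log(geno$priors), "+")
      m <- apply(lpm, 1, max)
      wm <- exp(lpm - m)
      W[!obs, ] <- wm / rowSums(wm)
    }
  }
  params <- lapply(seq_len(J), function(j)
    validate_nge_params(cpp_nge_untransform(tpar[idx[, j]])))
  names(params) <- geno$labels
  new_model_fit(params, sad_untransform(sad_t), ll, J = J, trace = trace,
                iterations = it, converged = conv, grid = grid,
                counts = as.numeric(cnt), posteriors = W,
                labels = geno$labels)
}

#' Fit the genotype-specific (QTL) model
#'
#' One biphasic parameter set per genotype class with the SAD(1) covariance
#' shared across classes, maximized by EM: responsibilities for samples
#' with missing genotypes (E-step) and Nelder-Mead refinements of the
#' genotype curves and the shared covariance on the responsibility-weighted
#' likelihood (M-step).  With fully observed genotypes this reduces to
#' grouped maximization.  All genotype parameter sets are seeded from a
#' null fit, so the alternative never falls below the null likelihood.
#'
#' @param pheno a [trait_matrix].
#' @param geno a [genotype_column] (or a plain code vector).
#' @param grid a [time_grid].
#' @param control a [fit_control].
#' @param null_fit optional [fit_null] result used for seeding (computed
#'   when absent).
#' @param covariance `"refit"` re-estimates the shared SAD parameters under
#'   the genotype-specific model; `"fixed"` keeps the null-fit covariance
#'   (the genome-scan convention, in which the covariance parameters are
#'   held consistent between the two models).
#' @return A `model_fit` with `J` parameter sets.
#' @export
fit_alternative <- function(pheno, geno, grid = time_grid(tm_T(pheno)),
                            control = fit_control(), null_fit = NULL,
                            covariance = c("refit", "fixed")) {
  covariance <- match.arg(covariance)
  geno <- as_genotype_column(geno)
  if (is.null(null_fit))
    null_fit <- fit_null(pheno, grid, control)
  fit_genotype_model(pheno, geno, grid, control, null_fit,
                     covariance = covariance)
}
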