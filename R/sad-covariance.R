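#' First-order structured antedependence (SAD(1)) parameters
#'
#' Residuals of each trait follow `e_k(t) = phi_k e_k(t-1) + eps_k(t)` on
#' the annual grid with innovation SD `gamma_k`; the innovations of the two
#' traits at the same time point are correlated with coefficient `rho`.
#' Five parameters structure the full `2T x 2T` longitudinal covariance.
#'
#' @param phi_1,phi_2 antedependence coefficients, `|phi| < 1`.
#' @param gamma_1,gamma_2 innovation standard deviations (trait units), > 0.
#' @param rho cross-trait innovation correlation, `|rho| < 1`.
#' @return An object of class `sad_params` (named numeric vector).
#' @export
sad_params <- function(phi_1, phi_2, gamma_1, gamma_2, rho) {
  x <- c(phi_1 = phi_1, phi_2 = phi_2, gamma_1 = gamma_1,
         gamma_2 = gamma_2, rho = rho)
  validate_sad_params(x)
}

validate_sad_params <- function(x) {
  x <- as.numeric(x)[1:5]
  names(x) <- c("phi_1", "phi_2", "gamma_1", "gamma_2", "rho")
  if (any(!is.finite(x))) stop("sad_params: parameters must be finite")
  if (any(abs(x[c("phi_1", "phi_2")]) >= 1))
    stop("sad_params: |phi| must be < 1")
  if (any(x[c("gamma_1", "gamma_2")] <= 0))
    stop("sad_params: gamma must be > 0")
  if (abs(x["rho"]) >= 1) stop("sad_params: |rho| must be < 1")
  class(x) <- "sad_params"
  x
}

as_sad_params <- function(x) {
  if (inherits(x, "sad_params")) return(x)
  validate_sad_params(x)
}

sad_transform <- function(x) {
  x <- as.numeric(x)
  c(atanh(x[1]), atanh(x[2]), log(x[3]), log(x[4]), atanh(x[5]))
}

sad_untransform <- function(t) {
  validate_sad_params(c(tanh(t[1]), tanh(t[2]), exp(t[3]), exp(t[4]),
                        tanh(t[5])))
}

#' Build the SAD(1) residual covariance matrix
#'
#' Assembles the `2T x 2T` covariance in block layout
#' `[[Sigma_1, Sigma_12], [Sigma_12', Sigma_2]]` with trait-1 rows first and
#' time indices `1..T`.  Within-trait entries use
#' `Var_k(t) = gamma_k^2 (1 - phi_k^{2t}) / (1 - phi_k^2)` and
#' `Cov_k(t1, t2) = phi_k^{t2 - t1} Var_k(t1)` (`t2 > t1`); cross-trait
#' entries use
#' `(phi_2^{t2-t1} - phi_1^{t1} phi_2^{t2}) / (1 - phi_1 phi_2) rho
#' gamma_1 gamma_2` for trait 1 at `t1 <= t2`, its `t2 -> t1` limit at equal
#' times, and the phi-swapped mirror for the reversed trait order, which
#' together are exactly the covariance of the generating antedependence
#' process and hence symmetric and positive definite for admissible
#' parameters.
#'
#' @param params an [sad_params] object.
#' @param T number of time points per trait.
#' @return A symmetric `2T x 2T` matrix with attribute
#'   `"positive_definite"` (logical, from a Cholesky check).
#' @export
build_covariance <- function(params, T) {
  params <- as_sad_params(params)
  if (T < 1) stop("build_covariance: T must be >= 1")
  S <- cpp_sad_cov(params["phi_1"], params["phi_2"], params["gamma_1"],
                   params["gamma_2"], params["rho"], as.integer(T))
  attr(S, "positive_definite") <- is_positive_definite(S)$pd
  S
}

#' Cholesky-based positive-definiteness check
#'
#' @param m a square symmetric matrix.
#' @return A list with `pd` (logical) and `min_eigenvalue` (smallest
#'   eigenvalue, computed only when the Cholesky factorization fails,
#'   otherwise `NA`).
#' @export
is_positive_definite <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop("is_positive_definite: need a square matrix")
  ok <- tryCatch({ chol(m); TRUE }, error = function(e) FALSE)
  list(pd = ok,
       min_eigenvalue = if (ok) NA_real_ else
         min(eigen(m, symmetric = TRUE, only.values = TRUE)$values))
}
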