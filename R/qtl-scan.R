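#' Likelihood-ratio test between nested model fits
#'
#' `LR = 2 (logL1 - logL0)` referred to a chi-square distribution whose
#' degrees of freedom equal the difference in parameter counts
#' (`12 (J - 1)` for the overall genotype test).
#'
#' @param null_fit,alt_fit `model_fit` objects on the same data, the
#'   alternative nesting the null.
#' @param tol negative-LR tolerance attributed to optimizer noise; a
#'   negative LR within `tol` is clamped to zero with a warning, a larger
#'   deficit is an error (the alternative needs refitting).
#' @return A list with `LR`, `df`, `p`.
#' @export
lr_test <- function(null_fit, alt_fit, tol = 1e-6) {
  lr <- 2 * (alt_fit$loglik - null_fit$loglik)
  if (lr < -tol)
    stop(sprintf(
      "lr_test: alternative log-likelihood below null by %.3g; refit required",
      -lr / 2))
  if (lr < 0) {
    warning("lr_test: small negative LR clamped to 0 (optimizer noise)")
    lr <- 0
  }
  df <- alt_fit$n_params - null_fit$n_params
  if (df <= 0) df <- 12 * (alt_fit$J - 1)
  p <- if (df == 0) 1 else pchisq(lr, df = df, lower.tail = FALSE)
  if (lr == 0) p <- 1
  list(LR = lr, df = df, p = p)
}

#' Multiple-testing adjustment for a marker scan
#'
#' @param p_raw vector of raw p-values.
#' @param M number of tests (defaults to `length(p_raw)`); the Bonferroni
#'   per-test level is `alpha / M`.
#' @param alpha family-wise / FDR level.
#' @return A list with `bonferroni_threshold`, `p_fdr`
#'   (Benjamini-Hochberg step-up adjusted), `significant_bonferroni`,
#'   `significant_fdr`.
#' @export
adjust_pvalues <- function(p_raw, M = length(p_raw), alpha = 0.05) {
  if (length(p_raw) == 0) stop("adjust_pvalues: empty p-value list")
  if (any(p_raw < 0 | p_raw > 1, na.rm = TRUE))
    stop("adjust_pvalues: p-values must lie in [0, 1]")
  thr <- alpha / M
  p_fdr <- p.adjust(p_raw, method = "BH", n = M)
  list(bonferroni_threshold = thr,
       p_fdr = p_fdr,
       significant_bonferroni = !is.na(p_raw) & p_raw <= thr,
       significant_fdr = !is.na(p_fdr) & p_fdr <= alpha)
}

#' Genome scan for multiphasic-growth QTLs
#'
#' Fits the null model once, then per marker fits the genotype-specific
#' model and computes the likelihood-ratio statistic, raw chi-square
#' p-value, Benjamini-Hochberg adjusted p-value and Bonferroni flag.
#' Markers with fewer than two observed genotype classes, or a class with
#' fewer than two members, are skipped with a reason code.
#'
#' @param pheno a [trait_matrix].
#' @param markers a marker table as returned by [read_markers] or
#'   [simulate_markers]: a data frame with columns `marker_id`, `chrom`,
#'   `pos_bp`, `seg_type`, then one genotype-code column per sample.
#' @param grid a [time_grid].
#' @param control a [fit_control].
#' @param alpha significance level for the corrections.
#' @param covariance per-marker covariance treatment: `"refit"` (default)
#'   re-estimates the shared SAD parameters under the genotype-specific
#'   model — the calibrated scan statistic — while `"fixed"` holds them at
#'   the null estimate, which is considerably cheaper for large panels
#'   (see [fit_alternative]).
#' @param threshold optional p-value threshold overriding the Bonferroni
#'   default `alpha / M`.
#' @param null_fit optional precomputed null fit.
#' @return A data frame of class `scan_result`, one row per marker, sorted
#'   by genome position: `marker_id`, `chrom`, `pos_bp`, `seg_type`, `J`,
#'   `LR`, `df`, `p_raw`, `p_fdr`, `significant`, `skipped`, `reason`;
#'   the null fit is attached as attribute `null_fit`.
#' @export
qtl_scan <- function(pheno, markers, grid = time_grid(tm_T(pheno)),
                     control = fit_control(), alpha = 0.05,
                     covariance = c("refit", "fixed"), threshold = NULL,
                     null_fit = NULL) {
  covariance <- match.arg(covariance)
  grid <- as_time_grid(grid)
  meta_cols <- c("marker_id", "chrom", "pos_bp", "seg_type")
  if (!all(meta_cols %in% names(markers)))
    stop("qtl_scan: marker table must have columns ",
         paste(meta_cols, collapse = ", "))
  samp_cols <- setdiff(names(markers), meta_cols)
  if (!all(rownames(pheno) %in% samp_cols))
    stop("qtl_scan: sample ids in phenotypes and markers do not align")
  G <- as.matrix(markers[, rownames(pheno), drop = FALSE])
  if (is.null(null_fit)) null_fit <- fit_null(pheno, grid, control)
  M <- nrow(markers)
  res <- data.frame(marker_id = markers$marker_id, chrom = markers$chrom,
                    pos_bp = markers$pos_bp, seg_type = markers$seg_type,
                    J = NA_integer_, LR = NA_real_, df = NA_integer_,
                    p_raw = NA_real_, p_fdr = NA_real_,
                    significant = FALSE, skipped = FALSE,
                    reason = "", stringsAsFactors = FALSE)
  for (m in seq_len(M)) {
    codes <- G[m, ]
    labs <- unique(codes[!is.na(codes)])
    if (length(labs) < 2) {
      res$skipped[m] <- TRUE
      res$reason[m] <- "single_genotype_class"
      next
    }
    cnt <- table(codes)
    if (any(cnt < 2)) {
      res$skipped[m] <- TRUE
      res$reason[m] <- "class_below_2"
      next
    }
    gc <- genotype_column(codes, segregation = as.character(
      markers$seg_type[m]))
    alt <- fit_genotype_model(pheno, gc, grid, control, null_fit,
                              covariance = covariance)
    lt <- tryCatch(lr_test(null_fit, alt),
                   error = function(e) NULL,
                   warning = function(w) list(LR = 0,
                                              df = 12 * (gc$J - 1), p = 1))
    if (is.null(lt)) {
      # refit once from scratch before giving up on a negative LR
      alt <- fit_genotype_model(pheno, gc, grid, control, null_fit,
                                covariance = covariance)
      lt <- tryCatch(lr_test(null_fit, alt), error = function(e)
        list(LR = 0, df = 12 * (gc$J - 1), p = 1))
    }
    res$J[m] <- gc$J
    res$LR[m] <- lt$LR
    res$df[m] <- lt$df
    res$p_raw[m] <- lt$p
  }
  tested <- !res$skipped
  if (any(tested)) {
    adj <- adjust_pvalues(res$p_raw[tested], M = sum(tested), alpha = alpha)
    res$p_fdr[tested] <- adj$p_fdr
    thr <- if (is.null(threshold)) adj$bonferroni_threshold else threshold
    res$significant[tested] <- res$p_raw[tested] <= thr
  }
  res <- res[order(res$chrom, res$pos_bp), ]
  rownames(res) <- NULL
  attr(res, "null_fit") <- null_fit
  attr(res, "alpha") <- alpha
  class(res) <- c("scan_result", "data.frame")
  res
}

# named parameter blocks for phase-specific sub-hypotheses
.block_index <- function(block) {
  blocks <- list(
    phase1 = 1:6,
    phase2_H = 7:9,
    phase2_D = 10:12,
    full = 1:12
  )
  if (block %in% names(blocks)) return(blocks[[block]])
  i <- match(block, .nge_names)
  if (is.na(i))
    stop("unknown block '", block, "'; valid blocks: ",
         paste(c(names(blocks), .nge_names), collapse = ", "))
  i
}

#' Phase-specific sub-hypothesis test
#'
#' Tests whether a named subset of the biphasic parameters differs between
#' genotypes: the constrained model equates the block across genotypes
#' while the remaining parameters stay genotype-specific, and the LR
#' statistic compares it against the full genotype-specific model with
#' `df = block size x (J - 1)`.
#'
#' Blocks: `"phase1"` (the six juvenile-phase parameters), `"phase2_H"` /
#' `"phase2_D"` (the three adult-phase parameters of one trait), `"full"`
#' (all twelve; then the test coincides with the overall QTL test), or any
#' single parameter name such as `"beta_H_from_D"`.
#'
#' @inheritParams fit_alternative
#' @param block block name (see Details).
#' @param alt_fit optional precomputed full alternative fit.
#' @return A list with `LR`, `df`, `p`, `block`, plus the two fits.
#' @export
sub_hypothesis_test <- function(pheno, geno, block,
                                grid = time_grid(tm_T(pheno)),
                                control = fit_control(), null_fit = NULL,
                                alt_fit = NULL,
                                covariance = c("fixed", "refit")) {
  covariance <- match.arg(covariance)
  geno <- as_genotype_column(geno)
  idx <- .block_index(block)
  if (is.null(null_fit)) null_fit <- fit_null(pheno, grid, control)
  if (is.null(alt_fit))
    alt_fit <- fit_genotype_model(pheno, geno, grid, control, null_fit,
                                  covariance = covariance)
  constrained <- fit_genotype_model(pheno, geno, grid, control, null_fit,
                                    covariance = covariance,
                                    shared_idx = idx)
  lr <- 2 * (alt_fit$loglik - constrained$loglik)
  if (lr < 0) lr <- 0
  df <- length(idx) * (geno$J - 1)
  list(LR = lr, df = df,
       p = pchisq(lr, df = df, lower.tail = FALSE),
       block = block, constrained_fit = constrained, alt_fit = alt_fit)
}
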