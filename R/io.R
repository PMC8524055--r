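#' Read a phenotype CSV
#'
#' Expected layout: header `sample_id, height_1..height_T,
#' diameter_1..diameter_T`, one row per sample, all cells numeric.  The
#' number of time points is inferred from the header.  Missing or
#' non-numeric values are rejected with their cell coordinates (the SAD(1)
#' structure is defined on the complete grid; imputation is out of scope).
#'
#' @param path CSV file path.
#' @return A [trait_matrix].
#' @export
read_phenotypes <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                 colClasses = "character")
  if (names(df)[1] != "sample_id")
    stop("read_phenotypes: first column must be sample_id")
  ids <- df$sample_id
  if (anyDuplicated(ids))
    stop("read_phenotypes: duplicate sample ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow(vals), ncol(vals),
                                 dimnames = dimnames(vals)))
  bad <- which(!is.finite(num), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    cells <- apply(head(bad, 10), 1, function(b)
      sprintf("(%s, %s)", ids[b[1]], colnames(vals)[b[2]]))
    stop("read_phenotypes: missing or non-numeric cells: ",
         paste(cells, collapse = ", "))
  }
  Tn <- ncol(num) %/% 2
  expected <- c(paste0("height_", seq_len(Tn)),
                paste0("diameter_", seq_len(Tn)))
  if (!identical(colnames(num), expected))
    stop("read_phenotypes: columns must be height_1..height_T then ",
         "diameter_1..diameter_T")
  trait_matrix(num, sample_ids = ids)
}

#' Write a phenotype CSV
#'
#' @param pheno a [trait_matrix].
#' @param path output path.
#' @export
write_phenotypes <- function(pheno, path) {
  vals <- unclass(pheno)
  # %.17g guarantees an exact double round trip through the text file
  txt <- apply(vals, 2, function(col) sprintf("%.17g", col))
  df <- data.frame(sample_id = rownames(pheno), txt, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a marker TSV
#'
#' Expected layout: tab-separated with columns `marker_id`, `chrom`,
#' `pos_bp`, `seg_type` (`testcross` or `intercross`), then one
#' genotype-code column per sample; missing genotypes are `NA`.  Each
#' marker may carry at most three distinct non-missing codes.
#'
#' @param path TSV file path.
#' @param pheno optional [trait_matrix]; when given, sample ids are
#'   checked for alignment.
#' @return The marker data frame, with an attribute `J` holding the
#'   per-marker count of observed genotype classes.
#' @export
read_markers <- function(path, pheno = NULL) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  meta <- c("marker_id", "chrom", "pos_bp", "seg_type")
  if (!all(meta %in% names(df)))
    stop("read_markers: required columns: ", paste(meta, collapse = ", "))
  if (!all(df$seg_type %in% c("testcross", "intercross")))
    stop("read_markers: seg_type must be testcross or intercross")
  samp <- setdiff(names(df), meta)
  G <- as.matrix(df[, samp, drop = FALSE])
  nlev <- apply(G, 1, function(g) length(unique(g[!is.na(g)])))
  if (any(nlev > 3))
    stop("read_markers: more than 3 genotype codes at marker(s): ",
         paste(df$marker_id[nlev > 3], collapse = ", "))
  if (!is.null(pheno) && !all(rownames(pheno) %in% samp))
    stop("read_markers: sample ids do not align with the phenotypes: ",
         paste(setdiff(rownames(pheno), samp), collapse = ", "))
  attr(df, "J") <- nlev
  df
}

#' Write a marker TSV
#'
#' @param markers a marker data frame.
#' @param path output path.
#' @export
write_markers <- function(markers, path) {
  write.table(markers, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write scan results as a Manhattan-ready TSV
#'
#' Adds a `neg_log10_p_fdr` column to the [qtl_scan] table.
#'
#' @param res a `scan_result`.
#' @param path output path.
#' @export
write_scan_results <- function(res, path) {
  out <- as.data.frame(res)
  out$neg_log10_p_fdr <- -log10(pmax(out$p_fdr, .Machine$double.xmin))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Serialize a model fit as a flat key-value text record
#'
#' Writes every parameter at full precision (`%.17g`), so a read back
#' reproduces the fit exactly.
#'
#' @param fit a `model_fit` from [fit_null] or [fit_alternative].
#' @param path output file.
#' @export
write_model_fit <- function(fit, path) {
  num <- function(x) sprintf("%.17g", x)
  lines <- c(
    paste0("J = ", fit$J),
    paste0("labels = ", paste(fit$labels, collapse = ",")),
    paste0("loglik = ", num(fit$loglik)),
    paste0("n_params = ", fit$n_params),
    paste0("iterations = ", fit$iterations),
    paste0("converged = ", fit$converged)
  )
  for (j in seq_len(fit$J)) {
    p <- fit$params[[j]]
    lines <- c(lines, paste0("param.", fit$labels[j], ".", names(p),
                             " = ", num(as.numeric(p))))
  }
  s <- fit$sad
  lines <- c(lines, paste0("sad.", names(s), " = ", num(as.numeric(s))))
  lines <- c(lines,
             paste0("grid.T = ", length(fit$grid$times)),
             paste0("grid.step = ", num(fit$grid$step)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a model fit written by [write_model_fit]
#'
#' @param path input file.
#' @return A `model_fit` (without posteriors or iteration trace).
#' @export
read_model_fit <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- do.call(rbind, strsplit(lines, " = ", fixed = TRUE))
  vals <- setNames(kv[, 2], kv[, 1])
  J <- as.integer(vals[["J"]])
  labels <- strsplit(vals[["labels"]], ",", fixed = TRUE)[[1]]
  params <- lapply(labels, function(lb)
    validate_nge_params(as.numeric(
      vals[paste0("param.", lb, ".", .nge_names)])))
  names(params) <- labels
  sad <- validate_sad_params(as.numeric(
    vals[paste0("sad.", c("phi_1", "phi_2", "gamma_1", "gamma_2",
                          "rho"))]))
  new_model_fit(params, sad,
                loglik = as.numeric(vals[["loglik"]]), J = J,
                trace = NULL,
                iterations = as.integer(vals[["iterations"]]),
                converged = as.logical(vals[["converged"]]),
                grid = time_grid(T = as.integer(vals[["grid.T"]]),
                                 step = as.numeric(vals[["grid.step"]])),
                labels = labels)
}

#' Read a plain-text run configuration
#'
#' `key = value` lines (or `key: value`); `#` starts a comment.  Unknown
#' keys are rejected; numeric fields are validated.
#'
#' @param path config file path.
#' @return A named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  known <- list(phenotypes = "character", markers = "character",
                out_dir = "character", alpha = "numeric",
                threshold = "numeric", step = "numeric",
                tol = "numeric", restarts = "integer", seed = "integer",
                n = "integer", M = "integer", T = "integer",
                H2 = "numeric", reps = "integer",
                segregation = "character")
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "[=:]", fixed = FALSE)[[1]]
    if (length(kv) < 2)
      stop("read_run_config: cannot parse line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = ":"))
    if (!key %in% names(known))
      stop("read_run_config: unknown key '", key, "'")
    out[[key]] <- switch(known[[key]],
      character = val,
      numeric = {
        x <- suppressWarnings(as.numeric(val))
        if (!is.finite(x)) stop("read_run_config: non-numeric value for ",
                                key)
        x
      },
      integer = {
        x <- suppressWarnings(as.integer(val))
        if (is.na(x)) stop("read_run_config: non-integer value for ", key)
        x
      })
  }
  class(out) <- "run_config"
  out
}
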