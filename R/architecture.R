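#' Time-resolved genetic effect curves
#'
#' Decomposes the genetic effect of a marker on each trait over time, using
#' the standard quantitative-genetics definitions on each curve component
#' (total, juvenile phase, juvenile independent, juvenile interaction,
#' adult phase).  For two genotypes the effect is half the difference of
#' the genotype means; for three genotypes the additive effect is half the
#' difference of the homozygote means and the dominance effect is the
#' heterozygote deviation from the homozygote midpoint.
#'
#' @param params_list named list of 2 or 3 [nge_params] (genotype order is
#'   the label order; for J = 3 the second entry is the heterozygote).
#' @param grid a [time_grid].
#' @param init_eps juvenile-phase initial value.
#' @return A long data frame of class `effect_curves` with columns `time`,
#'   `trait` (`"height"`/`"diameter"`), `component` (`"net"`, `"phase1"`,
#'   `"phase1_independent"`, `"phase1_interaction"`, `"phase2"`), `type`
#'   (`"additive"`/`"dominance"`), `effect`.
#' @export
effect_curves <- function(params_list, grid, init_eps = 0.01) {
  J <- length(params_list)
  if (J < 2 || J > 3)
    stop("effect_curves: need 2 or 3 genotype parameter sets")
  grid <- as_time_grid(grid)
  traj <- lapply(params_list, nge_mean, grid = grid,
                 init = c(init_eps, init_eps))
  comp <- function(tr, trait) {
    if (trait == "height")
      cbind(net = tr$H_total, phase1 = tr$H1,
            phase1_independent = tr$H1_ind,
            phase1_interaction = tr$H1 - tr$H1_ind, phase2 = tr$H2)
    else
      cbind(net = tr$D_total, phase1 = tr$D1,
            phase1_independent = tr$D1_ind,
            phase1_interaction = tr$D1 - tr$D1_ind, phase2 = tr$D2)
  }
  out <- list()
  for (trait in c("height", "diameter")) {
    mats <- lapply(traj, comp, trait = trait)
    effs <- if (J == 2) {
      list(additive = (mats[[1]] - mats[[2]]) / 2)
    } else {
      list(additive = (mats[[1]] - mats[[3]]) / 2,
           dominance = mats[[2]] - (mats[[1]] + mats[[3]]) / 2)
    }
    for (type in names(effs)) {
      E <- effs[[type]]
      for (cn in colnames(E)) {
        out[[length(out) + 1]] <- data.frame(
          time = grid$times, trait = trait, component = cn, type = type,
          effect = E[, cn], stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  class(out) <- c("effect_curves", "data.frame")
  out
}

#' Phenotypic variance explained (PVE) over time
#'
#' `PVE_k(t) = sum_j f_j (mu_jk(t) - mubar_k(t))^2 / Var_k(t)`, the
#' between-genotype variance of the fitted mean curves over the observed
#' phenotypic variance, clipped to `[0, 1]` with a warning when the genetic
#' variance exceeds the phenotypic estimate.
#'
#' @param params_list list of J [nge_params].
#' @param freqs genotype frequencies (summing to 1; typically observed
#'   counts `n_j / n`).
#' @param pheno_var `T x 2` matrix (or data frame) of per-time phenotypic
#'   variances, columns height then diameter.
#' @param grid a [time_grid].
#' @param init_eps juvenile-phase initial value.
#' @return A data frame with columns `time`, `trait`, `pve`.
#' @export
pve_curves <- function(params_list, freqs, pheno_var, grid,
                       init_eps = 0.01) {
  grid <- as_time_grid(grid)
  if (abs(sum(freqs) - 1) > 1e-8)
    stop("pve_curves: frequencies must sum to 1")
  pheno_var <- as.matrix(pheno_var)
  Tn <- length(grid$times)
  if (any(pheno_var <= 0)) stop("pve_curves: variances must be > 0")
  mus <- vapply(params_list, function(p)
    nge_mu_vec(as_nge_params(p), grid, init_eps), numeric(2 * Tn))
  gv <- genetic_variance(mus, freqs)
  pve <- cbind(gv[seq_len(Tn)] / pheno_var[, 1],
               gv[Tn + seq_len(Tn)] / pheno_var[, 2])
  if (any(pve > 1)) {
    warning("pve_curves: genetic variance exceeds the phenotypic ",
            "estimate at some time points; PVE clipped to 1")
    pve[pve > 1] <- 1
  }
  data.frame(time = rep(grid$times, 2),
             trait = rep(c("height", "diameter"), each = Tn),
             pve = c(pve[, 1], pve[, 2]))
}

# between-genotype variance per stacked time point
genetic_variance <- function(mus, freqs) {
  mbar <- as.numeric(mus %*% freqs)
  as.numeric(((mus - mbar)^2) %*% freqs)
}

#' Two-phase clustering of PVE trajectories
#'
#' Agglomerative hierarchical clustering (Euclidean distance, Ward
#' linkage) of the time points, each described by the vector of PVE values
#' across significant SNPs, cut into `n_clusters` groups.  Labels are
#' renumbered so that the cluster containing the first time point is
#' cluster 1.
#'
#' @param pve numeric matrix, SNPs in rows, time points in columns (one
#'   trait).
#' @param n_clusters number of clusters (default 2, juvenile vs adult).
#' @return Integer vector of cluster labels, one per time point.
#' @export
cluster_phases <- function(pve, n_clusters = 2) {
  pve <- as.matrix(pve)
  if (nrow(pve) < 2 || ncol(pve) < 4)
    stop("cluster_phases: need >= 2 SNPs and >= 4 time points")
  if (max(pve) - min(pve) < .Machine$double.eps * 100) {
    warning("cluster_phases: constant PVE matrix; all time points in ",
            "cluster 1")
    return(rep(1L, ncol(pve)))
  }
  hc <- hclust(dist(t(pve), method = "euclidean"), method = "ward.D2")
  raw <- cutree(hc, k = n_clusters)
  # renumber by first appearance so cluster 1 contains time point 1
  map <- match(raw, unique(raw))
  as.integer(map)
}

#' Growth-phase features of a genotype curve
#'
#' Operational curve features per trait: the juvenile phase ends (offset)
#' when its curve first reaches `fraction` of its own asymptote (the
#' coupled-equilibrium value; the independent curve uses its logistic
#' asymptote `K1`); the adult phase starts (onset) when the Gompertz curve
#' reaches `1 - fraction` of `K2` and ends when it reaches `fraction` of
#' `K2` (closed form from the Gompertz inverse, so it may exceed the
#' measurement window); the phase overlap is offset minus onset, floored
#' at zero.  Maximum juvenile growth rates come from the system right-hand
#' side evaluated on the dense solver grid; the maximum adult rate is the
#' analytic Gompertz rate `q K / e` at `t = p / q`.  A juvenile offset not
#' reached within the grid is right-censored at the grid end and flagged.
#'
#' @param params an [nge_params].
#' @param grid a [time_grid].
#' @param fraction asymptote fraction defining onset/offset (default 0.95).
#' @param init_eps juvenile-phase initial value.
#' @return A data frame of class `phase_features` with one row per trait.
#' @export
phase_features <- function(params, grid, fraction = 0.95,
                           init_eps = 0.01) {
  params <- as_nge_params(params)
  grid <- as_time_grid(grid)
  tmax <- max(grid$times)
  dense <- seq(0, tmax, by = grid$step)
  dgrid <- time_grid(times = dense[-1], step = grid$step)
  ph1 <- solve_phase1(params, dgrid, init = rep(init_eps, 2))
  ph1i <- solve_phase1(params, dgrid, init = rep(init_eps, 2),
                       independent = TRUE)
  # coupled-equilibrium asymptotes of the juvenile system
  aH <- params["K_H1"]; aD <- params["K_D1"]
  bH <- params["beta_H_from_D"]; bD <- params["beta_D_from_H"]
  det <- 1 - aH * aD * bH * bD
  Hstar <- as.numeric(aH * (1 + bH * aD) / det)
  Dstar <- as.numeric(aD * (1 + bD * aH) / det)
  t_reach <- function(tt, y, target) {
    i <- which(y >= target)
    if (length(i) == 0) NA_real_ else tt[i[1]]
  }
  rate1 <- function(H, D) {
    p <- as.numeric(params)
    list(H = p[1] * (1 - H / p[2]) * H + p[1] * p[3] * H * D,
         D = p[4] * (1 - D / p[5]) * D + p[4] * p[6] * D * H)
  }
  r <- rate1(ph1$H1, ph1$D1)
  ri <- rate1_indep(params, ph1i$H1, ph1i$D1)
  row_for <- function(trait) {
    if (trait == "height") {
      K1 <- aH; K2 <- params["K_H2"]; p <- params["p_H"]; q <- params["q_H"]
      y <- ph1$H1; yi <- ph1i$H1; astar <- Hstar; rr <- r$H; rri <- ri$H
    } else {
      K1 <- aD; K2 <- params["K_D2"]; p <- params["p_D"]; q <- params["q_D"]
      y <- ph1$D1; yi <- ph1i$D1; astar <- Dstar; rr <- r$D; rri <- ri$D
    }
    off1 <- t_reach(ph1$time, y, fraction * astar)
    off1i <- t_reach(ph1i$time, yi, fraction * K1)
    cens <- is.na(off1)
    if (cens) off1 <- tmax
    if (is.na(off1i)) off1i <- tmax
    onset2 <- as.numeric((p - log(-log(1 - fraction))) / q)
    offset2 <- as.numeric((p - log(-log(fraction))) / q)
    data.frame(
      trait = trait,
      phase1_offset = off1, phase1_offset_censored = cens,
      independent_offset = off1i,
      phase1_asymptote = astar, independent_asymptote = as.numeric(K1),
      interaction_magnitude = astar - as.numeric(K1),
      phase2_onset = onset2, phase2_offset = offset2,
      phase2_duration = offset2 - onset2,
      overlap = max(off1 - onset2, 0),
      max_rate_phase1 = max(rr), max_rate_phase1_time = ph1$time[which.max(rr)],
      max_rate_independent = max(rri),
      max_rate_phase2 = as.numeric(q * K2 / exp(1)),
      max_rate_phase2_time = as.numeric(p / q),
      stringsAsFactors = FALSE)
  }
  out <- rbind(row_for("height"), row_for("diameter"))
  class(out) <- c("phase_features", "data.frame")
  out
}

rate1_indep <- function(params, H, D) {
  p <- as.numeric(params)
  list(H = p[1] * (1 - H / p[2]) * H, D = p[4] * (1 - D / p[5]) * D)
}

#' Write effect or PVE curves as long-format TSV
#'
#' @param x a data frame (e.g. from [effect_curves] or [pve_curves]).
#' @param path output file.
#' @export
write_long_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
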