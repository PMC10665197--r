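#' Configuration for the synthetic hashed-embryo experiment generator
#'
#' Collects every parameter of the simulator into a validated list. The
#' generator draws, per embryo, a total cell yield and a cell-type composition
#' whose between-embryo variability follows a Dirichlet-multinomial law chosen
#' so that each single cell type's marginal count is beta-binomial with mean
#' \eqn{\mu} and intra-class correlation ("litter effect") \eqn{\rho} -- the
#' same law the abundance model fits. Perturbation effects are planted as
#' additive shifts on baseline log-odds before softmax renormalization.
#'
#' @param n_timepoints number of developmental stages simulated.
#' @param n_cell_types number of cell types.
#' @param n_genotypes number of genotypes including the control; genotype 0 is
#'   always the unperturbed control.
#' @param embryos_per_condition replicate embryos per perturbed
#'   genotype-timepoint condition (default 8, matching a heavily replicated
#'   crispant screen).
#' @param control_embryos replicate control embryos per timepoint (default 26,
#'   the pooled stage-matched wild-type group such screens accumulate).
#' @param baseline_logits matrix (timepoint x cell type) of baseline log-odds;
#'   rows are softmaxed into baseline compositions. If `NULL`, a deterministic
#'   geometric abundance ladder spanning roughly two orders of magnitude is
#'   used, giving both common and rare (<1%) types.
#' @param effect_table data.frame with columns `genotype`, `timepoint`,
#'   `cell_type` (integer indices) and `delta` (shift in log-odds); `NULL`
#'   means no planted effects.
#' @param litter_effect beta-binomial overdispersion rho, strictly in (0,1).
#' @param total_cells_mean,total_cells_cv arithmetic mean and coefficient of
#'   variation of the lognormal per-embryo cell yield (floored at 50 cells).
#' @param hash_signal_rate expected hash-oligo count from a cell's own embryo.
#' @param hash_background_rate expected ambient count for every other oligo.
#' @param doublet_fraction fraction of cells carrying two embryos' material.
#' @param n_genes number of genes in the expression simulation.
#' @param centroid_separation distance between cell-type centroids in units of
#'   the within-type standard deviation of log-expression (per gene).
#' @param within_type_sd within-type standard deviation of log-expression.
#' @param mean_umi,depth_cv mean and CV of the per-cell depth factor scaling
#'   expected total UMIs per cell.
#' @param mito_mean_pass,mito_mean_fail mean mitochondrial fraction of healthy
#'   cells and of the failing subpopulation.
#' @param mito_fail_rate fraction of cells drawn from the failing population.
#' @param seed integer seed; the whole simulation is a pure function of
#'   (config, seed).
#'
#' @return an object of class `sim_config` (a validated named list) with an
#'   attached `type_hierarchy` data.frame mapping each cell type to broad,
#'   tissue and major-group labels.
#' @export
sim_config <- function(n_timepoints = 1,
                       n_cell_types = 40,
                       n_genotypes = 2,
                       embryos_per_condition = 8,
                       control_embryos = 26,
                       baseline_logits = NULL,
                       effect_table = NULL,
                       litter_effect = 0.02,
                       total_cells_mean = 1800,
                       total_cells_cv = 0.4,
                       hash_signal_rate = 40,
                       hash_background_rate = 2,
                       doublet_fraction = 0.05,
                       n_genes = 200,
                       centroid_separation = 5,
                       within_type_sd = 0.5,
                       mean_umi = 1000,
                       depth_cv = 0.3,
                       mito_mean_pass = 0.05,
                       mito_mean_fail = 0.4,
                       mito_fail_rate = 0.02,
                       seed = 1L) {
  cfg <- list(
    n_timepoints = as.integer(n_timepoints),
    n_cell_types = as.integer(n_cell_types),
    n_genotypes = as.integer(n_genotypes),
    embryos_per_condition = as.integer(embryos_per_condition),
    control_embryos = as.integer(control_embryos),
    baseline_logits = baseline_logits,
    effect_table = effect_table,
    litter_effect = litter_effect,
    total_cells_mean = total_cells_mean,
    total_cells_cv = total_cells_cv,
    hash_signal_rate = hash_signal_rate,
    hash_background_rate = hash_background_rate,
    doublet_fraction = doublet_fraction,
    n_genes = as.integer(n_genes),
    centroid_separation = centroid_separation,
    within_type_sd = within_type_sd,
    mean_umi = mean_umi,
    depth_cv = depth_cv,
    mito_mean_pass = mito_mean_pass,
    mito_mean_fail = mito_mean_fail,
    mito_fail_rate = mito_fail_rate,
    seed = as.integer(seed)
  )
  if (cfg$n_timepoints < 1L || cfg$n_cell_types < 1L || cfg$n_genotypes < 1L ||
      cfg$embryos_per_condition < 1L || cfg$control_embryos < 1L ||
      cfg$n_genes < 1L) {
    stop("all counts in a sim_config must be >= 1")
  }
  if (!(cfg$litter_effect > 0 && cfg$litter_effect < 1)) {
    stop("litter_effect must lie strictly inside (0, 1)")
  }
  if (cfg$doublet_fraction < 0 || cfg$doublet_fraction >= 1) {
    stop("doublet_fraction must lie in [0, 1)")
  }
  if (cfg$hash_signal_rate < 0 || cfg$hash_background_rate < 0) {
    stop("hash rates must be nonnegative")
  }
  if (is.null(cfg$baseline_logits)) {
    cfg$baseline_logits <- default_baseline_logits(cfg$n_timepoints,
                                                   cfg$n_cell_types)
  }
  cfg$baseline_logits <- as.matrix(cfg$baseline_logits)
  if (!identical(dim(cfg$baseline_logits),
                 c(cfg$n_timepoints, cfg$n_cell_types))) {
    stop("baseline_logits must be an n_timepoints x n_cell_types matrix")
  }
  if (!is.null(cfg$effect_table)) {
    et <- as.data.frame(cfg$effect_table)
    need <- c("genotype", "timepoint", "cell_type", "delta")
    if (!all(need %in% names(et))) {
      stop("effect_table needs columns genotype, timepoint, cell_type, delta")
    }
    if (any(et$genotype < 1 | et$genotype >= cfg$n_genotypes) ||
        any(et$timepoint < 1 | et$timepoint > cfg$n_timepoints) ||
        any(et$cell_type < 1 | et$cell_type > cfg$n_cell_types)) {
      stop("effect_table indices out of range (genotype 0 is the control ",
           "and cannot carry effects)")
    }
    cfg$effect_table <- et
  }
  cfg$type_hierarchy <- default_type_hierarchy(cfg$n_cell_types)
  class(cfg) <- "sim_config"
  cfg
}

## Deterministic abundance ladder: log-odds decay linearly so compositions
## span common (~15%) to rare (<0.5%) types; timepoints share the ladder but
## rotate it by one position so stages are not identical.
default_baseline_logits <- function(n_timepoints, n_cell_types) {
  base <- -3.5 * (seq_len(n_cell_types) - 1) / max(1, n_cell_types - 1)
  out <- matrix(0, n_timepoints, n_cell_types)
  for (t in seq_len(n_timepoints)) {
    shift <- (seq_len(n_cell_types) + t - 2L) %% n_cell_types + 1L
    out[t, ] <- base[shift]
  }
  dimnames(out) <- list(paste0("t", seq_len(n_timepoints)),
                        sprintf("ct%02d", seq_len(n_cell_types)))
  out
}

## Three-level annotation hierarchy over the simulated types: every broad
## type belongs to a tissue (groups of ~5) and one of four major groups.
default_type_hierarchy <- function(n_cell_types) {
  idx <- seq_len(n_cell_types)
  data.frame(
    cell_type = sprintf("ct%02d", idx),
    tissue = sprintf("tissue%02d", (idx - 1L) %/% 5L + 1L),
    major_group = sprintf("group%d", (idx - 1L) %% 4L + 1L),
    stringsAsFactors = FALSE
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_genotypes, "genotypes x", x$n_timepoints,
      "timepoints,", x$n_cell_types, "cell types\n")
  cat("  embryos:", x$control_embryos, "control +", x$embryos_per_condition,
      "per perturbed condition; litter effect rho =", x$litter_effect, "\n")
  cat("  planted effects:",
      if (is.null(x$effect_table)) 0L else nrow(x$effect_table), "\n")
  invisible(x)
}
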