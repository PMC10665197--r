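#' Simulate per-embryo cell-type compositions with a litter effect
#'
#' Each condition's mean composition \eqn{\mu} is the softmax of baseline
#' log-odds plus any planted effect deltas. Per embryo, a total cell yield is
#' drawn (lognormal, floored at 50), a composition is drawn from
#' Dirichlet\eqn{(\alpha_0 \mu)} with total concentration
#' \eqn{\alpha_0 = (1-\rho)/\rho}, and counts are multinomial. This makes each
#' single cell type's marginal count exactly beta-binomial with mean
#' \eqn{\mu_j} and intra-class correlation \eqn{\rho}, while counts still sum
#' to the embryo total -- the generative twin of the abundance model.
#'
#' @param config a [sim_config()].
#' @return list with `composition` (an [embryo_composition()]) and `truth`
#'   (embryo table, per-embryo true composition vectors, condition means, and
#'   the planted effect table).
#' @export
simulate_compositions <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  rho <- config$litter_effect
  alpha0 <- (1 - rho) / rho
  K <- config$n_cell_types
  type_names <- colnames(config$baseline_logits)

  ## mean composition per (genotype, timepoint)
  mu <- array(0, dim = c(config$n_genotypes, config$n_timepoints, K))
  for (g in seq_len(config$n_genotypes) - 1L) {
    for (t in seq_len(config$n_timepoints)) {
      lg <- config$baseline_logits[t, ]
      if (g > 0 && !is.null(config$effect_table)) {
        et <- config$effect_table
        hit <- et$genotype == g & et$timepoint == t
        if (any(hit)) lg[et$cell_type[hit]] <- lg[et$cell_type[hit]] + et$delta[hit]
      }
      mu[g + 1L, t, ] <- softmax(lg)
    }
  }

  rows <- list()
  comps <- list()
  counts <- list()
  id <- 0L
  for (t in seq_len(config$n_timepoints)) {
    for (g in seq_len(config$n_genotypes) - 1L) {
      n_emb <- if (g == 0L) config$control_embryos else config$embryos_per_condition
      for (e in seq_len(n_emb)) {
        id <- id + 1L
        n_cells <- max(50L, as.integer(round(
          rlnorm_mean_cv(1, config$total_cells_mean, config$total_cells_cv))))
        p <- rdirichlet1(alpha0 * mu[g + 1L, t, ])
        k <- as.integer(rmultinom(1, n_cells, p))
        rows[[id]] <- data.frame(
          embryo = sprintf("emb%04d", id), genotype = g, timepoint = t,
          n_cells = n_cells, stringsAsFactors = FALSE)
        comps[[id]] <- p
        counts[[id]] <- k
      }
    }
  }
  meta <- do.call(rbind, rows)
  cnt <- do.call(rbind, counts)
  colnames(cnt) <- type_names
  truth <- list(
    embryos = meta,
    compositions = do.call(rbind, comps),
    condition_means = mu,
    effect_table = config$effect_table,
    type_names = type_names
  )
  colnames(truth$compositions) <- type_names
  rownames(truth$compositions) <- meta$embryo
  list(composition = embryo_composition(cnt, meta), truth = truth)
}

#' Simulate hashed single-cell data for a drawn composition
#'
#' Expression is Poisson-lognormal around cell-type centroids separated by
#' `centroid_separation` within-type standard deviations per gene; each cell
#' carries a lognormal depth factor. Hash counts put Poisson signal on the
#' cell's own embryo oligo and Poisson background everywhere else; a
#' `doublet_fraction` of cells merge two embryos' expression and split the
#' hash signal at half rate each. Mitochondrial fractions come from a healthy
#' beta population with a small failing spike.
#'
#' @param config a [sim_config()].
#' @param truth the `truth` element returned by [simulate_compositions()].
#' @return list with `experiment` (a [hashed_experiment()]) and `cells`
#'   (ground-truth cell table: id, true embryo, true cell type, doublet flag
#'   and partner embryo).
#' @export
simulate_cells <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  emb <- truth$embryos
  K <- config$n_cell_types
  G <- config$n_genes
  sw <- config$within_type_sd

  ## enumerate cells per embryo from the realized composition draws
  per_embryo <- truth$cell_counts
  if (is.null(per_embryo)) {
    stop("truth must carry cell_counts; use simulate_experiment() or pass ",
         "the truth augmented by simulate_compositions()")
  }

  cell_embryo <- rep(seq_len(nrow(emb)), times = rowSums(per_embryo))
  cell_type <- unlist(lapply(seq_len(nrow(emb)), function(e) {
    rep.int(seq_len(K), per_embryo[e, ])
  }), use.names = FALSE)
  n_cells <- length(cell_embryo)

  ## cell-type centroids in log space, separation per gene in units of sw
  centroids <- matrix(rnorm(K * G, sd = config$centroid_separation * sw / sqrt(2)),
                      K, G)
  base_rate <- exp(rnorm(G, 0, 1))
  ## scale base rates so the expected per-cell UMI total matches mean_umi
  expect_gene <- base_rate * exp((config$centroid_separation * sw)^2 / 4 + sw^2 / 2)
  base_rate <- base_rate * config$mean_umi / sum(expect_gene)

  depth <- rlnorm_mean_cv(n_cells, 1, config$depth_cv)

  sim_expr <- function(types, depths) {
    ## returns a (length(types) x G) integer matrix
    lam <- exp(sweep(centroids[types, , drop = FALSE] +
                       matrix(rnorm(length(types) * G, 0, sw),
                              length(types), G),
                     2, log(base_rate), "+")) * depths
    matrix(rpois(length(lam), lam), nrow(lam), G)
  }

  ## simulate in chunks to bound memory
  chunk <- 5000L
  parts <- split(seq_len(n_cells), (seq_len(n_cells) - 1L) %/% chunk)
  expr <- do.call(rbind, lapply(parts, function(i) {
    sim_expr(cell_type[i], depth[i])
  }))

  ## doublets: merge a partner cell from another embryo of the same timepoint
  n_doub <- as.integer(round(config$doublet_fraction * n_cells))
  is_doublet <- rep(FALSE, n_cells)
  partner_embryo <- rep(NA_integer_, n_cells)
  if (n_doub > 0) {
    doub_idx <- sample.int(n_cells, n_doub)
    is_doublet[doub_idx] <- TRUE
    for (i in doub_idx) {
      tp <- emb$timepoint[cell_embryo[i]]
      others <- which(emb$timepoint == tp)
      others <- setdiff(others, cell_embryo[i])
      if (!length(others)) next
      pe <- if (length(others) == 1L) others else sample(others, 1L)
      partner_embryo[i] <- pe
      ptype <- sample.int(K, 1L, prob = truth$compositions[pe, ])
      expr[i, ] <- expr[i, ] + sim_expr(ptype, depth[i])[1L, ]
    }
  }

  ## hash counts: signal on own oligo (split in half for doublets), Poisson
  ## background everywhere
  n_oligo <- nrow(emb)
  hash <- matrix(rpois(n_cells * n_oligo, config$hash_background_rate),
                 n_cells, n_oligo)
  sig <- ifelse(is_doublet & !is.na(partner_embryo),
                config$hash_signal_rate / 2, config$hash_signal_rate)
  own <- rpois(n_cells, sig)
  hash[cbind(seq_len(n_cells), cell_embryo)] <-
    hash[cbind(seq_len(n_cells), cell_embryo)] + own
  has_partner <- which(is_doublet & !is.na(partner_embryo))
  if (length(has_partner)) {
    hash[cbind(has_partner, partner_embryo[has_partner])] <-
      hash[cbind(has_partner, partner_embryo[has_partner])] +
      rpois(length(has_partner), config$hash_signal_rate / 2)
  }

  ## mitochondrial fraction: healthy population plus failing spike
  failing <- runif(n_cells) < config$mito_fail_rate
  mito <- ifelse(failing,
                 rbeta(n_cells, config$mito_mean_fail * 50,
                       (1 - config$mito_mean_fail) * 50),
                 rbeta(n_cells, config$mito_mean_pass * 50,
                       (1 - config$mito_mean_pass) * 50))

  cell_ids <- sprintf("cell%06d", seq_len(n_cells))
  oligo_names <- sprintf("hash%03d", seq_len(n_oligo))
  rownames(expr) <- cell_ids
  colnames(expr) <- sprintf("g%04d", seq_len(G))
  rownames(hash) <- cell_ids
  colnames(hash) <- oligo_names

  exp_obj <- hashed_experiment(
    Matrix::Matrix(expr, sparse = TRUE),
    Matrix::Matrix(hash, sparse = TRUE),
    setNames(emb$embryo, oligo_names),
    mito
  )
  cells <- data.frame(
    cell = cell_ids,
    embryo = emb$embryo[cell_embryo],
    cell_type = truth$type_names[cell_type],
    is_doublet = is_doublet,
    partner_embryo = ifelse(is.na(partner_embryo), NA_character_,
                            emb$embryo[partner_embryo]),
    stringsAsFactors = FALSE
  )
  list(experiment = exp_obj, cells = cells)
}

#' Run the full generator: compositions, then cells
#'
#' @param config a [sim_config()].
#' @return list with `composition` ([embryo_composition()]), `experiment`
#'   ([hashed_experiment()]), `cells` (ground-truth cell table) and `truth`.
#' @export
simulate_experiment <- function(config) {
  comp <- simulate_compositions(config)
  comp$truth$cell_counts <- comp$composition$counts
  cells <- simulate_cells(config, comp$truth)
  list(composition = comp$composition, experiment = cells$experiment,
       cells = cells$cells, truth = comp$truth)
}

#' Write a simulated experiment to disk in plain-text formats
#'
#' Writes `counts.mtx` (cell x gene), `hashes.mtx` (cell x oligo),
#' `cells.tsv`, `embryos.tsv` and `truth.json` under `dir`.
#'
#' @param sim result of [simulate_experiment()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(sim$experiment$gene_counts, file.path(dir, "counts.mtx"))
  Matrix::writeMM(sim$experiment$hash_counts, file.path(dir, "hashes.mtx"))
  cells <- sim$cells
  cells$mito_fraction <- sim$experiment$mito_fraction
  write.table(cells, file.path(dir, "cells.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  embryos <- sim$truth$embryos
  embryos$oligo <- names(sim$experiment$oligo_to_embryo)
  write.table(embryos, file.path(dir, "embryos.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(effect_table = sim$truth$effect_table,
         type_names = sim$truth$type_names,
         compositions = sim$truth$compositions),
    file.path(dir, "truth.json"), digits = NA)
  invisible(dir)
}
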