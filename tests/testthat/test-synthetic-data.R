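test_that("sim_config rejects invalid parameters", {
  expect_error(sim_config(litter_effect = 0), "litter_effect")
  expect_error(sim_config(litter_effect = 1), "litter_effect")
  expect_error(sim_config(doublet_fraction = 1), "doublet_fraction")
  expect_error(sim_config(n_cell_types = 0), ">= 1")
  expect_error(sim_config(effect_table = data.frame(
    genotype = 0, timepoint = 1, cell_type = 1, delta = 1)), "control")
  expect_error(sim_config(hash_signal_rate = -1), "nonnegative")
})

test_that("baseline compositions renormalize to one and truth is consistent", {
  cfg <- sim_config(n_cell_types = 12, control_embryos = 5,
                    embryos_per_condition = 3, total_cells_mean = 200,
                    seed = 9)
  out <- simulate_compositions(cfg)
  expect_equal(unname(rowSums(out$truth$condition_means[1, , , drop = FALSE])),
               1, tolerance = 1e-12)
  expect_true(all(abs(rowSums(out$truth$compositions) - 1) < 1e-12))
  expect_equal(unname(rowSums(out$composition$counts)),
               out$truth$embryos$n_cells)
  expect_true(all(out$composition$counts >= 0))
  expect_true(all(out$truth$embryos$n_cells >= 50))
})

test_that("identical seed and config give byte-identical simulations", {
  cfg <- sim_config(n_cell_types = 6, control_embryos = 4,
                    embryos_per_condition = 2, total_cells_mean = 100,
                    n_genes = 30, seed = 77)
  a <- simulate_experiment(cfg)
  b <- simulate_experiment(cfg)
  expect_identical(a$composition$counts, b$composition$counts)
  expect_identical(as.matrix(a$experiment$gene_counts),
                   as.matrix(b$experiment$gene_counts))
  expect_identical(as.matrix(a$experiment$hash_counts),
                   as.matrix(b$experiment$hash_counts))
  expect_identical(a$cells, b$cells)
})

test_that("per-embryo counts follow the beta-binomial marginal law", {
  ## mu = 0.2, rho = 0.05, n = 1000: Var[k] = n mu (1-mu) (1 + (n-1) rho)
  base <- matrix(log(c(0.2, 0.8)), 1, 2)
  cfg <- sim_config(n_cell_types = 2, n_genotypes = 1, control_embryos = 2000,
                    baseline_logits = base, litter_effect = 0.05,
                    total_cells_mean = 1000, total_cells_cv = 1e-9,
                    seed = 11)
  k <- simulate_compositions(cfg)$composition$counts[, 1]
  expect_equal(mean(k), 200, tolerance = 0.03)
  v_expected <- 1000 * 0.2 * 0.8 * (1 + 999 * 0.05)
  expect_equal(var(k), v_expected, tolerance = 0.10)

  ## rho -> 0 limit: variance collapses to the binomial n mu (1-mu) = 160
  cfg0 <- sim_config(n_cell_types = 2, n_genotypes = 1, control_embryos = 2000,
                     baseline_logits = base, litter_effect = 1e-7,
                     total_cells_mean = 1000, total_cells_cv = 1e-9,
                     seed = 12)
  k0 <- simulate_compositions(cfg0)$composition$counts[, 1]
  expect_equal(var(k0), 160, tolerance = 0.12)
})

test_that("null effects leave genotypes exchangeable at nominal test level", {
  rej <- vapply(1:100, function(r) {
    cfg <- sim_config(n_cell_types = 5, n_genotypes = 2, control_embryos = 8,
                      embryos_per_condition = 8, total_cells_mean = 400,
                      litter_effect = 0.02, seed = 500 + r)
    cm <- simulate_compositions(cfg)$composition
    prop <- cm$counts[, 1] / rowSums(cm$counts)
    g <- cm$metadata$genotype
    t.test(prop[g == 0], prop[g == 1])$p.value < 0.05
  }, logical(1))
  expect_gte(mean(rej), 0.0)
  expect_lte(mean(rej), 0.13)
})

test_that("hash structure behaves as configured", {
  ## zero background: every singlet has exactly one nonzero hash column
  cfg <- sim_config(n_cell_types = 4, n_genotypes = 1, control_embryos = 6,
                    total_cells_mean = 80, n_genes = 20,
                    hash_background_rate = 0, doublet_fraction = 0, seed = 21)
  sim <- simulate_experiment(cfg)
  nz <- Matrix::rowSums(sim$experiment$hash_counts > 0)
  expect_true(all(nz == 1))

  ## signal 40 / background 2 over 96 oligos: median top/second ratio > 5
  cfg2 <- sim_config(n_cell_types = 4, n_genotypes = 1, control_embryos = 96,
                     total_cells_mean = 50, total_cells_cv = 0.1, n_genes = 20,
                     hash_signal_rate = 40, hash_background_rate = 2,
                     doublet_fraction = 0, seed = 22)
  sim2 <- simulate_experiment(cfg2)
  h <- as.matrix(sim2$experiment$hash_counts)
  top <- apply(h, 1, max)
  second <- apply(h, 1, function(r) sort(r, decreasing = TRUE)[2])
  expect_gt(median(top / pmax(second, 1)), 5)
})

test_that("the configured doublet fraction is realized", {
  cfg <- sim_config(n_cell_types = 5, n_genotypes = 1, control_embryos = 10,
                    total_cells_mean = 1000, total_cells_cv = 0.05,
                    n_genes = 20, doublet_fraction = 0.1, seed = 31)
  sim <- simulate_experiment(cfg)
  n <- nrow(sim$cells)
  expect_equal(sum(sim$cells$is_doublet), round(0.1 * n))
})

test_that("simulation writes and reads back through the plain-text formats", {
  dir <- withr::local_tempdir()
  sim <- small_sim()
  write_simulation(sim, dir)
  expect_true(all(file.exists(file.path(
    dir, c("counts.mtx", "hashes.mtx", "cells.tsv", "embryos.tsv",
           "truth.json")))))
  back <- read_hashed_experiment(dir)
  expect_equal(unname(back$umi), unname(sim$experiment$umi))
  expect_equal(as.matrix(back$hash_counts),
               as.matrix(sim$experiment$hash_counts),
               ignore_attr = TRUE)
})
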