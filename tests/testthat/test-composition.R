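test_that("tally builds exact contingency counts with explicit zeros", {
  cells <- data.frame(embryo = c("e1", "e1", "e1", "e2"),
                      cell_type = c("A", "A", "B", "A"))
  meta <- data.frame(embryo = c("e1", "e2"), genotype = 0, timepoint = 1)
  m <- tally(cells, meta, cell_types = c("A", "B", "C"))
  expect_error(embryo_composition(matrix(-1, 1, 1),
                                  data.frame(embryo = "x", genotype = 0,
                                             timepoint = 1)),
               "nonnegative")
  expect_equal(unname(m$counts["e1", ]), c(2L, 1L, 0L))
  ## type C never occurs but keeps an explicit zero column
  expect_equal(unname(m$counts[, "C"]), c(0L, 0L))
  ## an embryo with zero assigned cells fails loudly in size factoring
  expect_error(tally(cells[1:3, ], meta), "zero assigned")
  expect_error(tally(data.frame(embryo = "eX", cell_type = "A"), meta),
               "unknown embryo")
})

test_that("tally of simulated cells equals the generator's multinomial draws", {
  sim <- small_sim()
  singlets <- sim$cells[!sim$cells$is_doublet, ]
  m <- tally(singlets, sim$truth$embryos,
             cell_types = colnames(sim$composition$counts))
  ## doublets were removed, so tallies equal truth minus doublet cells
  doub <- table(factor(sim$cells$embryo[sim$cells$is_doublet],
                       levels = sim$truth$embryos$embryo),
                factor(sim$cells$cell_type[sim$cells$is_doublet],
                       levels = colnames(sim$composition$counts)))
  expect_equal(m$counts + matrix(as.integer(doub), nrow(doub)),
               sim$composition$counts, ignore_attr = TRUE)
  expect_equal(sum(m$counts), nrow(singlets))
})

test_that("size factors are per-timepoint geometric-mean normalized", {
  meta <- data.frame(embryo = paste0("e", 1:3), genotype = 0, timepoint = 1)
  m <- embryo_composition(matrix(c(50, 50, 50), 3, 1), meta)
  expect_equal(m$metadata$size_factor, rep(1, 3))

  meta2 <- data.frame(embryo = c("a", "b"), genotype = 0, timepoint = 1)
  m2 <- embryo_composition(matrix(c(25, 100, 25, 100), 2, 2), meta2)
  expect_equal(m2$metadata$size_factor, c(0.5, 2.0))
  expect_equal(unname(rowSums(m2$normalized)), c(100, 100))

  ## timepoints are normalized independently
  meta3 <- data.frame(embryo = paste0("e", 1:4), genotype = 0,
                      timepoint = c(1, 1, 2, 2))
  m3 <- embryo_composition(matrix(c(50, 200, 10, 1000), 4, 1), meta3)
  for (tp in 1:2) {
    sf <- m3$metadata$size_factor[m3$metadata$timepoint == tp]
    expect_equal(exp(mean(log(sf))), 1, tolerance = 1e-9)
  }
  expect_equal(m3$metadata$size_factor[1:2], c(0.5, 2.0))

  expect_error(embryo_composition(matrix(c(0, 5), 2, 1),
                                  data.frame(embryo = c("z1", "z2"),
                                             genotype = 0, timepoint = 1)),
               "z1")
})

test_that("normalized counts are invariant to per-timepoint count scaling", {
  sim <- small_sim()
  m <- sim$composition
  scaled <- m$counts * 3L
  m2 <- embryo_composition(scaled, m$metadata)
  expect_equal(m2$normalized, m$normalized * 3, tolerance = 1e-12)
  ## proportions within an embryo are untouched by normalization
  expect_equal(m$normalized / rowSums(m$normalized),
               m$counts / rowSums(m$counts), tolerance = 1e-12)
})

test_that("composition PCA is an isometry at full rank and separates effects", {
  sim <- small_sim()
  m <- sim$composition
  pc <- composition_pca(m, n_components = min(dim(m$counts)) - 1)
  x <- scale(log1p(m$normalized), center = TRUE, scale = FALSE)
  expect_equal(as.matrix(dist(pc$loadings)), as.matrix(dist(x)),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(composition_pca(m, n_components = 99), "exceeds")

  ## identical embryos get identical loadings
  meta <- data.frame(embryo = c("a", "b", "c"), genotype = 0, timepoint = 1)
  dup <- embryo_composition(matrix(c(10, 10, 30, 5, 5, 1), 3, 2), meta)
  pd <- composition_pca(dup, 2)
  expect_equal(pd$loadings[1, ], pd$loadings[2, ], tolerance = 1e-10)

  ## planted large effect separates genotypes linearly (positive silhouette)
  cfg <- sim_config(n_cell_types = 15, control_embryos = 10,
                    embryos_per_condition = 10, total_cells_mean = 500,
                    seed = 13,
                    effect_table = data.frame(genotype = 1, timepoint = 1,
                                              cell_type = c(2, 5), delta = 2))
  cm <- simulate_compositions(cfg)$composition
  L <- composition_pca(cm, 2)$loadings
  g <- cm$metadata$genotype
  d <- as.matrix(dist(L))
  sil <- vapply(seq_along(g), function(i) {
    a <- sum(d[i, g == g[i]]) / (sum(g == g[i]) - 1)
    b <- mean(d[i, g != g[i]])
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0)
})
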