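ref_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_cell_types = 8, n_genotypes = 1,
                        control_embryos = 8, total_cells_mean = 150,
                        n_genes = 80, centroid_separation = 5,
                        doublet_fraction = 0, seed = 91)
      cache <<- simulate_experiment(cfg)
    }
    cache
  }
})

test_that("reference projection is idempotent and rotation orthonormal", {
  sim <- ref_sim()
  mod <- fit_reference(sim$experiment$gene_counts,
                       data.frame(cell_type = sim$cells$cell_type),
                       n_components = 20)
  expect_lt(max(abs(crossprod(mod$rotation) - diag(ncol(mod$rotation)))),
            1e-6)
  back <- project_cells(mod, sim$experiment$gene_counts)
  expect_lt(max(abs(back - mod$ref_loadings)), 1e-8)
  ## explained variance is non-increasing
  expect_true(all(diff(mod$sdev) <= 1e-12))
})

test_that("duplicated cells project to identical loadings", {
  sim <- ref_sim()
  mod <- fit_reference(sim$experiment$gene_counts,
                       data.frame(cell_type = sim$cells$cell_type), 10)
  q <- sim$experiment$gene_counts[c(1, 1, 2), ]
  rownames(q) <- c("a", "b", "c")
  L <- project_cells(mod, q)
  expect_equal(L[1, ], L[2, ], tolerance = 1e-12)
})

test_that("depth changes act only through the stored linear depth term", {
  counts <- matrix(rpois(50 * 5, 20), 50, 5,
                   dimnames = list(paste0("c", 1:50), paste0("g", 1:5)))
  mod <- fit_reference(counts, data.frame(lab = rep(c("x", "y"), 25)), 3)
  q <- counts[1:4, , drop = FALSE]
  L1 <- project_cells(mod, q)
  L2 <- project_cells(mod, q * 2L)
  ## doubling counts leaves normalized expression unchanged; only the
  ## log10-UMI residualization moves, by exactly slope * log10(2)
  shift <- outer(rep(log10(2), 4), mod$depth_slopes)
  expect_equal(L2, L1 - shift, tolerance = 1e-10)
})

test_that("queries land nearest their own type and transfer is accurate", {
  sim <- ref_sim()
  lab <- data.frame(cell_type = sim$cells$cell_type)
  set.seed(1)
  hold <- sample(nrow(lab), round(0.2 * nrow(lab)))
  mod <- fit_reference(sim$experiment$gene_counts[-hold, ],
                       lab[-hold, , drop = FALSE], 20)
  L <- project_cells(mod, sim$experiment$gene_counts[hold, ])
  ## centroid proximity in component space
  cent <- apply(mod$ref_loadings, 2, function(col)
    tapply(col, mod$ref_labels$cell_type, mean))
  d <- as.matrix(dist(rbind(cent, L)))[-seq_len(nrow(cent)),
                                       seq_len(nrow(cent))]
  nearest <- rownames(cent)[max.col(-d)]
  expect_gte(mean(nearest == lab$cell_type[hold]), 0.99)

  tr <- transfer_labels(mod, L, k = 10)
  expect_gte(mean(tr$label == lab$cell_type[hold]), 0.95)
  expect_true(all(tr$vote_frac > 0 & tr$vote_frac <= 1))

  ## approximate backend agrees with exact on almost all labels
  tr2 <- transfer_labels(mod, L, k = 10, method = "ivf")
  expect_gte(mean(tr$label == tr2$label), 0.99)
})

test_that("k-NN votes break ties deterministically toward the nearer side", {
  ref <- rbind(matrix(rep(c(0, 0), 5), 5, 2, byrow = TRUE) +
                 cbind(seq(0.1, 0.5, 0.1), 0),
               matrix(rep(c(10, 0), 5), 5, 2, byrow = TRUE) +
                 cbind(seq(2.1, 4.5, 0.6), 0))
  mod <- structure(list(
    genes = character(0), centers = numeric(0), scales = numeric(0),
    constant_genes = character(0), rotation = diag(2), sdev = c(1, 1),
    geo_umi = 1, depth_slopes = c(0, 0), mean_log10_umi = 0,
    ref_loadings = ref,
    ref_labels = data.frame(lab = rep(c("near", "far"), each = 5))
  ), class = "projection_model")
  tr <- transfer_labels(mod, matrix(c(0, 0), 1, 2), k = 10)
  expect_equal(tr$label, "near")
  expect_error(transfer_labels(mod, matrix(0, 1, 2), k = 11), "exceeds")
})

test_that("hierarchical transfer routes queries through sub-models", {
  sim <- ref_sim()
  hier <- sim$config
  types <- sim$cells$cell_type
  major <- ifelse(types %in% sprintf("ct%02d", 1:4), "groupA", "groupB")
  lab <- data.frame(major_group = major, cell_type = types)
  set.seed(2)
  hold <- sample(length(types), 300)
  expr <- sim$experiment$gene_counts
  glob <- fit_reference(expr[-hold, ], lab[-hold, c("major_group", "cell_type")], 15)
  subs <- lapply(split(seq_len(nrow(lab))[-hold],
                       lab$major_group[-hold]), function(i) {
    fit_reference(expr[i, ], lab[i, "cell_type", drop = FALSE], 10)
  })
  tr <- transfer_hierarchy(glob, subs, expr[hold, ], k = 10)
  expect_gte(mean(tr$major_group == major[hold]), 0.95)
  expect_gte(mean(tr$label == types[hold], na.rm = TRUE), 0.9)
})

test_that("serialized models reproduce transfers exactly", {
  sim <- ref_sim()
  mod <- fit_reference(sim$experiment$gene_counts,
                       data.frame(cell_type = sim$cells$cell_type), 10)
  path <- withr::local_tempfile(fileext = ".json")
  save_projection_model(mod, path)
  mod2 <- load_projection_model(path)
  q <- sim$experiment$gene_counts[1:50, ]
  expect_equal(project_cells(mod, q), project_cells(mod2, q),
               tolerance = 1e-12, ignore_attr = TRUE)
  t1 <- transfer_labels(mod, project_cells(mod, q), 10)
  t2 <- transfer_labels(mod2, project_cells(mod2, q), 10)
  expect_identical(t1$label, t2$label)
})

test_that("poor gene overlap is refused and missing genes reported", {
  sim <- ref_sim()
  mod <- fit_reference(sim$experiment$gene_counts,
                       data.frame(cell_type = sim$cells$cell_type), 5)
  q <- sim$experiment$gene_counts[1:5, 1:10]
  expect_error(project_cells(mod, q), "refusing")
  q2 <- sim$experiment$gene_counts[1:5, 1:70]
  L <- project_cells(mod, q2)
  expect_equal(length(attr(L, "missing_genes")), 10)
})
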