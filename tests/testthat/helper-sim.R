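## Small shared fixtures, generated in code at test time.

## A compact hashed experiment with known truth: 10 embryos, 10 types,
## ~300 cells per embryo, strong hash signal, 5% doublets.
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(n_cell_types = 10, n_genotypes = 2,
                        control_embryos = 6, embryos_per_condition = 4,
                        total_cells_mean = 300, n_genes = 60,
                        mean_umi = 600, seed = 42)
      cache <<- c(simulate_experiment(cfg), list(config = cfg))
    }
    cache
  }
})

## Tiny hand-built hashed experiment for demux edge cases: hash rows are
## given explicitly, gene counts are a diagonal-ish filler.
toy_experiment <- function(hash_rows, umi = NULL, mito = NULL) {
  n <- nrow(hash_rows)
  if (is.null(umi)) umi <- rep(500, n)
  if (is.null(mito)) mito <- rep(0.05, n)
  genes <- matrix(0, n, 2, dimnames = list(sprintf("c%02d", seq_len(n)),
                                           c("gA", "gB")))
  genes[, 1] <- umi
  rownames(hash_rows) <- rownames(genes)
  colnames(hash_rows) <- sprintf("h%d", seq_len(ncol(hash_rows)))
  hashed_experiment(genes, hash_rows,
                    setNames(sprintf("e%d", seq_len(ncol(hash_rows))),
                             colnames(hash_rows)),
                    mito)
}
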