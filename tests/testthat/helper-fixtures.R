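# Small fixture builders shared across the suite. Everything is
# generated in code; no data files.

tiny_matrix <- function(nr = 4, nc = 3, seed = 1, counts = FALSE) {
  set.seed(seed)
  v <- if (counts) matrix(rpois(nr * nc, 5), nr, nc) else
    matrix(rnorm(nr * nc), nr, nc)
  dimnames(v) <- list(sprintf("G%02d", seq_len(nr)),
                      sprintf("S%02d", seq_len(nc)))
  v
}

tiny_domain_matrix <- function(nr = 4, nc = 3, seed = 1,
                               domain = "target", counts = FALSE) {
  DomainMatrix(tiny_matrix(nr, nc, seed, counts), domain = domain,
               valueKind = if (counts) "counts" else "continuous")
}

tiny_source <- function(nr = 6, nc = 8, seed = 1) {
  v <- tiny_matrix(nr, nc, seed, counts = TRUE)
  SourceDataset(v, stages = rep(differentiationStages(),
                                length.out = nc))
}

# A small separable continuous source: two informative coordinates per
# stage, used by model/training tests.
toy_labeled_source <- function(n_per = 30, n_genes = 20, seed = 1,
                               sep = 3) {
  set.seed(seed)
  stages <- differentiationStages()
  v <- matrix(rnorm(n_genes * n_per * 4), n_genes)
  for (k in seq_along(stages)) {
    cols <- (k - 1) * n_per + seq_len(n_per)
    v[k, cols] <- v[k, cols] + sep
  }
  dimnames(v) <- list(sprintf("G%03d", seq_len(n_genes)),
                      sprintf("C%03d", seq_len(ncol(v))))
  SourceDataset(v, stages = rep(stages, each = n_per),
                valueKind = "continuous")
}

toy_target <- function(n = 60, n_genes = 20, seed = 2, shift = 0) {
  set.seed(seed)
  v <- matrix(rnorm(n_genes * n), n_genes) + shift
  dimnames(v) <- list(sprintf("G%03d", seq_len(n_genes)),
                      sprintf("T%03d", seq_len(n)))
  DomainMatrix(v, domain = "target", valueKind = "continuous")
}

# Small preprocessed benchmark shared by training/scoring tests:
# simulation -> log transform -> top-k genes -> standardization.
small_processed_benchmark <- function(seed = 1, n_genes = 60,
                                      n_source = 400, n_target = 400,
                                      k = 40, ...) {
  cfg <- simulationConfig(n_genes = n_genes, n_source = n_source,
                          n_target = n_target,
                          n_informative_genes = 20L, seed = seed, ...)
  src <- simulateSource(cfg)
  tgt <- simulateTarget(cfg, src)
  lg <- logTransform(src$dataset)
  fs <- selectFeatures(lg, k = k)
  al <- alignGenes(lg[fs@geneIds, ], tgt$matrix)
  list(source = standardizeTarget(al$source),
       target = standardizeTarget(al$target),
       metadata = tgt$metadata,
       truth = tgt$truth,
       config = cfg)
}
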