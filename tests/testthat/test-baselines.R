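# Independent running-sum ssGSEA oracle: explicit loop over the
# ranked genes.
oracle_ssgsea <- function(values, gene_ids, set, alpha) {
  ord <- order(-values, gene_ids, method = "radix")
  ids <- gene_ids[ord]; v <- abs(values[ord])^alpha
  inset <- ids %in% set
  n <- length(ids)
  p_in <- 0; p_out <- 0; acc <- 0
  for (i in seq_len(n)) {
    if (inset[i]) p_in <- p_in + v[i] / sum(v[inset])
    else p_out <- p_out + 1 / (n - sum(inset))
    acc <- acc + (p_in - p_out)
  }
  unname(acc)
}

test_that("random scores are seeded Uniform(0,1)", {
  a <- randomScores(1000, seed = 3)
  b <- randomScores(1000, seed = 3)
  expect_identical(a, b)
  expect_true(all(a >= 0 & a < 1))
  big <- randomScores(1e5, seed = 4)
  expect_equal(mean(big), 0.5, tolerance = 0.01)
  expect_gt(stats::ks.test(big, "punif")$p.value, 0.001)
  expect_error(randomScores(0), ">= 1")
})

test_that("stage signatures average the cells and balance to zero", {
  v <- tiny_matrix(10, 8, seed = 2)
  # two identical cells per stage -> centroid equals the cell vector
  v <- v[, rep(1:4, each = 2)]
  colnames(v) <- paste0("C", 1:8)
  src <- SourceDataset(v, rep(differentiationStages(), each = 2),
                       valueKind = "continuous")
  sig <- buildSignatures(src, top_n = 5)
  expect_equal(unname(sig@centroids[, "proliferative"]),
               unname(v[, 3]))
  # class-size-weighted mean of differentials is exactly zero
  w <- as.numeric(table(stageLabels(src))) / ncol(src)
  expect_lt(max(abs(sig@differentials %*% w)), 1e-12)
  expect_true(all(lengths(sig@topSets) == 5L))
  expect_equal(unname(colSums(sig@unitDifferentials^2)), rep(1, 4),
               tolerance = 1e-12)
  # a stage without cells is an error
  expect_error(buildSignatures(
    SourceDataset(v, rep(c("core_pluripotent", "proliferative"), 4),
                  valueKind = "continuous")), "zero cells")
})

test_that("cosine similarity matches its definition", {
  expect_equal(cosineSimilarity(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(cosineSimilarity(c(1, 0), c(0, 1)), 0)
  set.seed(5)
  for (rep in 1:50) {
    u <- rnorm(10); v <- rnorm(10)
    expect_equal(cosineSimilarity(u, v),
                 sum(u * v) / sqrt(sum(u^2) * sum(v^2)),
                 tolerance = 1e-12)
  }
  expect_error(cosineSimilarity(rep(0, 3), 1:3), "zero vector")
  expect_error(cosineSimilarity(1:3, 1:4), "equal length")
})

test_that("cosine baseline recognizes centroids and planted profiles", {
  src <- toy_labeled_source(n_per = 20, n_genes = 30, sep = 3)
  sig <- buildSignatures(src)
  prof <- sig@centroids[, "early_primed", drop = FALSE]
  colnames(prof) <- "P1"
  got <- gepCosineScore(prof, sig, mode = "argmax",
                        signature_type = "centroid")
  expect_identical(got$stage, "early_primed")
  # a profile orthogonal to every signature scores zero
  S <- sig@unitDifferentials
  null_dir <- qr.Q(qr(cbind(S, rnorm(nrow(S)))))[, 5]
  ortho <- matrix(null_dir, ncol = 1,
                  dimnames = list(rownames(S), "P2"))
  expect_equal(gepCosineScore(ortho, sig)$score, 0, tolerance = 1e-9)
  # planted target profiles outscore inert ones in the mean
  bench <- small_processed_benchmark(seed = 10, n_genes = 80,
                                     n_source = 500, n_target = 500,
                                     k = 60, planted_fraction = 0.2)
  sigb <- buildSignatures(bench$source)
  sc <- gepCosineScore(bench$target, sigb)$score
  act <- bench$truth$target_is_active
  expect_gt(mean(sc[act]), mean(sc[!act]))
})

test_that("Jaccard baseline counts top-set overlaps", {
  # hand-built signatures on a 12-gene space with known top sets
  genes <- sprintf("G%02d", 1:12)
  diffs <- matrix(0, 12, 4, dimnames = list(genes,
                                            differentiationStages()))
  diffs[1:3, 1] <- 3; diffs[4:6, 2] <- 3
  diffs[7:9, 3] <- 3; diffs[10:12, 4] <- 3
  sig <- new("SignatureSet", stages = differentiationStages(),
             centroids = diffs, differentials = diffs,
             unitDifferentials = diffs,
             topSets = list(core_pluripotent = genes[1:3],
                            proliferative = genes[4:6],
                            early_primed = genes[7:9],
                            late_primed = genes[10:12]),
             topN = 3L)
  # profile whose top 3 genes are exactly stage 1's set:
  # Jaccard = (1 + 0 + 0 + 0) / 4
  prof <- matrix(c(rep(5, 3), rep(0.1, 9)), ncol = 1,
                 dimnames = list(genes, "P"))
  expect_equal(gepJaccardScore(prof, sig), 0.25, tolerance = 1e-12)
  # one overlap of 1 out of union 5 with each set: mean = 1/5... built:
  prof2 <- matrix(0.1, 12, 1, dimnames = list(genes, "P"))
  prof2[c(1, 4, 7), 1] <- 5   # one gene from three different sets
  expect_equal(gepJaccardScore(prof2, sig),
               mean(c(1 / 5, 1 / 5, 1 / 5, 0 / 6)), tolerance = 1e-12)
  expect_true(all(gepJaccardScore(matrix(rnorm(12), 12, 1,
                                         dimnames = list(genes, "Q")),
                                  sig) >= 0))
})

test_that("ssGSEA matches the brute-force running sum", {
  set.seed(7)
  genes <- sprintf("G%02d", 1:10)
  v <- matrix(rnorm(30), 10, 3, dimnames = list(genes, paste0("P", 1:3)))
  sets <- list(top = genes[1:4], other = genes[c(2, 5, 9)])
  got <- ssgseaScores(v, sets, alpha = 0.25, normalize = FALSE)
  for (j in 1:3) for (k in 1:2)
    expect_equal(got[k, j],
                 oracle_ssgsea(v[, j], genes, sets[[k]], 0.25),
                 tolerance = 1e-9)
  # a set of exactly the top-ranked genes scores positive; the
  # complementary bottom set scores negative
  x <- matrix(10:1, 10, 1, dimnames = list(genes, "P"))
  expect_gt(ssgseaScores(x, list(s = genes[1:3]),
                         normalize = FALSE)[1, 1], 0)
  expect_lt(ssgseaScores(x, list(s = genes[8:10]),
                         normalize = FALSE)[1, 1], 0)
  # alpha = 0 reduces the weights to the uniform ECDF difference
  got0 <- ssgseaScores(v, sets, alpha = 0, normalize = FALSE)
  for (j in 1:3)
    expect_equal(got0[1, j], oracle_ssgsea(v[, j], genes, sets$top, 0),
                 tolerance = 1e-9)
  # relabeling genes together with the sets leaves scores unchanged
  relab <- setNames(sprintf("X%02d", 1:10), genes)
  v2 <- v; rownames(v2) <- unname(relab[genes])
  sets2 <- lapply(sets, function(s) unname(relab[s]))
  expect_equal(ssgseaScores(v2, sets2, normalize = FALSE), got,
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_warning(ssgseaScores(v, list(gone = c("Z1", "Z2"))),
                 "no overlap")
})

test_that("pathway-activation cosine scores behave at the poles", {
  pa <- c(0.5, -0.2, 0.8)
  expect_equal(paCosineScore(pa, pa), 1)
  expect_equal(paCosineScore(c(1, 0, 0), c(0, 1, 0)), 0)
  S <- cbind(a = pa, b = -pa)
  expect_equal(paCosineScore(pa, S), 0, tolerance = 1e-12)
  # planted synthetic profiles outscore inert ones with
  # informative-gene sets
  bench <- small_processed_benchmark(seed = 11, n_genes = 60,
                                     n_source = 400, n_target = 300,
                                     k = 60, planted_fraction = 0.25)
  sig <- buildSignatures(bench$source)
  cfg <- bench$config
  src <- simulateSource(cfg)
  info <- intersect(src$truth$informative_genes, geneIds(bench$target))
  rest <- setdiff(geneIds(bench$target), info)
  sets <- list(informative = info,
               noise1 = rest[seq_len(15)],
               noise2 = rest[16:30])
  pa_t <- ssgseaScores(bench$target, sets)
  pa_s <- ssgseaScores(sig@differentials, sets)
  sc <- paCosineScore(pa_t, pa_s)
  act <- bench$truth$target_is_active
  expect_gt(mean(sc[act]), mean(sc[!act]))
})

test_that("GMT collections round-trip through fgsea's reader", {
  sets <- list(alpha = c("G1", "G2", "G3"), beta = c("G2", "G9"))
  path <- withr::local_tempfile(fileext = ".gmt")
  writeGMT(sets, path)
  back <- readGMT(path)
  expect_identical(back, sets)
  expect_error(writeGMT(unname(sets), path), "named")
})

test_that("the ablation runs the full pipeline without adaptation", {
  bench <- small_processed_benchmark(seed = 12, n_genes = 40,
                                     n_source = 200, n_target = 150,
                                     k = 30)
  mc <- modelConfig(input_dim = 30, encoder_widths = 8L,
                    latent_dim = 4L, decoder_widths = 8L, seed = 3)
  tc <- trainConfig(n_steps = 50L, eval_every = 25L, seed = 3,
                    batch_size_per_domain = 32L)
  ab1 <- runAblation(bench$source, bench$target, mc, tc,
                     metadata = bench$metadata)
  ab2 <- runAblation(bench$source, bench$target, mc, tc,
                     metadata = bench$metadata)
  expect_identical(ab1$scores$priority_score, ab2$scores$priority_score)
  expect_true(all(is.na(ab1$log$adversarial_accuracy)))
  probs <- as.matrix(ab1$scores[, paste0("p_", differentiationStages())])
  expect_equal(unname(rowSums(probs)), rep(1, nrow(probs)),
               tolerance = 1e-9)
})
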