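# Independent ZINB oracle built from explicit gamma-function
# arithmetic (no dnbinom).
oracle_zinb_nll <- function(x, mu, theta, pi) {
  lognb <- lgamma(x + theta) - lgamma(theta) - lgamma(x + 1) +
    theta * (log(theta) - log(theta + mu)) +
    x * (log(mu) - log(theta + mu))
  -log(pi * (x == 0) + (1 - pi) * exp(lognb))
}

test_that("zinbNLL reproduces closed-form values and limits", {
  # pi=0, x=0, mu=1, theta=1: NB(0) = 1/2, NLL = log 2
  expect_equal(zinbNLL(0, 1, 1, 0), log(2), tolerance = 1e-12)
  expect_equal(zinbNLL(0, 1, 1, 0), 0.693147, tolerance = 1e-6)
  # zero-inflation saturates the zero mass
  expect_lt(zinbNLL(0, 1, 1, 1 - 1e-12), 1e-10)
  # reduces to the plain NB NLL at pi = 0
  set.seed(5)
  x <- rpois(50, 4); mu <- runif(50, 0.1, 20); th <- runif(50, 0.2, 5)
  expect_equal(zinbNLL(x, mu, th, 0),
               -dnbinom(x, size = th, mu = mu, log = TRUE),
               tolerance = 1e-12)
  expect_error(zinbNLL(1, -1, 1, 0), "mu")
  expect_error(zinbNLL(1, 1, 0, 0), "theta")
  expect_error(zinbNLL(-1, 1, 1, 0), "non-negative")
})

test_that("zinbNLL matches a brute-force mixture oracle on random inputs", {
  set.seed(10)
  x <- rpois(1000, 3)
  mu <- runif(1000, 0.05, 30)
  th <- runif(1000, 0.1, 8)
  pi <- runif(1000)
  expect_equal(zinbNLL(x, mu, th, pi), oracle_zinb_nll(x, mu, th, pi),
               tolerance = 1e-9)
})

test_that("log transform uses the stated epsilon and identities", {
  expect_equal(logTransform(matrix(0), eps = 1e-5)[1], log(1e-5))
  expect_equal(logTransform(matrix(0), eps = 1e-5)[1], -11.512925,
               tolerance = 1e-6)
  expect_equal(logTransform(matrix(1 - 1e-5), eps = 1e-5)[1], 0)
  expect_error(logTransform(matrix(-0.1)), "non-negative")
  x <- tiny_domain_matrix(3, 2, counts = TRUE, domain = "source")
  lt <- logTransform(x)
  expect_s4_class(lt, "DomainMatrix")
  expect_identical(valueKind(lt), "continuous")
  expect_equal(exprValues(lt), log(exprValues(x) + 1e-5))
})

test_that("mutual information behaves at the independence and identity poles", {
  labels <- rep(c("a", "b"), each = 50)
  expect_equal(mutualInformation(rep(1, 100), labels), 0)
  expect_equal(mutualInformation(rep(c(0, 1), each = 50), labels), 1)
  expect_error(mutualInformation(1, "a"), "observations")
})

test_that("permuted genes stay inside the MI permutation null", {
  set.seed(21)
  labels <- sample(rep(differentiationStages(), each = 25))
  g <- rnorm(100)
  observed <- mutualInformation(sample(g), labels)
  null <- replicate(400, mutualInformation(sample(g), labels))
  expect_gte(observed, quantile(null, 0.005))
  expect_lte(observed, quantile(null, 0.995))
})

test_that("selectFeatures ranks by MI with lexicographic tie-break", {
  src <- toy_labeled_source(n_per = 25, n_genes = 12, sep = 4)
  fs <- selectFeatures(src, k = 4)
  # the four informative coordinates are genes 1..4 by construction
  expect_setequal(fs@geneIds, sprintf("G%03d", 1:4))
  # k >= n_genes selects everything
  expect_length(selectFeatures(src, k = 100)@geneIds, 12)
  expect_error(selectFeatures(src, k = 0), "positive")
  # exact ties (duplicated gene content) resolve lexicographically
  v <- exprValues(src)
  v["G011", ] <- v["G001", ]
  src2 <- SourceDataset(v, stageLabels(src), valueKind = "continuous")
  fs2 <- selectFeatures(src2, k = 12)
  ix <- match(c("G001", "G011"), fs2@geneIds)
  expect_identical(diff(ix), 1L)  # adjacent, G001 first
})

test_that("selectFeatures is invariant to gene-row permutation", {
  src <- toy_labeled_source(n_per = 20, n_genes = 15, sep = 2)
  set.seed(4)
  perm <- sample(nrow(src))
  src_p <- SourceDataset(exprValues(src)[perm, ], stageLabels(src),
                         valueKind = "continuous")
  expect_identical(selectFeatures(src, k = 6)@geneIds,
                   selectFeatures(src_p, k = 6)@geneIds)
})

test_that("feature selection TSV round-trips", {
  src <- toy_labeled_source(n_per = 15, n_genes = 10)
  fs <- selectFeatures(src, k = 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeFeatureSelection(fs, path)
  back <- readFeatureSelection(path)
  expect_identical(back@geneIds, fs@geneIds)
  expect_equal(unname(back@miScores[back@geneIds]),
               unname(fs@miScores[fs@geneIds]), tolerance = 1e-12)
})

test_that("standardizeTarget centers, scales and is idempotent", {
  x <- tiny_domain_matrix(6, 10, seed = 9)
  z <- standardizeTarget(x)
  expect_lt(max(abs(rowMeans(exprValues(z)))), 1e-9)
  z2 <- standardizeTarget(z)
  expect_equal(exprValues(z2), exprValues(z), tolerance = 1e-9)
  # identical profiles collapse to zero after centering
  v <- matrix(rep(1:4, 3), 4, 3,
              dimnames = list(paste0("G", 1:4), paste0("S", 1:3)))
  zc <- standardizeTarget(DomainMatrix(v, "target", "continuous"))
  expect_equal(max(abs(exprValues(zc))), 0)
  expect_error(standardizeTarget(tiny_domain_matrix(3, 1)), "two profiles")
})

test_that("the ZINB denoiser optimizes its likelihood and fits degenerate genes", {
  set.seed(8)
  cfg <- simulationConfig(n_genes = 30L, n_source = 150L,
                          n_informative_genes = 10L, seed = 8)
  src <- simulateSource(cfg)
  v <- exprValues(src$dataset)
  v[1, ] <- 0L   # a gene that is always zero
  counts <- SourceDataset(v, stageLabels(src$dataset))
  fit <- fitDenoiser(counts, n_iter = 200L, seed = 1)
  expect_s4_class(fit, "ZINBParams")
  # moving-average loss decreases over training
  sm <- stats::filter(fit@loss, rep(1 / 25, 25), sides = 1)
  sm <- sm[!is.na(sm)]
  expect_lt(tail(sm, 1), head(sm, 1))
  # the all-zero gene reaches near-zero NLL via the dropout mass
  nll_zero <- mean(zinbNLL(0L, fit@mu[1, ], fit@theta[1], fit@pi[1, ]))
  nll_all <- mean(zinbNLL(as.integer(v), fit@mu, fit@theta, fit@pi))
  expect_lt(nll_zero, 0.25 * nll_all)
  expect_error(fitDenoiser(tiny_domain_matrix(3, 4)), "count")
})

test_that("denoised means recover the simulated truth better than raw counts", {
  cfg <- simulationConfig(n_genes = 60L, n_source = 400L,
                          n_informative_genes = 20L, seed = 12)
  src <- simulateSource(cfg)
  # capacity sized to the fixture: the default trunk overfits 400 cells
  fit <- fitDenoiser(src$dataset, hidden = 16L, bottleneck = 8L,
                     n_iter = 400L, seed = 2)
  den <- denoiseCounts(src$dataset, fit)
  expect_identical(dim(exprValues(den)), dim(exprValues(src$dataset)))
  expect_true(all(exprValues(den) > 0))
  truth <- as.vector(src$truth$mu)
  cor_fit <- cor(as.vector(exprValues(den)), truth)
  cor_raw <- cor(as.vector(exprValues(src$dataset)), truth)
  expect_gt(cor_fit, cor_raw)
  mse_fit <- mean((as.vector(exprValues(den)) - truth)^2)
  mse_raw <- mean((as.vector(exprValues(src$dataset)) - truth)^2)
  expect_lt(mse_fit, mse_raw)
})
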