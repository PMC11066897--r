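small_model_cfg <- function(n_genes, seed = 1, ...)
  modelConfig(input_dim = n_genes, encoder_widths = 8L, latent_dim = 4L,
              decoder_widths = 8L, classifier_widths = 6L,
              adversary_widths = 6L, seed = seed, ...)

test_that("train configuration validates", {
  expect_error(trainConfig(batch_size_per_domain = 0), "positive")
  expect_error(trainConfig(lr_min = 0), "learning rates")
  expect_false(trainConfig()$disable_domain_adaptation)
})

test_that("balanced batches draw equal counts from both domains", {
  src <- toy_labeled_source(n_per = 10)
  tgt <- toy_target(n = 25)
  set.seed(1)
  b <- sampleBalancedBatch(src, tgt, 8)
  expect_identical(nrow(b$X_source), 8L)
  expect_identical(nrow(b$X_target), 8L)
  expect_length(b$stages, 8L)
  expect_false(anyDuplicated(b$source_idx) > 0)
  set.seed(1)
  b2 <- sampleBalancedBatch(src, tgt, 8)
  expect_identical(b$source_idx, b2$source_idx)
  expect_warning(sampleBalancedBatch(src, tgt, 60), "replacement")
})

test_that("each phase updates only its own parameter set", {
  src <- toy_labeled_source(n_per = 8, n_genes = 10)
  tgt <- toy_target(n = 40, n_genes = 10)
  m <- dreddaModel(small_model_cfg(10))
  cfg <- trainConfig(batch_size_per_domain = 8)
  set.seed(3)
  batch <- sampleBalancedBatch(src, tgt, 8)
  set.seed(4)
  out_min <- trainStep(m, batch, cfg, phases = "min")
  expect_identical(out_min$model@adversary, m@adversary)
  expect_false(identical(out_min$model@sourceEncoder, m@sourceEncoder))
  expect_false(identical(out_min$model@classifier, m@classifier))
  set.seed(4)
  out_max <- trainStep(m, batch, cfg, phases = "max")
  expect_identical(out_max$model@sourceEncoder, m@sourceEncoder)
  expect_identical(out_max$model@targetEncoder, m@targetEncoder)
  expect_identical(out_max$model@decoder, m@decoder)
  expect_identical(out_max$model@classifier, m@classifier)
  expect_false(identical(out_max$model@adversary, m@adversary))
  # the two phases together touch every module exactly once
  set.seed(4)
  out <- trainStep(m, batch, cfg)
  expect_false(identical(out$model@adversary, m@adversary))
  expect_false(identical(out$model@sourceEncoder, m@sourceEncoder))
})

test_that("disabling domain adaptation reduces to a pure classifier update", {
  src <- toy_labeled_source(n_per = 8, n_genes = 10)
  tgt <- toy_target(n = 40, n_genes = 10)
  m <- dreddaModel(small_model_cfg(10))
  cfg <- trainConfig(batch_size_per_domain = 8,
                     disable_domain_adaptation = TRUE)
  set.seed(5)
  batch <- sampleBalancedBatch(src, tgt, 8)
  set.seed(6)
  out <- trainStep(m, batch, cfg)
  expect_identical(out$model@adversary, m@adversary)
  expect_identical(out$model@targetEncoder, m@targetEncoder)
  expect_identical(out$losses$L_adv, 0)
  expect_identical(out$losses$L_dc, 0)
  expect_equal(out$losses$total, out$losses$L_cls, tolerance = 1e-12)
})

test_that("phase-1 feature updates make a frozen adversary worse", {
  # two shifted domains; adversary pre-trained, then frozen (tiny lr);
  # the -L_adv term must push features toward higher adversary loss
  set.seed(9)
  src <- toy_labeled_source(n_per = 20, n_genes = 6, sep = 1)
  tgt <- toy_target(n = 80, n_genes = 6, shift = 3)
  m <- dreddaModel(small_model_cfg(6, dropout_rate = 0, lambda_dc = 0))
  cfg <- trainConfig(batch_size_per_domain = 40)
  batch <- sampleBalancedBatch(src, tgt, 40)
  state <- NULL
  # let the adversary learn the shift first
  for (i in 1:80) {
    out <- trainStep(m, batch, cfg, state, phases = "max")
    m <- out$model; state <- out$state
  }
  adv_loss <- function(model) {
    Rs <- decodeLatent(model, encodeSamples(model, batch$X_source,
                                            "source"))
    Rt <- decodeLatent(model, encodeSamples(model, batch$X_target,
                                            "target"))
    adversaryLoss(c(classifyDomain(model, Rs), classifyDomain(model, Rt)),
                  c(rep("source", 40), rep("target", 40)))
  }
  before <- adv_loss(m)
  frozen <- trainConfig(batch_size_per_domain = 40, lr_max = 1e-12)
  for (i in 1:40) {
    out <- trainStep(m, batch, frozen, state)
    m <- out$model; state <- out$state
  }
  expect_gt(adv_loss(m), before)
})

test_that("training is bitwise reproducible and logs both accuracies", {
  bench <- small_processed_benchmark(seed = 2, n_genes = 40,
                                     n_source = 200, n_target = 200,
                                     k = 30)
  tc <- trainConfig(n_steps = 60L, eval_every = 30L, seed = 11,
                    batch_size_per_domain = 32L)
  f1 <- fitDredda(bench$source, bench$target,
                  small_model_cfg(30, seed = 11), tc)
  f2 <- fitDredda(bench$source, bench$target,
                  small_model_cfg(30, seed = 11), tc)
  expect_identical(f1$log, f2$log)
  expect_equal(f1$model@classifier, f2$model@classifier)
  expect_true(all(f1$log$main_task_accuracy >= 0 &
                    f1$log$main_task_accuracy <= 1))
  expect_true(all(f1$log$adversarial_accuracy >= 0 &
                    f1$log$adversarial_accuracy <= 1))
  expect_identical(f1$log$step[nrow(f1$log)], 60L)
})

test_that("without DA the classifier trajectory ignores the target values", {
  bench <- small_processed_benchmark(seed = 3, n_genes = 40,
                                     n_source = 200, n_target = 200,
                                     k = 30)
  tc <- trainConfig(n_steps = 40L, eval_every = 20L, seed = 5,
                    batch_size_per_domain = 32L,
                    disable_domain_adaptation = TRUE)
  f1 <- fitDredda(bench$source, bench$target,
                  small_model_cfg(30, seed = 5), tc)
  # scramble the target values entirely (same shape and ids)
  v <- exprValues(bench$target)
  set.seed(99)
  v2 <- matrix(rnorm(length(v), sd = 5), nrow(v), dimnames = dimnames(v))
  target2 <- DomainMatrix(v2, "target", "continuous")
  f2 <- fitDredda(bench$source, target2,
                  small_model_cfg(30, seed = 5), tc)
  expect_identical(f1$model@classifier, f2$model@classifier)
  expect_identical(f1$model@sourceEncoder, f2$model@sourceEncoder)
  expect_identical(f1$log$main_task_accuracy, f2$log$main_task_accuracy)
})

test_that("a trained model classifies separable source stages above prior", {
  bench <- small_processed_benchmark(seed = 4, n_genes = 50,
                                     n_source = 300, n_target = 300,
                                     k = 40, effect_size = 1.5)
  tc <- trainConfig(n_steps = 250L, eval_every = 125L, seed = 7,
                    batch_size_per_domain = 48L)
  fit <- fitDredda(bench$source, bench$target,
                   small_model_cfg(40, seed = 7), tc)
  acc <- evaluateAccuracy(fit$model, "stage", source = bench$source)
  expect_gt(acc, max(bench$config$class_proportions))
  dom <- evaluateAccuracy(fit$model, "domain", source = bench$source,
                          target = bench$target)
  expect_true(dom >= 0 && dom <= 1)
  expect_error(evaluateAccuracy(fit$model, "stage"), "source")
  expect_error(evaluateAccuracy(fit$model, "domain",
                                source = bench$source), "both")
})

test_that("a stand-alone domain classifier separates shifted domains only", {
  set.seed(12)
  a <- matrix(rnorm(3000), nrow = 20)   # genes x samples
  rownames(a) <- paste0("G", 1:20)
  b <- a + 2
  dc <- fitDomainClassifier(a, b, n_steps = 200L, seed = 2)
  expect_gt(dc$holdout_accuracy, 0.9)
  # identical distributions: near-chance accuracy
  b2 <- matrix(rnorm(3000), nrow = 20)
  dc2 <- fitDomainClassifier(a, b2, n_steps = 200L, seed = 2)
  expect_lt(abs(dc2$holdout_accuracy - 0.5), 0.2)
})
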