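#' @include cli.R
NULL

#' Run the full benchmark experiment for one seed
#'
#' One end-to-end evaluation on the synthetic benchmark: simulate both
#' domains, denoise and log-transform the source counts, select genes
#' by mutual information, align and standardize, train the adversarial
#' model and its no-adaptation ablation, score the target profiles
#' with both (snapshot-averaged), score the cosine-signature and
#' random baselines, fit a stand-alone pre-adaptation domain
#' classifier, and measure the 30-NN domain-mixing shift between the
#' unharmonized input space and the adapted decoded space. Recovery of
#' the planted-active profiles is summarized by profile-level AUROC
#' and nDCG@50.
#'
#' @param seed Integer seed driving every stage of this replicate.
#' @param config A \code{\link{simulationConfig}}; defaults to the
#'   standard benchmark (200 genes, 2000 + 2000 samples, effect size
#'   1.0, domain shift 0.5) at this seed.
#' @param k Genes kept by mutual-information selection.
#' @param n_steps Adversarial training steps.
#' @param snapshot_tail Snapshots averaged at scoring time.
#' @param denoiser_iters Mini-batch iterations of the ZINB denoiser.
#' @return A named list of scalar metrics (see Details in the
#'   package vignette).
#' @export
benchmarkExperiment <- function(seed,
                                config = simulationConfig(seed = seed),
                                k = 100L, n_steps = 1500L,
                                snapshot_tail = 12L,
                                denoiser_iters = 400L) {
  src <- simulateSource(config)
  tgt <- simulateTarget(config, src)
  params <- fitDenoiser(src$dataset, n_iter = denoiser_iters,
                        seed = seed)
  den <- logTransform(denoiseCounts(src$dataset, params))
  fs <- selectFeatures(den, k = k)
  aligned <- alignGenes(den[fs@geneIds, ], tgt$matrix)
  S <- standardizeTarget(aligned$source)
  Tm <- standardizeTarget(aligned$target)
  active <- tgt$truth$target_is_active
  active_ids <- sampleIds(Tm)[active]

  profile_metrics <- function(scores) {
    ord <- .order_score_id(scores, sampleIds(Tm))
    c(auroc = aurocScore(scores, active),
      ndcg50 = ndcgAtK(sampleIds(Tm)[ord], active_ids, 50L))
  }

  tc <- function(disable)
    trainConfig(seed = seed, n_steps = n_steps,
                disable_domain_adaptation = disable)
  fit_da <- fitDredda(S, Tm, train_config = tc(FALSE),
                      snapshot_tail = snapshot_tail)
  fit_ab <- fitDredda(S, Tm, train_config = tc(TRUE),
                      snapshot_tail = snapshot_tail)
  m_da <- profile_metrics(
    scoreProfiles(fit_da$snapshots, Tm)$priority_score)
  m_ab <- profile_metrics(
    scoreProfiles(fit_ab$snapshots, Tm)$priority_score)
  m_cos <- profile_metrics(
    gepCosineScore(Tm, buildSignatures(S))$score)
  m_rnd <- profile_metrics(randomScores(ncol(Tm), seed = seed))

  adversary <- fitDomainClassifier(S, Tm, seed = seed)

  before <- rbind(t(exprValues(aligned$source)),
                  t(exprValues(aligned$target)))
  model <- fit_da$model
  after <- rbind(
    decodeLatent(model, encodeSamples(model, t(exprValues(S)),
                                      "source")),
    decodeLatent(model, encodeSamples(model, t(exprValues(Tm)),
                                      "target")))
  domains <- c(rep("source", ncol(S)), rep("target", ncol(Tm)))
  mixing <- compareMixing(before, after, domains, k = 30L)

  final <- utils::tail(fit_da$log, 1L)
  list(main_accuracy = final$main_task_accuracy,
       adversarial_accuracy = final$adversarial_accuracy,
       standalone_adversary_accuracy = adversary$holdout_accuracy,
       mixing_before_median = stats::median(mixing$before),
       mixing_after_median = stats::median(mixing$after),
       auroc_da = unname(m_da["auroc"]),
       ndcg50_da = unname(m_da["ndcg50"]),
       auroc_noda = unname(m_ab["auroc"]),
       ndcg50_noda = unname(m_ab["ndcg50"]),
       auroc_cos = unname(m_cos["auroc"]),
       ndcg50_cos = unname(m_cos["ndcg50"]),
       auroc_random = unname(m_rnd["auroc"]),
       ndcg50_random = unname(m_rnd["ndcg50"]))
}

#' Denoiser and feature-selection recovery experiment
#'
#' Simulates a source dataset, fits the ZINB denoiser and checks (a)
#' how much better the fitted means correlate with the true simulated
#' means than the raw counts do, and (b) whether mutual-information
#' selection recovers the planted informative genes at a strong effect
#' size.
#'
#' @param seed Integer seed.
#' @param config Simulation configuration; default uses effect size 2
#'   at benchmark gene/cell counts.
#' @param denoiser_iters Denoiser iterations.
#' @return A named list: correlations of denoised/raw values with the
#'   true means, the number of informative genes, and how many of them
#'   fall inside the top \code{2 * n_informative_genes} MI selection.
#' @export
recoveryExperiment <- function(seed,
                               config = simulationConfig(
                                 effect_size = 2, seed = seed),
                               denoiser_iters = 400L) {
  src <- simulateSource(config)
  params <- fitDenoiser(src$dataset, n_iter = denoiser_iters,
                        seed = seed)
  truth <- as.vector(src$truth$mu)
  den <- logTransform(denoiseCounts(src$dataset, params))
  fs <- selectFeatures(den, k = 2L * config$n_informative_genes)
  list(cor_denoised = stats::cor(as.vector(params@mu), truth),
       cor_raw = stats::cor(as.vector(exprValues(src$dataset)), truth),
       n_informative = length(src$truth$informative_genes),
       n_recovered = sum(src$truth$informative_genes %in% fs@geneIds))
}
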