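#' @include AllClasses.R synthetic_data.R training.R scoring.R
NULL

#' Uniform random baseline scores
#'
#' @param n_items Number of items.
#' @param seed Seed.
#' @return \code{n_items} i.i.d. Uniform(0,1) scores.
#' @export
randomScores <- function(n_items, seed = 1L) {
  if (n_items < 1L) stop("n_items must be >= 1")
  set.seed(seed)
  stats::runif(n_items)
}

#' Build per-stage expression signatures from the source domain
#'
#' Per-stage centroids of the (preprocessed, log-scale) source
#' expression, the differential signatures (centroid minus grand
#' mean over all cells), their unit-norm versions, and the top-N gene
#' sets by absolute differential value (lexicographic tie-break).
#'
#' @param source A continuous \linkS4class{SourceDataset}.
#' @param top_n Size of the per-stage top gene sets (default 50,
#'   capped at the number of genes).
#' @return A \linkS4class{SignatureSet}.
#' @export
buildSignatures <- function(source, top_n = 50L) {
  v <- exprValues(source)
  st <- stageLabels(source)
  stages <- differentiationStages()
  sizes <- table(st)
  if (any(sizes == 0L))
    stop("stage(s) with zero cells: ",
         paste(names(sizes)[sizes == 0L], collapse = ", "))
  grand <- rowMeans(v)
  centroids <- vapply(stages, function(s)
    rowMeans(v[, st == s, drop = FALSE]), numeric(nrow(v)))
  diffs <- centroids - grand
  units <- apply(diffs, 2L, function(d) d / sqrt(sum(d^2)))
  n <- min(top_n, nrow(v))
  tops <- lapply(stages, function(s) {
    ord <- .order_score_id(abs(diffs[, s]), geneIds(source))
    geneIds(source)[ord[seq_len(n)]]
  })
  names(tops) <- stages
  new("SignatureSet", stages = stages, centroids = centroids,
      differentials = diffs, unitDifferentials = units,
      topSets = tops, topN = as.integer(n))
}

#' Cosine similarity of two vectors
#'
#' @param u,v Non-zero numeric vectors of equal length.
#' @return Cosine in [-1, 1].
#' @export
cosineSimilarity <- function(u, v) {
  if (length(u) != length(v)) stop("vectors must have equal length")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("cosine undefined for the zero vector")
  sum(u * v) / (nu * nv)
}

#' Cosine-similarity baseline against the stage signatures
#'
#' For each profile computes the cosine similarity to the four stage
#' signatures. \code{mode = "mean_all"} returns the average over the
#' four stages (the ranking score); \code{mode = "argmax"} returns the
#' best-matching stage (the 4-state classification used for the
#' diversity comparison).
#'
#' @param profiles Genes x profiles matrix or
#'   \linkS4class{DomainMatrix} on the signatures' gene space.
#' @param signatures A \linkS4class{SignatureSet}.
#' @param mode \code{"mean_all"} or \code{"argmax"}.
#' @param signature_type \code{"differential"} (default; appropriate
#'   for differential target profiles) or \code{"centroid"}.
#' @return A \code{data.frame} with per-profile \code{score} and
#'   \code{stage}.
#' @export
gepCosineScore <- function(profiles, signatures,
                           mode = c("mean_all", "argmax"),
                           signature_type = c("differential",
                                              "centroid")) {
  mode <- match.arg(mode)
  signature_type <- match.arg(signature_type)
  v <- if (is(profiles, "DomainMatrix")) exprValues(profiles) else
    as.matrix(profiles)
  S <- if (signature_type == "differential") signatures@unitDifferentials
  else signatures@centroids
  if (nrow(v) != nrow(S)) stop("gene space mismatch with the signatures")
  cs <- vapply(seq_len(ncol(v)), function(j)
    vapply(seq_len(ncol(S)), function(c)
      cosineSimilarity(v[, j], S[, c]), numeric(1L)),
    numeric(ncol(S)))
  cs <- t(cs)                                 # profiles x stages
  colnames(cs) <- signatures@stages
  data.frame(
    sample_id = colnames(v),
    score = if (mode == "mean_all") rowMeans(cs) else
      apply(cs, 1L, max),
    stage = signatures@stages[max.col(cs, ties.method = "first")],
    stringsAsFactors = FALSE)
}

#' Jaccard-similarity baseline on top differential genes
#'
#' Takes each profile's top genes by absolute value (same set size as
#' the signatures' top sets, lexicographic tie-break) and averages the
#' Jaccard similarity with the four per-stage top sets.
#'
#' @inheritParams gepCosineScore
#' @return Numeric vector of scores in [0, 1], one per profile.
#' @export
gepJaccardScore <- function(profiles, signatures) {
  v <- if (is(profiles, "DomainMatrix")) exprValues(profiles) else
    as.matrix(profiles)
  gid <- rownames(v)
  if (!identical(gid, rownames(signatures@differentials)))
    stop("gene space mismatch with the signatures")
  n <- signatures@topN
  vapply(seq_len(ncol(v)), function(j) {
    ord <- .order_score_id(abs(v[, j]), gid)
    top <- gid[ord[seq_len(n)]]
    mean(vapply(signatures@topSets, function(s)
      length(intersect(top, s)) / length(union(top, s)), numeric(1L)))
  }, numeric(1L))
}

#' Single-sample gene-set enrichment (ssGSEA) pathway activations
#'
#' Per profile, genes are ranked by decreasing value (lexicographic
#' tie-break); each set's enrichment score is the running-sum
#' difference between the rank-weighted ECDF of in-set genes (weights
#' \eqn{|x|^\alpha} at the gene's value) and the uniform ECDF of
#' out-of-set genes, summed over the whole ranking. Scores are
#' optionally normalized by the global score range. Sets with no
#' overlap with the gene universe yield \code{NA} with a warning.
#'
#' @param profiles Genes x profiles matrix or
#'   \linkS4class{DomainMatrix}.
#' @param sets Named list of gene-id character vectors.
#' @param alpha Rank weight exponent (default 0.25).
#' @param normalize Divide all scores by the overall max - min range
#'   (default TRUE).
#' @return Sets x profiles matrix of pathway activations.
#' @export
ssgseaScores <- function(profiles, sets, alpha = 0.25,
                         normalize = TRUE) {
  v <- if (is(profiles, "DomainMatrix")) exprValues(profiles) else
    as.matrix(profiles)
  gid <- rownames(v)
  if (is.null(names(sets)) || !length(sets))
    stop("sets must be a non-empty named list")
  overlap <- vapply(sets, function(s) length(intersect(s, gid)), 1L)
  if (any(overlap == 0L))
    warning("set(s) with no overlap flagged NA: ",
            paste(names(sets)[overlap == 0L], collapse = ", "))
  G <- nrow(v)
  out <- matrix(NA_real_, length(sets), ncol(v),
                dimnames = list(names(sets), colnames(v)))
  for (j in seq_len(ncol(v))) {
    ord <- .order_score_id(v[, j], gid)      # decreasing value
    ranked_genes <- gid[ord]
    w_all <- abs(v[ord, j])^alpha
    for (k in seq_along(sets)) {
      if (overlap[k] == 0L) next
      inset <- ranked_genes %in% sets[[k]]
      w <- w_all * inset
      p_in <- cumsum(w) / sum(w)
      p_out <- cumsum(!inset) / (G - sum(inset))
      out[k, j] <- sum(p_in - p_out)
    }
  }
  if (normalize && any(is.finite(out))) {
    rng <- range(out, na.rm = TRUE)
    if (diff(rng) > 0) out <- out / diff(rng)
  }
  out
}

#' Cosine similarity in pathway-activation space
#'
#' @param profile_pa Pathway-activation vector (or sets x profiles
#'   matrix) of the profile(s).
#' @param signature_pa Pathway-activation vector of one signature, or
#'   a sets x stages matrix of the four stage signatures (the result
#'   is then the average cosine over stages).
#' @return Numeric score(s).
#' @export
paCosineScore <- function(profile_pa, signature_pa) {
  P <- if (is.matrix(profile_pa)) profile_pa else
    matrix(profile_pa, ncol = 1L)
  S <- if (is.matrix(signature_pa)) signature_pa else
    matrix(signature_pa, ncol = 1L)
  if (nrow(P) != nrow(S)) stop("pathway spaces differ")
  scores <- vapply(seq_len(ncol(P)), function(j)
    mean(vapply(seq_len(ncol(S)), function(c)
      cosineSimilarity(P[, j], S[, c]), numeric(1L))), numeric(1L))
  if (ncol(P) == 1L) scores[[1L]] else scores
}

#' Run the no-domain-adaptation ablation end to end
#'
#' Trains the model with adversarial training and domain confusion
#' disabled (pure source classifier) and scores the target profiles
#' with it — the "without DA" comparison arm.
#'
#' @inheritParams fitDredda
#' @param metadata Optional profile metadata for the score table.
#' @param score_mode Passed to \code{\link{scoreProfiles}}.
#' @return A list with \code{model}, \code{log} and \code{scores}.
#' @export
runAblation <- function(source, target, model_config = NULL,
                        train_config = trainConfig(),
                        metadata = NULL,
                        score_mode = "terminal") {
  train_config$disable_domain_adaptation <- TRUE
  fit <- fitDredda(source, target, model_config, train_config)
  scores <- scoreProfiles(fit$model, target, metadata = metadata,
                          score_mode = score_mode)
  list(model = fit$model, log = fit$log, scores = scores)
}

#' Read / write gene-set collections in GMT format
#'
#' Reading delegates to \code{fgsea::gmtPathways}; writing emits the
#' standard three-plus-column tab format (name, description, genes).
#'
#' @param path GMT file path.
#' @return \code{readGMT}: named list of gene-id vectors.
#' @export
readGMT <- function(path) {
  fgsea::gmtPathways(path)
}

#' @rdname readGMT
#' @param sets Named list of gene-id vectors.
#' @export
writeGMT <- function(sets, path) {
  if (is.null(names(sets))) stop("sets must be named")
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}
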