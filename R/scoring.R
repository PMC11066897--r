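#' @include AllClasses.R model_core.R
NULL

#' Scalarize stage probabilities into a priority score
#'
#' \code{"terminal"} (default): the probability of the most
#' differentiated stage (late primed). \code{"ordinal"}: the expected
#' stage index under the ordered vocabulary, rescaled to [0, 1].
#'
#' @param probabilities A 4-vector on the simplex, or a samples x 4
#'   matrix.
#' @param score_mode \code{"terminal"} or \code{"ordinal"}.
#' @return Numeric score(s) in [0, 1].
#' @export
#' @examples
#' priorityScore(c(0.25, 0.25, 0.25, 0.25))              # 0.25
#' priorityScore(c(0.25, 0.25, 0.25, 0.25), "ordinal")   # 0.5
priorityScore <- function(probabilities,
                          score_mode = c("terminal", "ordinal")) {
  score_mode <- match.arg(score_mode)
  P <- if (is.matrix(probabilities)) probabilities else
    matrix(probabilities, nrow = 1L)
  if (ncol(P) != 4L) stop("probabilities must have four classes")
  if (any(P < -1e-9) || any(abs(rowSums(P) - 1) > 1e-6))
    stop("rows must lie on the probability simplex")
  out <- if (score_mode == "terminal") P[, 4L] else
    as.vector(P %*% (0:3)) / 3
  unname(out)
}

#' Score target profiles with the trained model
#'
#' Routes every profile through the target encoder and shared decoder
#' and reads the stage classifier's probabilities; the scalar priority
#' score (\code{\link{priorityScore}}) rates how strongly a profile
#' expresses the learned differentiation signature.
#'
#' @param model A trained \linkS4class{DreddaModel}, or a list of
#'   snapshot models (see \code{\link{fitDredda}}); for a list the
#'   per-profile probabilities are averaged over the snapshots, which
#'   damps the oscillation inherent to adversarial optimization.
#' @param target A \linkS4class{DomainMatrix} aligned to the model's
#'   gene space.
#' @param metadata Optional profile metadata \code{data.frame} with a
#'   \code{sample_id} column; matching columns are carried into the
#'   result.
#' @param score_mode Passed to \code{\link{priorityScore}}.
#' @return A \code{data.frame} with one row per profile: sample id,
#'   the four stage probabilities, the predicted stage, the priority
#'   score and any metadata.
#' @export
scoreProfiles <- function(model, target, metadata = NULL,
                          score_mode = c("terminal", "ordinal")) {
  score_mode <- match.arg(score_mode)
  models <- if (is(model, "DreddaModel")) list(model) else model
  stopifnot(length(models) > 0L,
            all(vapply(models, is, TRUE, "DreddaModel")))
  X <- t(exprValues(target))
  if (ncol(X) != models[[1L]]@config$input_dim)
    stop("target gene space does not match the model; align first")
  P <- Reduce(`+`, lapply(models, function(m)
    classifyStage(m, decodeLatent(m, encodeSamples(m, X, "target"))))) /
    length(models)
  out <- data.frame(sample_id = sampleIds(target),
                    stringsAsFactors = FALSE)
  probs <- as.data.frame(P)
  colnames(probs) <- paste0("p_", differentiationStages())
  out <- cbind(out, probs)
  out$predicted_stage <- colnames(P)[max.col(P, ties.method = "first")]
  out$priority_score <- priorityScore(P, score_mode)
  if (!is.null(metadata)) {
    m <- match(out$sample_id, metadata$sample_id)
    if (anyNA(m)) stop("metadata is missing sample(s): ",
                       paste(utils::head(out$sample_id[is.na(m)], 3L),
                             collapse = ", "))
    extra <- setdiff(colnames(metadata), "sample_id")
    out[extra] <- metadata[m, extra, drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Aggregate per-profile scores to a ranked drug table
#'
#' Each compound's profiles are reduced with \code{method}; compounds
#' are then dense-ranked by decreasing score (ties share a rank), with
#' a deterministic secondary sort by compound id.
#'
#' @param scores A score table from \code{\link{scoreProfiles}} (or any
#'   \code{data.frame} with \code{compound_id} and a score column).
#' @param method \code{"max"} (default), \code{"mean"} or
#'   \code{"median"}.
#' @param score_column Column to aggregate.
#' @return A \code{data.frame} with columns \code{rank},
#'   \code{compound_id}, \code{score}, \code{n_profiles}, sorted by
#'   rank then compound id.
#' @export
aggregateByDrug <- function(scores, method = c("max", "mean", "median"),
                            score_column = "priority_score") {
  method <- match.arg(method)
  if (!"compound_id" %in% colnames(scores))
    stop("scores must carry compound_id metadata")
  if (!score_column %in% colnames(scores))
    stop("no column called ", score_column)
  f <- switch(method, max = max, mean = mean, median = stats::median)
  sp <- split(scores[[score_column]], scores$compound_id)
  agg <- data.frame(compound_id = names(sp),
                    score = vapply(sp, f, numeric(1L)),
                    n_profiles = lengths(sp),
                    stringsAsFactors = FALSE)
  agg <- agg[order(-agg$score, agg$compound_id, method = "radix"), ]
  agg$rank <- match(-agg$score, sort(unique(-agg$score)))  # dense ranks
  rownames(agg) <- NULL
  agg[, c("rank", "compound_id", "score", "n_profiles")]
}

#' Write / read a drug ranking TSV
#'
#' @param table A ranking from \code{\link{aggregateByDrug}}.
#' @param path TSV path.
#' @return \code{readRanking}: the ranking \code{data.frame}.
#' @export
exportRanking <- function(table, path) {
  stopifnot(all(c("rank", "compound_id", "score", "n_profiles") %in%
                  colnames(table)))
  data.table::fwrite(table, path, sep = "\t")
  invisible(path)
}

#' @rdname exportRanking
#' @export
readRanking <- function(path) {
  data.table::fread(path, data.table = FALSE,
                    colClasses = list(character = "compound_id"))
}
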