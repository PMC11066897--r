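#' @include AllClasses.R
NULL

.check_ranked <- function(l, s) {
  if (anyDuplicated(l)) stop("ranked list contains duplicates")
  if (!length(s)) stop("target set is empty")
  missing <- setdiff(s, l)
  if (length(missing))
    stop("target item(s) absent from the ranked list: ",
         paste(utils::head(missing, 3L), collapse = ", "))
}

#' Mean reciprocal rank of a target set in a ranked list
#'
#' Averages the reciprocal rank of every member of the target set
#' \code{s} within the ordered list \code{l}:
#' \eqn{\mathrm{MRR} = |s|^{-1} \sum_i 1/\mathrm{rank}(l, s_i)}.
#' Note this averages over all target items, not only the first hit.
#'
#' @param l Ordered character vector of unique item ids.
#' @param s Target set (must be contained in \code{l}).
#' @return MRR in (0, 1].
#' @export
#' @examples
#' meanReciprocalRank(letters[1:10], c("b", "d"))  # (1/2 + 1/4) / 2
meanReciprocalRank <- function(l, s) {
  .check_ranked(l, s)
  mean(1 / match(s, l))
}

#' Discounted cumulative gain at cutoff K (indicator gains)
#'
#' \eqn{\mathrm{DCG}@K = \sum_{i \le K} [l_i \in s] / \log_2(i + 1)}.
#' A cutoff beyond the list length is truncated with a message.
#'
#' @param l Ordered character vector of unique item ids.
#' @param s Target set.
#' @param K Cutoff (positive integer).
#' @return Non-negative DCG.
#' @export
dcgAtK <- function(l, s, K) {
  .check_ranked(l, s)
  if (K < 1) stop("K must be >= 1")
  if (K > length(l)) {
    message("K exceeds list length; truncating to ", length(l))
    K <- length(l)
  }
  i <- seq_len(K)
  sum((l[i] %in% s) / log2(i + 1))
}

#' Ideal DCG at cutoff K
#'
#' DCG of the reordered list with all target items packed at the top:
#' \eqn{\sum_{i \le \min(K, |s|)} 1/\log_2(i+1)}. Independent of the
#' ranked list itself.
#'
#' @param s Target set.
#' @param K Cutoff.
#' @return Positive ideal DCG.
#' @export
idcgAtK <- function(s, K) {
  if (!length(s)) stop("target set is empty")
  if (K < 1) stop("K must be >= 1")
  i <- seq_len(min(K, length(s)))
  sum(1 / log2(i + 1))
}

#' Normalized DCG at cutoff K
#'
#' @inheritParams dcgAtK
#' @return \code{dcgAtK(l, s, K) / idcgAtK(s, K)}, in [0, 1].
#' @export
ndcgAtK <- function(l, s, K) dcgAtK(l, s, K) / idcgAtK(s, K)

#' Compute the full IR report for a ranking
#'
#' @param l Ordered item ids.
#' @param s Target set.
#' @param ndcg_cutoffs Cutoffs for nDCG (default 50, 100, 150, 200).
#' @return A list with \code{mrr} and \code{ndcg_at} (named vector).
#' @export
irReport <- function(l, s, ndcg_cutoffs = c(50L, 100L, 150L, 200L)) {
  nd <- vapply(ndcg_cutoffs, function(K) ndcgAtK(l, s, K), numeric(1L))
  names(nd) <- paste0("ndcg@", ndcg_cutoffs)
  list(mrr = meanReciprocalRank(l, s), ndcg_at = nd)
}

#' Prediction diversity of stage assignments
#'
#' Entropy of the empirical frequencies of the predicted labels,
#' normalized by the maximum entropy of a four-class distribution
#' (the base cancels in the ratio).
#'
#' @param predicted_labels Character/factor vector of predicted stages.
#' @param n_classes Number of classes in the normalizer (default 4).
#' @return Diversity in [0, 1].
#' @export
#' @examples
#' predictionDiversity(rep(differentiationStages(), 5))  # 1
predictionDiversity <- function(predicted_labels, n_classes = 4L) {
  if (!length(predicted_labels)) stop("empty input")
  p <- table(as.character(predicted_labels))
  p <- p / sum(p)
  p <- p[p > 0]
  as.numeric(-sum(p * log(p)) / log(n_classes))
}

#' Fraction of source-domain points among the k nearest neighbours
#'
#' For every row of the query domain, finds its \code{k} Euclidean
#' nearest neighbours among all rows (self excluded, ties broken by
#' row index) and reports the fraction carrying the source tag. A high
#' per-target fraction means the two domains are well mixed in the
#' embedding.
#'
#' @param embedding Samples x features matrix.
#' @param domains Character vector of \code{"source"}/\code{"target"}
#'   per row.
#' @param k Neighbourhood size (default 30).
#' @param query_domain Which rows to query (default \code{"target"}).
#' @return Named vector of per-query source fractions in [0, 1].
#' @export
knnSourceFraction <- function(embedding, domains, k = 30L,
                              query_domain = c("target", "source")) {
  query_domain <- match.arg(query_domain)
  embedding <- as.matrix(embedding)
  n <- nrow(embedding)
  if (length(domains) != n) stop("one domain tag per row is required")
  if (k >= n) stop("k must be smaller than the number of rows")
  is_source <- domains == "source"
  queries <- which(domains == query_domain)
  sq <- rowSums(embedding^2)
  out <- numeric(length(queries))
  # cross-distance computation in blocks keeps memory bounded
  block <- max(1L, floor(2e6 / n))
  for (start in seq(1L, length(queries), by = block)) {
    ix <- queries[seq(start, min(start + block - 1L, length(queries)))]
    D2 <- outer(sq[ix], sq, "+") - 2 * tcrossprod(
      embedding[ix, , drop = FALSE], embedding)
    for (j in seq_along(ix)) {
      d <- D2[j, ]
      d[ix[j]] <- Inf                       # exclude self
      nb <- order(d, seq_len(n), method = "radix")[seq_len(k)]
      out[start + j - 1L] <- mean(is_source[nb])
    }
  }
  names(out) <- rownames(embedding)[queries]
  out
}

#' Compare domain mixing before and after adaptation
#'
#' Computes \code{\link{knnSourceFraction}} in two embeddings of the
#' same samples and summarizes the change. A positive median shift
#' means target profiles gained source-domain neighbours, i.e. the
#' domains became better mixed.
#'
#' @param before,after Samples x features matrices (same rows).
#' @param domains Per-row domain tags shared by both embeddings.
#' @param k Neighbourhood size.
#' @param query_domain Rows to query.
#' @return A list with \code{before} and \code{after} per-query
#'   fraction vectors and \code{median_shift}.
#' @export
compareMixing <- function(before, after, domains, k = 30L,
                          query_domain = "target") {
  if (!identical(nrow(as.matrix(before)), nrow(as.matrix(after))))
    stop("embeddings must describe the same rows")
  fb <- knnSourceFraction(before, domains, k, query_domain)
  fa <- knnSourceFraction(after, domains, k, query_domain)
  list(before = fb, after = fa,
       median_shift = stats::median(fa - fb))
}

#' Rank-based AUROC of a score for a binary truth
#'
#' Probability that a randomly chosen positive outscores a randomly
#' chosen negative (ties count half), computed from rank sums.
#'
#' @param scores Numeric scores.
#' @param truth Logical vector (TRUE = positive).
#' @return AUROC in [0, 1].
#' @export
aurocScore <- function(scores, truth) {
  truth <- as.logical(truth)
  np <- sum(truth); nn <- sum(!truth)
  if (!np || !nn) stop("need both positives and negatives")
  r <- rank(scores)
  (sum(r[truth]) - np * (np + 1) / 2) / (np * nn)
}
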