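#' @include AllClasses.R nn.R
NULL

#' Zero-inflated negative binomial negative log-likelihood
#'
#' Per-observation NLL of the ZINB mixture
#' \eqn{-\log[\pi 1\{x=0\} + (1-\pi)\,\mathrm{NB}(x;\mu,\theta)]},
#' where \eqn{\mathrm{NB}} is the negative binomial with mean
#' \eqn{\mu} and dispersion (size) \eqn{\theta}. Vectorized over all
#' arguments with the usual recycling.
#'
#' @param x Non-negative integer counts.
#' @param mu Strictly positive means.
#' @param theta Strictly positive dispersions.
#' @param pi Dropout probabilities in [0, 1].
#' @return Non-negative NLL values (finite whenever \code{pi < 1} or
#'   \code{x = 0}).
#' @export
#' @examples
#' zinbNLL(0, mu = 1, theta = 1, pi = 0)  # log(2)
zinbNLL <- function(x, mu, theta, pi = 0) {
  if (any(x < 0) || any(x != round(x))) stop("x must be non-negative integers")
  if (any(mu <= 0)) stop("mu must be strictly positive")
  if (any(theta <= 0)) stop("theta must be strictly positive")
  if (any(pi < 0 | pi > 1)) stop("pi must lie in [0, 1]")
  lnb <- stats::dnbinom(x, size = theta, mu = mu, log = TRUE)
  n <- max(length(x), length(mu), length(theta), length(pi))
  x <- rep_len(x, n); pi <- rep_len(pi, n); lnb <- rep_len(lnb, n)
  out <- -(log1p(-pi) + lnb)  # x > 0 branch
  z <- x == 0
  if (any(z))
    out[z] <- -log(pi[z] + exp(log1p(-pi[z]) + lnb[z]))
  out
}

#' Fit the ZINB denoising autoencoder to a count matrix
#'
#' A small encoder--decoder network with three output heads — mean
#' \eqn{M} (per entry), dropout \eqn{\pi} (per entry) and a free
#' per-gene dispersion \eqn{\theta} — trained full-batch with Adam to
#' minimize the mean \code{\link{zinbNLL}} over all matrix entries.
#' The input presented to the network is the per-gene standardized
#' \code{log1p} of the counts; the likelihood is evaluated on the raw
#' counts. The estimated mean \eqn{M} is the denoised expression
#' matrix.
#'
#' @param counts A \linkS4class{DomainMatrix} (or
#'   \linkS4class{SourceDataset}) with \code{valueKind = "counts"}.
#' @param hidden,bottleneck Layer widths of the encoder/decoder trunk.
#' @param n_iter Number of mini-batch Adam iterations.
#' @param batch_size Cells per mini-batch (capped at the number of
#'   cells).
#' @param lr Learning rate.
#' @param seed Seed for parameter initialization and batch order.
#' @return A \linkS4class{ZINBParams} with the fitted \code{mu},
#'   \code{theta}, \code{pi} and the training-loss trace (per-batch
#'   mean NLL).
#' @export
fitDenoiser <- function(counts, hidden = 32L, bottleneck = 16L,
                        n_iter = 400L, batch_size = 256L, lr = 1e-2,
                        seed = 1L) {
  if (!is(counts, "DomainMatrix")) stop("counts must be a DomainMatrix")
  if (valueKind(counts) != "counts")
    stop("the denoiser requires integer count data")
  X <- t(exprValues(counts))            # cells x genes
  G <- ncol(X); n <- nrow(X)
  inp <- log1p(X)
  mu0 <- colMeans(inp); sd0 <- pmax(apply(inp, 2L, stats::sd), 1e-6)
  inp <- sweep(sweep(inp, 2L, mu0), 2L, sd0, "/")

  set.seed(seed)
  trunk <- .nn_init_stack(c(G, hidden, bottleneck, hidden))
  head_mu <- .nn_init_stack(c(hidden, G))
  head_pi <- .nn_init_stack(c(hidden, G))
  # start near the marginal solution: mean head at per-gene log-means,
  # low dropout, moderate dispersion
  head_mu[[1L]]$b <- log(colMeans(X) + 1e-3)
  head_pi[[1L]]$b <- rep(-2, G)
  ltheta <- rep(log(1), G)

  st_trunk <- .adam_init(trunk)
  st_mu <- .adam_init(head_mu)
  st_pi <- .adam_init(head_pi)
  st_th <- list(m = ltheta * 0, v = ltheta * 0)
  loss_trace <- numeric(n_iter)
  bs <- min(batch_size, n)

  for (it in seq_len(n_iter)) {
    ix <- sample.int(n, bs)
    Xb <- X[ix, , drop = FALSE]
    fw <- .nn_forward(trunk, inp[ix, , drop = FALSE])
    Hmask <- fw$out > 0
    H <- fw$out * Hmask
    fw_mu <- .nn_forward(head_mu, H)
    fw_pi <- .nn_forward(head_pi, H)
    am <- pmin(pmax(fw_mu$out, -10), 10)
    M <- exp(am)
    P <- .sigmoid(fw_pi$out)
    TH <- matrix(exp(ltheta), bs, G, byrow = TRUE)

    lnb <- stats::dnbinom(Xb, size = TH, mu = M, log = TRUE)
    z <- Xb == 0
    Lmix <- P * z + (1 - P) * exp(lnb)
    loss_trace[it] <- mean(-log(Lmix + 1e-300))

    # d(NLL)/d(log NB) and d(NLL)/d(pi), entrywise
    dlnb <- -(1 - P) * exp(lnb) / (Lmix + 1e-300)
    dpi <- -(z - exp(lnb)) / (Lmix + 1e-300)
    # chain rule into heads, scaled for the mean batch loss
    N <- length(Xb)
    dlogm <- dlnb * (Xb - (Xb + TH) * M / (TH + M)) / N
    dlogm[am <= -10 | am >= 10] <- 0
    dzpi <- dpi * P * (1 - P) / N
    dltheta_mat <- dlnb * TH *
      (digamma(Xb + TH) - digamma(TH) + log(TH / (TH + M)) +
         (M - Xb) / (TH + M)) / N
    dltheta <- colSums(dltheta_mat)

    bk_mu <- .nn_backward(head_mu, fw_mu, dlogm)
    bk_pi <- .nn_backward(head_pi, fw_pi, dzpi)
    dH <- (bk_mu$dX + bk_pi$dX) * Hmask
    bk_tr <- .nn_backward(trunk, fw, dH)

    up <- .adam_step(trunk, bk_tr$grads, st_trunk, lr, it)
    trunk <- up$layers; st_trunk <- up$state
    up <- .adam_step(head_mu, bk_mu$grads, st_mu, lr, it)
    head_mu <- up$layers; st_mu <- up$state
    up <- .adam_step(head_pi, bk_pi$grads, st_pi, lr, it)
    head_pi <- up$layers; st_pi <- up$state
    up <- .adam_vec_step(ltheta, dltheta, st_th, lr, it)
    ltheta <- up$x; st_th <- up$state
  }

  fw <- .nn_forward(trunk, inp)
  H <- pmax(fw$out, 0)
  M <- exp(pmin(pmax(.nn_forward(head_mu, H)$out, -10), 10))
  P <- .sigmoid(.nn_forward(head_pi, H)$out)
  mu <- t(M); piM <- t(P)
  dimnames(mu) <- dimnames(exprValues(counts))
  dimnames(piM) <- dimnames(mu)
  new("ZINBParams", mu = mu,
      theta = stats::setNames(exp(ltheta), rownames(mu)),
      pi = piM, loss = loss_trace)
}

#' Denoise counts with fitted ZINB parameters
#'
#' Returns the estimated ZINB mean matrix \eqn{M} as the denoised
#' version of the count matrix, as a continuous
#' \linkS4class{DomainMatrix} (stage labels are preserved for
#' \linkS4class{SourceDataset} input).
#'
#' @param counts The count matrix the parameters were fitted to.
#' @param params A \linkS4class{ZINBParams}.
#' @return A continuous object of the same class as \code{counts}.
#' @export
denoiseCounts <- function(counts, params) {
  stopifnot(is(params, "ZINBParams"))
  if (!identical(dim(params@mu), dim(exprValues(counts))))
    stop("parameter shape does not match the count matrix")
  replaceValues(counts, params@mu, valueKind = "continuous")
}

#' Elementwise log(x + eps) transform
#'
#' @param x A \linkS4class{DomainMatrix} (any subclass) or numeric
#'   matrix with non-negative entries.
#' @param eps Positive offset guarding against log(0); default 1e-5.
#' @return Same class as the input, natural-log transformed.
#' @export
logTransform <- function(x, eps = 1e-5) {
  stopifnot(eps > 0)
  v <- if (is(x, "DomainMatrix")) exprValues(x) else x
  if (any(v < 0)) stop("log transform requires non-negative values")
  lg <- log(v + eps)
  if (is(x, "DomainMatrix"))
    replaceValues(x, lg, valueKind = "continuous")
  else lg
}

#' Plug-in mutual information between a gene and categorical labels
#'
#' The gene's values are discretized into (at most) \code{n_bins}
#' equal-frequency bins; MI with the labels is computed from the joint
#' empirical table, in bits.
#'
#' @param gene_values Numeric vector.
#' @param labels Categorical vector of the same length.
#' @param n_bins Maximum number of quantile bins (default 32).
#' @return Non-negative MI in bits.
#' @export
mutualInformation <- function(gene_values, labels, n_bins = 32L) {
  n <- length(gene_values)
  if (n < 2L || length(labels) != n)
    stop("need >= 2 paired observations")
  qs <- stats::quantile(gene_values,
                        probs = seq(0, 1, length.out = n_bins + 1L),
                        names = FALSE, type = 1L)
  interior <- unique(qs[-c(1L, n_bins + 1L)])
  if (!length(interior)) return(0)   # constant gene
  bins <- findInterval(gene_values, interior, left.open = TRUE)
  tab <- table(bins, as.character(labels))
  p <- tab / n
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / outer(px, py)[nz]))
}

#' Select the top-k genes by mutual information with stage labels
#'
#' Computes \code{\link{mutualInformation}} between every gene of a
#' preprocessed (denoised, log-transformed) source dataset and the
#' stage labels, and returns the \code{k} genes with the highest MI;
#' ties are broken lexicographically by gene identifier.
#'
#' @param source A \linkS4class{SourceDataset} with continuous values.
#' @param k Number of genes to keep (default 1000; capped at the number
#'   of genes available).
#' @param n_bins Bins for the MI estimator.
#' @return A \linkS4class{FeatureSelection}.
#' @export
selectFeatures <- function(source, k = 1000L, n_bins = 32L) {
  if (k <= 0) stop("k must be positive")
  v <- exprValues(source)
  labels <- stageLabels(source)
  mi <- apply(v, 1L, mutualInformation, labels = labels, n_bins = n_bins)
  mi <- pmax(mi, 0)
  ord <- .order_score_id(mi, geneIds(source))
  keep <- ord[seq_len(min(k, length(ord)))]
  new("FeatureSelection", geneIds = geneIds(source)[keep],
      miScores = stats::setNames(mi, geneIds(source)),
      k = as.integer(k))
}

#' Serialize / load a FeatureSelection as two-column TSV
#'
#' @param fs A \linkS4class{FeatureSelection}.
#' @param path TSV path (columns \code{gene_id}, \code{mi_bits};
#'   selected genes in rank order).
#' @return \code{readFeatureSelection}: a
#'   \linkS4class{FeatureSelection} limited to the serialized genes.
#' @export
writeFeatureSelection <- function(fs, path) {
  data.table::fwrite(
    data.frame(gene_id = fs@geneIds,
               mi_bits = unname(fs@miScores[fs@geneIds])),
    path, sep = "\t")
  invisible(path)
}

#' @rdname writeFeatureSelection
#' @export
readFeatureSelection <- function(path) {
  df <- data.table::fread(path, data.table = FALSE)
  new("FeatureSelection", geneIds = as.character(df$gene_id),
      miScores = stats::setNames(df$mi_bits, df$gene_id),
      k = nrow(df))
}

#' Standardize target profiles gene-wise
#'
#' Centers and scales each gene across profiles to zero mean and unit
#' variance (variance floored at 1e-8 to keep constant genes finite).
#'
#' @param profiles A continuous \linkS4class{DomainMatrix} with at
#'   least two profiles.
#' @return The standardized \linkS4class{DomainMatrix}.
#' @export
standardizeTarget <- function(profiles) {
  v <- if (is(profiles, "DomainMatrix")) exprValues(profiles) else profiles
  if (ncol(v) < 2L) stop("standardization needs at least two profiles")
  mu <- rowMeans(v)
  va <- pmax(apply(v, 1L, stats::var), 1e-8)
  z <- (v - mu) / sqrt(va)
  if (is(profiles, "DomainMatrix"))
    replaceValues(profiles, z, valueKind = "continuous")
  else z
}
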