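#' @include AllClasses.R nn.R
NULL

#' Architecture configuration for the domain-adaptation network
#'
#' The network has two domain-specific encoders (source and target), a
#' shared decoder mapping the latent code back to gene space, a
#' four-stage main-task classifier and a binary adversarial domain
#' classifier. Both classifiers consume the decoder output (gene-space
#' reconstruction), not the latent code. The composite training
#' objective is \eqn{L_{cls} - L_{adv} + \lambda L_{dc}} (optionally
#' plus a reconstruction term, off by default).
#'
#' @param input_dim Number of (selected) genes.
#' @param encoder_widths Hidden widths of each encoder.
#' @param latent_dim Latent code width.
#' @param decoder_widths Hidden widths of the shared decoder.
#' @param classifier_widths Hidden widths of the stage classifier.
#' @param adversary_widths Hidden widths of the domain classifier.
#' @param dropout_rate Dropout on hidden activations during training.
#' @param lambda_dc Weight \eqn{\lambda} of the MMD domain-confusion
#'   penalty.
#' @param mmd_kernel \code{"linear"} or \code{"rbf"}.
#' @param mmd_layer Where the MMD acts: \code{"latent"} (encoder
#'   output, default) or \code{"decoded"} (gene-space reconstruction).
#' @param recon_weight Optional weight of a mean-squared
#'   reconstruction term (0 disables it; the printed composite loss has
#'   none).
#' @param target_init \code{"warm"} (default) starts the target
#'   encoder as a lightly jittered copy of the source encoder, so that
#'   the two domains begin from a near-identity correspondence and
#'   adaptation only has to remove the residual shift (the usual
#'   warm start of adversarial discriminative domain adaptation);
#'   \code{"independent"} draws it afresh.
#' @param seed Seed for parameter initialization.
#' @return A validated list of class \code{"ModelConfig"}.
#' @export
modelConfig <- function(input_dim,
                        encoder_widths = c(64L),
                        latent_dim = 32L,
                        decoder_widths = c(64L),
                        classifier_widths = c(32L),
                        adversary_widths = c(32L),
                        dropout_rate = 0.1,
                        lambda_dc = 1.0,
                        mmd_kernel = c("linear", "rbf"),
                        mmd_layer = c("latent", "decoded"),
                        recon_weight = 0,
                        target_init = c("warm", "independent"),
                        seed = 1L) {
  cfg <- list(input_dim = as.integer(input_dim),
              encoder_widths = as.integer(encoder_widths),
              latent_dim = as.integer(latent_dim),
              decoder_widths = as.integer(decoder_widths),
              classifier_widths = as.integer(classifier_widths),
              adversary_widths = as.integer(adversary_widths),
              dropout_rate = dropout_rate,
              lambda_dc = lambda_dc,
              mmd_kernel = match.arg(mmd_kernel),
              mmd_layer = match.arg(mmd_layer),
              recon_weight = recon_weight,
              target_init = match.arg(target_init),
              seed = as.integer(seed))
  if (cfg$input_dim < 1L || cfg$latent_dim < 1L ||
      any(c(cfg$encoder_widths, cfg$decoder_widths,
            cfg$classifier_widths, cfg$adversary_widths) < 1L))
    stop("all layer widths must be positive")
  if (cfg$lambda_dc < 0 || cfg$recon_weight < 0)
    stop("lambda_dc and recon_weight must be non-negative")
  if (cfg$dropout_rate < 0 || cfg$dropout_rate >= 1)
    stop("dropout_rate must be in [0, 1)")
  class(cfg) <- "ModelConfig"
  cfg
}

#' Initialize a DreddaModel from a configuration
#'
#' Parameters are drawn sequentially from \code{config$seed}, so the
#' source and target encoders start at different random points.
#'
#' @param config A \code{\link{modelConfig}}.
#' @return A \linkS4class{DreddaModel}.
#' @export
dreddaModel <- function(config) {
  stopifnot(inherits(config, "ModelConfig"))
  set.seed(config$seed)
  n_stage <- length(differentiationStages())
  enc_dims <- c(config$input_dim, config$encoder_widths,
                config$latent_dim)
  enc_s <- .nn_init_stack(enc_dims)
  enc_t <- .nn_init_stack(enc_dims)
  if (identical(config$target_init, "warm"))
    enc_t <- lapply(enc_s, function(l)
      list(W = l$W + matrix(stats::rnorm(length(l$W), sd = 0.01),
                            nrow(l$W)),
           b = l$b))
  new("DreddaModel",
      sourceEncoder = enc_s,
      targetEncoder = enc_t,
      decoder = .nn_init_stack(c(config$latent_dim,
                                 config$decoder_widths,
                                 config$input_dim)),
      classifier = .nn_init_stack(c(config$input_dim,
                                    config$classifier_widths, n_stage)),
      adversary = .nn_init_stack(c(config$input_dim,
                                   config$adversary_widths, 1L)),
      config = unclass(config))
}

#' Encode samples with the domain-specific encoder
#'
#' @param model A \linkS4class{DreddaModel}.
#' @param X Samples x genes matrix (\code{input_dim} columns).
#' @param domain \code{"source"} or \code{"target"}: selects the
#'   encoder.
#' @return Samples x \code{latent_dim} latent matrix (evaluation mode,
#'   no dropout).
#' @export
encodeSamples <- function(model, X, domain = c("source", "target")) {
  domain <- match.arg(domain)
  X <- as.matrix(X)
  if (ncol(X) != model@config$input_dim)
    stop("X must have input_dim columns")
  enc <- if (domain == "source") model@sourceEncoder else model@targetEncoder
  .nn_forward(enc, X)$out
}

#' Decode latent codes through the shared decoder
#'
#' @param model A \linkS4class{DreddaModel}.
#' @param Z Samples x \code{latent_dim} matrix.
#' @return Samples x \code{input_dim} gene-space reconstruction.
#' @export
decodeLatent <- function(model, Z) {
  Z <- as.matrix(Z)
  if (ncol(Z) != model@config$latent_dim)
    stop("Z must have latent_dim columns")
  .nn_forward(model@decoder, Z)$out
}

#' Stage-classification probabilities from decoded profiles
#'
#' @param model A \linkS4class{DreddaModel}.
#' @param R Samples x \code{input_dim} decoded (gene-space) matrix.
#' @return Samples x 4 matrix of stage probabilities (rows on the
#'   simplex), columns named by \code{\link{differentiationStages}}.
#' @export
classifyStage <- function(model, R) {
  R <- as.matrix(R)
  if (ncol(R) != model@config$input_dim)
    stop("R must have input_dim columns")
  P <- .softmax(.nn_forward(model@classifier, R)$out)
  colnames(P) <- differentiationStages()
  P
}

#' Source-domain probability from the adversarial classifier
#'
#' @param model A \linkS4class{DreddaModel}.
#' @param R Samples x \code{input_dim} decoded matrix.
#' @return Vector of probabilities that each sample comes from the
#'   source domain.
#' @export
classifyDomain <- function(model, R) {
  R <- as.matrix(R)
  if (ncol(R) != model@config$input_dim)
    stop("R must have input_dim columns")
  as.vector(.sigmoid(.nn_forward(model@adversary, R)$out))
}

#' Main-task (stage) cross-entropy loss
#'
#' @param probabilities Samples x 4 matrix of stage probabilities.
#' @param labels Stage labels (character or factor over the
#'   four-stage vocabulary).
#' @return Mean categorical cross-entropy (natural log).
#' @export
stageLoss <- function(probabilities, labels) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), differentiationStages())
  if (length(bad)) stop("label outside vocabulary: ",
                        paste(bad, collapse = ", "))
  idx <- match(labels, colnames(probabilities))
  p <- probabilities[cbind(seq_along(idx), idx)]
  -mean(log(pmax(p, 1e-12)))
}

#' Adversarial (domain) binary cross-entropy loss
#'
#' @param domain_probabilities Predicted probabilities of the source
#'   domain.
#' @param domain_labels Character vector of \code{"source"} /
#'   \code{"target"} (or a 0/1 vector, 1 = source).
#' @return Mean binary cross-entropy (natural log).
#' @export
adversaryLoss <- function(domain_probabilities, domain_labels) {
  if (!length(domain_probabilities)) stop("empty batch")
  y <- if (is.numeric(domain_labels)) domain_labels else
    as.numeric(domain_labels == "source")
  p <- pmin(pmax(domain_probabilities, 1e-12), 1 - 1e-12)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Maximum mean discrepancy between two sample batches
#'
#' Linear kernel: squared Euclidean distance between the column-mean
#' vectors (the biased estimator, which is exactly that distance).
#' RBF: multi-kernel unbiased estimator with bandwidths set by the
#' median-distance heuristic scaled by (1/4, 1/2, 1, 2, 4), clamped at
#' zero.
#'
#' @param Z_s,Z_t Matrices with the same number of columns.
#' @param kernel \code{"linear"} (default) or \code{"rbf"}.
#' @return Non-negative scalar.
#' @export
mmd <- function(Z_s, Z_t, kernel = c("linear", "rbf")) {
  kernel <- match.arg(kernel)
  Z_s <- as.matrix(Z_s); Z_t <- as.matrix(Z_t)
  if (!nrow(Z_s) || !nrow(Z_t)) stop("empty batch")
  if (ncol(Z_s) != ncol(Z_t)) stop("batches must share the feature space")
  if (kernel == "linear") {
    d <- colMeans(Z_s) - colMeans(Z_t)
    return(sum(d^2))
  }
  pool <- rbind(Z_s, Z_t)
  D2 <- as.matrix(stats::dist(pool))^2
  med2 <- stats::median(D2[upper.tri(D2)])
  if (!is.finite(med2) || med2 <= 0) med2 <- 1
  ns <- nrow(Z_s); nt <- nrow(Z_t)
  is_s <- seq_len(ns); is_t <- ns + seq_len(nt)
  val <- 0
  for (f in c(0.25, 0.5, 1, 2, 4)) {
    K <- exp(-D2 / (2 * f * med2))
    kss <- (sum(K[is_s, is_s]) - ns) / (ns * (ns - 1))
    ktt <- (sum(K[is_t, is_t]) - nt) / (nt * (nt - 1))
    kst <- mean(K[is_s, is_t])
    val <- val + (kss + ktt - 2 * kst)
  }
  max(val, 0)
}

#' Assemble the composite adversarial loss
#'
#' \code{total = L_cls - L_adv + lambda * L_dc + recon_weight * L_rec}.
#'
#' @param L_cls,L_adv,L_dc Loss components (finite).
#' @param lambda Domain-confusion weight.
#' @param recon_weight,L_rec Optional reconstruction term (defaults 0).
#' @return A list with the components and their \code{total}.
#' @export
compositeLoss <- function(L_cls, L_adv, L_dc, lambda,
                          recon_weight = 0, L_rec = 0) {
  parts <- c(L_cls = L_cls, L_adv = L_adv, L_dc = L_dc, L_rec = L_rec)
  if (any(!is.finite(parts))) stop("non-finite loss component")
  list(L_cls = L_cls, L_adv = L_adv, L_dc = L_dc, L_rec = L_rec,
       total = L_cls - L_adv + lambda * L_dc + recon_weight * L_rec)
}

#' Save / load a DreddaModel checkpoint
#'
#' The parameters go to an RDS checkpoint; the architecture
#' configuration is additionally written to a JSON sidecar
#' (\code{<path>.json}) and checked on load.
#'
#' @param model A \linkS4class{DreddaModel}.
#' @param path Checkpoint path.
#' @return \code{readModel}: the restored \linkS4class{DreddaModel}.
#' @export
writeModel <- function(model, path) {
  saveRDS(model, path)
  jsonlite::write_json(model@config, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeModel
#' @export
readModel <- function(path) {
  model <- readRDS(path)
  stopifnot(is(model, "DreddaModel"))
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    cfg <- jsonlite::read_json(side, simplifyVector = TRUE)
    stopifnot(identical(as.integer(cfg$input_dim),
                        model@config$input_dim))
  }
  model
}
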