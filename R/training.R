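#' @include AllClasses.R nn.R model_core.R
NULL

#' Training configuration for the two-phase adversarial optimization
#'
#' Each training step runs two phases: phase 1 updates the
#' minimization-objective parameters (both encoders, the shared
#' decoder and the stage classifier) against the composite loss
#' \eqn{L_{cls} - L_{adv} + \lambda L_{dc}}; phase 2 updates the
#' adversarial domain classifier alone to minimize its own binary
#' cross-entropy. Every step samples an equal number of source and
#' target examples.
#'
#' @param batch_size_per_domain Samples drawn from each domain per
#'   step.
#' @param n_steps Number of training steps (fixed; no early stopping).
#' @param lr_min,lr_max Adam learning rates for phase 1 (minimization)
#'   and phase 2 (adversary).
#' @param eval_every Evaluation cadence (steps) for the training log.
#' @param seed Seed controlling the split, batch order and dropout.
#' @param disable_domain_adaptation If \code{TRUE}, the adversarial
#'   and domain-confusion terms are disabled and the target data is
#'   never touched: the run reduces to a pure source classifier
#'   (the no-DA ablation).
#' @return A validated list of class \code{"TrainConfig"}.
#' @export
trainConfig <- function(batch_size_per_domain = 64L, n_steps = 1500L,
                        lr_min = 1e-3, lr_max = 1e-3,
                        eval_every = 100L, seed = 1L,
                        disable_domain_adaptation = FALSE) {
  cfg <- list(batch_size_per_domain = as.integer(batch_size_per_domain),
              n_steps = as.integer(n_steps),
              lr_min = lr_min, lr_max = lr_max,
              eval_every = as.integer(eval_every),
              seed = as.integer(seed),
              disable_domain_adaptation = isTRUE(disable_domain_adaptation))
  if (cfg$batch_size_per_domain < 1L || cfg$n_steps < 1L ||
      cfg$eval_every < 1L)
    stop("sizes and step counts must be positive")
  if (cfg$lr_min <= 0 || cfg$lr_max <= 0)
    stop("learning rates must be positive")
  class(cfg) <- "TrainConfig"
  cfg
}

#' Sample a balanced two-domain batch
#'
#' Draws exactly \code{batch_size_per_domain} samples from each domain,
#' without replacement when possible; if a domain has fewer samples
#' than requested, sampling falls back to with-replacement and a
#' warning is emitted.
#'
#' @param source A \linkS4class{SourceDataset} (continuous,
#'   preprocessed).
#' @param target A \linkS4class{DomainMatrix}.
#' @param batch_size_per_domain Batch size per domain.
#' @return A list with \code{X_source} (batch x genes), \code{stages},
#'   \code{X_target}, and the drawn column indices
#'   \code{source_idx} / \code{target_idx}.
#' @export
sampleBalancedBatch <- function(source, target, batch_size_per_domain) {
  b <- as.integer(batch_size_per_domain)
  ns <- ncol(source); nt <- ncol(target)
  if (!ns || !nt) stop("both domains must be non-empty")
  repl_s <- b > ns; repl_t <- b > nt
  if (repl_s || repl_t)
    warning("batch larger than dataset; sampling with replacement")
  si <- sample.int(ns, b, replace = repl_s)
  ti <- sample.int(nt, b, replace = repl_t)
  list(X_source = t(exprValues(source)[, si, drop = FALSE]),
       stages = stageLabels(source)[si],
       X_target = t(exprValues(target)[, ti, drop = FALSE]),
       source_idx = si, target_idx = ti)
}

.onehot_stages <- function(stages) {
  lv <- differentiationStages()
  idx <- match(as.character(stages), lv)
  Y <- matrix(0, length(idx), length(lv))
  Y[cbind(seq_along(idx), idx)] <- 1
  Y
}

.new_opt_state <- function(model) {
  list(enc_s = .adam_init(model@sourceEncoder),
       enc_t = .adam_init(model@targetEncoder),
       dec = .adam_init(model@decoder),
       cls = .adam_init(model@classifier),
       adv = .adam_init(model@adversary),
       t1 = 0L, t2 = 0L)
}

#' One two-phase adversarial training step
#'
#' Phase 1 updates only the source encoder, target encoder, shared
#' decoder and stage classifier against the composite loss; the
#' adversary's parameters are read (its gradient flows into the
#' features with a reversed sign) but left bit-unchanged. Phase 2
#' recomputes the features in evaluation mode and updates only the
#' adversary to minimize its binary cross-entropy. With
#' \code{disable_domain_adaptation} the step never touches the target
#' batch and reduces to a plain classifier update.
#'
#' @param model A \linkS4class{DreddaModel}.
#' @param batch A list as returned by \code{\link{sampleBalancedBatch}}
#'   (\code{X_source}, \code{stages}, \code{X_target}).
#' @param config A \code{\link{trainConfig}}.
#' @param state Optimizer state from the previous step, or \code{NULL}
#'   to start fresh.
#' @param phases \code{"both"} (default) runs the full two-phase step;
#'   \code{"min"} / \code{"max"} apply only the corresponding phase's
#'   parameter updates (the other phase's parameters stay
#'   bit-unchanged) — useful for testing the update-set contract.
#' @return A list with the updated \code{model}, \code{state} and the
#'   \code{losses} (components of \code{\link{compositeLoss}}).
#' @export
trainStep <- function(model, batch, config, state = NULL,
                      phases = c("both", "min", "max")) {
  phases <- match.arg(phases)
  if (is.null(state)) state <- .new_opt_state(model)
  cfg <- model@config
  da <- !config$disable_domain_adaptation
  if (da && cfg$mmd_kernel != "linear" && cfg$lambda_dc > 0)
    stop("training supports the linear MMD kernel only; ",
         "the rbf estimator is for evaluation")
  drop <- cfg$dropout_rate
  Xs <- batch$X_source
  ns <- nrow(Xs)
  Y <- .onehot_stages(batch$stages)

  # phase 1 forward (train mode; RNG order: source path, target path,
  # classifier, adversary)
  fw_es <- .nn_forward(model@sourceEncoder, Xs, drop, train = TRUE)
  Zs <- fw_es$out
  fw_ds <- .nn_forward(model@decoder, Zs, drop, train = TRUE)
  Rs <- fw_ds$out
  if (da) {
    Xt <- batch$X_target
    nt <- nrow(Xt)
    fw_et <- .nn_forward(model@targetEncoder, Xt, drop, train = TRUE)
    Zt <- fw_et$out
    fw_dt <- .nn_forward(model@decoder, Zt, drop, train = TRUE)
    Rt <- fw_dt$out
  }
  fw_c <- .nn_forward(model@classifier, Rs, drop, train = TRUE)
  P <- .softmax(fw_c$out)
  L_cls <- -mean(log(pmax(P[cbind(seq_len(ns),
                                  match(as.character(batch$stages),
                                        differentiationStages()))],
                          1e-12)))
  if (da) {
    fw_a <- .nn_forward(model@adversary, rbind(Rs, Rt), drop, train = TRUE)
    q <- .sigmoid(fw_a$out)
    ydom <- c(rep(1, ns), rep(0, nt))
    L_adv <- -mean(ydom * log(pmax(q, 1e-12)) +
                     (1 - ydom) * log(pmax(1 - q, 1e-12)))
    L_dc <- if (cfg$lambda_dc > 0) {
      if (cfg$mmd_layer == "latent") mmd(Zs, Zt) else mmd(Rs, Rt)
    } else 0
  } else {
    L_adv <- 0; L_dc <- 0
  }
  L_rec <- if (cfg$recon_weight > 0) {
    if (da) (sum((Rs - Xs)^2) + sum((Rt - Xt)^2)) / (length(Rs) + length(Rt))
    else mean((Rs - Xs)^2)
  } else 0
  losses <- compositeLoss(L_cls, L_adv, L_dc, cfg$lambda_dc,
                          cfg$recon_weight, L_rec)
  if (!is.finite(losses$total))
    stop("non-finite training loss at step ", state$t1 + 1L)

  # phase 1 backward
  dlog <- (P - Y) / ns
  bk_c <- .nn_backward(model@classifier, fw_c, dlog)
  dRs <- bk_c$dX
  if (da) {
    dza <- (q - ydom) / (ns + nt)          # gradient of +L_adv
    bk_a <- .nn_backward(model@adversary, fw_a, dza)
    dRs <- dRs - bk_a$dX[seq_len(ns), , drop = FALSE]
    dRt <- -bk_a$dX[ns + seq_len(nt), , drop = FALSE]
    if (cfg$lambda_dc > 0 && cfg$mmd_layer == "decoded") {
      dmu <- 2 * (colMeans(Rs) - colMeans(Rt))
      dRs <- dRs + cfg$lambda_dc *
        matrix(dmu / ns, ns, length(dmu), byrow = TRUE)
      dRt <- dRt - cfg$lambda_dc *
        matrix(dmu / nt, nt, length(dmu), byrow = TRUE)
    }
  }
  if (cfg$recon_weight > 0) {
    denom <- if (da) length(Rs) + length(Rt) else length(Rs)
    dRs <- dRs + cfg$recon_weight * 2 * (Rs - Xs) / denom
    if (da) dRt <- dRt + cfg$recon_weight * 2 * (Rt - Xt) / denom
  }
  bk_ds <- .nn_backward(model@decoder, fw_ds, dRs)
  dZs <- bk_ds$dX
  grads_dec <- bk_ds$grads
  if (da) {
    bk_dt <- .nn_backward(model@decoder, fw_dt, dRt)
    grads_dec <- .nn_add_grads(grads_dec, bk_dt$grads)
    dZt <- bk_dt$dX
    if (cfg$lambda_dc > 0 && cfg$mmd_layer == "latent") {
      dmu <- 2 * (colMeans(Zs) - colMeans(Zt))
      dZs <- dZs + cfg$lambda_dc *
        matrix(dmu / ns, ns, length(dmu), byrow = TRUE)
      dZt <- dZt - cfg$lambda_dc *
        matrix(dmu / nt, nt, length(dmu), byrow = TRUE)
    }
  }
  bk_es <- .nn_backward(model@sourceEncoder, fw_es, dZs)

  if (phases != "max") {
  state$t1 <- state$t1 + 1L
  up <- .adam_step(model@sourceEncoder, bk_es$grads, state$enc_s,
                   config$lr_min, state$t1)
  model@sourceEncoder <- up$layers; state$enc_s <- up$state
  up <- .adam_step(model@decoder, grads_dec, state$dec,
                   config$lr_min, state$t1)
  model@decoder <- up$layers; state$dec <- up$state
  up <- .adam_step(model@classifier, bk_c$grads, state$cls,
                   config$lr_min, state$t1)
  model@classifier <- up$layers; state$cls <- up$state
  if (da) {
    bk_et <- .nn_backward(model@targetEncoder, fw_et, dZt)
    up <- .adam_step(model@targetEncoder, bk_et$grads, state$enc_t,
                     config$lr_min, state$t1)
    model@targetEncoder <- up$layers; state$enc_t <- up$state
  }
  }

  # phase 2: adversary alone, on evaluation-mode features
  if (da && phases != "min") {
    Rs2 <- decodeLatent(model, encodeSamples(model, Xs, "source"))
    Rt2 <- decodeLatent(model, encodeSamples(model, Xt, "target"))
    fw_a2 <- .nn_forward(model@adversary, rbind(Rs2, Rt2), drop,
                         train = TRUE)
    q2 <- .sigmoid(fw_a2$out)
    dza2 <- (q2 - ydom) / (ns + nt)
    bk_a2 <- .nn_backward(model@adversary, fw_a2, dza2)
    state$t2 <- state$t2 + 1L
    up <- .adam_step(model@adversary, bk_a2$grads, state$adv,
                     config$lr_max, state$t2)
    model@adversary <- up$layers; state$adv <- up$state
  }

  list(model = model, state = state, losses = losses)
}

# Draw-without-replacement pool over an index set; reshuffles when a
# full pass completes.
.pool_new <- function(idx) list(idx = idx, perm = sample(idx), pos = 1L)
.pool_draw <- function(pool, b) {
  out <- integer(0)
  while (length(out) < b) {
    take <- min(b - length(out), length(pool$perm) - pool$pos + 1L)
    out <- c(out, pool$perm[seq(pool$pos, length.out = take)])
    pool$pos <- pool$pos + take
    if (pool$pos > length(pool$perm)) {
      pool$perm <- sample(pool$idx)
      pool$pos <- 1L
    }
  }
  list(pool = pool, idx = out)
}

#' Fit the full adversarial domain-adaptation model
#'
#' Runs the two-phase optimization of \code{\link{trainStep}} over
#' balanced mini-batches, holding out a stratified 20\% of source
#' cells (and 20\% of target profiles) for the learning curves: the
#' main-task accuracy is evaluated on held-out source cells, the
#' adversarial accuracy on a held-out mixed batch with equal domain
#' counts. Fully reproducible from the configuration seeds on a single
#' thread.
#'
#' @param source A preprocessed continuous \linkS4class{SourceDataset}.
#' @param target A \linkS4class{DomainMatrix} on the same gene space
#'   (same identifiers, same order).
#' @param model_config A \code{\link{modelConfig}}; defaults to the
#'   desk-scale architecture for \code{nrow(source)} genes.
#' @param train_config A \code{\link{trainConfig}}.
#' @param snapshot_tail Number of trailing evaluation-point model
#'   snapshots to keep (0 disables). Adversarial optimization
#'   oscillates around its equilibrium rather than converging to a
#'   point; averaging predictions over a tail of snapshots
#'   (\code{\link{scoreProfiles}} accepts the snapshot list) damps
#'   that oscillation.
#' @return A list with the fitted \code{model}, the \code{log}
#'   (a data frame of per-evaluation records), the \code{snapshots}
#'   list and the held-out index sets.
#' @export
fitDredda <- function(source, target,
                      model_config = NULL,
                      train_config = trainConfig(),
                      snapshot_tail = 12L) {
  if (!identical(geneIds(source), geneIds(target)))
    stop("source and target must be aligned to the same gene space; ",
         "see alignGenes()")
  if (is.null(model_config))
    # with adaptation disabled, every domain-coupling mechanism goes:
    # the target encoder is then drawn independently rather than
    # warm-started from the source encoder
    model_config <- modelConfig(
      input_dim = nrow(source),
      target_init = if (train_config$disable_domain_adaptation)
        "independent" else "warm",
      seed = train_config$seed)
  stopifnot(identical(as.integer(model_config$input_dim),
                      as.integer(nrow(source))))
  model <- dreddaModel(model_config)   # seeds its own RNG
  b <- train_config$batch_size_per_domain
  da <- !train_config$disable_domain_adaptation

  set.seed(train_config$seed + 1L)
  st <- stageLabels(source)
  hold_s <- unlist(lapply(split(seq_len(ncol(source)), st), function(ix) {
    if (!length(ix)) return(integer(0))
    sample(ix, max(1L, round(0.2 * length(ix))))
  }), use.names = FALSE)
  hold_s <- sort(hold_s)
  train_s <- setdiff(seq_len(ncol(source)), hold_s)
  hold_t <- sort(sample.int(ncol(target), max(1L, round(0.2 * ncol(target)))))
  train_t <- setdiff(seq_len(ncol(target)), hold_t)

  Xs_all <- t(exprValues(source))
  Xt_all <- t(exprValues(target))
  ys <- as.character(st)

  pool_s <- .pool_new(train_s)
  pool_t <- .pool_new(train_t)
  state <- NULL
  log_rows <- list()
  snapshots <- list()
  m_eval <- min(length(hold_s), length(hold_t))

  eval_now <- function(step, losses) {
    Ps <- classifyStage(model,
                        decodeLatent(model,
                                     encodeSamples(model,
                                                   Xs_all[hold_s, ,
                                                          drop = FALSE],
                                                   "source")))
    main_acc <- mean(colnames(Ps)[max.col(Ps, ties.method = "first")] ==
                       ys[hold_s])
    adv_acc <- NA_real_
    if (da) {
      Rs <- decodeLatent(model,
                         encodeSamples(model,
                                       Xs_all[hold_s[seq_len(m_eval)], ,
                                              drop = FALSE], "source"))
      Rt <- decodeLatent(model,
                         encodeSamples(model,
                                       Xt_all[hold_t[seq_len(m_eval)], ,
                                              drop = FALSE], "target"))
      qs <- classifyDomain(model, Rs)
      qt <- classifyDomain(model, Rt)
      adv_acc <- mean(c(qs > 0.5, qt <= 0.5))
    }
    data.frame(step = step, main_task_accuracy = main_acc,
               adversarial_accuracy = adv_acc,
               L_cls = losses$L_cls, L_adv = losses$L_adv,
               L_dc = losses$L_dc, total = losses$total)
  }

  for (step in seq_len(train_config$n_steps)) {
    ds <- .pool_draw(pool_s, b); pool_s <- ds$pool
    dt <- .pool_draw(pool_t, b); pool_t <- dt$pool
    batch <- list(X_source = Xs_all[ds$idx, , drop = FALSE],
                  stages = ys[ds$idx],
                  X_target = Xt_all[dt$idx, , drop = FALSE])
    out <- trainStep(model, batch, train_config, state)
    model <- out$model; state <- out$state
    if (step %% train_config$eval_every == 0L ||
        step == train_config$n_steps) {
      log_rows[[length(log_rows) + 1L]] <- eval_now(step, out$losses)
      if (snapshot_tail > 0L) {
        snapshots[[length(snapshots) + 1L]] <- model
        if (length(snapshots) > snapshot_tail)
          snapshots <- snapshots[-1L]
      }
    }
  }

  list(model = model, log = do.call(rbind, log_rows),
       snapshots = snapshots,
       holdout_source = hold_s, holdout_target = hold_t)
}

#' Accuracy of the main or adversarial task
#'
#' @param model A \linkS4class{DreddaModel}.
#' @param task \code{"stage"} (main task, source domain) or
#'   \code{"domain"} (adversarial task).
#' @param source For \code{"stage"}: a continuous
#'   \linkS4class{SourceDataset} (labels taken from it unless
#'   \code{labels} is given). For \code{"domain"}: the source-domain
#'   matrix.
#' @param target For \code{"domain"}: the target-domain matrix.
#' @param labels Optional explicit stage labels.
#' @return Fraction of correct predictions in [0, 1].
#' @export
evaluateAccuracy <- function(model, task = c("stage", "domain"),
                             source = NULL, target = NULL,
                             labels = NULL) {
  task <- match.arg(task)
  as_samples <- function(x)
    if (is(x, "DomainMatrix")) t(exprValues(x)) else as.matrix(x)
  if (task == "stage") {
    if (is.null(source)) stop("stage accuracy needs source data")
    if (is.null(labels)) {
      if (!is(source, "SourceDataset"))
        stop("labels are required unless source is a SourceDataset")
      labels <- stageLabels(source)
    }
    X <- as_samples(source)
    if (!nrow(X)) stop("empty dataset")
    P <- classifyStage(model,
                       decodeLatent(model, encodeSamples(model, X,
                                                         "source")))
    pred <- colnames(P)[max.col(P, ties.method = "first")]
    mean(pred == as.character(labels))
  } else {
    if (is.null(source) || is.null(target))
      stop("domain accuracy needs both domains")
    Xs <- as_samples(source); Xt <- as_samples(target)
    if (!nrow(Xs) || !nrow(Xt)) stop("empty dataset")
    qs <- classifyDomain(model,
                         decodeLatent(model, encodeSamples(model, Xs,
                                                           "source")))
    qt <- classifyDomain(model,
                         decodeLatent(model, encodeSamples(model, Xt,
                                                           "target")))
    mean(c(qs > 0.5, qt <= 0.5))
  }
}

#' Train a stand-alone domain classifier on raw inputs
#'
#' Fits a small MLP to separate source from target samples in the given
#' representation (typically the raw, pre-adaptation input space) and
#' reports its held-out accuracy. Used as the "before adaptation"
#' reference: on systematically shifted domains this classifier is
#' nearly perfect.
#'
#' @param source,target Matrices (genes x samples) or
#'   \linkS4class{DomainMatrix} objects on the same gene space.
#' @param widths Hidden widths of the classifier.
#' @param n_steps Mini-batch Adam steps.
#' @param batch_size Batch size (balanced across domains).
#' @param lr Learning rate.
#' @param seed Seed.
#' @return A list with \code{layers} (the fitted stack) and
#'   \code{holdout_accuracy}.
#' @export
fitDomainClassifier <- function(source, target, widths = c(32L),
                                n_steps = 400L, batch_size = 128L,
                                lr = 1e-3, seed = 1L) {
  as_samples <- function(x)
    if (is(x, "DomainMatrix")) t(exprValues(x)) else t(as.matrix(x))
  Xs <- as_samples(source); Xt <- as_samples(target)
  stopifnot(ncol(Xs) == ncol(Xt))
  X <- rbind(Xs, Xt)
  y <- c(rep(1, nrow(Xs)), rep(0, nrow(Xt)))
  set.seed(seed)
  layers <- .nn_init_stack(c(ncol(X), widths, 1L))
  hold <- sort(sample.int(nrow(X), max(2L, round(0.2 * nrow(X)))))
  train <- setdiff(seq_len(nrow(X)), hold)
  state <- .adam_init(layers)
  for (it in seq_len(n_steps)) {
    ix <- sample(train, min(batch_size, length(train)))
    fw <- .nn_forward(layers, X[ix, , drop = FALSE])
    q <- .sigmoid(fw$out)
    dz <- (q - y[ix]) / length(ix)
    bk <- .nn_backward(layers, fw, dz)
    up <- .adam_step(layers, bk$grads, state, lr, it)
    layers <- up$layers; state <- up$state
  }
  qh <- .sigmoid(.nn_forward(layers, X[hold, , drop = FALSE])$out)
  list(layers = layers,
       holdout_accuracy = mean((qh > 0.5) == (y[hold] > 0.5)))
}
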