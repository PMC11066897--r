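#' @include AllClasses.R
NULL

#' Configuration of the synthetic two-domain benchmark
#'
#' Defines a paired generator: ZINB-distributed counts with four latent
#' differentiation-stage classes for the source domain, and signed
#' continuous differential profiles — mostly inert, with a planted
#' minority carrying a class signature — plus a systematic per-gene
#' domain shift for the target domain.
#'
#' @param n_genes Number of genes shared by both domains.
#' @param n_source Number of source cells.
#' @param n_target Number of target profiles.
#' @param n_classes Number of latent stage classes (4 by default,
#'   matching the differentiation-stage vocabulary).
#' @param class_proportions Simplex vector of class frequencies among
#'   source cells. Default (0.40, 0.25, 0.20, 0.15): an unperturbed
#'   pluripotent culture dominated by core-pluripotent cells with
#'   progressively fewer primed cells.
#' @param n_informative_genes Number of genes whose class means differ.
#' @param effect_size Scale (natural-log fold units) of the per-class
#'   mean separation on informative genes; also scales the planted
#'   signal amplitude in target profiles.
#' @param zinb_dispersion Negative-binomial dispersion (size) theta.
#' @param zinb_dropout Zero-inflation probability pi.
#' @param domain_shift_scale Scale of the systematic per-gene affine
#'   distortion of target profiles (log-normal gain and normal offset).
#' @param planted_fraction Fraction of target compounds whose profiles
#'   carry a class signature.
#' @param seed Integer seed; all outputs are pure functions of this
#'   configuration.
#' @return A validated list of class \code{"SimulationConfig"}.
#' @export
simulationConfig <- function(n_genes = 200L, n_source = 2000L,
                             n_target = 2000L, n_classes = 4L,
                             class_proportions = c(0.40, 0.25, 0.20, 0.15),
                             n_informative_genes = 40L,
                             effect_size = 1.0,
                             zinb_dispersion = 2.0,
                             zinb_dropout = 0.3,
                             domain_shift_scale = 0.5,
                             planted_fraction = 0.1,
                             seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_source = as.integer(n_source),
              n_target = as.integer(n_target),
              n_classes = as.integer(n_classes),
              class_proportions = as.numeric(class_proportions),
              n_informative_genes = as.integer(n_informative_genes),
              effect_size = effect_size,
              zinb_dispersion = zinb_dispersion,
              zinb_dropout = zinb_dropout,
              domain_shift_scale = domain_shift_scale,
              planted_fraction = planted_fraction,
              seed = as.integer(seed))
  if (cfg$n_classes < 1L || cfg$n_classes > length(differentiationStages()))
    stop("n_classes must be between 1 and 4")
  if (length(cfg$class_proportions) != cfg$n_classes)
    stop("class_proportions must have n_classes entries")
  if (abs(sum(cfg$class_proportions) - 1) > 1e-9)
    stop("class_proportions must sum to 1")
  if (any(cfg$class_proportions < 0))
    stop("class_proportions must be non-negative")
  if (cfg$n_informative_genes > cfg$n_genes)
    stop("n_informative_genes must not exceed n_genes")
  if (cfg$zinb_dropout < 0 || cfg$zinb_dropout > 1)
    stop("zinb_dropout must be a probability")
  if (cfg$planted_fraction < 0 || cfg$planted_fraction > 1)
    stop("planted_fraction must be a probability")
  if (cfg$effect_size < 0 || cfg$zinb_dispersion <= 0 ||
      cfg$domain_shift_scale < 0)
    stop("effect_size/zinb_dispersion/domain_shift_scale out of range")
  class(cfg) <- "SimulationConfig"
  cfg
}

.sim_gene_ids <- function(n) sprintf("G%04d", seq_len(n))

#' Simulate the labeled source domain (ZINB counts, 4 stage classes)
#'
#' Each cell draws a stage from \code{class_proportions}; each gene has
#' a log-normal baseline mean, and informative genes additionally carry
#' normal per-class offsets of scale \code{effect_size} in natural-log
#' units. Counts are zero-inflated negative binomial with dispersion
#' \code{zinb_dispersion} and dropout \code{zinb_dropout}.
#'
#' @param config A \code{\link{simulationConfig}}.
#' @return A list with \code{dataset} (a \linkS4class{SourceDataset} of
#'   counts) and \code{truth} (labels, informative gene ids, per-class
#'   log offsets, and the true ZINB mean matrix \code{mu}).
#' @export
simulateSource <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  G <- config$n_genes; n <- config$n_source; C <- config$n_classes
  stages <- differentiationStages()[seq_len(C)]
  genes <- .sim_gene_ids(G)
  labels <- sample(stages, n, replace = TRUE, prob = config$class_proportions)
  labels <- factor(labels, levels = differentiationStages())
  base_log_mean <- stats::rnorm(G, mean = log(5), sd = 0.8)
  informative <- sort(sample.int(G, config$n_informative_genes))
  offsets <- matrix(0, G, C, dimnames = list(genes, stages))
  if (length(informative))
    offsets[informative, ] <- config$effect_size *
      stats::rnorm(length(informative) * C)
  class_idx <- as.integer(factor(labels, levels = stages))
  mu <- exp(base_log_mean + offsets[, class_idx, drop = FALSE])
  dimnames(mu) <- list(genes, sprintf("CELL%05d", seq_len(n)))
  x <- stats::rnbinom(length(mu), size = config$zinb_dispersion, mu = mu)
  drop <- stats::runif(length(mu)) < config$zinb_dropout
  x[drop] <- 0L
  counts <- matrix(x, G, n, dimnames = dimnames(mu))
  dataset <- SourceDataset(counts, stages = labels, valueKind = "counts")
  truth <- list(source_labels = labels,
                informative_genes = genes[informative],
                base_log_mean = stats::setNames(base_log_mean, genes),
                class_offsets = offsets,
                mu = mu)
  list(dataset = dataset, truth = truth)
}

# Unit-norm differential class signatures of a (counts) source
# simulation, computed on log(x + eps) values: per-class centroid minus
# the grand mean, each normalized to unit Euclidean length.
.class_signatures <- function(dataset, eps = 1e-5) {
  lg <- log(exprValues(dataset) + eps)
  st <- stageLabels(dataset)
  stages <- levels(droplevels(st))
  grand <- rowMeans(lg)
  sig <- vapply(stages, function(s)
    rowMeans(lg[, st == s, drop = FALSE]) - grand, numeric(nrow(lg)))
  apply(sig, 2L, function(v) v / sqrt(sum(v^2)))
}

#' Simulate the target domain (differential profiles with planted signal)
#'
#' Inert profiles are i.i.d. standard normal per gene. Active profiles
#' additionally carry \code{effect_size * sqrt(n_genes)} times the
#' unit-norm differential signature of their planted class (computed
#' from the paired source simulation), so the per-gene signal is of
#' order \code{effect_size} against unit noise. All profiles then
#' receive a systematic per-gene affine domain shift: gain
#' \code{LogNormal(0, domain_shift_scale)} and offset
#' \code{Normal(0, domain_shift_scale)}, emulating platform bias
#' between scRNA-seq counts and L1000-style differential signatures.
#'
#' Profiles are grouped two-per-compound; activity is decided at the
#' compound level so that drug-level rankings have a planted truth. By
#' default planted profiles carry the terminal (late-primed) stage
#' signature — the benchmark emulates a screen for differentiation
#' inducers; set \code{planted_classes} for other designs.
#'
#' @param config A \code{\link{simulationConfig}}.
#' @param source_sim Result of \code{\link{simulateSource}} on the same
#'   config (provides the class signatures).
#' @param planted_classes \code{"terminal"} (default), \code{"uniform"},
#'   or an explicit vector of stage names to sample from.
#' @return A list with \code{matrix} (target \linkS4class{DomainMatrix}),
#'   \code{metadata} (profile annotations), and \code{truth}
#'   (per-profile \code{target_is_active} / \code{target_planted_class},
#'   plus the signature matrix used for planting).
#' @export
simulateTarget <- function(config, source_sim,
                           planted_classes = "terminal") {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed + 1L)
  G <- config$n_genes; n <- config$n_target
  genes <- geneIds(source_sim$dataset)
  sig <- .class_signatures(source_sim$dataset)
  stages <- colnames(sig)
  profiles_per_compound <- 2L
  n_compounds <- ceiling(n / profiles_per_compound)
  compound <- rep(sprintf("CPD%05d", seq_len(n_compounds)),
                  each = profiles_per_compound)[seq_len(n)]
  n_active <- round(config$planted_fraction * n_compounds)
  active_compounds <- sort(sample.int(n_compounds, n_active))
  active_ids <- sprintf("CPD%05d", active_compounds)
  if (identical(planted_classes, "terminal")) {
    pool <- stages[length(stages)]
  } else if (identical(planted_classes, "uniform")) {
    pool <- stages
  } else {
    stopifnot(all(planted_classes %in% stages))
    pool <- planted_classes
  }
  compound_class <- stats::setNames(
    sample(pool, n_active, replace = TRUE), active_ids)
  is_active <- compound %in% active_ids
  planted_class <- rep(NA_character_, n)
  planted_class[is_active] <- compound_class[compound[is_active]]
  Z <- matrix(stats::rnorm(G * n), G, n)
  amp <- config$effect_size * sqrt(G)
  if (any(is_active))
    Z[, is_active] <- Z[, is_active] +
      amp * sig[, planted_class[is_active], drop = FALSE]
  gain <- stats::rlnorm(G, meanlog = 0, sdlog = config$domain_shift_scale)
  offset <- stats::rnorm(G, 0, config$domain_shift_scale)
  Y <- Z * gain + offset
  sample_ids <- sprintf("SIG%05d", seq_len(n))
  dimnames(Y) <- list(genes, sample_ids)
  metadata <- data.frame(
    sample_id = sample_ids,
    compound_id = compound,
    cell_line = rep(c("CLA", "CLB", "CLC"), length.out = n),
    dose = "10 uM",
    time = "24 h",
    stringsAsFactors = FALSE)
  truth <- list(target_is_active = is_active,
                target_planted_class = planted_class,
                active_compounds = active_ids,
                compound_class = compound_class,
                signatures = sig,
                gain = gain,
                offset = offset)
  list(matrix = DomainMatrix(Y, domain = "target",
                             valueKind = "continuous",
                             sampleData = S4Vectors::DataFrame(
                               metadata[, -1L], row.names = sample_ids)),
       metadata = metadata,
       truth = truth)
}

#' Generate and write a complete benchmark bundle
#'
#' Runs \code{\link{simulateSource}} and \code{\link{simulateTarget}}
#' and writes all pieces in plain-text formats: source counts (GCT and
#' sparse MatrixMarket), stage labels, target profiles (GCT), profile
#' metadata, planted truth tables, and a JSON manifest recording the
#' configuration and seed.
#'
#' @param config A \code{\link{simulationConfig}}.
#' @param dir Output directory (created if absent).
#' @param planted_classes Passed to \code{\link{simulateTarget}}.
#' @return Invisibly, the in-memory bundle
#'   (\code{list(source, target, config)}).
#' @export
makeBenchmark <- function(config = simulationConfig(), dir,
                          planted_classes = "terminal") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  src <- simulateSource(config)
  tgt <- simulateTarget(config, src, planted_classes = planted_classes)
  writeGCT(src$dataset, file.path(dir, "source_counts.gct"))
  writeSparseCounts(src$dataset, file.path(dir, "source_counts.mtx"))
  data.table::fwrite(
    data.frame(sample_id = sampleIds(src$dataset),
               stage = as.character(stageLabels(src$dataset))),
    file.path(dir, "source_labels.tsv"), sep = "\t")
  writeGCT(tgt$matrix, file.path(dir, "target_profiles.gct"))
  writeProfileMetadata(tgt$metadata, file.path(dir, "target_metadata.tsv"))
  data.table::fwrite(
    data.frame(sample_id = tgt$metadata$sample_id,
               is_active = tgt$truth$target_is_active,
               planted_class = ifelse(is.na(tgt$truth$target_planted_class),
                                      "none",
                                      tgt$truth$target_planted_class)),
    file.path(dir, "target_truth.tsv"), sep = "\t")
  jsonlite::write_json(
    list(config = unclass(config), planted_classes = planted_classes,
         package_version = as.character(utils::packageVersion("dredda"))),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(source = src, target = tgt, config = config))
}

#' Load a benchmark bundle written by makeBenchmark
#'
#' @param dir Benchmark directory.
#' @return A list with \code{source} (a \linkS4class{SourceDataset}),
#'   \code{target} (a \linkS4class{DomainMatrix}), \code{metadata} and
#'   \code{truth} data frames, and the manifest list.
#' @export
readBenchmark <- function(dir) {
  counts <- readGCT(file.path(dir, "source_counts.gct"),
                    domain = "source", valueKind = "counts")
  labels <- data.table::fread(file.path(dir, "source_labels.tsv"),
                              data.table = FALSE)
  stopifnot(identical(labels$sample_id, sampleIds(counts)))
  source <- SourceDataset(exprValues(counts), stages = labels$stage,
                          valueKind = "counts")
  target <- readGCT(file.path(dir, "target_profiles.gct"),
                    domain = "target", valueKind = "continuous")
  metadata <- readProfileMetadata(file.path(dir, "target_metadata.tsv"))
  truth <- data.table::fread(file.path(dir, "target_truth.tsv"),
                             data.table = FALSE)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  list(source = source, target = target, metadata = metadata,
       truth = truth, manifest = manifest)
}
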