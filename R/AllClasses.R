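#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' Ordered vocabulary of hiPSC differentiation stages
#'
#' The four stages used to label source-domain cells, ordered from the
#' least to the most differentiated state.
#'
#' @return Character vector of the four stage names.
#' @export
#' @examples
#' differentiationStages()
differentiationStages <- function() {
  c("core_pluripotent", "proliferative", "early_primed", "late_primed")
}

#' DomainMatrix: a genes x samples matrix tagged with its data domain
#'
#' Thin \linkS4class{SummarizedExperiment} subclass holding either raw
#' single-cell counts (source domain) or continuous differential
#' expression profiles (target domain). Row names are gene identifiers,
#' column names are sample identifiers; both must be unique.
#'
#' @slot domain Either \code{"source"} or \code{"target"}.
#' @slot valueKind Either \code{"counts"} or \code{"continuous"};
#'   \code{"counts"} requires all entries to be finite non-negative
#'   integers.
#' @exportClass DomainMatrix
setClass("DomainMatrix",
  contains = "SummarizedExperiment",
  slots = c(domain = "character", valueKind = "character")
)

setValidity("DomainMatrix", function(object) {
  msg <- character()
  if (length(object@domain) != 1L || !object@domain %in% c("source", "target"))
    msg <- c(msg, "domain must be 'source' or 'target'")
  if (length(object@valueKind) != 1L ||
      !object@valueKind %in% c("counts", "continuous"))
    msg <- c(msg, "valueKind must be 'counts' or 'continuous'")
  v <- SummarizedExperiment::assay(object, withDimnames = FALSE)
  gid <- rownames(object)
  sid <- colnames(object)
  if (nrow(object) > 0L && (is.null(gid) || anyDuplicated(gid)))
    msg <- c(msg, "gene ids must be present and unique")
  if (ncol(object) > 0L && (is.null(sid) || anyDuplicated(sid)))
    msg <- c(msg, "sample ids must be present and unique")
  if (identical(object@valueKind, "counts") && length(v)) {
    if (anyNA(v) || any(!is.finite(v)))
      msg <- c(msg, "counts must be finite")
    else if (any(v < 0) || any(v != round(v)))
      msg <- c(msg, "counts must be non-negative integers")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a DomainMatrix
#'
#' @param values Numeric matrix, genes in rows, samples in columns, with
#'   unique row and column names.
#' @param domain \code{"source"} or \code{"target"}.
#' @param valueKind \code{"counts"} or \code{"continuous"}.
#' @param sampleData Optional \code{DataFrame}/\code{data.frame} of
#'   per-sample annotations (one row per column of \code{values}).
#' @param rowData Optional per-gene annotations.
#' @return A \linkS4class{DomainMatrix}.
#' @export
#' @examples
#' m <- matrix(0:5, 2, 3, dimnames = list(c("G1", "G2"), c("S1", "S2", "S3")))
#' DomainMatrix(m, domain = "source", valueKind = "counts")
DomainMatrix <- function(values, domain = c("source", "target"),
                         valueKind = c("counts", "continuous"),
                         sampleData = NULL, rowData = NULL) {
  domain <- match.arg(domain)
  valueKind <- match.arg(valueKind)
  values <- as.matrix(values)
  if (is.null(sampleData))
    sampleData <- S4Vectors::DataFrame(row.names = colnames(values))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(values = values),
    colData = sampleData
  )
  if (!is.null(rowData)) SummarizedExperiment::rowData(se) <- rowData
  new("DomainMatrix", se, domain = domain, valueKind = valueKind)
}

#' SourceDataset: labeled source-domain expression
#'
#' A \linkS4class{DomainMatrix} whose columns (cells) each carry one of
#' the four differentiation-stage labels in \code{colData(x)$stage}.
#'
#' @exportClass SourceDataset
setClass("SourceDataset", contains = "DomainMatrix")

setValidity("SourceDataset", function(object) {
  msg <- character()
  if (!identical(object@domain, "source"))
    msg <- c(msg, "SourceDataset must have domain 'source'")
  cd <- SummarizedExperiment::colData(object)
  if (!"stage" %in% colnames(cd)) {
    msg <- c(msg, "colData must contain a 'stage' column")
  } else {
    st <- cd$stage
    if (!is.factor(st) || !identical(levels(st), differentiationStages()))
      msg <- c(msg, "stage must be a factor with the four differentiation stages as levels")
    if (anyNA(st)) msg <- c(msg, "every sample needs a stage label")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SourceDataset
#'
#' @param values Genes x cells matrix (counts or processed continuous
#'   values; see \code{valueKind}).
#' @param stages Character or factor vector of per-cell stage labels
#'   drawn from \code{\link{differentiationStages}}.
#' @param valueKind \code{"counts"} (raw) or \code{"continuous"}
#'   (denoised/log-transformed).
#' @param sampleData Optional additional per-cell annotations.
#' @return A \linkS4class{SourceDataset}.
#' @export
SourceDataset <- function(values, stages,
                          valueKind = c("counts", "continuous"),
                          sampleData = NULL) {
  valueKind <- match.arg(valueKind)
  values <- as.matrix(values)
  if (length(stages) != ncol(values))
    stop("need one stage label per sample")
  bad <- setdiff(unique(as.character(stages)), differentiationStages())
  if (length(bad))
    stop("unknown stage label(s): ", paste(bad, collapse = ", "))
  stages <- factor(as.character(stages), levels = differentiationStages())
  if (is.null(sampleData))
    sampleData <- S4Vectors::DataFrame(row.names = colnames(values))
  sampleData$stage <- stages
  dm <- DomainMatrix(values, domain = "source", valueKind = valueKind,
                     sampleData = sampleData)
  new("SourceDataset", dm)
}

#' ZINB parameter estimates from the denoising autoencoder
#'
#' @slot mu Positive matrix of estimated means (same shape as the
#'   input counts); this is the denoised expression matrix.
#' @slot theta Positive per-gene dispersion vector.
#' @slot pi Per-entry dropout (zero-inflation) probabilities in [0, 1].
#' @slot loss Numeric vector of per-iteration mean negative
#'   log-likelihood during fitting.
#' @exportClass ZINBParams
setClass("ZINBParams",
  slots = c(mu = "matrix", theta = "numeric", pi = "matrix",
            loss = "numeric")
)

setValidity("ZINBParams", function(object) {
  msg <- character()
  if (any(object@mu <= 0)) msg <- c(msg, "mu must be strictly positive")
  if (any(object@theta <= 0)) msg <- c(msg, "theta must be strictly positive")
  if (length(object@theta) != nrow(object@mu))
    msg <- c(msg, "theta must have one entry per gene (row of mu)")
  if (any(object@pi < 0 | object@pi > 1))
    msg <- c(msg, "pi must lie in [0, 1]")
  if (!identical(dim(object@mu), dim(object@pi)))
    msg <- c(msg, "mu and pi must have identical shapes")
  if (length(msg)) msg else TRUE
})

#' Mutual-information feature selection result
#'
#' @slot geneIds Selected gene identifiers, ordered by decreasing
#'   mutual information (ties broken lexicographically).
#' @slot miScores Named non-negative vector of MI scores (bits) for all
#'   genes scored.
#' @slot k Number of genes requested.
#' @exportClass FeatureSelection
setClass("FeatureSelection",
  slots = c(geneIds = "character", miScores = "numeric", k = "integer")
)

setValidity("FeatureSelection", function(object) {
  msg <- character()
  if (any(object@miScores < -1e-12)) msg <- c(msg, "MI scores must be >= 0")
  if (length(object@geneIds) != min(object@k, length(object@miScores)))
    msg <- c(msg, "number of selected genes must equal min(k, n_genes)")
  if (!all(object@geneIds %in% names(object@miScores)))
    msg <- c(msg, "selected genes must carry MI scores")
  if (length(msg)) msg else TRUE
})

#' DREDDA model: two encoders, shared decoder, two classifiers
#'
#' Holds the parameters of the source encoder, the target encoder, the
#' shared decoder, the stage (main-task) classifier and the adversarial
#' domain classifier, plus the architecture configuration.
#'
#' @slot sourceEncoder,targetEncoder,decoder,classifier,adversary Lists
#'   of dense-layer parameters (\code{W}, \code{b} per layer).
#' @slot config The \code{\link{modelConfig}} list used to build the
#'   network.
#' @exportClass DreddaModel
setClass("DreddaModel",
  slots = c(sourceEncoder = "list", targetEncoder = "list",
            decoder = "list", classifier = "list", adversary = "list",
            config = "list")
)

#' Per-stage expression signatures of the source domain
#'
#' @slot stages Stage names (columns of the matrices).
#' @slot centroids Genes x stages matrix of per-stage mean expression.
#' @slot differentials Centroid minus grand mean per stage.
#' @slot unitDifferentials Unit-norm differential signatures.
#' @slot topSets List of per-stage top-gene ID sets by absolute
#'   differential value.
#' @slot topN Size requested for the top sets.
#' @exportClass SignatureSet
setClass("SignatureSet",
  slots = c(stages = "character", centroids = "matrix",
            differentials = "matrix", unitDifferentials = "matrix",
            topSets = "list", topN = "integer")
)

setMethod("show", "DomainMatrix", function(object) {
  cat(sprintf("%s: %d genes x %d samples [%s, %s]\n",
              class(object), nrow(object), ncol(object),
              object@domain, object@valueKind))
})

setMethod("show", "SourceDataset", function(object) {
  callNextMethod()
  print(table(SummarizedExperiment::colData(object)$stage))
})

setMethod("show", "ZINBParams", function(object) {
  cat(sprintf("ZINBParams: %d genes x %d samples; final NLL %.4f\n",
              nrow(object@mu), ncol(object@mu),
              utils::tail(object@loss, 1)))
})

setMethod("show", "FeatureSelection", function(object) {
  cat(sprintf("FeatureSelection: %d of %d genes (k = %d); top MI %.3f bits\n",
              length(object@geneIds), length(object@miScores), object@k,
              if (length(object@geneIds))
                object@miScores[[object@geneIds[1L]]] else NA_real_))
})

setMethod("show", "DreddaModel", function(object) {
  cfg <- object@config
  cat(sprintf(
    "DreddaModel: %d genes -> latent %d; lambda_dc = %g, mmd = %s@%s\n",
    cfg$input_dim, cfg$latent_dim, cfg$lambda_dc, cfg$mmd_kernel,
    cfg$mmd_layer))
})

setMethod("show", "SignatureSet", function(object) {
  cat(sprintf("SignatureSet: %d genes, %d stages, top-%d sets\n",
              nrow(object@centroids), length(object@stages), object@topN))
})
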