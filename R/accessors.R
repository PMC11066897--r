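#' @include AllClasses.R
NULL

#' Accessors for DomainMatrix and friends
#'
#' \code{exprValues} returns the numeric genes x samples matrix;
#' \code{geneIds} and \code{sampleIds} the row/column identifiers;
#' \code{domainTag} and \code{valueKind} the domain and value-kind tags;
#' \code{stageLabels} the per-cell stage factor of a
#' \linkS4class{SourceDataset}.
#'
#' @param x A \linkS4class{DomainMatrix} (or subclass).
#' @return See description.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname accessors
#' @export
setMethod("exprValues", "DomainMatrix", function(x)
  SummarizedExperiment::assay(x, "values"))

#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname accessors
#' @export
setMethod("geneIds", "DomainMatrix", function(x) rownames(x))

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname accessors
#' @export
setMethod("sampleIds", "DomainMatrix", function(x) colnames(x))

#' @rdname accessors
#' @export
setGeneric("domainTag", function(x) standardGeneric("domainTag"))

#' @rdname accessors
#' @export
setMethod("domainTag", "DomainMatrix", function(x) x@domain)

#' @rdname accessors
#' @export
setGeneric("valueKind", function(x) standardGeneric("valueKind"))

#' @rdname accessors
#' @export
setMethod("valueKind", "DomainMatrix", function(x) x@valueKind)

#' @rdname accessors
#' @export
setGeneric("stageLabels", function(x) standardGeneric("stageLabels"))

#' @rdname accessors
#' @export
setMethod("stageLabels", "SourceDataset", function(x)
  SummarizedExperiment::colData(x)$stage)

#' Replace the values of a DomainMatrix, keeping ids and tags
#'
#' Utility used by the preprocessing steps: returns a copy of \code{x}
#' whose assay is \code{values} and whose value kind is
#' \code{valueKind}.
#'
#' @param x A \linkS4class{DomainMatrix}.
#' @param values Replacement matrix (same shape and dimnames).
#' @param valueKind Value kind of the replacement.
#' @return Object of the same class as \code{x}.
#' @export
replaceValues <- function(x, values, valueKind = x@valueKind) {
  stopifnot(identical(dim(values), dim(exprValues(x))))
  dimnames(values) <- dimnames(exprValues(x))
  SummarizedExperiment::assay(x, "values", withDimnames = FALSE) <- values
  x@valueKind <- valueKind
  validObject(x)
  x
}
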