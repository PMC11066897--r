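#' @include AllClasses.R
NULL

# Locale-independent lexicographic sort (C collation via radix).
.lexsort <- function(x) sort(x, method = "radix")

# Deterministic ordering by decreasing score with lexicographic id
# tie-break; returns a permutation.
.order_score_id <- function(score, id) order(-score, id, method = "radix")

#' Read a GCT 1.3 text matrix
#'
#' Parses the LINCS-ecosystem GCT 1.3 text format: a \code{#1.3}
#' version line, a dimensions line (\code{nrow ncol [nrowmeta ncolmeta]}),
#' a header line, optional column-metadata rows and one data row per
#' gene. Row-metadata columns beyond the ID are kept as opaque strings
#' in \code{rowData}; column metadata goes to \code{colData}.
#'
#' @param path Path to a GCT file.
#' @param domain,valueKind Tags for the returned
#'   \linkS4class{DomainMatrix}.
#' @return A \linkS4class{DomainMatrix}.
#' @export
readGCT <- function(path, domain = c("target", "source"),
                    valueKind = c("continuous", "counts")) {
  domain <- match.arg(domain)
  valueKind <- match.arg(valueKind)
  lines <- readLines(path)
  if (length(lines) < 3L || !grepl("^#1\\.3\\s*$", lines[1L]))
    stop("malformed GCT header: expected version line '#1.3'")
  dims <- suppressWarnings(as.integer(strsplit(trimws(lines[2L]), "\t")[[1L]]))
  if (anyNA(dims) || !length(dims) %in% c(2L, 4L))
    stop("malformed GCT dimensions line")
  nr <- dims[1L]; nc <- dims[2L]
  nrm <- if (length(dims) == 4L) dims[3L] else 0L
  ncm <- if (length(dims) == 4L) dims[4L] else 0L
  header <- strsplit(lines[3L], "\t")[[1L]]
  if (length(header) != 1L + nrm + nc)
    stop("GCT header row does not match declared dimensions")
  rmeta_names <- if (nrm > 0L) header[seq(2L, 1L + nrm)] else character()
  sample_ids <- header[seq(2L + nrm, length.out = nc)]
  body <- lines[-(1:3)]
  if (length(body) != ncm + nr)
    stop("GCT body does not match declared dimensions")
  cmeta <- NULL
  if (ncm > 0L) {
    cm <- strsplit(body[seq_len(ncm)], "\t")
    bad <- vapply(cm, length, 1L) != 1L + nrm + nc
    if (any(bad)) stop("malformed GCT column-metadata row")
    cmeta <- S4Vectors::DataFrame(row.names = sample_ids)
    for (row in cm)
      cmeta[[row[1L]]] <- row[seq(2L + nrm, length.out = nc)]
  }
  data <- strsplit(body[seq(ncm + 1L, length.out = nr)], "\t")
  if (any(vapply(data, length, 1L) != 1L + nrm + nc))
    stop("malformed GCT data row")
  gene_ids <- vapply(data, `[`, "", 1L)
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids in GCT file: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  values <- matrix(NA_real_, nr, nc, dimnames = list(gene_ids, sample_ids))
  for (i in seq_len(nr))
    values[i, ] <- suppressWarnings(
      as.numeric(data[[i]][seq(2L + nrm, length.out = nc)]))
  if (anyNA(values) && valueKind == "counts")
    stop("missing values are not allowed in count matrices")
  rmeta <- NULL
  if (nrm > 0L) {
    rmeta <- S4Vectors::DataFrame(row.names = gene_ids)
    for (j in seq_len(nrm))
      rmeta[[rmeta_names[j]]] <- vapply(data, `[`, "", 1L + j)
  }
  DomainMatrix(values, domain = domain, valueKind = valueKind,
               sampleData = cmeta, rowData = rmeta)
}

#' Write a GCT 1.3 text matrix
#'
#' Inverse of \code{\link{readGCT}}: character columns of
#' \code{rowData}/\code{colData} become row/column metadata. Values are
#' printed with full double precision (\code{\%.17g}), so a read
#' round-trip reproduces them exactly.
#'
#' @param x A \linkS4class{DomainMatrix}.
#' @param path Output path.
#' @param allowMissing If \code{FALSE} (default) any non-finite value
#'   is an error; if \code{TRUE} missing values are written as
#'   \code{NA} (continuous matrices only).
#' @return Invisibly, \code{path}.
#' @export
writeGCT <- function(x, path, allowMissing = FALSE) {
  v <- exprValues(x)
  if (!all(is.finite(v))) {
    if (!allowMissing || valueKind(x) == "counts")
      stop("non-finite values; set allowMissing=TRUE for continuous data")
  }
  rd <- SummarizedExperiment::rowData(x)
  rd <- rd[, vapply(rd, is.character, TRUE), drop = FALSE]
  cd <- SummarizedExperiment::colData(x)
  cd <- cd[, vapply(cd, is.character, TRUE), drop = FALSE]
  nrm <- ncol(rd); ncm <- ncol(cd)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#1.3", con)
  writeLines(paste(nrow(v), ncol(v), nrm, ncm, sep = "\t"), con)
  writeLines(paste(c("id", colnames(rd), colnames(v)), collapse = "\t"), con)
  if (ncm > 0L)
    for (j in seq_len(ncm))
      writeLines(paste(c(colnames(cd)[j], rep("", nrm), cd[[j]]),
                       collapse = "\t"), con)
  num <- function(z) {
    out <- sprintf("%.17g", z)
    out[!is.finite(z)] <- "NA"
    out
  }
  for (i in seq_len(nrow(v))) {
    meta <- if (nrm > 0L) vapply(seq_len(nrm), function(j) rd[i, j], "") else
      character()
    writeLines(paste(c(rownames(v)[i], meta, num(v[i, ])),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a delimited (TSV/CSV) expression matrix
#'
#' @param path Path to a rectangular delimited file with a header row
#'   and an ID column first.
#' @param orientation \code{"genes_in_rows"} (default) or
#'   \code{"genes_in_columns"} (the matrix is transposed after
#'   reading).
#' @param sep Field separator; guessed from the extension by default
#'   (\code{.csv} is comma, anything else tab).
#' @param domain,valueKind Tags for the result.
#' @return A \linkS4class{DomainMatrix}.
#' @export
readDelimited <- function(path,
                          orientation = c("genes_in_rows",
                                          "genes_in_columns"),
                          sep = NULL,
                          domain = c("target", "source"),
                          valueKind = c("continuous", "counts")) {
  orientation <- match.arg(orientation)
  domain <- match.arg(domain)
  valueKind <- match.arg(valueKind)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  nf <- utils::count.fields(path, sep = sep, quote = "\"",
                            blank.lines.skip = FALSE)
  if (length(unique(nf)) != 1L)
    stop("ragged delimited file: rows have differing field counts")
  dt <- data.table::fread(path, sep = sep, header = TRUE,
                          data.table = FALSE, check.names = FALSE)
  ids <- as.character(dt[[1L]])
  m <- as.matrix(dt[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (orientation == "genes_in_columns") m <- t(m)
  DomainMatrix(m, domain = domain, valueKind = valueKind)
}

#' Write a delimited expression matrix
#'
#' @param x A \linkS4class{DomainMatrix}.
#' @param path Output path; \code{.csv} selects comma separation.
#' @param orientation As in \code{\link{readDelimited}}.
#' @param idColumn Name of the leading identifier column.
#' @return Invisibly, \code{path}.
#' @export
writeDelimited <- function(x, path,
                           orientation = c("genes_in_rows",
                                           "genes_in_columns"),
                           idColumn = "id") {
  orientation <- match.arg(orientation)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  m <- exprValues(x)
  if (orientation == "genes_in_columns") m <- t(m)
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- idColumn
  data.table::fwrite(df, path, sep = sep)
  invisible(path)
}

#' Read/write sparse coordinate count matrices (MatrixMarket)
#'
#' Counts are stored as a MatrixMarket triplet file plus two sidecar
#' text files with the gene and sample identifiers (one per line).
#'
#' @param path Path of the \code{.mtx} file; sidecars use suffixes
#'   \code{.genes.txt} and \code{.samples.txt}.
#' @param domain Domain tag (counts are normally source data).
#' @return \code{readSparseCounts}: a \linkS4class{DomainMatrix} with
#'   \code{valueKind = "counts"}.
#' @export
readSparseCounts <- function(path, domain = c("source", "target")) {
  domain <- match.arg(domain)
  m <- as.matrix(Matrix::readMM(path))
  rownames(m) <- readLines(paste0(path, ".genes.txt"))
  colnames(m) <- readLines(paste0(path, ".samples.txt"))
  DomainMatrix(m, domain = domain, valueKind = "counts")
}

#' @rdname readSparseCounts
#' @param x A counts \linkS4class{DomainMatrix}.
#' @export
writeSparseCounts <- function(x, path) {
  stopifnot(valueKind(x) == "counts")
  Matrix::writeMM(Matrix::Matrix(exprValues(x), sparse = TRUE), path)
  writeLines(geneIds(x), paste0(path, ".genes.txt"))
  writeLines(sampleIds(x), paste0(path, ".samples.txt"))
  invisible(path)
}

#' Read/write per-profile metadata
#'
#' Tab-separated with columns \code{sample_id}, \code{compound_id},
#' \code{cell_line}, \code{dose}, \code{time}.
#'
#' @param path TSV path.
#' @return \code{readProfileMetadata}: a \code{data.frame}.
#' @export
readProfileMetadata <- function(path) {
  md <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE, colClasses = "character")
  need <- c("sample_id", "compound_id", "cell_line", "dose", "time")
  miss <- setdiff(need, colnames(md))
  if (length(miss))
    stop("metadata is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(md$sample_id)) stop("duplicate sample_id in metadata")
  md
}

#' @rdname readProfileMetadata
#' @param metadata A metadata \code{data.frame}.
#' @export
writeProfileMetadata <- function(metadata, path) {
  data.table::fwrite(metadata, path, sep = "\t")
  invisible(path)
}

#' Restrict two matrices to their shared gene space
#'
#' Both matrices are subset to the intersection of their gene
#' identifiers, in identical lexicographic (C-collation) order, so that
#' rows correspond one-to-one across domains.
#'
#' @param source,target \linkS4class{DomainMatrix} objects.
#' @return A list with elements \code{source} and \code{target}.
#' @export
alignGenes <- function(source, target) {
  shared <- .lexsort(intersect(geneIds(source), geneIds(target)))
  if (!length(shared))
    stop("the two matrices share no gene identifiers")
  list(source = source[shared, ], target = target[shared, ])
}
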