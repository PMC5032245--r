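#' @import methods
#' @import S4Vectors
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   rowData colData assayNames
#' @importFrom GenomicRanges GRanges seqnames start end strand
#'   findOverlaps distance distanceToNearest resize
#' @importFrom IRanges IRanges
NULL

#' Methylation beta-value container
#'
#' A \code{BetaSet} holds a CpG x sample matrix of methylation beta values
#' (fractions in \[0, 1\]) in the \code{"beta"} assay, per-CpG genomic
#' coordinates in \code{rowData} (columns \code{chrom} and \code{pos},
#' 1-based point positions; \code{NA} for CpGs without an annotation), and
#' per-sample covariates in \code{colData} (\code{age} in years, \code{sex}
#' coded 0/1, optional \code{batch}, and one column per blood cell-type
#' fraction).  Cell-fraction column names are recorded in
#' \code{metadata(x)$cellFractionNames}.
#'
#' CpGs lacking coordinates stay in the object and take part in all
#' matrix-level analyses; only positional analyses (region calling, eQTM
#' distance filters, enrichment) exclude them.
#'
#' @slot ... inherits all slots from
#'   \linkS4class{SummarizedExperiment}.
#' @seealso [BetaSet()] for the constructor, [scanVariability()] for the
#'   main analysis entry point.
#' @export
setClass("BetaSet", contains = "SummarizedExperiment")

#' Normalized gene-expression container
#'
#' An \code{ExprSet} holds a gene x sample matrix of normalized, log-scale
#' expression values in the \code{"expr"} assay and per-gene coordinates in
#' \code{rowData} (\code{chrom}, \code{start}, \code{end}, \code{strand},
#' optional logical \code{coding}).
#'
#' @slot ... inherits all slots from
#'   \linkS4class{SummarizedExperiment}.
#' @seealso [ExprSet()], [cisMap()], [transMap()].
#' @export
setClass("ExprSet", contains = "SummarizedExperiment")

.validBetaSet <- function(object) {
  msg <- character()
  if (!("beta" %in% assayNames(object)))
    msg <- c(msg, "assay 'beta' is required")
  else {
    b <- assay(object, "beta")
    bad <- !is.na(b) & (b < 0 | b > 1)
    if (any(bad))
      msg <- c(msg, sprintf("%d beta values outside [0, 1]", sum(bad)))
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate CpG identifiers")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicate sample identifiers")
  rd <- rowData(object)
  if (all(c("chrom", "pos") %in% colnames(rd))) {
    has <- !is.na(rd$pos)
    if (any(has & (is.na(rd$chrom) | rd$chrom == "")))
      msg <- c(msg, "positioned CpGs must have a non-empty chrom")
    if (any(has & rd$pos < 1))
      msg <- c(msg, "CpG positions must be >= 1 (1-based points)")
  }
  cd <- colData(object)
  if ("age" %in% colnames(cd)) {
    if (any(is.na(cd$age)) || any(cd$age <= 0))
      msg <- c(msg, "ages must be positive and non-missing")
  }
  fr <- S4Vectors::metadata(object)$cellFractionNames
  if (length(fr)) {
    if (!all(fr %in% colnames(cd)))
      msg <- c(msg, "cellFractionNames not all present in colData")
    else {
      fm <- as.matrix(as.data.frame(cd[, fr, drop = FALSE]))
      if (any(fm < 0 | fm > 1))
        msg <- c(msg, "cell fractions must lie in [0, 1]")
      if (isTRUE(S4Vectors::metadata(object)$fractionsComplete)) {
        s <- rowSums(fm)
        if (any(s < 0.9 | s > 1.1))
          msg <- c(msg, "complete cell fractions must sum to [0.9, 1.1]")
      }
    }
  }
  if (length(msg)) msg else TRUE
}
setValidity("BetaSet", .validBetaSet)

.validExprSet <- function(object) {
  msg <- character()
  if (!("expr" %in% assayNames(object)))
    msg <- c(msg, "assay 'expr' is required")
  rd <- rowData(object)
  if (all(c("start", "end") %in% colnames(rd))) {
    ok <- is.na(rd$start) | is.na(rd$end) | rd$start <= rd$end
    if (!all(ok)) msg <- c(msg, "gene start must be <= end")
  }
  if ("strand" %in% colnames(rd)) {
    if (!all(rd$strand %in% c("+", "-", "*", NA)))
      msg <- c(msg, "strand must be one of '+', '-', '*'")
  }
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate gene identifiers")
  if (length(msg)) msg else TRUE
}
setValidity("ExprSet", .validExprSet)

#' Construct a BetaSet
#'
#' @param beta numeric matrix of methylation fractions, CpGs in rows,
#'   samples in columns; dimnames required.
#' @param annot optional per-CpG annotation `data.frame` with columns
#'   `cpg_id`, `chrom`, `pos` (1-based) and optionally `cgi_class`.  CpGs
#'   absent from `annot` get `NA` coordinates.
#' @param covariates optional per-sample `data.frame` with a `sample_id`
#'   column plus `age`, `sex` and further covariate columns; rows are
#'   matched to `colnames(beta)` by `sample_id`.
#' @param cellFractionNames character vector naming the covariate columns
#'   holding cell-type fractions.  Defaults to every covariate column other
#'   than `sample_id`, `age`, `sex` and `batch`.
#' @param fractionsComplete logical; declare that the named fractions cover
#'   whole blood, enabling the sum-to-one validity check.
#' @return a [BetaSet-class] object.
#' @examples
#' b <- matrix(runif(6), 3, 2,
#'             dimnames = list(paste0("cg", 1:3), c("s1", "s2")))
#' BetaSet(b)
#' @export
BetaSet <- function(beta, annot = NULL, covariates = NULL,
                    cellFractionNames = NULL, fractionsComplete = FALSE) {
  beta <- as.matrix(beta)
  if (is.null(rownames(beta)) || is.null(colnames(beta)))
    stop("'beta' must have row (CpG) and column (sample) names")
  storage.mode(beta) <- "double"
  rd <- S4Vectors::DataFrame(row.names = rownames(beta))
  if (!is.null(annot)) {
    idx <- match(rownames(beta), annot$cpg_id)
    rd$chrom <- as.character(annot$chrom[idx])
    rd$pos <- as.integer(annot$pos[idx])
    if ("cgi_class" %in% colnames(annot))
      rd$cgi_class <- as.character(annot$cgi_class[idx])
  } else {
    rd$chrom <- NA_character_
    rd$pos <- NA_integer_
  }
  cd <- S4Vectors::DataFrame(row.names = colnames(beta))
  md <- list(cellFractionNames = character(0),
             fractionsComplete = fractionsComplete)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (!("sample_id" %in% colnames(covariates)))
      stop("'covariates' must contain a sample_id column")
    idx <- match(colnames(beta), covariates$sample_id)
    if (any(is.na(idx)))
      stop("covariates missing for samples: ",
           paste(colnames(beta)[is.na(idx)], collapse = ", "),
           " (use alignSamples() to intersect first)")
    keep <- setdiff(colnames(covariates), "sample_id")
    cd <- S4Vectors::DataFrame(covariates[idx, keep, drop = FALSE],
                               row.names = colnames(beta))
    if (is.null(cellFractionNames))
      cellFractionNames <- setdiff(keep, c("age", "sex", "batch"))
    md$cellFractionNames <- cellFractionNames
  }
  new("BetaSet",
      SummarizedExperiment(assays = list(beta = beta), rowData = rd,
                           colData = cd, metadata = md))
}

#' Construct an ExprSet
#'
#' @param expr numeric matrix of normalized log-scale expression, genes in
#'   rows, samples in columns; dimnames required.
#' @param geneAnnot optional `data.frame` with columns `gene_id`, `chrom`,
#'   `start`, `end`, `strand` and optionally logical `coding`.
#' @return an [ExprSet-class] object.
#' @export
ExprSet <- function(expr, geneAnnot = NULL) {
  expr <- as.matrix(expr)
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("'expr' must have row (gene) and column (sample) names")
  storage.mode(expr) <- "double"
  rd <- S4Vectors::DataFrame(row.names = rownames(expr))
  if (!is.null(geneAnnot)) {
    idx <- match(rownames(expr), geneAnnot$gene_id)
    rd$chrom <- as.character(geneAnnot$chrom[idx])
    rd$start <- as.integer(geneAnnot$start[idx])
    rd$end <- as.integer(geneAnnot$end[idx])
    st <- as.character(geneAnnot$strand[idx])
    st[is.na(st) | !(st %in% c("+", "-"))] <- "*"
    rd$strand <- st
    if ("coding" %in% colnames(geneAnnot))
      rd$coding <- as.logical(geneAnnot$coding[idx])
  }
  new("ExprSet", SummarizedExperiment(assays = list(expr = expr),
                                      rowData = rd))
}

setMethod("show", "BetaSet", function(object) {
  cat("BetaSet with", nrow(object), "CpGs and", ncol(object), "samples\n")
  npos <- sum(!is.na(rowData(object)$pos))
  cat("  positioned CpGs:", npos, "\n")
  cd <- colData(object)
  if ("age" %in% colnames(cd))
    cat(sprintf("  age: %.1f-%.1f years\n", min(cd$age), max(cd$age)))
  fr <- S4Vectors::metadata(object)$cellFractionNames
  if (length(fr))
    cat("  cell fractions:", paste(fr, collapse = ", "), "\n")
})

setMethod("show", "ExprSet", function(object) {
  cat("ExprSet with", nrow(object), "genes and", ncol(object), "samples\n")
})
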