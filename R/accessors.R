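#' Accessors for BetaSet and ExprSet
#'
#' Small accessor layer over the underlying
#' \linkS4class{SummarizedExperiment} slots.
#'
#' @param x a [BetaSet-class] or [ExprSet-class].
#' @return `betaValues`/`exprValues` return the assay matrix;
#'   `sampleAges`, `sampleSex` numeric vectors; `cellFractions` a numeric
#'   matrix (samples x fractions, possibly 0 columns); `cpgRanges` and
#'   `geneRanges` a [GenomicRanges::GRanges] restricted to annotated
#'   rows (CpG positions become width-1 ranges).
#' @name accessors
NULL

#' @rdname accessors
#' @export
betaValues <- function(x) {
  stopifnot(is(x, "BetaSet"))
  assay(x, "beta")
}

#' @rdname accessors
#' @export
exprValues <- function(x) {
  stopifnot(is(x, "ExprSet"))
  assay(x, "expr")
}

#' @rdname accessors
#' @export
sampleAges <- function(x) {
  cd <- colData(x)
  if (!("age" %in% colnames(cd))) stop("no 'age' covariate attached")
  stats::setNames(as.numeric(cd$age), rownames(cd))
}

#' @rdname accessors
#' @export
sampleSex <- function(x) {
  cd <- colData(x)
  if (!("sex" %in% colnames(cd))) stop("no 'sex' covariate attached")
  stats::setNames(as.numeric(cd$sex), rownames(cd))
}

#' @rdname accessors
#' @export
cellFractions <- function(x) {
  fr <- S4Vectors::metadata(x)$cellFractionNames
  cd <- colData(x)
  m <- as.matrix(as.data.frame(cd[, fr, drop = FALSE]))
  rownames(m) <- rownames(cd)
  m
}

#' @rdname accessors
#' @export
cpgRanges <- function(x) {
  rd <- rowData(x)
  if (!all(c("chrom", "pos") %in% colnames(rd)))
    stop("no CpG coordinates attached")
  has <- !is.na(rd$pos) & !is.na(rd$chrom)
  GRanges(rd$chrom[has], IRanges(rd$pos[has], width = 1),
          cpg_id = rownames(x)[has])
}

#' @rdname accessors
#' @export
geneRanges <- function(x) {
  rd <- rowData(x)
  if (!all(c("chrom", "start", "end") %in% colnames(rd)))
    stop("no gene coordinates attached")
  has <- !is.na(rd$start) & !is.na(rd$chrom)
  strand <- if ("strand" %in% colnames(rd)) rd$strand[has] else "*"
  gr <- GRanges(rd$chrom[has], IRanges(rd$start[has], rd$end[has]),
                strand = strand, gene_id = rownames(x)[has])
  if ("coding" %in% colnames(rd)) gr$coding <- rd$coding[has]
  gr
}
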