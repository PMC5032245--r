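#' @importFrom utils read.delim write.table
NULL

.readMatrixTsv <- function(path, what = "CpG") {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character")
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop("duplicate ", what, " identifier(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(storage.mode(m) <- "double")
  bad <- which(is.na(m) & df[, -1, drop = FALSE] != "NA" &
                 df[, -1, drop = FALSE] != "", arr.ind = TRUE)
  if (nrow(bad))
    stop("non-numeric value at ", what, " '", ids[bad[1, 1]],
         "', sample '", colnames(m)[bad[1, 2]], "'")
  rownames(m) <- ids
  m
}

#' Read a methylation beta matrix
#'
#' Reads a tab-delimited CpG x sample matrix (first column CpG identifiers,
#' header row of sample identifiers) and, optionally, BED4 CpG coordinates.
#' BED intervals are 0-based half-open; the CpG point position is taken as
#' the BED `end` coordinate, giving a 1-based point.  CpGs without an
#' annotation row keep `NA` coordinates and are excluded from positional
#' analyses only.
#'
#' @param path path to the beta matrix file.
#' @param annotPath optional path to a BED4 file (`chrom start end cpg_id`).
#' @return a [BetaSet-class] (without covariates; see [alignSamples()]).
#' @export
readBetaMatrix <- function(path, annotPath = NULL) {
  m <- .readMatrixTsv(path, "CpG")
  out <- which(!is.na(m) & (m < 0 | m > 1), arr.ind = TRUE)
  if (nrow(out))
    stop("beta value outside [0, 1] at CpG '", rownames(m)[out[1, 1]],
         "', sample '", colnames(m)[out[1, 2]], "'")
  annot <- if (!is.null(annotPath)) readCpgAnnotation(annotPath)
  BetaSet(m, annot = annot)
}

#' Read BED4 CpG coordinates
#'
#' @param path BED4 file: `chrom start end cpg_id`, 0-based half-open.
#' @return `data.frame` with `cpg_id`, `chrom`, `pos` (1-based point = BED
#'   end).
#' @export
readCpgAnnotation <- function(path) {
  bed <- read.delim(path, header = FALSE, sep = "\t",
                    colClasses = c("character", "integer", "integer",
                                   "character"))
  data.frame(cpg_id = bed[[4]], chrom = bed[[1]],
             pos = bed[[3]], stringsAsFactors = FALSE)
}

#' Read a per-sample covariate table
#'
#' Expects a tab-delimited table with columns `sample_id`, `age`, `sex`,
#' optionally `batch`, and one column per cell-type fraction.  Sex is
#' recoded to 0/1 via `config$sexLevels` when textual.
#'
#' @param path file path.
#' @param config a [vmpConfig()]; supplies the plausible age range and the
#'   sex coding.
#' @return `data.frame` with numeric `age` and 0/1 `sex`.
#' @export
readCovariateTable <- function(path, config = vmpConfig()) {
  # read as character: type.convert would turn sex codes like "F" into
  # logicals
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE, colClasses = "character")
  num <- suppressWarnings(lapply(df, as.numeric))
  for (j in seq_along(df))
    if (!anyNA(num[[j]])) df[[j]] <- num[[j]]
  need <- c("sample_id", "age", "sex")
  if (!all(need %in% colnames(df)))
    stop("covariate table must contain columns: ",
         paste(need, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample identifiers in covariate table")
  df$age <- suppressWarnings(as.numeric(df$age))
  if (any(is.na(df$age)))
    stop("missing or non-numeric age")
  rng <- config$ageRangePlausible
  if (any(df$age < rng[1] | df$age > rng[2]))
    stop("age outside the declared plausible range [", rng[1], ", ",
         rng[2], "]")
  if (!is.numeric(df$sex)) {
    sx <- match(as.character(df$sex), config$sexLevels) - 1L
    if (any(is.na(sx)))
      stop("sex codes not covered by config$sexLevels: ",
           paste(unique(df$sex[is.na(sx)]), collapse = ", "))
    df$sex <- sx
  }
  if (any(is.na(df$sex))) stop("missing sex")
  fr <- setdiff(colnames(df), c("sample_id", "age", "sex", "batch"))
  for (f in fr) {
    df[[f]] <- suppressWarnings(as.numeric(df[[f]]))
    if (any(is.na(df[[f]]) | df[[f]] < 0 | df[[f]] > 1))
      stop("cell fraction column '", f, "' must lie in [0, 1]")
  }
  df
}

#' Read a normalized expression matrix with gene coordinates
#'
#' @param path tab-delimited gene x sample matrix (first column gene id).
#' @param geneAnnotPath tab-delimited gene annotation with header
#'   `gene_id chrom start end strand` (optionally `coding`).
#' @return an [ExprSet-class].
#' @export
readExpressionMatrix <- function(path, geneAnnotPath = NULL) {
  m <- .readMatrixTsv(path, "gene")
  ga <- if (!is.null(geneAnnotPath))
    read.delim(geneAnnotPath, header = TRUE, sep = "\t",
               stringsAsFactors = FALSE)
  ExprSet(m, geneAnnot = ga)
}

#' Read interval annotation tracks
#'
#' Reads a BED3+name file into a named `GRangesList`-like list: intervals
#' sharing a name column value form one track (e.g. one chromatin state).
#' BED coordinates are 0-based half-open and are converted to the usual
#' 1-based inclusive `GRanges` convention, so that a 1-based CpG point
#' overlaps a track interval exactly when `pos - 1` lies in
#' `[start0, end0)`.
#'
#' @param path BED file path.
#' @return named list of [GenomicRanges::GRanges], one element per label.
#' @export
readAnnotationTracks <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (is.null(gr$name)) gr$name <- "track"
  if (any(GenomicRanges::width(gr) < 1))
    stop("degenerate interval (start >= end) in ", path)
  lst <- split(gr, gr$name)
  lapply(as.list(lst), function(g) sort(g))
}

#' Restrict objects to their shared samples
#'
#' Intersects the sample identifiers of a beta matrix, a covariate table
#' and (optionally) an expression matrix, reorders everything to the beta
#' matrix's order over the intersection, and attaches the covariates to the
#' returned [BetaSet-class].
#'
#' @param beta a [BetaSet-class].
#' @param covariates covariate `data.frame` with a `sample_id` column.
#' @param expr optional [ExprSet-class]; its samples may be a subset.
#' @param config a [vmpConfig()].
#' @return list with elements `beta` (covariates attached), `expr` (or
#'   `NULL`), and `dropped`, a named integer vector of per-input dropped
#'   sample counts.
#' @export
alignSamples <- function(beta, covariates, expr = NULL,
                         config = vmpConfig()) {
  ids <- intersect(colnames(beta), covariates$sample_id)
  if (!is.null(expr)) {
    if (length(intersect(ids, colnames(expr))) == 0 && length(ids) == 0)
      stop("no shared samples")
  }
  if (length(ids) == 0)
    stop("no shared samples between beta matrix and covariate table")
  dropped <- c(beta = ncol(beta) - length(ids),
               covariates = nrow(covariates) - length(ids))
  ids <- colnames(beta)[colnames(beta) %in% ids]
  b <- betaValues(beta)[, ids, drop = FALSE]
  annotDf <- as.data.frame(rowData(beta))
  annot <- if ("pos" %in% colnames(annotDf))
    data.frame(cpg_id = rownames(beta), annotDf, stringsAsFactors = FALSE)
  out <- BetaSet(b, annot = annot, covariates = covariates)
  exprOut <- NULL
  if (!is.null(expr)) {
    eids <- ids[ids %in% colnames(expr)]
    if (length(eids) == 0) stop("no shared samples with expression matrix")
    dropped <- c(dropped, expr = ncol(expr) - length(eids))
    exprOut <- expr[, eids]
  }
  list(beta = out, expr = exprOut, dropped = dropped)
}

#' Write a matrix or table as tab-delimited text
#'
#' Deterministic writers used by [runPipeline()]; numbers are written with
#' full precision so that write/read round-trips are exact.
#'
#' @param x matrix (with dimnames) or data.frame.
#' @param path output path.
#' @param idColumn name of the first column holding rownames (matrices).
#' @export
writeMatrixTsv <- function(x, path, idColumn = "id") {
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- idColumn
  writeTableTsv(df, path)
  invisible(path)
}

#' @rdname writeMatrixTsv
#' @export
writeTableTsv <- function(x, path) {
  x <- as.data.frame(x)
  # 17 significant digits: doubles survive the write/read round trip
  for (j in seq_along(x))
    if (is.double(x[[j]]))
      x[[j]] <- sprintf("%.17g", x[[j]])
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
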