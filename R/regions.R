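#' Call age-related variably methylated regions (aVMRs)
#'
#' Greedy one-dimensional clustering of positioned aVMPs per chromosome:
#' walking along sorted positions, a CpG joins the current chain while its
#' gap to the previous member is at most `avmrMaxGap` (1 kb by default);
#' chains with at least `avmrMinCpgs` members (3 by default) become
#' regions spanning their first to last member position (1-based
#' inclusive).  Regions are optionally annotated with the nearest
#' protein-coding gene by distance to the gene's nearest boundary; an
#' exact distance tie between an upstream and a downstream gene is
#' resolved toward the gene whose transcription start site is nearer.
#'
#' @param avmps `data.frame` with columns `cpg_id`, `chrom`, `pos`
#'   (1-based points), e.g. scan output joined to coordinates via
#'   [cpgRanges()], or any positioned CpG subset.
#' @param genes optional [GenomicRanges::GRanges] of genes with a
#'   `gene_id` column (and optional logical `coding`, used as a filter).
#' @param config a [vmpConfig()].
#' @return list with `regions` (`region_id`, `chrom`, `start`, `end`,
#'   `n_members`, `nearest_gene`) and `members` (`region_id`, `cpg_id`,
#'   `pos`).  Unsorted input is sorted internally; two distinct CpGs at an
#'   identical position are an error.
#' @export
callAvmrs <- function(avmps, genes = NULL, config = vmpConfig()) {
  need <- c("cpg_id", "chrom", "pos")
  if (!all(need %in% colnames(avmps)))
    stop("'avmps' needs columns: ", paste(need, collapse = ", "))
  avmps <- avmps[!is.na(avmps$pos) & !is.na(avmps$chrom), need]
  avmps <- avmps[!duplicated(avmps$cpg_id), ]
  avmps <- avmps[order(avmps$chrom, avmps$pos, avmps$cpg_id), ]
  dup <- duplicated(avmps[, c("chrom", "pos")])
  if (any(dup))
    stop("distinct CpGs at identical position: ",
         paste(utils::head(avmps$cpg_id[dup], 5), collapse = ", "))

  regions <- list(); members <- list()
  rid <- 0L
  for (ch in unique(avmps$chrom)) {
    sub <- avmps[avmps$chrom == ch, ]
    breaks <- c(0L, which(diff(sub$pos) > config$avmrMaxGap),
                nrow(sub))
    for (k in seq_len(length(breaks) - 1L)) {
      idx <- (breaks[k] + 1L):breaks[k + 1L]
      if (length(idx) < config$avmrMinCpgs) next
      rid <- rid + 1L
      id <- sprintf("avmr%04d", rid)
      regions[[rid]] <- data.frame(
        region_id = id, chrom = ch,
        start = sub$pos[idx[1]], end = sub$pos[idx[length(idx)]],
        n_members = length(idx), nearest_gene = NA_character_,
        stringsAsFactors = FALSE)
      members[[rid]] <- data.frame(region_id = id,
                                   cpg_id = sub$cpg_id[idx],
                                   pos = sub$pos[idx],
                                   stringsAsFactors = FALSE)
    }
  }
  regions <- if (length(regions)) do.call(rbind, regions) else
    data.frame(region_id = character(), chrom = character(),
               start = integer(), end = integer(), n_members = integer(),
               nearest_gene = character(), stringsAsFactors = FALSE)
  members <- if (length(members)) do.call(rbind, members) else
    data.frame(region_id = character(), cpg_id = character(),
               pos = integer(), stringsAsFactors = FALSE)

  if (!is.null(genes) && nrow(regions)) {
    if (!is.null(genes$coding)) genes <- genes[genes$coding]
    regions$nearest_gene <- vapply(seq_len(nrow(regions)), function(i) {
      onCh <- genes[as.character(seqnames(genes)) == regions$chrom[i]]
      if (!length(onCh)) return(NA_character_)
      d <- pmax(start(onCh) - regions$end[i],
                regions$start[i] - end(onCh), 0L)
      best <- which(d == min(d))
      if (length(best) > 1L) {
        tss <- ifelse(as.character(strand(onCh[best])) == "-",
                      end(onCh[best]), start(onCh[best]))
        mid <- (regions$start[i] + regions$end[i]) / 2
        best <- best[order(abs(tss - mid), onCh$gene_id[best])]
      }
      onCh$gene_id[best[1]]
    }, character(1))
  }
  list(regions = regions, members = members)
}

#' Write regions as BED6
#'
#' @param avmrs output of [callAvmrs()].
#' @param path output path; the BED interval is `[start - 1, end)` in the
#'   0-based half-open convention, score is the member count.
#' @export
writeAvmrBed <- function(avmrs, path) {
  r <- avmrs$regions
  bed <- data.frame(r$chrom, r$start - 1L, r$end, r$region_id,
                    r$n_members, rep(".", nrow(r)))
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
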