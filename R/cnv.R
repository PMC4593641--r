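#' @include readers.R
NULL

#' Genes overlapped by a CNV
#'
#' Every gene whose interval overlaps the CNV by at least 1 bp (the
#' BEDTools-intersect default), in positional order. A CNV on a chromosome
#' absent from the gene models yields an empty list with a warning.
#'
#' @param cnv a length-1 [GenomicRanges::GRanges] (one CNV).
#' @param gene_models gene intervals with a `gene_id` column
#'   ([readGeneModels()]).
#' @return character vector of gene identifiers.
#' @export
mapCNVGenes <- function(cnv, gene_models) {
  stopifnot(length(cnv) == 1L)
  chr <- as.character(GenomeInfoDb::seqnames(cnv))
  if (!chr %in% as.character(GenomeInfoDb::seqnames(gene_models))) {
    warning("CNV chromosome not present in gene models: ", chr)
    return(character(0))
  }
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(cnv, gene_models, minoverlap = 1L,
                                ignore.strand = TRUE))
  idx <- S4Vectors::subjectHits(hits)
  hit <- gene_models[idx]
  hit <- hit[order(BiocGenerics::start(hit), BiocGenerics::end(hit))]
  as.character(hit$gene_id)
}

#' Merge the regions of one benign-variant study
#'
#' Unions overlapping or touching intervals so that, within a study, no two
#' regions overlap; idempotent and base-coverage-preserving.
#'
#' @param regions a [GenomicRanges::GRanges] of one study's regions.
#' @return merged, position-sorted [GenomicRanges::GRanges].
#' @export
mergeStudyRegions <- function(regions) {
  GenomicRanges::reduce(
    BiocGenerics::sort(regions, ignore.strand = TRUE), ignore.strand = TRUE)
}

#' Benign-overlap frequency of a CNV
#'
#' Over all studies' merged benign regions, sums overlap_bp / CNV_length
#' for every merged region covering at least `threshold` (default 50%,
#' ties included) of the CNV's length. Each study that fully covers the
#' CNV therefore contributes 1, so common variants score near the number
#' of studies observing them and rare ones score 0.
#'
#' @param cnv a length-1 [GenomicRanges::GRanges]; when `type_match` is
#'   TRUE it must carry a `type` column.
#' @param dgv a named [GenomicRanges::GRangesList] of merged study regions
#'   ([readDGVStudySet()]); when `type_match` is TRUE each element must
#'   carry a `type` column.
#' @param threshold minimal overlap as a fraction of CNV length; default 0.5.
#' @param type_match restrict to regions of the CNV's DUP/DEL type
#'   (off by default: benign evidence is type-agnostic).
#' @return a non-negative number.
#' @export
dgvFrequency <- function(cnv, dgv, threshold = 0.5, type_match = FALSE) {
  stopifnot(length(cnv) == 1L)
  len <- BiocGenerics::width(cnv)
  total <- 0
  for (study in names(dgv)) {
    regions <- dgv[[study]]
    if (type_match) regions <- regions[regions$type == cnv$type]
    hits <- suppressWarnings(
      GenomicRanges::findOverlaps(cnv, regions, ignore.strand = TRUE))
    if (!length(hits)) next
    ov <- GenomicRanges::pintersect(
      rep(GenomicRanges::granges(cnv), length(hits)),
      GenomicRanges::granges(regions[S4Vectors::subjectHits(hits)]))
    w <- BiocGenerics::width(ov)
    w <- w[w >= threshold * len]
    total <- total + sum(w / len)
  }
  total
}

#' Derive the CNV-classifier features for a CNV table
#'
#' Computes, per CNV: its overlapped genes, its length (end - start) and
#' its benign-overlap frequency. The causative-gene flag is added later by
#' the gene classifier.
#'
#' @param cnvs a [GenomicRanges::GRanges] CNV table ([readCNVTable()]).
#' @param gene_models gene intervals ([readGeneModels()]).
#' @param dgv merged study regions ([readDGVStudySet()]).
#' @param threshold,type_match passed to [dgvFrequency()].
#' @return the CNV table with added metadata columns `genes`
#'   (CharacterList), `length` and `dgv_frequency`.
#' @export
annotateCNVs <- function(cnvs, gene_models, dgv, threshold = 0.5,
                         type_match = FALSE) {
  genes <- lapply(seq_along(cnvs), function(i)
    mapCNVGenes(cnvs[i], gene_models))
  cnvs$genes <- IRanges::CharacterList(genes)
  cnvs$length <- BiocGenerics::width(cnvs)
  cnvs$dgv_frequency <- vapply(seq_along(cnvs), function(i)
    dgvFrequency(cnvs[i], dgv, threshold = threshold,
                 type_match = type_match), numeric(1))
  cnvs
}
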