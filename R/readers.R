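## Readers for the plain-text resource formats. All formats are
## tab-separated unless stated; lines starting with '!' or '#' are comments.

#' Read an OBO ontology into a Taxonomy
#'
#' Consumes only `[Term]` stanzas and their `id`, `name`, `is_a` and
#' `is_obsolete` fields; obsolete terms are dropped, as are is-a edges that
#' point at dropped terms. All other relations are ignored: only "is a"
#' participates in similarity.
#'
#' @param path path to an OBO file.
#' @return a [Taxonomy-class]. Term names are attached as the `termNames`
#'   attribute (named character vector).
#' @export
readOBO <- function(path) {
  lines <- readLines(path, warn = FALSE)
  in_term <- FALSE
  terms <- character(); nm <- character()
  child <- character(); parent <- character()
  obsolete <- character()
  id <- NA_character_
  for (ln in lines) {
    ln <- sub("\\s+$", "", ln)
    if (grepl("^\\[", ln)) {
      in_term <- identical(ln, "[Term]")
      id <- NA_character_
      next
    }
    if (!in_term || !nzchar(ln)) next
    if (grepl("^id:", ln)) {
      id <- sub("^id:\\s*", "", ln)
      terms <- c(terms, id)
    } else if (grepl("^name:", ln) && !is.na(id)) {
      nm[id] <- sub("^name:\\s*", "", ln)
    } else if (grepl("^is_a:", ln) && !is.na(id)) {
      p <- sub("^is_a:\\s*", "", ln)
      p <- sub("\\s*!.*$", "", p)      # strip trailing comment
      child <- c(child, id); parent <- c(parent, p)
    } else if (grepl("^is_obsolete:\\s*true", ln) && !is.na(id)) {
      obsolete <- c(obsolete, id)
    }
  }
  keep <- setdiff(unique(terms), obsolete)
  sel <- child %in% keep & parent %in% keep
  tax <- Taxonomy(keep, data.frame(child = child[sel], parent = parent[sel],
                                   stringsAsFactors = FALSE))
  attr(tax, "termNames") <- nm[intersect(names(nm), keep)]
  tax
}

#' Read gene/target annotations (GAF or minimal dialect)
#'
#' Accepts three layouts, distinguished by column count: full GAF 2.x
#' (>= 15 columns; gene symbol, term and evidence code are taken from
#' columns 3, 5 and 7), a 3-column dialect `target, term, evidence`, and a
#' 2-column dialect `target, term` (evidence `NA`), used for phenotype-to-
#' disorder annotations and small fixtures.
#'
#' @param path path to the annotation file.
#' @return data.frame with character columns `target`, `term`, `evidence`.
#' @export
readAnnotations <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !grepl("^[!#]", lines)]
  if (!length(lines))
    return(data.frame(target = character(), term = character(),
                      evidence = character(), stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nc <- lengths(parts)
  pick <- function(p) {
    if (length(p) >= 15L) c(p[[3L]], p[[5L]], p[[7L]])
    else if (length(p) == 3L) c(p[[1L]], p[[2L]], p[[3L]])
    else if (length(p) == 2L) c(p[[1L]], p[[2L]], NA_character_)
    else stop("annotation rows must have 2, 3 or >=15 columns (found ",
              length(p), ")")
  }
  m <- t(vapply(parts, pick, character(3)))
  unique(data.frame(target = m[, 1L], term = m[, 2L], evidence = m[, 3L],
                    stringsAsFactors = FALSE))
}

#' Read a slim term list
#'
#' @param path flat file with one term identifier per line.
#' @return character vector of slim term identifiers.
#' @export
readSlimTerms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  unique(lines[nzchar(lines) & !grepl("^[!#]", lines)])
}

#' Read a weighted gene interaction edge list
#'
#' GeneMANIA precombined style: three tab-separated columns
#' `gene_a`, `gene_b`, `weight`. Duplicate (unordered) pairs are summed;
#' self-loops are rejected.
#'
#' @param path path to the edge list.
#' @return a [GeneNetwork-class].
#' @export
readGeneNetwork <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("from", "to", "weight"),
                          colClasses = c("character", "character", "numeric"),
                          comment.char = "#", quote = "")
  GeneNetwork(df)
}

#' Construct a GeneNetwork from an edge data.frame
#'
#' @param edges data.frame with columns `from`, `to`, `weight`; unordered
#'   duplicate pairs are summed.
#' @param nodes optional full node set (to keep isolates).
#' @return a [GeneNetwork-class].
#' @export
GeneNetwork <- function(edges, nodes = NULL) {
  from <- pmin(as.character(edges$from), as.character(edges$to))
  to <- pmax(as.character(edges$from), as.character(edges$to))
  if (any(from == to)) stop("self-loops are not allowed")
  w <- as.numeric(edges$weight)
  if (any(!is.finite(w)) || any(w <= 0)) stop("edge weights must be positive")
  key <- paste0(from, "\r", to)
  agg <- rowsum(w, key)
  uk <- rownames(agg)
  sp <- strsplit(uk, "\r", fixed = TRUE)
  e <- data.frame(from = vapply(sp, `[[`, "", 1L),
                  to = vapply(sp, `[[`, "", 2L),
                  weight = as.numeric(agg[, 1L]), stringsAsFactors = FALSE)
  e <- e[order(e$from, e$to, method = "radix"), , drop = FALSE]
  rownames(e) <- NULL
  nodes <- csort(unique(c(nodes, e$from, e$to)))
  new("GeneNetwork", nodes = nodes, edges = e,
      maxWeight = if (nrow(e)) max(e$weight) else NA_real_)
}

#' Read a gene-to-phenotype catalog
#'
#' Tab-separated `gene`, `phenotype terms` where the second column is a
#' semicolon-joined list of phenotype term identifiers (the style of HPO
#' annotation extracts of OMIM gene-disease links).
#'
#' @param path path to the catalog file.
#' @return data.frame with character column `gene` and list column
#'   `phenotypes`.
#' @export
readGenePhenotypeCatalog <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !grepl("^[!#]", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stop("catalog rows must have exactly 2 tab-separated columns")
  df <- data.frame(gene = vapply(parts, `[[`, "", 1L),
                   stringsAsFactors = FALSE)
  df$phenotypes <- lapply(parts, function(p)
    unique(strsplit(p[[2L]], ";", fixed = TRUE)[[1L]]))
  df
}

#' Read gene models from BED4
#'
#' Columns: chrom, start, end, gene identifier, 0-based half-open.
#'
#' @param path path to the BED file.
#' @return a [GenomicRanges::GRanges] with a `gene_id` metadata column,
#'   sorted by position.
#' @export
readGeneModels <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "gene_id"),
                          colClasses = c("character", "integer", "integer",
                                         "character"),
                          comment.char = "#", quote = "")
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1L, df$end),
                               gene_id = df$gene_id)
  GenomicRanges::sort(gr, ignore.strand = TRUE)
}

#' Read a DGV-style benign region table
#'
#' Tab-separated `study_id`, `chrom`, `start`, `end` (0-based half-open).
#' Regions are merged per study on reading (overlapping or touching
#' intervals are unioned), as benign-overlap scoring requires.
#'
#' @param path path to the region table.
#' @return a named [GenomicRanges::GRangesList], one merged element per
#'   study.
#' @export
readDGVStudySet <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("study", "chrom", "start", "end"),
                          colClasses = c("character", "character", "integer",
                                         "integer"),
                          comment.char = "#", quote = "")
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1L, df$end))
  grl <- GenomicRanges::split(gr, factor(df$study, levels = csort(unique(df$study))))
  S4Vectors::endoapply(grl, mergeStudyRegions)
}

#' Read a clinical CNV table
#'
#' The six-column dialect `chromosome, start, end, type [DUP/DEL],
#' phenotype, classification [HARMFUL/BENIGN]` (tab-separated, optional
#' header line, 0-based half-open coordinates; the phenotype column may hold
#' several semicolon-joined terms). An optional seventh column `patient`
#' carries a patient identifier, needed only for the patient-based
#' ("unbalanced") evaluation regime. The classification column may be empty
#' in inference mode.
#'
#' @param path path to the CNV table.
#' @return a [GenomicRanges::GRanges] with metadata columns `cnv_id`,
#'   `type`, `phenotypes`, `label`, `patient`; CNV length (end - start) is
#'   the range width.
#' @export
readCNVTable <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  lineno <- seq_along(lines)
  drop <- grepl("^#", lines)
  if (length(lines) && grepl("^chrom", lines[1L], ignore.case = TRUE))
    drop[1L] <- TRUE
  lines <- lines[!drop]; lineno <- lineno[!drop]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  n <- length(parts)
  rec <- function(i) {
    p <- parts[[i]]
    if (!length(p) %in% c(6L, 7L))
      stop("line ", lineno[i], ": expected 6 or 7 tab-separated columns, got ",
           length(p))
    start <- suppressWarnings(as.integer(p[[2L]]))
    end <- suppressWarnings(as.integer(p[[3L]]))
    if (is.na(start) || is.na(end))
      stop("line ", lineno[i], ": non-numeric coordinates")
    if (end <= start)
      stop("line ", lineno[i], ": end must exceed start")
    type <- toupper(p[[4L]])
    if (!type %in% c("DUP", "DEL"))
      stop("line ", lineno[i], ": type must be DUP or DEL, got '", p[[4L]], "'")
    lab <- toupper(p[[6L]])
    if (!lab %in% c("HARMFUL", "BENIGN", ""))
      stop("line ", lineno[i],
           ": classification must be HARMFUL, BENIGN or empty, got '",
           p[[6L]], "'")
    list(chrom = p[[1L]], start = start, end = end, type = type,
         phen = p[[5L]], label = if (nzchar(lab)) lab else NA_character_,
         patient = if (length(p) == 7L) p[[7L]] else NA_character_)
  }
  recs <- lapply(seq_len(n), rec)
  g <- function(f, mode) vapply(recs, `[[`, vector(mode, 1L), f)
  gr <- GenomicRanges::GRanges(
    g("chrom", "character"),
    IRanges::IRanges(g("start", "integer") + 1L, g("end", "integer")))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    cnv_id = sprintf("cnv%05d", seq_len(n)),
    type = g("type", "character"),
    phenotypes = g("phen", "character"),
    label = g("label", "character"),
    patient = g("patient", "character"))
  gr
}
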