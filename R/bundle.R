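#' @include simulate.R
NULL

# Internal: serialize a Taxonomy as a minimal OBO document.
writeOBO <- function(tax, path, name = "toy ontology") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", paste0("ontology: ", name), ""), con)
  for (t in tax@terms) {
    writeLines(c("[Term]", paste0("id: ", t), paste0("name: term ", t)), con)
    for (p in tax@parents[[t]])
      writeLines(paste0("is_a: ", p, " ! parent"), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Write a resource bundle to a directory of plain-text files
#'
#' Serializes a [simulateCohort()] bundle into the same formats the
#' readers consume: `go.obo`, `hpo.obo`, `slim.txt`, `annotations.tsv`
#' (3-column), `disorders.tsv` (2-column), `network.tsv` (edge list),
#' `catalog.tsv`, `genes.bed`, `dgv.tsv` and `cnvs.tsv` (7-column, with
#' the patient column). Output is byte-identical for identical bundles.
#'
#' @param resources a resource bundle.
#' @param dir destination directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeFixtureBundle <- function(resources, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  writeOBO(resources$go_tax, fp("go.obo"), "toy gene function ontology")
  writeOBO(resources$hpo_tax, fp("hpo.obo"), "toy phenotype ontology")
  writeLines(resources$slim, fp("slim.txt"))
  ann <- resources$annotations
  writeLines(paste(ann$target, ann$term, ann$evidence, sep = "\t"),
             fp("annotations.tsv"))
  dis <- resources$disorder_annotations
  writeLines(paste(dis$target, dis$term, sep = "\t"), fp("disorders.tsv"))
  e <- resources$network@edges
  writeLines(paste(e$from, e$to, format(e$weight, digits = 15, trim = TRUE,
                                        scientific = FALSE), sep = "\t"),
             fp("network.tsv"))
  cat_lines <- paste(resources$catalog$gene,
                     vapply(resources$catalog$phenotypes, paste,
                            character(1), collapse = ";"), sep = "\t")
  writeLines(cat_lines, fp("catalog.tsv"))
  gm <- resources$gene_models
  writeLines(paste(as.character(GenomeInfoDb::seqnames(gm)),
                   BiocGenerics::start(gm) - 1L, BiocGenerics::end(gm),
                   gm$gene_id, sep = "\t"), fp("genes.bed"))
  dgv_lines <- unlist(lapply(names(resources$dgv), function(s) {
    g <- resources$dgv[[s]]
    if (!length(g)) return(character(0))
    paste(s, as.character(GenomeInfoDb::seqnames(g)),
          BiocGenerics::start(g) - 1L, BiocGenerics::end(g), sep = "\t")
  }), use.names = FALSE)
  writeLines(dgv_lines, fp("dgv.tsv"))
  cv <- resources$cnvs
  writeLines(c(paste("chromosome", "start", "end", "type", "phenotype",
                     "classification", "patient", sep = "\t"),
               paste(as.character(GenomeInfoDb::seqnames(cv)),
                     BiocGenerics::start(cv) - 1L, BiocGenerics::end(cv),
                     cv$type, cv$phenotypes,
                     ifelse(is.na(cv$label), "", cv$label),
                     cv$patient, sep = "\t")), fp("cnvs.tsv"))
  if (!is.null(resources$meta))
    yaml::write_yaml(resources$meta[c("planted_slim", "causative_genes",
                                      "phenotype_vocabulary")],
                     fp("meta.yml"))
  invisible(dir)
}

#' Load a resource bundle from a directory
#'
#' Reads back a [writeFixtureBundle()] directory (or any directory laid
#' out the same way with real resources) through the package's format
#' readers.
#'
#' @param dir the bundle directory.
#' @return a resource-bundle list as produced by [simulateCohort()]
#'   (without generator metadata unless `meta.yml` is present).
#' @export
loadResources <- function(dir) {
  fp <- function(f) file.path(dir, f)
  out <- list(
    go_tax = readOBO(fp("go.obo")),
    slim = readSlimTerms(fp("slim.txt")),
    hpo_tax = readOBO(fp("hpo.obo")),
    annotations = readAnnotations(fp("annotations.tsv")),
    disorder_annotations = readAnnotations(fp("disorders.tsv")),
    network = readGeneNetwork(fp("network.tsv")),
    catalog = readGenePhenotypeCatalog(fp("catalog.tsv")),
    gene_models = readGeneModels(fp("genes.bed")),
    dgv = readDGVStudySet(fp("dgv.tsv")),
    cnvs = readCNVTable(fp("cnvs.tsv")))
  if (file.exists(fp("meta.yml"))) out$meta <- yaml::read_yaml(fp("meta.yml"))
  out
}

#' Write a synthetic clinical CNV table at published-cohort scale
#'
#' Generates a stand-in for a clinical six-column CNV table (chromosome,
#' start, end, type, phenotype, classification) with the class balance of
#' a diagnostic-laboratory cohort: 2,643 CNVs from 140 patients by
#' default, 162 labeled HARMFUL and the rest BENIGN, most patients
#' annotated with developmental delay. The content is entirely synthetic
#' (random coordinates, no real patients); it exists to exercise the
#' reader and the split protocols at realistic scale.
#'
#' @param path destination file.
#' @param n_harmful,n_benign class counts; defaults 162 and 2481.
#' @param n_patients patient count; default 140.
#' @param seed RNG seed.
#' @return `path`, invisibly.
#' @export
simulateClinicalTable <- function(path, n_harmful = 162L, n_benign = 2481L,
                                  n_patients = 140L, seed = 1L) {
  phen_pool <- c("developmental delay", "facial dysmorphism", "autism",
                 "cleft palate", "congenital heart defect",
                 "failure to thrive", "microcephaly", "seizures",
                 "short stature")
  withSeed(seed, {
    pat_ph <- sample(phen_pool, n_patients, TRUE,
                     prob = c(0.85, 0.07, rep(0.01, 7)))
    n <- n_harmful + n_benign
    patient <- c(seq_len(n_patients),            # every patient >= 1 harmful
                 sample(n_patients, n - n_patients, TRUE))
    label <- c(rep("HARMFUL", n_harmful), rep("BENIGN", n_benign))
    chrom <- paste0("chr", sample(c(1:22, "X"), n, TRUE))
    len <- round(stats::rlnorm(n, ifelse(label == "HARMFUL",
                                         log(3e5), log(6e4)), 1))
    start <- round(stats::runif(n, 1e5, 1e8))
    lines <- paste(chrom, start, start + pmax(len, 50L),
                   sample(c("DEL", "DUP"), n, TRUE), pat_ph[patient],
                   label, sep = "\t")
    writeLines(c(paste("chromosome", "start", "end", "type", "phenotype",
                       "classification", sep = "\t"), lines), path)
  })
  invisible(path)
}
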