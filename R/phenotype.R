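#' @include ontology.R network.R
NULL

#' Phenotype relevance of a candidate gene
#'
#' Scores how likely a gene is to cause the patient's phenotypes, from
#' prior knowledge: the maximum, over catalog entries (g, P) of known
#' phenotype-causing genes, of
#' sim(GO(query gene), GO(g)) * sim(patient phenotypes, P),
#' both similarities being the asymmetric information-content measure
#' ([setSimilarity()]).
#'
#' When the direct score is exactly 0 (no functional or no phenotypic
#' overlap with any catalog entry), the gene falls back on its interaction
#' neighborhood: the maximum direct relevance among its subnetwork
#' neighbors, scaled by the normalized proximity 1/d(query, neighbor)
#' (in (0, 1], so a fallback can never beat the neighbor it borrows from).
#' The fallback is one hop only: neighbors contribute their *direct*
#' scores.
#'
#' @param gene the candidate gene.
#' @param patient_phenotypes character vector of phenotype terms observed
#'   in the patient.
#' @param catalog data.frame `gene` / list column `phenotypes`
#'   ([readGenePhenotypeCatalog()]).
#' @param gene_terms named list: for each gene (candidates and catalog
#'   genes), its set of function-ontology terms.
#' @param go_tax,go_ag function ontology and its propagated annotations.
#' @param hpo_tax,hpo_ag phenotype ontology and its propagated
#'   (phenotype -> disorder) annotations.
#' @param sub the gene's [QuerySubnetwork-class] (or NULL); only needed for
#'   the fallback.
#' @param caches optional list(go=, hpo=) of memo environments shared
#'   across calls (performance).
#' @return list with `score` (>= 0) and `source` ("direct" or
#'   "neighbor-fallback").
#' @export
geneRelevance <- function(gene, patient_phenotypes, catalog, gene_terms,
                          go_tax, go_ag, hpo_tax, hpo_ag, sub = NULL,
                          caches = NULL) {
  if (is.null(caches))
    caches <- list(go = new.env(parent = emptyenv()),
                   hpo = new.env(parent = emptyenv()))
  go_ic <- termIC(go_ag)
  hpo_ic <- termIC(hpo_ag)
  direct <- function(g) {
    gt <- gene_terms[[g]]
    if (is.null(gt) || !length(gt) || !nrow(catalog)) return(0)
    best <- 0
    for (i in seq_len(nrow(catalog))) {
      s_go <- setSimilarity(gt, gene_terms[[catalog$gene[i]]] %||% character(0),
                            go_tax, go_ag, ic = go_ic, cache = caches$go)
      if (s_go == 0) next
      s_ph <- setSimilarity(patient_phenotypes, catalog$phenotypes[[i]],
                            hpo_tax, hpo_ag, ic = hpo_ic, cache = caches$hpo)
      best <- max(best, s_go * s_ph)
    }
    best
  }
  score <- direct(gene)
  if (score > 0 || is.null(sub) || length(sub@members) == 1L)
    return(list(score = score, source = "direct"))
  neighbors <- setdiff(sub@members, sub@query)
  fb <- 0
  for (nb in neighbors) {
    s <- direct(nb)
    if (s > 0) fb <- max(fb, s / sub@distances[[nb]])
  }
  if (fb > 0) list(score = fb, source = "neighbor-fallback")
  else list(score = 0, source = "direct")
}

#' Relevance-proportional training copy counts
#'
#' Converts the relevance scores of the genes of one CNV into the number of
#' copies each gene contributes to the gene classifier's training set:
#' copies(g) = ceiling(relevance(g) / sum(relevance) * copies_per_cnv), so
#' every CNV is represented by (just over) `copies_per_cnv` rows and the
#' most relevant genes dominate. A CNV whose genes all have zero relevance
#' gets a single copy per gene instead - such genes are uninformative and
#' flooding the training set with them would only add noise.
#'
#' @param relevances numeric vector of per-gene relevance scores (one CNV).
#' @param copies_per_cnv total copies representing each CNV; default 1000.
#' @return integer vector of copy counts, same order as `relevances`.
#' @export
trainingWeightsPhenotype <- function(relevances, copies_per_cnv = 1000L) {
  if (!length(relevances)) return(integer(0))
  if (any(relevances < 0)) stop("relevance scores must be non-negative")
  total <- sum(relevances)
  if (total == 0) return(rep(1L, length(relevances)))
  as.integer(ceiling(relevances / total * copies_per_cnv))
}

#' Uniform training copy counts
#'
#' The phenotype-agnostic alternative: every gene of the CNV gets
#' ceiling(copies_per_cnv / #genes) copies.
#'
#' @param n_genes number of genes in the CNV.
#' @param copies_per_cnv total copies representing each CNV; default 1000.
#' @return integer vector of length `n_genes`.
#' @export
trainingWeightsUniform <- function(n_genes, copies_per_cnv = 1000L) {
  if (n_genes == 0L) return(integer(0))
  rep(as.integer(ceiling(copies_per_cnv / n_genes)), n_genes)
}
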