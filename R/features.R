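#' @include AllClasses.R ontology.R
NULL

#' GO evidence code tiers
#'
#' Two-level grouping of annotation evidence codes used to damp feature
#' weights: tier 1 for experimentally supported annotations, tier 2 for
#' computational / inferred ones. Codes with no traceable source or no data
#' support are ignored (annotations carrying them are dropped). Codes not
#' listed anywhere are treated as tier 2 (inferred), the conservative
#' choice; a missing evidence code (the 2-column fixture dialect) is tier 1
#' so that fixtures without evidence information are not damped.
#'
#' @format list with character vectors `tier1`, `tier2`, `ignored`.
#' @export
evidenceTiers <- list(
  tier1 = c("EXP", "IDA", "IPI", "IMP", "IGI", "IEP", "TAS", "IC"),
  tier2 = c("ISS", "ISO", "ISA", "ISM", "IGC", "IBA", "RCA", "IEA"),
  ignored = c("ND", "NAS", "NR"))

#' Map evidence codes to tiers
#'
#' @param code character vector of evidence codes (NA allowed).
#' @return integer vector: 1, 2 or NA (ignored).
#' @export
evidenceTier <- function(code) {
  out <- ifelse(is.na(code) | code %in% evidenceTiers$tier1, 1L,
         ifelse(code %in% evidenceTiers$ignored, NA_integer_, 2L))
  as.integer(out)
}

#' Map every taxonomy term to its nearest slim ancestors
#'
#' For each term, finds the slim terms at minimal is-a path length above it
#' (a slim term maps to itself, path length 0). All slim ancestors tied at
#' the minimal distance are kept; terms with no slim ancestor map to the
#' empty set and contribute no feature.
#'
#' @param taxonomy a [Taxonomy-class].
#' @param slim_terms character vector of slim terms, a subset of the
#'   taxonomy ("the cut").
#' @return a [SlimMap-class].
#' @export
buildSlimMap <- function(taxonomy, slim_terms) {
  slim_terms <- unique(as.character(slim_terms))
  bad <- setdiff(slim_terms, taxonomy@terms)
  if (length(bad)) stop("slim terms not in taxonomy: ", paste(bad, collapse = ", "))
  mapping <- lapply(taxonomy@terms, function(t) {
    level <- t
    seen <- character(0)
    repeat {
      hit <- intersect(level, slim_terms)
      if (length(hit)) return(csort(hit))
      seen <- c(seen, level)
      level <- setdiff(unique(unlist(taxonomy@parents[level],
                                     use.names = FALSE)), seen)
      if (!length(level)) return(character(0))
    }
  })
  names(mapping) <- taxonomy@terms
  new("SlimMap", slim = csort(slim_terms), mapping = mapping)
}

#' Slim-level functional profile of a gene
#'
#' Maps a gene's raw annotations into the slim feature space: drops
#' annotations with ignored evidence, replaces each term by its nearest
#' slim ancestor(s), and keeps the best (lowest) evidence tier per slim
#' term, so redundant annotation rows never double-count.
#'
#' @param gene a gene identifier.
#' @param annotations data.frame `target`, `term`, `evidence` (the
#'   [readAnnotations()] layout).
#' @param slim_map a [SlimMap-class].
#' @return data.frame with columns `term` (slim) and `tier` (integer),
#'   zero rows for an unannotated gene.
#' @export
geneGOProfile <- function(gene, annotations, slim_map) {
  rows <- annotations[annotations$target == gene, , drop = FALSE]
  tier <- evidenceTier(rows$evidence)
  rows <- rows[!is.na(tier), , drop = FALSE]
  tier <- tier[!is.na(tier)]
  if (!nrow(rows))
    return(data.frame(term = character(), tier = integer()))
  unknown <- setdiff(unique(rows$term), names(slim_map@mapping))
  if (length(unknown))
    stop("annotated term(s) absent from taxonomy: ",
         paste(unknown, collapse = ", "))
  slim <- slim_map@mapping[rows$term]
  df <- data.frame(term = unlist(slim, use.names = FALSE),
                   tier = rep(tier, lengths(slim)))
  if (!nrow(df)) return(data.frame(term = character(), tier = integer()))
  best <- stats::aggregate(tier ~ term, df, min)
  best <- best[order(best$term, method = "radix"), , drop = FALSE]
  rownames(best) <- NULL
  best$tier <- as.integer(best$tier)
  best
}

# Internal: the query plus its top-k ranked neighbors (k >= 0), with the
# damping rank r (0 for the query) of each. Unranked or neighbor-less
# subnetworks contribute the query alone. NULL subnetwork = gene absent
# from the network.
contributingMembers <- function(gene, sub, k_neighbors) {
  if (is.null(sub) || length(sub@members) == 1L || k_neighbors == 0L)
    return(stats::setNames(0L, gene))
  r <- sub@ranks[sub@ranks <= k_neighbors]
  stats::setNames(c(0L, as.integer(r)), c(sub@query, names(r)))
}

#' Network-Uniform feature weights
#'
#' Every slim term annotating the query gene or any of its considered
#' neighbors (top `k_neighbors` by random-walk rank) gets weight 1,
#' regardless of where it came from.
#'
#' @param gene the query gene.
#' @param sub the gene's ranked [QuerySubnetwork-class], or NULL when the
#'   gene is absent from the network (its own profile is then used alone).
#' @param profiles named list of [geneGOProfile()] results, covering the
#'   gene and its subnetwork members.
#' @param k_neighbors how many ranked neighbors contribute; default 10.
#' @return named numeric vector of feature weights (slim terms with
#'   nonzero weight only).
#' @export
featureWeightsUniform <- function(gene, sub, profiles, k_neighbors = 10L) {
  members <- names(contributingMembers(gene, sub, k_neighbors))
  terms <- unique(unlist(lapply(profiles[members], function(p) p$term),
                         use.names = FALSE))
  stats::setNames(rep(1, length(terms)), csort(terms))
}

#' Network-Weighted feature weights
#'
#' Each feature's weight sums, over the query gene (damping rank r = 0) and
#' its top-`k_neighbors` ranked neighbors, the contribution
#' 10^(-r) * 10^(-e) of that member's surviving annotation of the term,
#' where e is the evidence tier. One best-tier contribution per
#' (member, term): a direct experimental annotation of the query is worth
#' 0.1, a tier-2 annotation seen on the rank-1 neighbor 0.001, and so on.
#'
#' @inheritParams featureWeightsUniform
#' @return named numeric vector of positive feature weights.
#' @export
featureWeightsNetwork <- function(gene, sub, profiles, k_neighbors = 10L) {
  mem <- contributingMembers(gene, sub, k_neighbors)
  acc <- new.env(parent = emptyenv())
  for (m in names(mem)) {
    prof <- profiles[[m]]
    if (is.null(prof) || !nrow(prof)) next
    contrib <- 10^(-mem[[m]]) * 10^(-prof$tier)
    for (i in seq_len(nrow(prof))) {
      t <- prof$term[i]
      acc[[t]] <- (acc[[t]] %||% 0) + contrib[i]
    }
  }
  terms <- csort(ls(acc))
  stats::setNames(vapply(terms, function(t) acc[[t]], numeric(1)), terms)
}
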