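#' @import methods
NULL

#' Taxonomy: a DAG of ontology terms linked by is-a edges
#'
#' Represents an ontology (gene function or phenotype) as a directed acyclic
#' graph over term identifiers. Only the "is a" relation is stored; it is the
#' sole relation used for semantic similarity. Ancestor sets are precomputed
#' at construction so that annotation propagation and common-ancestor queries
#' are table lookups.
#'
#' @slot terms character vector of term identifiers.
#' @slot parents named list; for each term, the character vector of its
#'   direct parents ("is a" targets). Root terms have zero parents.
#' @slot ancestors named list; for each term, its proper ancestors
#'   (excluding the term itself), in no guaranteed order.
#' @slot roots character vector of terms with no parents. A multi-rooted
#'   object is treated as a forest: terms under different roots have no
#'   common ancestor.
#' @exportClass Taxonomy
setClass("Taxonomy",
  representation(terms = "character", parents = "list",
                 ancestors = "list", roots = "character"))

setValidity("Taxonomy", function(object) {
  msg <- character()
  if (anyDuplicated(object@terms)) msg <- c(msg, "duplicated term identifiers")
  if (!identical(csort(names(object@parents)), csort(object@terms)))
    msg <- c(msg, "parents list must be named by exactly the term set")
  unknown <- setdiff(unique(unlist(object@parents, use.names = FALSE)), object@terms)
  if (length(unknown))
    msg <- c(msg, paste0("parent terms not in taxonomy: ",
                         paste(unknown, collapse = ", ")))
  # cycle check: every term must be absent from its own ancestor set
  self <- vapply(object@terms, function(t)
    t %in% object@ancestors[[t]], logical(1))
  if (any(self)) msg <- c(msg, "taxonomy contains a directed cycle")
  if (length(msg)) msg else TRUE
})

#' AnnotationGraph: bipartite term-to-target annotations
#'
#' Links ontology terms to annotated targets (genes for a function ontology,
#' disorders for a phenotype ontology). Information content is only
#' meaningful after ancestor propagation ([propagateAnnotations()]), which
#' adds, for each annotation, the same annotation for every ancestor of the
#' term.
#'
#' @slot edges data.frame with character columns `term` and `target`;
#'   one row per (term, target) annotation, unique.
#' @slot targets character vector of all targets (the denominator of the
#'   annotation frequency; may include targets with no surviving edges).
#' @slot propagated logical flag; TRUE once ancestor closure was applied.
#' @exportClass AnnotationGraph
setClass("AnnotationGraph",
  representation(edges = "data.frame", targets = "character",
                 propagated = "logical"))

setValidity("AnnotationGraph", function(object) {
  msg <- character()
  if (!all(c("term", "target") %in% names(object@edges)))
    msg <- c(msg, "edges must have columns 'term' and 'target'")
  else {
    if (anyDuplicated(paste0(object@edges$term, "\r", object@edges$target)))
      msg <- c(msg, "duplicate (term, target) edges")
    if (!all(object@edges$target %in% object@targets))
      msg <- c(msg, "edge targets missing from target set")
  }
  if (length(object@propagated) != 1L) msg <- c(msg, "propagated must be a flag")
  if (length(msg)) msg else TRUE
})

#' GeneNetwork: weighted undirected gene interaction network
#'
#' A composite functional-association network (GeneMANIA precombined style):
#' undirected edges between gene identifiers with positive weights. Edges are
#' stored canonically (`from` < `to`); the maximum edge weight is cached
#' because it is the scale factor of the weight-to-distance transform.
#'
#' @slot nodes character gene identifiers (isolated nodes allowed).
#' @slot edges data.frame with columns `from`, `to` (character) and
#'   `weight` (positive numeric); no self-loops, no duplicate pairs.
#' @slot maxWeight largest edge weight (NA for an edgeless network).
#' @exportClass GeneNetwork
setClass("GeneNetwork",
  representation(nodes = "character", edges = "data.frame",
                 maxWeight = "numeric"))

setValidity("GeneNetwork", function(object) {
  msg <- character()
  e <- object@edges
  if (!all(c("from", "to", "weight") %in% names(e)))
    return("edges must have columns from, to, weight")
  if (nrow(e)) {
    if (any(e$weight <= 0)) msg <- c(msg, "edge weights must be positive")
    if (any(e$from == e$to)) msg <- c(msg, "self-loops are not allowed")
    if (any(e$from > e$to)) msg <- c(msg, "edges must be canonical (from < to)")
    if (anyDuplicated(paste0(e$from, "\r", e$to))) msg <- c(msg, "duplicate edges")
    if (!all(c(e$from, e$to) %in% object@nodes))
      msg <- c(msg, "edge endpoints missing from node set")
    if (!isTRUE(all.equal(object@maxWeight, max(e$weight))))
      msg <- c(msg, "cached maxWeight disagrees with edges")
  }
  if (length(msg)) msg else TRUE
})

#' QuerySubnetwork: the Dijkstra neighborhood of one query gene
#'
#' The subnetwork centered on a query gene: its closest neighbors by
#' shortest-path distance over inverse-weight edge lengths, the edges among
#' them, and a sink node standing in for the connections severed when the
#' subnetwork was cut out of the full network. After ranking
#' ([randomWalkRanks()]) it also carries the random-walk probability of each
#' node and the resulting neighbor ranks.
#'
#' @slot query the query gene.
#' @slot members gene identifiers in the subnetwork, query included, sink
#'   excluded.
#' @slot sink name of the sink node (`character(0)` when no edge was cut).
#' @slot edges data.frame `from`, `to`, `weight`: edges among members plus
#'   member-sink edges whose weight is the summed weight of that member's
#'   removed connections.
#' @slot distances named numeric, Dijkstra distance from the query per
#'   member (0 for the query itself, >= 1 otherwise).
#' @slot maxWeight maximum edge weight of the *full* filtered network, the
#'   numerator of the distance and neighbor-weight transforms.
#' @slot walkProbabilities named numeric over members (and sink), summing
#'   to 1; empty until the walk is run.
#' @slot ranks named integer over non-query members, 1 = most probable;
#'   empty until the walk is run. The query's own rank is 0 by convention.
#' @exportClass QuerySubnetwork
setClass("QuerySubnetwork",
  representation(query = "character", members = "character",
                 sink = "character", edges = "data.frame",
                 distances = "numeric", maxWeight = "numeric",
                 walkProbabilities = "numeric", ranks = "integer"))

setValidity("QuerySubnetwork", function(object) {
  msg <- character()
  if (!object@query %in% object@members) msg <- c(msg, "query must be a member")
  if (!identical(csort(names(object@distances)), csort(object@members)))
    msg <- c(msg, "distances must be named by exactly the member set")
  else {
    d <- object@distances[setdiff(object@members, object@query)]
    if (length(d) && any(d < 1)) msg <- c(msg, "non-query distances must be >= 1")
  }
  if (length(object@walkProbabilities)) {
    if (abs(sum(object@walkProbabilities) - 1) > 1e-9)
      msg <- c(msg, "walk probabilities must sum to 1")
    if (any(object@walkProbabilities < 0))
      msg <- c(msg, "walk probabilities must be non-negative")
  }
  if (length(object@ranks)) {
    k <- length(setdiff(object@members, object@query))
    if (!identical(csort(as.integer(object@ranks)), seq_len(k)))
      msg <- c(msg, "ranks must be a permutation of 1..k over non-query members")
  }
  if (length(msg)) msg else TRUE
})

#' SlimMap: mapping from ontology terms to their nearest slim ancestors
#'
#' @slot slim the slim terms (the "cut" across the ontology).
#' @slot mapping named list; for each taxonomy term, the character vector of
#'   its nearest slim ancestors (all slim terms at minimal is-a path length;
#'   a slim term maps to itself; empty when no slim ancestor exists).
#' @exportClass SlimMap
setClass("SlimMap", representation(slim = "character", mapping = "list"))
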