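#' @include AllClasses.R
NULL

#' Accessors for the core classes
#'
#' Small read-only accessors; slots are implementation detail.
#'
#' @param x a pathoCNV S4 object.
#' @return `ontoTerms`, `networkNodes`, `subnetworkMembers`: character
#'   vectors. `networkEdges`: a data.frame. `maxEdgeWeight`: a number.
#'   `dijkstraDistances`, `walkProbabilities`: named numeric vectors.
#'   `neighborRanks`: named integer vector. `isPropagated`: logical flag.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("ontoTerms", function(x) standardGeneric("ontoTerms"))
#' @rdname accessors
#' @export
setMethod("ontoTerms", "Taxonomy", function(x) x@terms)

#' @rdname accessors
#' @export
setGeneric("isPropagated", function(x) standardGeneric("isPropagated"))
#' @rdname accessors
#' @export
setMethod("isPropagated", "AnnotationGraph", function(x) x@propagated)

#' @rdname accessors
#' @export
setGeneric("annotationEdges", function(x) standardGeneric("annotationEdges"))
#' @rdname accessors
#' @export
setMethod("annotationEdges", "AnnotationGraph", function(x) x@edges)

#' @rdname accessors
#' @export
setGeneric("annotationTargets", function(x) standardGeneric("annotationTargets"))
#' @rdname accessors
#' @export
setMethod("annotationTargets", "AnnotationGraph", function(x) x@targets)

#' @rdname accessors
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))
#' @rdname accessors
#' @export
setMethod("networkNodes", "GeneNetwork", function(x) x@nodes)

#' @rdname accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))
#' @rdname accessors
#' @export
setMethod("networkEdges", "GeneNetwork", function(x) x@edges)
#' @rdname accessors
#' @export
setMethod("networkEdges", "QuerySubnetwork", function(x) x@edges)

#' @rdname accessors
#' @export
setGeneric("maxEdgeWeight", function(x) standardGeneric("maxEdgeWeight"))
#' @rdname accessors
#' @export
setMethod("maxEdgeWeight", "GeneNetwork", function(x) x@maxWeight)
#' @rdname accessors
#' @export
setMethod("maxEdgeWeight", "QuerySubnetwork", function(x) x@maxWeight)

#' @rdname accessors
#' @export
setGeneric("queryGene", function(x) standardGeneric("queryGene"))
#' @rdname accessors
#' @export
setMethod("queryGene", "QuerySubnetwork", function(x) x@query)

#' @rdname accessors
#' @export
setGeneric("subnetworkMembers", function(x) standardGeneric("subnetworkMembers"))
#' @rdname accessors
#' @export
setMethod("subnetworkMembers", "QuerySubnetwork", function(x) x@members)

#' @rdname accessors
#' @export
setGeneric("sinkNode", function(x) standardGeneric("sinkNode"))
#' @rdname accessors
#' @export
setMethod("sinkNode", "QuerySubnetwork", function(x) x@sink)

#' @rdname accessors
#' @export
setGeneric("dijkstraDistances", function(x) standardGeneric("dijkstraDistances"))
#' @rdname accessors
#' @export
setMethod("dijkstraDistances", "QuerySubnetwork", function(x) x@distances)

#' @rdname accessors
#' @export
setGeneric("walkProbabilities", function(x) standardGeneric("walkProbabilities"))
#' @rdname accessors
#' @export
setMethod("walkProbabilities", "QuerySubnetwork", function(x) x@walkProbabilities)

#' @rdname accessors
#' @export
setGeneric("neighborRanks", function(x) standardGeneric("neighborRanks"))
#' @rdname accessors
#' @export
setMethod("neighborRanks", "QuerySubnetwork", function(x) x@ranks)

#' @rdname accessors
#' @export
setGeneric("slimTerms", function(x) standardGeneric("slimTerms"))
#' @rdname accessors
#' @export
setMethod("slimTerms", "SlimMap", function(x) x@slim)

setMethod("show", "Taxonomy", function(object) {
  cat("Taxonomy with", length(object@terms), "terms,",
      sum(lengths(object@parents)), "is-a edges,",
      length(object@roots), "root(s)\n")
})

setMethod("show", "AnnotationGraph", function(object) {
  cat("AnnotationGraph:", nrow(object@edges), "annotations over",
      length(unique(object@edges$term)), "terms and",
      length(object@targets), "targets",
      if (object@propagated) "(propagated)" else "(raw)", "\n")
})

setMethod("show", "GeneNetwork", function(object) {
  cat("GeneNetwork with", length(object@nodes), "genes and",
      nrow(object@edges), "weighted edges")
  if (nrow(object@edges))
    cat("; max weight", format(object@maxWeight, digits = 4))
  cat("\n")
})

setMethod("show", "QuerySubnetwork", function(object) {
  cat("QuerySubnetwork of", object@query, "with",
      length(object@members) - 1L, "neighbors",
      if (length(object@sink)) "and a sink node" else "(no sink)",
      if (length(object@ranks)) "[ranked]" else "[unranked]", "\n")
})

setMethod("show", "SlimMap", function(object) {
  cat("SlimMap:", length(object@slim), "slim terms;",
      length(object@mapping), "terms mapped\n")
})
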