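#' @include AllClasses.R
NULL

#' Construct a Taxonomy from is-a edges
#'
#' @param terms character vector of term identifiers.
#' @param parent_edges data.frame with character columns `child` and
#'   `parent`, one row per "is a" edge.
#' @return a [Taxonomy-class] object with ancestor closure precomputed.
#' @examples
#' tax <- Taxonomy(c("root", "a", "b"),
#'                 data.frame(child = c("a", "b"), parent = c("root", "a")))
#' termAncestors(tax, "b")
#' @export
Taxonomy <- function(terms, parent_edges = data.frame(child = character(),
                                                      parent = character())) {
  terms <- as.character(terms)
  child <- as.character(parent_edges$child)
  parent <- as.character(parent_edges$parent)
  bad <- setdiff(unique(c(child, parent)), terms)
  if (length(bad))
    stop("edge refers to unknown term(s): ", paste(bad, collapse = ", "))
  parents <- split(parent, factor(child, levels = terms))
  names(parents) <- terms
  parents <- lapply(parents, unique)

  # Kahn topological order, then ancestor sets by dynamic programming.
  indeg <- lengths(parents)          # number of parents per term
  children <- split(child, factor(parent, levels = terms))
  order <- character(0)
  queue <- terms[indeg == 0L]        # roots first
  indeg_left <- indeg
  while (length(queue)) {
    t <- queue[1L]; queue <- queue[-1L]
    order <- c(order, t)
    for (ch in children[[t]]) {
      indeg_left[[ch]] <- indeg_left[[ch]] - 1L
      if (indeg_left[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(order) != length(terms))
    stop("taxonomy is not a DAG (cycle among: ",
         paste(setdiff(terms, order), collapse = ", "), ")")
  anc <- vector("list", length(terms))
  names(anc) <- terms
  for (t in order)
    anc[[t]] <- unique(c(unlist(lapply(parents[[t]], function(p)
      c(p, anc[[p]])), use.names = FALSE)))
  anc <- lapply(anc, function(a) if (is.null(a)) character(0) else a)
  new("Taxonomy", terms = terms, parents = parents, ancestors = anc,
      roots = terms[indeg == 0L])
}

#' Ancestors of a term
#'
#' @param taxonomy a [Taxonomy-class].
#' @param term a term identifier.
#' @param include.self include the term itself (a term is an ancestor of
#'   itself for common-ancestor purposes)? Default TRUE.
#' @return character vector of ancestor term identifiers.
#' @export
termAncestors <- function(taxonomy, term, include.self = TRUE) {
  if (!term %in% taxonomy@terms) stop("unknown term: ", term)
  a <- taxonomy@ancestors[[term]]
  if (include.self) c(term, a) else a
}

#' Construct an AnnotationGraph
#'
#' @param edges data.frame with character columns `term` and `target`.
#' @param targets all targets; defaults to the targets present in `edges`.
#'   Supply explicitly when some targets carry no annotation (they still
#'   count in annotation frequencies).
#' @param propagated whether ancestor closure has already been applied.
#' @return an [AnnotationGraph-class].
#' @export
AnnotationGraph <- function(edges, targets = NULL, propagated = FALSE) {
  edges <- data.frame(term = as.character(edges$term),
                      target = as.character(edges$target),
                      stringsAsFactors = FALSE)
  edges <- unique(edges)
  if (is.null(targets)) targets <- unique(edges$target)
  new("AnnotationGraph", edges = edges, targets = as.character(targets),
      propagated = isTRUE(propagated))
}

#' Propagate annotations to ancestor terms
#'
#' Applies the ancestor closure: a target annotated with a term is considered
#' annotated with every broader term above it, so annotation frequencies are
#' monotone non-decreasing toward the root. Idempotent.
#'
#' @param taxonomy the companion [Taxonomy-class].
#' @param ag an [AnnotationGraph-class] whose terms all exist in `taxonomy`.
#' @return a propagated [AnnotationGraph-class].
#' @export
propagateAnnotations <- function(taxonomy, ag) {
  stopifnot(is(taxonomy, "Taxonomy"), is(ag, "AnnotationGraph"))
  unknown <- setdiff(unique(ag@edges$term), taxonomy@terms)
  if (length(unknown))
    stop("annotation uses term(s) absent from taxonomy: ",
         paste(unknown, collapse = ", "))
  if (!nrow(ag@edges))
    return(AnnotationGraph(ag@edges, targets = ag@targets, propagated = TRUE))
  closure <- lapply(unique(ag@edges$term), function(t)
    termAncestors(taxonomy, t, include.self = TRUE))
  names(closure) <- unique(ag@edges$term)
  n_anc <- lengths(closure)[ag@edges$term]
  out <- data.frame(
    term = unlist(closure[ag@edges$term], use.names = FALSE),
    target = rep(ag@edges$target, n_anc),
    stringsAsFactors = FALSE)
  AnnotationGraph(out, targets = ag@targets, propagated = TRUE)
}

#' Information content of ontology terms
#'
#' IC(t) = -ln(frequency of t among annotated targets), computed on a
#' propagated annotation graph. Terms annotating every target (the root of a
#' fully used ontology) have IC 0; terms annotating no target carry no
#' information and get `NA` (the "no information" sentinel), never a silent 0.
#'
#' @param ag a propagated [AnnotationGraph-class].
#' @param terms term identifiers to score; default all terms of `ag`.
#' @return named numeric vector of information contents (natural-log units).
#' @export
termIC <- function(ag, terms = NULL) {
  stopifnot(is(ag, "AnnotationGraph"))
  if (!ag@propagated)
    stop("information content requires a propagated AnnotationGraph")
  n <- length(ag@targets)
  if (n == 0L) stop("annotation graph has no targets")
  counts <- table(ag@edges$term)
  if (is.null(terms)) terms <- names(counts)
  ic <- -log(as.numeric(counts[terms]) / n)
  ic[is.na(ic)] <- NA_real_   # absent term: zero targets, no information
  names(ic) <- terms
  ic
}

# Internal: IC of the most informative common ancestor of a term pair,
# with a memoisation environment. Returns 0 when there is no common
# ancestor with defined IC ("no shared information").
micaICPair <- function(x, y, taxonomy, ic, cache = NULL) {
  key <- if (x <= y) paste0(x, "\r", y) else paste0(y, "\r", x)
  if (!is.null(cache) && !is.null(v <- cache[[key]])) return(v)
  common <- intersect(termAncestors(taxonomy, x), termAncestors(taxonomy, y))
  vals <- ic[common]
  vals <- vals[!is.na(vals)]
  v <- if (length(vals)) max(vals) else 0
  if (!is.null(cache)) cache[[key]] <- v
  v
}

#' Most informative common ancestor (MICA)
#'
#' The common ancestor of `x` and `y` (each term being an ancestor of
#' itself) with maximal information content. Terms annotating zero targets
#' are not MICA candidates; if no candidate remains (e.g. the pair lies in
#' different roots of a forest) the result is `NA` — the "no information"
#' sentinel, which contributes 0 to set similarity.
#'
#' Ties on IC are broken by the lexicographically smallest term identifier,
#' so the result is deterministic; the IC value is identical either way.
#'
#' @param x,y term identifiers.
#' @param taxonomy a [Taxonomy-class].
#' @param ag a propagated [AnnotationGraph-class].
#' @return a term identifier, or `NA_character_`.
#' @export
mica <- function(x, y, taxonomy, ag) {
  stopifnot(x %in% taxonomy@terms, y %in% taxonomy@terms)
  ic <- termIC(ag)
  common <- intersect(termAncestors(taxonomy, x), termAncestors(taxonomy, y))
  vals <- ic[common]
  vals <- vals[!is.na(vals)]
  if (!length(vals)) return(NA_character_)
  best <- names(vals)[vals == max(vals)]
  csort(best)[1L]
}

#' Asymmetric information-content similarity between two term sets
#'
#' sim(X, Y) = avg over x in X of the max over y in Y of IC(MICA(x, y)).
#' The measure is asymmetric (the average runs over the first argument) and
#' is kept exactly in that form; `symmetrize = TRUE` averages the two
#' directions for callers that want a symmetric variant.
#'
#' An empty X or Y yields 0 ("no shared information"), as does a pair of
#' terms whose only common ancestors annotate nothing.
#'
#' @param X,Y character vectors of term identifiers.
#' @param taxonomy a [Taxonomy-class].
#' @param ag a propagated [AnnotationGraph-class].
#' @param symmetrize average sim(X,Y) and sim(Y,X)? Default FALSE.
#' @param ic optional precomputed [termIC()] vector (performance).
#' @param cache optional environment memoising MICA IC across calls.
#' @return a non-negative number.
#' @export
setSimilarity <- function(X, Y, taxonomy, ag, symmetrize = FALSE,
                          ic = NULL, cache = NULL) {
  if (is.null(ic)) ic <- termIC(ag)
  one <- function(A, B) {
    if (!length(A) || !length(B)) return(0)
    mean(vapply(A, function(x)
      max(vapply(B, function(y)
        micaICPair(x, y, taxonomy, ic, cache), numeric(1))), numeric(1)))
  }
  X <- unique(as.character(X)); Y <- unique(as.character(Y))
  bad <- setdiff(c(X, Y), taxonomy@terms)
  if (length(bad)) stop("unknown term(s): ", paste(bad, collapse = ", "))
  if (symmetrize) (one(X, Y) + one(Y, X)) / 2 else one(X, Y)
}
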