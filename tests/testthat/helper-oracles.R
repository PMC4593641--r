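# Independent brute-force oracles and tiny fixture builders. Everything in
# here works from raw edge lists / data frames and deliberately avoids the
# package's own graph and interval machinery.

# --- ontology oracles -------------------------------------------------------

# ancestor set (self included) by naive repeated expansion over raw edges
oracleAncestors <- function(term, edges) {
  anc <- term
  repeat {
    more <- unique(edges$parent[edges$child %in% anc])
    new <- setdiff(more, anc)
    if (!length(new)) return(anc)
    anc <- c(anc, new)
  }
}

# propagated (term -> targets) map by per-target ancestor enumeration
oraclePropagate <- function(ann, edges) {
  out <- list()
  for (i in seq_len(nrow(ann))) {
    for (a in oracleAncestors(ann$term[i], edges))
      out[[a]] <- unique(c(out[[a]], ann$target[i]))
  }
  out
}

# IC per term from the oracle propagation; NA for unannotated terms
oracleIC <- function(terms, ann, edges) {
  prop <- oraclePropagate(ann, edges)
  n <- length(unique(ann$target))
  ic <- sapply(terms, function(t)
    if (is.null(prop[[t]])) NA_real_ else -log(length(prop[[t]]) / n))
  names(ic) <- terms
  ic
}

# sim(X, Y) by exhaustive double loop over pairs and exhaustive
# common-ancestor intersection
oracleSetSim <- function(X, Y, terms, ann, edges) {
  if (!length(X) || !length(Y)) return(0)
  ic <- oracleIC(terms, ann, edges)
  pair <- function(x, y) {
    common <- intersect(oracleAncestors(x, edges), oracleAncestors(y, edges))
    v <- ic[common]
    v <- v[!is.na(v)]
    if (length(v)) max(v) else 0
  }
  mean(sapply(unique(X), function(x)
    max(sapply(unique(Y), function(y) pair(x, y)))))
}

# random DAG over n terms: term i (i > 1) picks 1-2 parents among 1..i-1
randomDAG <- function(n, seed) {
  set.seed(seed)
  terms <- sprintf("t%02d", seq_len(n))
  child <- character(0); parent <- character(0)
  for (i in 2:n) {
    k <- sample(1:min(2L, i - 1L), 1L)
    p <- sample(terms[seq_len(i - 1L)], k)
    child <- c(child, rep(terms[i], k)); parent <- c(parent, p)
  }
  list(terms = terms, edges = data.frame(child = child, parent = parent))
}

# random annotations: each target annotated with 1-3 random non-root terms
randomAnnotations <- function(dag, n_targets, seed) {
  set.seed(seed + 1000)
  do.call(rbind, lapply(seq_len(n_targets), function(i) {
    k <- sample(1:3, 1L)
    data.frame(target = sprintf("g%02d", i),
               term = sample(dag$terms[-1L], k))
  }))
}

# --- graph oracles ----------------------------------------------------------

# all-pairs shortest paths by Floyd-Warshall over a symmetric distance matrix
oracleFloydWarshall <- function(nodes, edges, dist) {
  n <- length(nodes)
  D <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(D) <- 0
  for (i in seq_len(nrow(edges))) {
    a <- edges$from[i]; b <- edges$to[i]
    D[a, b] <- min(D[a, b], dist[i]); D[b, a] <- D[a, b]
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

# restart-walk stationary distribution by direct dense linear solve:
# p = alpha * (I - (1-alpha) t(P))^{-1} e_q  (no dangling nodes assumed)
oracleWalkSolve <- function(sub, alpha = 0.5) {
  nodes <- c(subnetworkMembers(sub), sinkNode(sub))
  n <- length(nodes)
  W <- matrix(0, n, n, dimnames = list(nodes, nodes))
  e <- networkEdges(sub)
  for (i in seq_len(nrow(e))) {
    W[e$from[i], e$to[i]] <- W[e$from[i], e$to[i]] + e$weight[i]
    W[e$to[i], e$from[i]] <- W[e$to[i], e$from[i]] + e$weight[i]
  }
  P <- W / rowSums(W)
  eq <- as.numeric(nodes == queryGene(sub))
  p <- solve(diag(n) - (1 - alpha) * t(P), alpha * eq)
  names(p) <- nodes
  p
}

# random connected-ish weighted network: ring plus random chords
randomNetwork <- function(n, seed, chords = n) {
  set.seed(seed)
  nodes <- sprintf("n%02d", seq_len(n))
  from <- nodes; to <- nodes[c(2:n, 1L)]
  extra <- t(replicate(chords, sample(nodes, 2L)))
  df <- unique(data.frame(from = pmin(c(from, extra[, 1]), c(to, extra[, 2])),
                          to = pmax(c(from, extra[, 1]), c(to, extra[, 2]))))
  df <- df[df$from != df$to, ]
  df$weight <- round(runif(nrow(df), 0.5, 4), 3)
  GeneNetwork(df)
}

# --- interval oracles (0-based half-open coordinates) -----------------------

ivOverlap <- function(s1, e1, s2, e2) max(0L, min(e1, e2) - max(s1, s2))

oracleCNVGenes <- function(cnv, genes) {
  hits <- genes[genes$chrom == cnv$chrom &
    mapply(ivOverlap, cnv$start, cnv$end, genes$start, genes$end) > 0, ]
  hits$gene_id[order(hits$start, hits$end)]
}

oracleMerge <- function(df) {       # sort-and-sweep union per chromosome
  out <- NULL
  for (ch in sort(unique(df$chrom))) {
    d <- df[df$chrom == ch, ]
    d <- d[order(d$start, d$end), ]
    s <- d$start[1]; e <- d$end[1]
    for (i in seq_len(nrow(d))[-1]) {
      if (d$start[i] <= e) e <- max(e, d$end[i])
      else { out <- rbind(out, data.frame(chrom = ch, start = s, end = e))
             s <- d$start[i]; e <- d$end[i] }
    }
    out <- rbind(out, data.frame(chrom = ch, start = s, end = e))
  }
  out
}

oracleDGVFreq <- function(cnv, studies, threshold = 0.5) {
  len <- cnv$end - cnv$start
  total <- 0
  for (st in studies) {
    m <- oracleMerge(st)
    ov <- mapply(ivOverlap, cnv$start, cnv$end, m$start, m$end)
    ov <- ov[m$chrom == cnv$chrom & ov >= threshold * len]
    total <- total + sum(ov / len)
  }
  total
}

# --- shared small fixtures --------------------------------------------------

# 8-term diamond DAG: root R; A, B under R; C under both A and B (diamond);
# D under A; E under C; F under D; G under R
diamondTaxonomy <- function() {
  Taxonomy(c("R", "A", "B", "C", "D", "E", "F", "G"),
           data.frame(child = c("A", "B", "C", "C", "D", "E", "F", "G"),
                      parent = c("R", "R", "A", "B", "A", "C", "D", "R")))
}

diamondEdges <- function()
  data.frame(child = c("A", "B", "C", "C", "D", "E", "F", "G"),
             parent = c("R", "R", "A", "B", "A", "C", "D", "R"))

# annotations of 8 targets over the diamond leaves/mid-terms
diamondAnnotations <- function()
  data.frame(target = sprintf("g%d", 1:8),
             term = c("E", "E", "F", "F", "G", "G", "C", "D"))
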