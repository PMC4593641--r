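#' @include classify.R features.R phenotype.R config.R
NULL

# Internal: memoising relevance scorer over (gene, patient-phenotype-set)
# pairs. Gene-vs-catalog GO similarities depend only on the gene, and
# phenotype-vs-catalog similarities only on the phenotype set, so both are
# cached; direct scores are the max over entries of their product.
makeRelevanceScorer <- function(gene_terms, catalog, go_tax, go_ag,
                                hpo_tax, hpo_ag, fallback_scope = "subnetwork",
                                k_neighbors = 10L) {
  go_ic <- termIC(go_ag)
  hpo_ic <- termIC(hpo_ag)
  go_cache <- new.env(parent = emptyenv())
  hpo_cache <- new.env(parent = emptyenv())
  sim_go <- new.env(parent = emptyenv())   # gene -> numeric over entries
  sim_ph <- new.env(parent = emptyenv())   # phen key -> numeric over entries
  n_entries <- nrow(catalog)
  goFor <- function(gene) {
    v <- sim_go[[gene]]
    if (is.null(v)) {
      gt <- gene_terms[[gene]] %||% character(0)
      v <- vapply(seq_len(n_entries), function(i)
        setSimilarity(gt, gene_terms[[catalog$gene[i]]] %||% character(0),
                      go_tax, go_ag, ic = go_ic, cache = go_cache),
        numeric(1))
      sim_go[[gene]] <- v
    }
    v
  }
  phFor <- function(phenset) {
    key <- paste(csort(phenset), collapse = ";")
    if (!nzchar(key)) key <- "."
    v <- sim_ph[[key]]
    if (is.null(v)) {
      v <- vapply(seq_len(n_entries), function(i)
        setSimilarity(phenset, catalog$phenotypes[[i]],
                      hpo_tax, hpo_ag, ic = hpo_ic, cache = hpo_cache),
        numeric(1))
      sim_ph[[key]] <- v
    }
    v
  }
  direct <- function(gene, phenset) {
    if (!n_entries) return(0)
    m <- max(goFor(gene) * phFor(phenset))
    if (m > 0) m else 0
  }
  function(gene, phenset, sub = NULL) {
    score <- direct(gene, phenset)
    if (score > 0 || is.null(sub) || length(sub@members) == 1L)
      return(list(score = score, source = "direct"))
    neighbors <- setdiff(sub@members, sub@query)
    if (identical(fallback_scope, "top_k") && length(sub@ranks))
      neighbors <- names(sub@ranks[sub@ranks <= k_neighbors])
    fb <- 0
    for (nb in neighbors) {
      s <- direct(nb, phenset)
      if (s > 0) fb <- max(fb, s / sub@distances[[nb]])
    }
    if (fb > 0) list(score = fb, source = "neighbor-fallback")
    else list(score = 0, source = "direct")
  }
}

#' Prepare a CNV cohort for classification
#'
#' Runs every split-independent stage once: filters the interaction network
#' to its strongest edges, builds the slim map and per-gene slim profiles,
#' cuts and ranks each CNV gene's subnetwork, computes both feature
#' weighting systems' per-gene weights, the per-(CNV, gene) relevance
#' scores and training copy counts, the patient-phenotype indicator block,
#' and the CNV-level length and benign-overlap features.
#'
#' @param resources a resource bundle ([loadResources()] or
#'   [simulateCohort()]).
#' @param config a [runConfig()].
#' @return an opaque list consumed by [runExperiment()] /
#'   [trainPipeline()]; notable elements: `cnvs` (annotated CNV table),
#'   `x` (gene-row feature matrix), `row_cnv` (cnv_id per row), `copies_*`
#'   (training copy counts per row), `relevance` (per-row scores).
#' @export
prepareAnalysis <- function(resources, config = runConfig()) {
  net <- filterTopEdges(resources$network, config$edge_fraction)
  slim_map <- buildSlimMap(resources$go_tax, resources$slim)
  cnvs <- resources$cnvs
  if (is.null(cnvs$genes))
    cnvs <- annotateCNVs(cnvs, resources$gene_models, resources$dgv,
                         threshold = config$dgv_threshold,
                         type_match = config$dgv_type_match)
  cnv_genes <- as.list(cnvs$genes)
  names(cnv_genes) <- cnvs$cnv_id
  uniq_genes <- unique(unlist(cnv_genes, use.names = FALSE))

  subs <- lapply(uniq_genes, function(g) {
    if (!g %in% net@nodes) return(NULL)
    geneSubnetwork(net, g, k_sub = config$k_sub, alpha = config$restart_alpha,
                   tol = config$walk_tol, max_iter = config$walk_max_iter)
  })
  names(subs) <- uniq_genes

  prof_genes <- unique(c(uniq_genes, unlist(lapply(subs, function(s)
    if (is.null(s)) character(0) else s@members), use.names = FALSE)))
  profiles <- lapply(prof_genes, geneGOProfile,
                     annotations = resources$annotations, slim_map = slim_map)
  names(profiles) <- prof_genes

  go_w <- lapply(uniq_genes, function(g)
    featureWeightsNetwork(g, subs[[g]], profiles, config$k_neighbors))
  go_u <- lapply(uniq_genes, function(g)
    featureWeightsUniform(g, subs[[g]], profiles, config$k_neighbors))
  names(go_w) <- names(go_u) <- uniq_genes

  gene_terms <- split(resources$annotations$term, resources$annotations$target)
  go_ag <- propagateAnnotations(resources$go_tax,
    AnnotationGraph(data.frame(term = resources$annotations$term,
                               target = resources$annotations$target)))
  hpo_ag <- propagateAnnotations(resources$hpo_tax,
    AnnotationGraph(data.frame(term = resources$disorder_annotations$term,
                               target = resources$disorder_annotations$target)))
  scorer <- makeRelevanceScorer(gene_terms, resources$catalog,
                                resources$go_tax, go_ag,
                                resources$hpo_tax, hpo_ag,
                                fallback_scope = config$fallback_scope,
                                k_neighbors = config$k_neighbors)

  phen_sets <- strsplit(cnvs$phenotypes, ";", fixed = TRUE)
  names(phen_sets) <- cnvs$cnv_id
  vocab <- csort(unique(unlist(phen_sets, use.names = FALSE)))

  slim_cols <- slim_map@slim
  row_cnv <- rep(cnvs$cnv_id, lengths(cnv_genes))
  row_gene <- unlist(cnv_genes, use.names = FALSE)
  n_row <- length(row_gene)
  cols <- c(slim_cols, paste0("PH|", vocab))
  x_network <- matrix(0, n_row, length(cols), dimnames = list(NULL, cols))
  x_uniform <- x_network
  relevance <- numeric(n_row)
  rel_source <- character(n_row)
  for (i in seq_len(n_row)) {
    w <- go_w[[row_gene[i]]]
    if (length(w)) x_network[i, names(w)] <- unname(w)
    u <- go_u[[row_gene[i]]]
    if (length(u)) x_uniform[i, names(u)] <- unname(u)
    ph <- phen_sets[[row_cnv[i]]]
    ph_cols <- paste0("PH|", intersect(ph, vocab))
    x_network[i, ph_cols] <- 1
    x_uniform[i, ph_cols] <- 1
    rel <- scorer(row_gene[i], ph, subs[[row_gene[i]]])
    relevance[i] <- rel$score
    rel_source[i] <- rel$source
  }
  x <- if (identical(config$feature_weighting, "network-weighted"))
    x_network else x_uniform
  copies_ph <- unlist(lapply(split(seq_len(n_row), factor(row_cnv,
      levels = cnvs$cnv_id)), function(idx)
    trainingWeightsPhenotype(relevance[idx], config$copies_per_cnv)),
    use.names = FALSE)
  copies_un <- unlist(lapply(split(seq_len(n_row), factor(row_cnv,
      levels = cnvs$cnv_id)), function(idx)
    trainingWeightsUniform(length(idx), config$copies_per_cnv)),
    use.names = FALSE)

  list(config = config, cnvs = cnvs, network = net, slim_map = slim_map,
       subnetworks = subs, profiles = profiles, vocab = vocab,
       x = x, x_network = x_network, x_uniform = x_uniform,
       row_cnv = row_cnv, row_gene = row_gene,
       relevance = relevance, relevance_source = rel_source,
       copies_phenotype = copies_ph, copies_uniform = copies_un)
}

# Internal: one full split -> train -> predict -> evaluate pass.
runOnce <- function(prep, config, seed, labels = NULL) {
  cnvs <- prep$cnvs
  if (!is.null(labels)) cnvs$label <- labels
  split <- if (identical(config$regime, "unbalanced"))
    unbalancedSplit(cnvs, seed) else balancedSplit(cnvs, seed)

  lab_of <- stats::setNames(cnvs$label, cnvs$cnv_id)
  copies <- if (identical(config$gene_weighting, "phenotype-weighted"))
    prep$copies_phenotype else prep$copies_uniform
  x_all <- if (identical(config$feature_weighting, "network-weighted"))
    prep$x_network else prep$x_uniform
  tr <- prep$row_cnv %in% split$gene_train
  idx <- rep(which(tr), copies[tr])
  x_train <- x_all[idx, , drop = FALSE]
  y_train <- lab_of[prep$row_cnv[idx]]
  model <- withSeed(seed + 1000000,
    trainGeneClassifier(x_train, y_train, n_trees = config$rf_trees,
                        mtry = config$rf_mtry))

  eval_ids <- c(split$cnv_train, split$cnv_test)
  ev <- prep$row_cnv %in% eval_ids
  calls <- predictCausative(model, x_all[ev, , drop = FALSE],
                            prep$row_cnv[ev], eval_ids)
  rows <- data.frame(cnv_id = eval_ids,
                     causative = calls$cnv_flag[eval_ids],
                     length = stats::setNames(cnvs$length, cnvs$cnv_id)[eval_ids],
                     dgv = stats::setNames(cnvs$dgv_frequency,
                                           cnvs$cnv_id)[eval_ids],
                     label = lab_of[eval_ids])
  nb <- trainCNVClassifier(rows[rows$cnv_id %in% split$cnv_train, ],
                           features = config$cnv_features)
  test <- rows[rows$cnv_id %in% split$cnv_test, ]
  pred <- predictCNVClass(nb, test)
  metrics <- evaluatePredictions(pred, test$label)
  imp <- model$importance[, 1L]
  list(metrics = metrics, importance = imp, n_test = nrow(test),
       n_train_rows = nrow(x_train),
       predictions = stats::setNames(pred, test$cnv_id))
}

#' Run the full two-layer experiment
#'
#' End-to-end evaluation: for each run, split the cohort (balanced
#' phenotype-stratified or patient-based, per `config$regime`), train the
#' gene Random Forest on relevance-replicated gene rows, derive each
#' held-out CNV's causative-gene flag by OR over its genes' calls, train
#' the Naive Bayes CNV classifier on the middle pool, predict the test
#' pool, and score precision/recall/F on the harmful class. Metrics are
#' computed per run and then averaged. Fully reproducible: run i uses seed
#' `config$seeds[i]` (default 1..runs).
#'
#' @param resources a resource bundle ([loadResources()] /
#'   [simulateCohort()]).
#' @param config a [runConfig()].
#' @param prep optionally, a precomputed [prepareAnalysis()] result for
#'   these resources (it only depends on the feature-weighting side of the
#'   config), to share work across configurations.
#' @return a `pathoCNVReport` list: `per_run` (data.frame of run metrics),
#'   `aggregate` (mean precision/recall/f), `importance` (mean Gini
#'   importance of the gene classifier's features across runs), `config`.
#' @export
runExperiment <- function(resources, config = runConfig(), prep = NULL) {
  config <- validateConfig(config)
  if (is.null(prep)) prep <- prepareAnalysis(resources, config)
  seeds <- config$seeds %||% seq_len(config$runs)
  labels <- NULL
  if (isTRUE(config$permute_labels))
    labels <- withSeed(config$permutation_seed,
                       sample(prep$cnvs$label))
  runs <- vector("list", length(seeds))
  for (i in seq_along(seeds)) {
    runs[[i]] <- tryCatch(runOnce(prep, config, seeds[i], labels = labels),
      error = function(e)
        stop("run ", i, " (seed ", seeds[i], ") failed: ",
             conditionMessage(e), call. = FALSE))
  }
  per_run <- data.frame(run = seq_along(seeds), seed = seeds,
    precision = vapply(runs, function(r) r$metrics[["precision"]], numeric(1)),
    recall = vapply(runs, function(r) r$metrics[["recall"]], numeric(1)),
    f = vapply(runs, function(r) r$metrics[["f"]], numeric(1)),
    n_test = vapply(runs, function(r) r$n_test, integer(1)))
  imp <- Reduce(`+`, lapply(runs, `[[`, "importance")) / length(runs)
  out <- list(per_run = per_run,
              aggregate = c(precision = mean(per_run$precision),
                            recall = mean(per_run$recall),
                            f = mean(per_run$f)),
              importance = imp, config = config)
  class(out) <- "pathoCNVReport"
  out
}

#' @export
print.pathoCNVReport <- function(x, ...) {
  cat("pathoCNV evaluation report —", nrow(x$per_run), "runs,",
      x$config$regime, "regime\n")
  cat(sprintf("  mean precision %.4f | recall %.4f | F %.4f\n",
              x$aggregate[["precision"]], x$aggregate[["recall"]],
              x$aggregate[["f"]]))
  cat("  feature weighting:", x$config$feature_weighting,
      "| gene weighting:", x$config$gene_weighting,
      "| CNV features:", paste(x$config$cnv_features, collapse = "+"), "\n")
  invisible(x)
}

#' Train the two-layer classifier on a full labeled cohort
#'
#' Deployment path (no held-out evaluation): trains the gene classifier on
#' all labeled CNVs and the CNV classifier on the resulting causative
#' flags plus length and benign-overlap features.
#'
#' @param resources labeled resource bundle.
#' @param config a [runConfig()].
#' @param seed RNG seed for the forest.
#' @return a `pathoCNVModel` list usable with [predictPipeline()].
#' @export
trainPipeline <- function(resources, config = runConfig(), seed = 1L) {
  config <- validateConfig(config)
  prep <- prepareAnalysis(resources, config)
  lab_of <- stats::setNames(prep$cnvs$label, prep$cnvs$cnv_id)
  if (anyNA(lab_of)) stop("training requires labeled CNVs")
  copies <- if (identical(config$gene_weighting, "phenotype-weighted"))
    prep$copies_phenotype else prep$copies_uniform
  idx <- rep(seq_along(copies), copies)
  model <- withSeed(seed,
    trainGeneClassifier(prep$x[idx, , drop = FALSE],
                        lab_of[prep$row_cnv[idx]],
                        n_trees = config$rf_trees, mtry = config$rf_mtry))
  ids <- prep$cnvs$cnv_id
  calls <- predictCausative(model, prep$x, prep$row_cnv, ids)
  rows <- data.frame(causative = calls$cnv_flag[ids],
                     length = prep$cnvs$length, dgv = prep$cnvs$dgv_frequency,
                     label = prep$cnvs$label)
  nb <- trainCNVClassifier(rows, features = config$cnv_features)
  out <- list(gene_model = model, cnv_model = nb, config = config,
              vocab = prep$vocab, columns = colnames(prep$x))
  class(out) <- "pathoCNVModel"
  out
}

#' Score a CNV table with a trained model
#'
#' @param model a `pathoCNVModel` ([trainPipeline()]).
#' @param resources resource bundle whose `cnvs` are to be scored (labels
#'   not required). Phenotype terms unseen at training time are ignored.
#' @return data.frame: one row per CNV with its coordinates, derived
#'   features, causative flag and predicted label.
#' @export
predictPipeline <- function(model, resources) {
  config <- model$config
  prep <- prepareAnalysis(resources, config)
  x <- matrix(0, nrow(prep$x), length(model$columns),
              dimnames = list(NULL, model$columns))
  shared <- intersect(colnames(prep$x), model$columns)
  x[, shared] <- prep$x[, shared]
  ids <- prep$cnvs$cnv_id
  calls <- predictCausative(model$gene_model, x, prep$row_cnv, ids)
  rows <- data.frame(causative = calls$cnv_flag[ids],
                     length = prep$cnvs$length, dgv = prep$cnvs$dgv_frequency)
  pred <- predictCNVClass(model$cnv_model, rows)
  data.frame(chromosome = as.character(GenomeInfoDb::seqnames(prep$cnvs)),
             start = BiocGenerics::start(prep$cnvs) - 1L,
             end = BiocGenerics::end(prep$cnvs),
             type = prep$cnvs$type, phenotypes = prep$cnvs$phenotypes,
             cnv_id = ids, n_genes = lengths(prep$cnvs$genes),
             length = prep$cnvs$length, dgv_frequency = prep$cnvs$dgv_frequency,
             causative_gene = unname(rows$causative),
             predicted_label = pred)
}
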