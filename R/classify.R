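#' @include cnv.R
NULL

# pool labels used throughout: gene_train (50%), cnv_train (25%, doubles as
# the gene-classifier test pool) and cnv_test (25%)
.pools <- c("gene_train", "gene_train", "cnv_train", "cnv_test")

#' Balanced, phenotype-stratified three-way split
#'
#' Splits labeled CNVs into the three pools of the evaluation protocol:
#' 50% to train the gene classifier, 25% to test it and train the CNV
#' classifier, 25% to test the CNV classifier. Selection is
#' phenotype-stratified and class-matched: phenotypes are visited in
#' deterministic order and, while a phenotype still has at least two
#' unassigned cases (HARMFUL) and two controls (BENIGN), a round of two
#' random cases plus two random controls is drawn and assigned to the next
#' pool in the 2:1:1 cycle, keeping every pool balanced 1:1. CNVs never
#' picked by the sweep are left out of the run.
#'
#' @param cnvs a labeled CNV table ([readCNVTable()]); the `phenotypes`
#'   column may hold several semicolon-joined terms.
#' @param seed split seed (deterministic: same seed, same split).
#' @return list of `cnv_id` character vectors: `gene_train`, `cnv_train`,
#'   `cnv_test`, `unassigned`.
#' @export
balancedSplit <- function(cnvs, seed) {
  lab <- cnvs$label
  if (anyNA(lab)) stop("balanced split requires labeled CNVs")
  phen <- strsplit(cnvs$phenotypes, ";", fixed = TRUE)
  vocab <- csort(unique(unlist(phen, use.names = FALSE)))
  ids <- cnvs$cnv_id
  withSeed(seed, {
    assigned <- stats::setNames(rep(NA_character_, length(ids)), ids)
    round_i <- 0L
    any_round <- FALSE
    for (p in vocab) {
      has_p <- vapply(phen, function(x) p %in% x, logical(1))
      repeat {
        free <- is.na(assigned[ids])
        cases <- ids[has_p & free & lab == "HARMFUL"]
        controls <- ids[has_p & free & lab == "BENIGN"]
        if (length(cases) < 2L || length(controls) < 2L) break
        pick <- c(sample(cases, 2L), sample(controls, 2L))
        pool <- .pools[round_i %% length(.pools) + 1L]
        assigned[pick] <- pool
        round_i <- round_i + 1L
        any_round <- TRUE
      }
    }
    if (!any_round)
      stop("no phenotype has at least two cases and two controls")
    list(gene_train = ids[assigned[ids] %in% "gene_train"],
         cnv_train = ids[assigned[ids] %in% "cnv_train"],
         cnv_test = ids[assigned[ids] %in% "cnv_test"],
         unassigned = ids[is.na(assigned[ids])])
  })
}

#' Patient-based ("unbalanced") three-way split
#'
#' Assigns whole patients to the three pools in the same 2:1:1 cycle, so
#' that no patient's CNVs straddle pools and the benign:harmful imbalance
#' of the cohort is carried into the test pool, mirroring the clinical
#' setting.
#'
#' @param cnvs a CNV table whose `patient` column is filled.
#' @param seed split seed.
#' @return list of `cnv_id` vectors: `gene_train`, `cnv_train`,
#'   `cnv_test`, `unassigned` (always empty here).
#' @export
unbalancedSplit <- function(cnvs, seed) {
  pat <- cnvs$patient
  if (anyNA(pat)) stop("unbalanced split requires the patient column")
  patients <- csort(unique(pat))
  if (length(patients) < 4L)
    stop("unbalanced split needs at least 4 patients, got ", length(patients))
  withSeed(seed, {
    shuffled <- sample(patients)
    pool <- stats::setNames(.pools[(seq_along(shuffled) - 1L) %% 4L + 1L],
                            shuffled)
    byp <- pool[pat]
    list(gene_train = cnvs$cnv_id[byp == "gene_train"],
         cnv_train = cnvs$cnv_id[byp == "cnv_train"],
         cnv_test = cnvs$cnv_id[byp == "cnv_test"],
         unassigned = character(0))
  })
}

#' Train the gene-level Random Forest
#'
#' @param x numeric feature matrix: one row per (replicated) gene training
#'   instance, columns = slim features followed by phenotype indicators.
#' @param y labels, "HARMFUL"/"BENIGN", one per row.
#' @param n_trees forest size; default 100.
#' @param mtry features tried per split; default floor(sqrt(ncol(x))).
#' @return a fitted `randomForest` model.
#' @export
trainGeneClassifier <- function(x, y, n_trees = 100L, mtry = NULL) {
  y <- factor(y, levels = c("BENIGN", "HARMFUL"))
  if (nlevels(droplevels(y)) < 2L)
    stop("gene training set has a single class; cannot train")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  randomForest::randomForest(x = x, y = y, ntree = n_trees, mtry = mtry,
                             importance = FALSE)
}

#' Per-gene causative calls and the per-CNV OR flag
#'
#' Applies the gene classifier to the (unreplicated) gene rows of a set of
#' CNVs and combines them with a plain logical OR: a CNV is flagged as
#' containing a causative gene when any of its genes is called harmful.
#' A gene-less CNV is flagged FALSE.
#'
#' @param model a fitted gene classifier ([trainGeneClassifier()]).
#' @param x feature matrix of gene rows (same columns as training).
#' @param row_cnv `cnv_id` of each row of `x`.
#' @param cnv_ids the CNVs to flag (including gene-less ones).
#' @return list: `gene_calls` (logical, per row of `x`), `cnv_flag`
#'   (named logical, per `cnv_ids`).
#' @export
predictCausative <- function(model, x, row_cnv, cnv_ids) {
  if (nrow(x)) {
    feat <- rownames(model$importance)
    if (!is.null(feat) && !identical(colnames(x), feat))
      stop("feature space mismatch between model and prediction rows")
    calls <- stats::predict(model, x) == "HARMFUL"
  } else calls <- logical(0)
  flag <- vapply(cnv_ids, function(id) any(calls[row_cnv == id]), logical(1))
  list(gene_calls = calls, cnv_flag = flag)
}

#' Train the CNV-level Naive Bayes
#'
#' Naive Bayes over up to three features: the causative-gene flag
#' (Bernoulli), log10 CNV length (Gaussian) and the benign-overlap
#' frequency (Gaussian). The lengths of harmful and benign CNVs separate
#' far better on the log scale, hence the transform.
#'
#' @param rows data.frame with columns `causative` (logical), `length`
#'   (bp), `dgv` (numeric) and `label` ("HARMFUL"/"BENIGN").
#' @param features which predictors to use; any non-empty subset of
#'   c("gene", "length", "dgv").
#' @param laplace Laplace smoothing for the Bernoulli feature; default 1
#'   (keeps a never-observed flag value from zeroing the posterior).
#' @return a fitted `naiveBayes` model; its `features` attribute records
#'   the subset.
#' @export
trainCNVClassifier <- function(rows, features = c("gene", "length", "dgv"),
                               laplace = 1) {
  features <- match.arg(features, c("gene", "length", "dgv"),
                        several.ok = TRUE)
  y <- factor(rows$label, levels = c("BENIGN", "HARMFUL"))
  if (nlevels(droplevels(y)) < 2L)
    stop("CNV training set has a single class; cannot train")
  df <- cnvFeatureFrame(rows, features)
  model <- e1071::naiveBayes(x = df, y = y, laplace = laplace)
  attr(model, "features") <- features
  model
}

# Internal: predictor frame for the CNV classifier.
cnvFeatureFrame <- function(rows, features) {
  df <- data.frame(row.names = seq_len(nrow(rows)))
  if ("gene" %in% features)
    df$causative <- factor(rows$causative, levels = c(FALSE, TRUE))
  if ("length" %in% features) df$log_length <- log10(rows$length)
  if ("dgv" %in% features) df$dgv <- rows$dgv
  df
}

#' Predict CNV harmfulness
#'
#' @param model a fitted CNV classifier ([trainCNVClassifier()]).
#' @param rows data.frame in the [trainCNVClassifier()] layout (`label`
#'   not required).
#' @return character vector of "HARMFUL"/"BENIGN" predictions.
#' @export
predictCNVClass <- function(model, rows) {
  df <- cnvFeatureFrame(rows, attr(model, "features"))
  as.character(stats::predict(model, df))
}

#' Precision, recall and F-measure on the harmful class
#'
#' @param predictions character vector of predicted labels.
#' @param labels character vector of true labels.
#' @return named numeric vector `precision`, `recall`, `f`; with zero
#'   predicted positives, precision is reported as 0 and the result carries
#'   attribute `no_positive_predictions = TRUE`.
#' @export
evaluatePredictions <- function(predictions, labels) {
  stopifnot(length(predictions) == length(labels))
  tp <- sum(predictions == "HARMFUL" & labels == "HARMFUL")
  fp <- sum(predictions == "HARMFUL" & labels == "BENIGN")
  fn <- sum(predictions == "BENIGN" & labels == "HARMFUL")
  no_pos <- (tp + fp) == 0L
  precision <- if (no_pos) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0L) 0 else tp / (tp + fn)
  f <- if (precision + recall > 0) 2 * precision * recall / (precision + recall)
       else 0
  out <- c(precision = precision, recall = recall, f = f)
  if (no_pos) attr(out, "no_positive_predictions") <- TRUE
  out
}
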