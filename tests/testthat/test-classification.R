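mkCNVTable <- function(n, labels, phen, patient = NA_character_) {
  gr <- GenomicRanges::GRanges(rep("chr1", n),
                               IRanges::IRanges(seq_len(n) * 1000L,
                                                width = 500L))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    cnv_id = sprintf("cnv%05d", seq_len(n)), type = rep("DEL", n),
    phenotypes = phen, label = labels, patient = patient)
  gr
}

test_that("the balanced split is a stratified 2:1:1 partition of matched pairs", {
  cnvs <- mkCNVTable(16, rep(c("HARMFUL", "BENIGN"), each = 8), "dd")
  sp <- balancedSplit(cnvs, seed = 3)
  expect_length(sp$gene_train, 8L)
  expect_length(sp$cnv_train, 4L)
  expect_length(sp$cnv_test, 4L)
  expect_length(sp$unassigned, 0L)
  lab <- stats::setNames(cnvs$label, cnvs$cnv_id)
  for (pool in sp[1:3])     # 1:1 class ratio inside every pool
    expect_equal(sum(lab[pool] == "HARMFUL"), length(pool) / 2)
  # a partition: each CNV in exactly one pool
  expect_setequal(unlist(sp), cnvs$cnv_id)
  expect_identical(balancedSplit(cnvs, seed = 3), sp)   # deterministic
  expect_false(identical(balancedSplit(cnvs, seed = 4), sp))

  # multi-phenotype cohort keeps balance within pools
  set.seed(5)
  cnvs3 <- mkCNVTable(60, sample(rep(c("HARMFUL", "BENIGN"), 30)),
                      sample(c("p1", "p2", "p3"), 60, TRUE))
  sp3 <- balancedSplit(cnvs3, seed = 1)
  lab3 <- stats::setNames(cnvs3$label, cnvs3$cnv_id)
  for (pool in sp3[1:3])
    expect_equal(sum(lab3[pool] == "HARMFUL"), length(pool) / 2)
  expect_length(intersect(sp3$gene_train, sp3$cnv_test), 0L)

  # protocol needs two cases and two controls somewhere
  lopsided <- mkCNVTable(6, c("HARMFUL", rep("BENIGN", 5)), "dd")
  expect_error(balancedSplit(lopsided, 1), "two cases")
})

test_that("the patient-based split never straddles a patient across pools", {
  set.seed(7)
  n <- 160
  labels <- c(rep("HARMFUL", 10), rep("BENIGN", 150))
  patient <- sprintf("P%02d", c(1:10, sample(16, 150, TRUE)))
  cnvs <- mkCNVTable(n, labels, "dd", patient)
  sp <- unbalancedSplit(cnvs, seed = 2)
  expect_setequal(unlist(sp), cnvs$cnv_id)
  pat <- stats::setNames(cnvs$patient, cnvs$cnv_id)
  pools <- sp[c("gene_train", "cnv_train", "cnv_test")]
  for (a in 1:2) for (b in (a + 1):3)
    expect_length(intersect(unique(pat[pools[[a]]]),
                            unique(pat[pools[[b]]])), 0L)
  # the ~15:1 imbalance carries into the test pool (binomial tolerance)
  lab <- stats::setNames(cnvs$label, cnvs$cnv_id)
  p_harm <- mean(lab[sp$cnv_test] == "HARMFUL")
  expect_lt(abs(p_harm - 10 / 160), 0.12)
  expect_identical(unbalancedSplit(cnvs, seed = 2), sp)
  expect_error(unbalancedSplit(mkCNVTable(4, labels[1:4], "dd",
                                          c("P1", "P1", "P2", "P2")), 1),
               "at least 4 patients")
})

test_that("evaluation metrics match direct confusion-table arithmetic", {
  expect_equal(evaluatePredictions(c("HARMFUL", "BENIGN"),
                                   c("HARMFUL", "BENIGN")),
               c(precision = 1, recall = 1, f = 1))
  # TP=3 FP=1 FN=1
  pred <- c(rep("HARMFUL", 4), "BENIGN", "BENIGN")
  lab <- c(rep("HARMFUL", 3), "BENIGN", "HARMFUL", "BENIGN")
  expect_equal(evaluatePredictions(pred, lab),
               c(precision = 0.75, recall = 0.75, f = 0.75))
  # zero predicted positives: precision reported 0, flagged
  out <- evaluatePredictions(rep("BENIGN", 3),
                             c("HARMFUL", "BENIGN", "BENIGN"))
  expect_equal(out[["precision"]], 0)
  expect_true(attr(out, "no_positive_predictions"))
  # random confusion tables vs independent counting
  set.seed(13)
  for (i in 1:10) {
    p <- sample(c("HARMFUL", "BENIGN"), 40, TRUE)
    l <- sample(c("HARMFUL", "BENIGN"), 40, TRUE)
    tp <- sum(p == "HARMFUL" & l == "HARMFUL")
    prec <- if (sum(p == "HARMFUL")) tp / sum(p == "HARMFUL") else 0
    rec <- if (sum(l == "HARMFUL")) tp / sum(l == "HARMFUL") else 0
    f <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    expect_equal(unname(evaluatePredictions(p, l)), c(prec, rec, f))
  }
})

test_that("the gene classifier separates a planted signal and rejects degenerate input", {
  set.seed(2)
  n <- 200
  x <- matrix(runif(n * 6), n, 6,
              dimnames = list(NULL, sprintf("f%d", 1:6)))
  y <- ifelse(x[, 1] > 0.5, "HARMFUL", "BENIGN")
  model <- trainGeneClassifier(x, y)
  expect_equal(mean(predict(model, x) == y), 1.0)     # separable fixture
  expect_error(trainGeneClassifier(x, rep("HARMFUL", n)), "single class")

  # permuted labels give chance-level held-out accuracy
  accs <- vapply(1:10, function(s) {
    set.seed(s)
    yp <- sample(y)
    m <- trainGeneClassifier(x[1:150, ], yp[1:150])
    mean(predict(m, x[151:200, ]) == yp[151:200])
  }, numeric(1))
  expect_lt(abs(mean(accs) - 0.5), 0.1)

  # OR combination of per-gene calls at CNV level
  xg <- x[1:6, ]
  rc <- c("c1", "c1", "c1", "c2", "c2", "c3")
  calls <- predictCausative(model, xg, row_cnv = rc,
                            cnv_ids = c("c1", "c2", "c3", "c4"))
  for (id in c("c1", "c2", "c3"))
    expect_identical(calls$cnv_flag[[id]], any(calls$gene_calls[rc == id]))
  expect_false(calls$cnv_flag[["c4"]])      # gene-less CNV
  expect_error(predictCausative(model, xg[, 1:3], rep("c1", 6), "c1"),
               "mismatch")
})

test_that("the CNV Naive Bayes matches closed-form posteriors and edge cases", {
  # perfectly informative causative flag: held-out recall 1
  rows <- data.frame(causative = rep(c(TRUE, FALSE), each = 30),
                     length = exp(rnorm(60, 11)), dgv = runif(60),
                     label = rep(c("HARMFUL", "BENIGN"), each = 30))
  m <- trainCNVClassifier(rows, features = "gene")
  held <- data.frame(causative = c(TRUE, TRUE, FALSE),
                     length = exp(rnorm(3, 11)), dgv = runif(3))
  expect_identical(predictCNVClass(m, held), c("HARMFUL", "HARMFUL", "BENIGN"))

  expect_error(trainCNVClassifier(
    data.frame(causative = TRUE, length = 10, dgv = 0, label = "HARMFUL")),
    "single class")

  # two numeric features: posterior equals the hand-computed Gaussian Bayes rule
  set.seed(17)
  n <- 80
  df <- data.frame(causative = FALSE,
                   length = exp(rnorm(n, ifelse(rbinom(n, 1, 0.4), 12, 10), 0.8)))
  df$dgv <- runif(n, 0, 3)
  df$label <- ifelse(log10(df$length) > 4.7, "HARMFUL", "BENIGN")
  nb <- trainCNVClassifier(df, features = c("length", "dgv"))
  probe <- data.frame(causative = FALSE, length = 10^4.71, dgv = 1.2)
  got <- predict(nb, data.frame(log_length = log10(probe$length),
                                dgv = probe$dgv), type = "raw")
  dens <- function(v, cls, x) {
    vals <- v[df$label == cls]
    stats::dnorm(x, mean(vals), stats::sd(vals))
  }
  lik <- function(cls) mean(df$label == cls) *
    dens(log10(df$length), cls, log10(probe$length)) *
    dens(df$dgv, cls, probe$dgv)
  manual <- lik("HARMFUL") / (lik("HARMFUL") + lik("BENIGN"))
  expect_equal(got[1, "HARMFUL"], manual, tolerance = 1e-9,
               ignore_attr = TRUE)

  # constant features fall back to the class prior (majority class)
  const <- data.frame(causative = FALSE, length = 1000, dgv = 1,
                      label = c(rep("BENIGN", 9), "HARMFUL"))
  mc <- trainCNVClassifier(const, features = c("length", "dgv"))
  expect_identical(predictCNVClass(mc, const[1, ]), "BENIGN")
})

test_that("gene training rows replicate exactly to the prescribed copy counts", {
  res <- simulateCohort(fixtureConfig(seed = 5, n_cnvs = 16, n_genes = 24,
                                      n_patients = 8, benign_ratio = 1))
  cfg <- runConfig(runs = 2)
  prep <- prepareAnalysis(res, cfg)
  per_cnv <- split(prep$copies_phenotype, prep$row_cnv)
  rel_cnv <- split(prep$relevance, prep$row_cnv)
  for (id in names(per_cnv)) {
    expect_identical(per_cnv[[id]],
                     trainingWeightsPhenotype(rel_cnv[[id]]))
  }
  per_u <- split(prep$copies_uniform, prep$row_cnv)
  for (id in names(per_u))
    expect_identical(per_u[[id]], trainingWeightsUniform(length(per_u[[id]])))
})

test_that("identical configuration and seeds reproduce identical reports", {
  res <- simulateCohort(fixtureConfig(seed = 11, n_cnvs = 16, n_genes = 24,
                                      n_patients = 8, benign_ratio = 1,
                                      n_terms = 22))
  cfg <- runConfig(runs = 2, rf_trees = 50L)
  r1 <- runExperiment(res, cfg)
  r2 <- runExperiment(res, cfg)
  expect_identical(r1$per_run, r2$per_run)
  expect_identical(r1$importance, r2$importance)
  expect_true(all(r1$per_run$precision >= 0 & r1$per_run$precision <= 1))
  expect_true(all(r1$per_run$f >= 0 & r1$per_run$f <= 1))
})
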