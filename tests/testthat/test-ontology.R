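test_that("annotation propagation yields the exact ancestor closure", {
  # chain t1 <- t2 <- t3 <- t4: a leaf annotation reaches all 4 terms
  chain <- Taxonomy(c("t1", "t2", "t3", "t4"),
                    data.frame(child = c("t2", "t3", "t4"),
                               parent = c("t1", "t2", "t3")))
  raw <- AnnotationGraph(data.frame(term = "t4", target = "g"))
  prop <- propagateAnnotations(chain, raw)
  expect_setequal(annotationEdges(prop)$term, c("t1", "t2", "t3", "t4"))
  expect_equal(nrow(annotationEdges(prop)), 4L)
  expect_true(isPropagated(prop))

  # idempotent, never removes edges
  again <- propagateAnnotations(chain, prop)
  expect_setequal(paste(annotationEdges(again)$term, annotationEdges(again)$target),
                  paste(annotationEdges(prop)$term, annotationEdges(prop)$target))

  # diamond closure equals the brute-force per-target enumeration
  tax <- diamondTaxonomy()
  ann <- diamondAnnotations()
  prop2 <- propagateAnnotations(tax, AnnotationGraph(ann))
  oracle <- oraclePropagate(ann, diamondEdges())
  for (t in names(oracle)) {
    got <- annotationEdges(prop2)$target[annotationEdges(prop2)$term == t]
    expect_setequal(got, oracle[[t]])
  }
  expect_setequal(unique(annotationEdges(prop2)$term), names(oracle))

  expect_error(
    propagateAnnotations(chain, AnnotationGraph(
      data.frame(term = "nope", target = "g"))), "nope")
})

test_that("information content follows -ln(annotation frequency)", {
  tax <- diamondTaxonomy()
  prop <- propagateAnnotations(tax, AnnotationGraph(diamondAnnotations()))
  ic <- termIC(prop)
  expect_equal(ic[["R"]], 0)                       # root annotates everything
  expect_equal(ic[["G"]], -log(0.25))              # 2 of 8 targets
  oracle <- oracleIC(ontoTerms(tax), diamondAnnotations(), diamondEdges())
  expect_equal(ic[names(ic)], oracle[names(ic)])

  # 1 of 10 targets
  one <- propagateAnnotations(
    Taxonomy("t"),
    AnnotationGraph(data.frame(term = "t", target = "g1"),
                    targets = sprintf("g%d", 1:10)))
  expect_equal(termIC(one)[["t"]], 2.302585093, tolerance = 1e-9)

  # unannotated term is a sentinel, not 0
  expect_true(is.na(termIC(prop, "unannotated-term")))
  expect_error(termIC(AnnotationGraph(diamondAnnotations())), "propagated")
})

test_that("IC never decreases from parent to child", {
  for (seed in 1:8) {
    dag <- randomDAG(12, seed)
    ann <- randomAnnotations(dag, 8, seed)
    tax <- Taxonomy(dag$terms, dag$edges)
    prop <- propagateAnnotations(tax, AnnotationGraph(ann))
    ic <- termIC(prop, dag$terms)
    for (i in seq_len(nrow(dag$edges))) {
      ip <- ic[[dag$edges$parent[i]]]; ic_c <- ic[[dag$edges$child[i]]]
      if (!is.na(ip) && !is.na(ic_c)) expect_lte(ip, ic_c)
    }
  }
})

test_that("MICA picks the highest-IC common ancestor deterministically", {
  tax <- diamondTaxonomy()
  prop <- propagateAnnotations(tax, AnnotationGraph(diamondAnnotations()))
  expect_identical(mica("E", "E", tax, prop), "E")      # self-ancestor
  expect_identical(mica("D", "F", tax, prop), "D")      # ancestor endpoint
  # B and C annotate identical target sets: equal IC, lexicographic tie-break
  expect_identical(mica("C", "E", tax, prop), "B")
  # diamond: E and F share A and R; A is rarer
  ic <- termIC(prop)
  expect_gt(ic[["A"]], ic[["R"]])
  expect_identical(mica("E", "F", tax, prop), "A")
  # exhaustive-intersection verification on all pairs
  for (x in ontoTerms(tax)) for (y in ontoTerms(tax)) {
    common <- intersect(oracleAncestors(x, diamondEdges()),
                        oracleAncestors(y, diamondEdges()))
    v <- ic[common]; v <- v[!is.na(v)]
    m <- mica(x, y, tax, prop)
    if (length(v)) expect_equal(ic[[m]], max(v)) else expect_true(is.na(m))
  }
  # forest: no common ancestor across roots
  forest <- Taxonomy(c("r1", "r2", "a", "b"),
                     data.frame(child = c("a", "b"), parent = c("r1", "r2")))
  fprop <- propagateAnnotations(forest, AnnotationGraph(
    data.frame(term = c("a", "b"), target = c("g1", "g2"))))
  expect_true(is.na(mica("a", "b", forest, fprop)))
})

test_that("set similarity matches the exhaustive-pair brute force", {
  tax <- diamondTaxonomy()
  ann <- diamondAnnotations()
  prop <- propagateAnnotations(tax, AnnotationGraph(ann))
  ic <- termIC(prop)
  # sim({t},{t}) = IC(t)
  expect_equal(setSimilarity("G", "G", tax, prop), ic[["G"]])
  # X subset of Y: every x matches itself
  X <- c("E", "G"); Y <- c("E", "F", "G")
  expect_equal(setSimilarity(X, Y, tax, prop), mean(ic[X]))
  # 3-term vs 2-term against the double-loop oracle, both directions
  A <- c("E", "F", "G"); B <- c("C", "D")
  expect_equal(setSimilarity(A, B, tax, prop),
               oracleSetSim(A, B, ontoTerms(tax), ann, diamondEdges()))
  expect_equal(setSimilarity(B, A, tax, prop),
               oracleSetSim(B, A, ontoTerms(tax), ann, diamondEdges()))
  # printed form is asymmetric; the flag averages the directions
  expect_false(isTRUE(all.equal(setSimilarity(A, B, tax, prop),
                                setSimilarity(B, A, tax, prop))))
  expect_equal(setSimilarity(A, B, tax, prop, symmetrize = TRUE),
               (setSimilarity(A, B, tax, prop) +
                setSimilarity(B, A, tax, prop)) / 2)
  # empty sets carry no information
  expect_equal(setSimilarity(character(0), A, tax, prop), 0)
  expect_equal(setSimilarity(A, character(0), tax, prop), 0)
})

test_that("sim(X, X) equals the mean IC of X on random DAG fixtures", {
  for (seed in 1:6) {
    dag <- randomDAG(10, seed)
    ann <- randomAnnotations(dag, 6, seed)
    tax <- Taxonomy(dag$terms, dag$edges)
    prop <- propagateAnnotations(tax, AnnotationGraph(ann))
    ic <- termIC(prop, dag$terms)
    X <- unique(ann$term[1:3])   # directly annotated, so IC is defined
    expect_equal(setSimilarity(X, X, tax, prop), mean(ic[X]))
  }
})
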