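#' @include config.R readers.R cnv.R
NULL

# generator defaults: toy-scale resources whose statistical structure
# mirrors what the two-layer classifier assumes — a function ontology with
# a slim cut and diamond structure, modules of functionally related genes
# wired into a composite network whose strongest edges are the module
# backbone, a phenotype vocabulary tied to modules through a catalog of
# known genes, benign variants recurrently seen in control studies, and a
# plantable association between specific slim functions and harmful labels
.fixtureDefaults <- function() list(
  seed = 1L,
  n_terms = 37L,            # function-ontology size (root + slim + leaves)
  diamond_fraction = 0.25,  # leaves given a second slim parent
  n_phenotypes = 6L,
  n_genes = 48L,
  n_patients = 24L,
  n_cnvs = 48L,
  benign_ratio = 15,        # benign : harmful, clinical-regime default
  planted_modules = 2L,     # slim modules carrying the harmful signal
  effect_strength = 0.95,   # P(harmful CNV contains a planted-module gene)
  benign_planted_noise = 0.02,
  annotation_noise = 0.25,  # per-gene rate of spurious inferred annotations
  tier1_prob = 0.6,         # curated annotations carrying experimental codes
  n_studies = 3L,
  dgv_benign_prob = 0.8,    # per study: benign CNV covered by a region
  dgv_noise = 0.05,         # harmful CNV covered in one study
  known_per_module = 2L,
  harmful_meanlog = log(3e5),
  benign_meanlog = log(6e4),
  length_sdlog = 0.5)

#' Synthetic-fixture configuration
#'
#' @param ... named overrides of the generator defaults (see
#'   [simulateCohort()] for their meaning). Unknown keys are rejected.
#' @return named list of class `pathoCNVFixtureConfig`.
#' @export
fixtureConfig <- function(...) {
  defaults <- .fixtureDefaults()
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown fixture configuration key(s): ",
         paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, over)
  if (cfg$n_terms < 5L) stop("n_terms must be >= 5")
  if (cfg$n_genes < 4L || cfg$n_patients < 4L || cfg$n_cnvs < 4L)
    stop("sizes too small for a viable cohort")
  if (cfg$benign_ratio < 0) stop("benign_ratio must be non-negative")
  if (cfg$effect_strength < 0 || cfg$effect_strength > 1)
    stop("effect_strength must be in [0, 1]")
  class(cfg) <- c("pathoCNVFixtureConfig", "list")
  cfg
}

#' Generate a toy function ontology with a slim cut
#'
#' Builds a rooted DAG of `n_terms` terms: a slim layer directly under the
#' root and leaf terms under the slim layer, a fraction of which get a
#' second slim parent so the DAG has diamonds (exercising common-ancestor
#' logic). With `n_terms` <= 6 the taxonomy degenerates to a path whose
#' slim cut is the root's child. Deterministic in (`n_terms`,
#' `diamond_fraction`, `seed`).
#'
#' @param n_terms total number of terms (>= 5).
#' @param diamond_fraction fraction of leaves with two slim parents.
#' @param seed RNG seed.
#' @param prefix identifier prefix; default "GO".
#' @return list with `taxonomy` (a [Taxonomy-class]) and `slim`
#'   (character vector, the cut).
#' @export
makeTaxonomy <- function(n_terms = 37L, diamond_fraction = 0.25, seed = 1L,
                         prefix = "GO") {
  if (n_terms < 5L) stop("n_terms must be >= 5")
  id <- function(i) sprintf("%s:%07d", prefix, i)
  root <- id(1L)
  withSeed(seed, {
    if (n_terms <= 6L) {
      terms <- id(seq_len(n_terms))
      edges <- data.frame(child = terms[-1L], parent = terms[-n_terms])
      return(list(taxonomy = Taxonomy(terms, edges), slim = terms[2L]))
    }
    n_slim <- max(2L, floor((n_terms - 1L) / 3L))
    n_leaf <- n_terms - 1L - n_slim
    slim <- id(1L + seq_len(n_slim))
    leaves <- id(1L + n_slim + seq_len(n_leaf))
    child <- c(slim, leaves)
    parent <- c(rep(root, n_slim), slim[(seq_len(n_leaf) - 1L) %% n_slim + 1L])
    n_dia <- floor(diamond_fraction * n_leaf)
    if (n_dia > 0L && n_slim >= 2L) {
      extra <- sample(leaves, n_dia)
      first <- parent[match(extra, child)]
      second <- vapply(first, function(p)
        sample(setdiff(slim, p), 1L), character(1))
      child <- c(child, extra)
      parent <- c(parent, second)
    }
    list(taxonomy = Taxonomy(id(seq_len(n_terms)),
                             data.frame(child = child, parent = parent)),
         slim = slim)
  })
}

# Internal: toy phenotype ontology — root, two branch terms, leaves split
# between the branches. Returns taxonomy plus the leaf vocabulary.
makePhenotypeOntology <- function(n_phenotypes) {
  id <- function(i) sprintf("HP:%07d", i)
  root <- id(1L)
  branches <- id(2:3)
  leaves <- id(3L + seq_len(n_phenotypes))
  edges <- data.frame(
    child = c(branches, leaves),
    parent = c(rep(root, 2L),
               branches[(seq_len(n_phenotypes) - 1L) %% 2L + 1L]))
  list(taxonomy = Taxonomy(c(root, branches, leaves), edges),
       vocabulary = leaves)
}

#' Simulate a complete classification cohort
#'
#' Generates, as a pure function of a [fixtureConfig()], every resource
#' the pipeline consumes: function and phenotype ontologies, gene models
#' on a toy genome, evidence-coded annotations, a weighted interaction
#' network whose strongest edges connect functionally related genes, a
#' known-gene catalog and disorder annotations, benign-region study sets,
#' and a patient cohort of labeled CNVs.
#'
#' The harmful signal is plantable: genes are grouped into functional
#' modules (one per slim term); `planted_modules` of them carry the
#' signal, and a harmful CNV contains at least one planted-module gene
#' with probability `effect_strength` (at 1 with no noise, every harmful
#' CNV does; at 0 harmful labels are unrelated to the planted functions).
#' Benign CNVs avoid planted genes (up to `benign_planted_noise`), are
#' drawn shorter on average (log-normal lengths, `benign_meanlog` vs
#' `harmful_meanlog`), and are recurrently covered by the benign study
#' regions; the catalog links every module's known genes to the module's
#' phenotype so gene-phenotype relevance is informative.
#'
#' @param config a [fixtureConfig()].
#' @return a resource-bundle list with elements `go_tax`, `slim`,
#'   `hpo_tax`, `annotations`, `disorder_annotations`, `network`,
#'   `catalog`, `gene_models`, `dgv`, `cnvs`, and `meta` (planted slim
#'   terms, causative genes, module map).
#' @export
simulateCohort <- function(config = fixtureConfig()) {
  stopifnot(inherits(config, "pathoCNVFixtureConfig"))
  go <- makeTaxonomy(config$n_terms, config$diamond_fraction,
                     seed = config$seed, prefix = "GO")
  hp <- makePhenotypeOntology(config$n_phenotypes)
  n_slim <- length(go$slim)
  planted <- go$slim[seq_len(min(config$planted_modules, n_slim))]
  # leaves of each slim module (first-parent assignment)
  leaf_of <- lapply(go$slim, function(s)
    names(Filter(function(p) p[1L] == s, go$taxonomy@parents)))
  names(leaf_of) <- go$slim

  withSeed(config$seed + 7L, {
    ## --- genes on a toy genome, assigned to modules round-robin
    n_genes <- config$n_genes
    genes <- sprintf("G%03d", seq_len(n_genes))
    module <- go$slim[(seq_len(n_genes) - 1L) %% n_slim + 1L]
    names(module) <- genes
    chrom <- paste0("chr", (seq_len(n_genes) - 1L) %% 4L + 1L)
    width <- round(stats::runif(n_genes, 5e3, 2e4))
    gap <- round(stats::runif(n_genes, 1e4, 5e4))
    start <- integer(n_genes)
    for (ch in unique(chrom)) {
      i <- which(chrom == ch)
      start[i] <- cumsum(c(1e4, (width[i] + gap[i])[-length(i)]))
    }
    gene_bed <- data.frame(chrom = chrom, start = start,
                           end = start + width, gene_id = genes)

    ## --- annotations: curated module leaves (mostly experimental codes)
    ##     plus spurious inferred annotations, which are always tier 2 —
    ##     computationally transferred noise is what the evidence damping
    ##     is meant to absorb
    nonroot <- setdiff(go$taxonomy@terms, go$taxonomy@roots)
    ann <- do.call(rbind, lapply(genes, function(g) {
      lv <- leaf_of[[module[[g]]]]
      picked <- sample(lv, min(length(lv), sample(1:2, 1L)))
      ev <- ifelse(stats::runif(length(picked)) < config$tier1_prob,
                   sample(evidenceTiers$tier1, length(picked), TRUE),
                   sample(evidenceTiers$tier2, length(picked), TRUE))
      n_noise <- stats::rbinom(1L, 2L, config$annotation_noise)
      if (n_noise > 0L) {
        picked <- c(picked, sample(nonroot, n_noise))
        ev <- c(ev, sample(evidenceTiers$tier2, n_noise, TRUE))
      }
      keep <- !duplicated(picked)
      data.frame(target = g, term = picked[keep], evidence = ev[keep])
    }))

    ## --- known (catalog) genes: every module gets some, so relevance is
    ##     informative for harmful and benign genes alike
    ph_of_module <- stats::setNames(
      hp$vocabulary[(seq_len(n_slim) - 1L) %% length(hp$vocabulary) + 1L],
      go$slim)
    known <- character(0); cat_gene <- character(0); cat_ph <- list()
    for (m in go$slim) {
      for (j in seq_len(config$known_per_module)) {
        kg <- sprintf("KNOWN_%s_%d", sub(".*:", "", m), j)
        known <- c(known, kg)
        lv <- leaf_of[[m]]
        picked <- sample(lv, min(length(lv), 2L))
        ann <- rbind(ann, data.frame(target = kg, term = picked,
                                     evidence = "TAS"))
        cat_gene <- c(cat_gene, kg)
        cat_ph <- c(cat_ph, list(ph_of_module[[m]]))
      }
    }
    catalog <- data.frame(gene = cat_gene, stringsAsFactors = FALSE)
    catalog$phenotypes <- cat_ph

    ## --- disorder annotations give phenotype terms their frequencies
    dis <- do.call(rbind, lapply(seq_along(hp$vocabulary), function(i)
      data.frame(target = sprintf("DIS%03d", i),
                 term = hp$vocabulary[i])))
    dis <- rbind(dis, do.call(rbind, lapply(1:3, function(i)
      data.frame(target = sprintf("DIS9%02d", i),
                 term = sample(hp$vocabulary, 2L)))))

    ## --- interaction network: strong module backbone + weak background
    pairs <- t(utils::combn(genes, 2L))
    same <- module[pairs[, 1L]] == module[pairs[, 2L]]
    backbone <- which(same)
    bg_pool <- which(!same)
    n_bg <- min(length(bg_pool), 19L * length(backbone))
    background <- sample(bg_pool, n_bg)
    net_edges <- data.frame(
      from = pairs[c(backbone, background), 1L],
      to = pairs[c(backbone, background), 2L],
      weight = c(stats::runif(length(backbone), 2, 4),
                 stats::runif(n_bg, 0.01, 1)))
    network <- GeneNetwork(net_edges, nodes = genes)

    ## --- cohort: patients, labels, CNV intervals
    n_harm <- max(2L, round(config$n_cnvs / (config$benign_ratio + 1)))
    n_benign <- config$n_cnvs - n_harm
    patients <- sprintf("P%03d", seq_len(config$n_patients))
    harm_module <- planted[(seq_len(n_harm) - 1L) %% length(planted) + 1L]
    harm_patient <- patients[(seq_len(n_harm) - 1L) %% config$n_patients + 1L]
    benign_patient <- patients[(seq_len(n_benign) - 1L) %% config$n_patients + 1L]
    # patient phenotypes: the module phenotype of their first harmful CNV,
    # otherwise a random term; occasional random secondary term
    pat_ph <- stats::setNames(sample(hp$vocabulary, config$n_patients, TRUE),
                              patients)
    for (i in rev(seq_len(n_harm)))
      pat_ph[harm_patient[i]] <- ph_of_module[[harm_module[i]]]
    pat_extra <- stats::runif(config$n_patients) < 0.3
    pat_phen_str <- vapply(patients, function(p) {
      ph <- pat_ph[[p]]
      if (pat_extra[[which(patients == p)]])
        ph <- unique(c(ph, sample(hp$vocabulary, 1L)))
      paste(ph, collapse = ";")
    }, character(1))

    ord <- order(gene_bed$chrom, gene_bed$start, method = "radix")
    bed_ord <- gene_bed[ord, ]
    blockFor <- function(anchor, extra, avoid = character(0)) {
      i <- which(bed_ord$gene_id == anchor)
      sel <- i:min(nrow(bed_ord), i + extra)
      sel <- sel[bed_ord$chrom[sel] == bed_ord$chrom[i]]
      hit <- which(bed_ord$gene_id[sel] %in% avoid)
      if (length(hit)) sel <- sel[seq_len(min(hit) - 1L)]
      bed_ord[sel, ]
    }
    # harmful CNVs are longer and therefore sweep in more passenger genes
    mkCNV <- function(anchor, meanlog, avoid = character(0),
                      extra = sample(0:1, 1L)) {
      block <- blockFor(anchor, extra, avoid)
      len <- max(round(stats::rlnorm(1, meanlog, config$length_sdlog)),
                 max(block$end) - min(block$start) + 2L)
      pad <- len - (max(block$end) - min(block$start))
      lead <- round(stats::runif(1, 0, pad))
      s <- max(0L, min(block$start) - lead)
      e <- s + len
      # keep the padded interval clear of avoided genes on this chromosome
      av <- bed_ord[bed_ord$gene_id %in% avoid &
                    bed_ord$chrom == block$chrom[1L], ]
      if (nrow(av)) {
        lo <- av$end[av$end <= min(block$start)]
        hi <- av$start[av$start >= max(block$end)]
        if (length(lo)) s <- max(s, max(lo))
        if (length(hi)) e <- min(e, min(hi))
      }
      c(list(chrom = block$chrom[1L], start = s, end = e),
        list(genes_hint = block$gene_id))
    }
    causative_pool <- genes[module[genes] %in% planted]
    benign_pool <- setdiff(genes, causative_pool)

    rows <- vector("list", config$n_cnvs)
    for (i in seq_len(n_harm)) {
      hit <- stats::runif(1) < config$effect_strength
      anchor <- if (hit)
        sample(genes[module[genes] == harm_module[i]], 1L)
      else sample(benign_pool, 1L)
      cv <- mkCNV(anchor, config$harmful_meanlog,
                  avoid = if (hit) character(0) else causative_pool,
                  extra = sample(1:4, 1L))
      rows[[i]] <- data.frame(chrom = cv$chrom, start = cv$start,
                              end = cv$end,
                              type = sample(c("DEL", "DUP"), 1L, prob = c(0.7, 0.3)),
                              phen = pat_phen_str[[harm_patient[i]]],
                              label = "HARMFUL", patient = harm_patient[i])
    }
    for (j in seq_len(n_benign)) {
      contaminated <- stats::runif(1) < config$benign_planted_noise
      pool <- if (contaminated) genes else benign_pool
      cv <- mkCNV(sample(pool, 1L), config$benign_meanlog,
                  avoid = if (contaminated) character(0) else causative_pool)
      rows[[n_harm + j]] <- data.frame(chrom = cv$chrom, start = cv$start,
                                       end = cv$end,
                                       type = sample(c("DEL", "DUP"), 1L),
                                       phen = pat_phen_str[[benign_patient[j]]],
                                       label = "BENIGN",
                                       patient = benign_patient[j])
    }
    cnv_df <- do.call(rbind, rows)

    ## --- benign study regions: recurrent coverage of benign CNVs
    dgv_rows <- list()
    for (i in seq_len(nrow(cnv_df))) {
      benign <- cnv_df$label[i] == "BENIGN"
      for (s in seq_len(config$n_studies)) {
        p_cover <- if (benign) config$dgv_benign_prob else
          config$dgv_noise / config$n_studies
        if (stats::runif(1) < p_cover) {
          len <- cnv_df$end[i] - cnv_df$start[i]
          shift <- round(stats::runif(1, -0.1, 0.1) * len)
          dgv_rows[[length(dgv_rows) + 1L]] <- data.frame(
            study = sprintf("study%02d", s), chrom = cnv_df$chrom[i],
            start = max(0L, cnv_df$start[i] + shift),
            end = cnv_df$end[i] + shift)
        }
      }
    }
    # background regions away from the cohort
    for (s in seq_len(config$n_studies)) {
      st <- round(stats::runif(3, 5e6, 9e6))
      dgv_rows[[length(dgv_rows) + 1L]] <- data.frame(
        study = sprintf("study%02d", s), chrom = sample(unique(chrom), 3, TRUE),
        start = st, end = st + round(stats::runif(3, 1e4, 1e5)))
    }
    dgv_df <- do.call(rbind, dgv_rows)

    gene_models <- GenomicRanges::GRanges(
      gene_bed$chrom, IRanges::IRanges(gene_bed$start + 1L, gene_bed$end),
      gene_id = gene_bed$gene_id)
    gene_models <- BiocGenerics::sort(gene_models, ignore.strand = TRUE)
    dgv_gr <- GenomicRanges::GRanges(
      dgv_df$chrom, IRanges::IRanges(dgv_df$start + 1L, dgv_df$end))
    dgv <- S4Vectors::split(dgv_gr,
      factor(dgv_df$study, levels = csort(unique(dgv_df$study))))
    dgv <- S4Vectors::endoapply(dgv, mergeStudyRegions)
    cnvs <- GenomicRanges::GRanges(
      cnv_df$chrom, IRanges::IRanges(cnv_df$start + 1L, cnv_df$end))
    S4Vectors::mcols(cnvs) <- S4Vectors::DataFrame(
      cnv_id = sprintf("cnv%05d", seq_len(nrow(cnv_df))),
      type = cnv_df$type, phenotypes = cnv_df$phen,
      label = cnv_df$label, patient = cnv_df$patient)

    list(go_tax = go$taxonomy, slim = go$slim, hpo_tax = hp$taxonomy,
         annotations = ann[order(ann$target, ann$term, method = "radix"), ],
         disorder_annotations = dis, network = network, catalog = catalog,
         gene_models = gene_models, dgv = dgv, cnvs = cnvs,
         meta = list(planted_slim = planted,
                     causative_genes = causative_pool,
                     module = module,
                     phenotype_vocabulary = hp$vocabulary,
                     config = unclass(config)))
  })
}
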