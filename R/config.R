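#' @include utils.R
NULL

# every known key with its default; defaults follow the published protocol
# where it states a value (top 5% of edges, 30-gene subnetworks, 10 closest
# neighbors, 1000 copies per CNV, 50% benign-overlap gate, 20 runs)
.configDefaults <- function() list(
  edge_fraction = 0.05,
  k_sub = 30L,
  k_neighbors = 10L,
  restart_alpha = 0.5,
  walk_tol = 1e-9,
  walk_max_iter = 10000L,
  copies_per_cnv = 1000L,
  dgv_threshold = 0.5,
  dgv_type_match = FALSE,
  feature_weighting = "network-weighted",
  gene_weighting = "phenotype-weighted",
  cnv_features = c("gene", "length", "dgv"),
  regime = "balanced",
  runs = 20L,
  seeds = NULL,
  rf_trees = 100L,
  rf_mtry = NULL,
  permute_labels = FALSE,
  permutation_seed = 20202L,
  symmetrize_similarity = FALSE,
  fallback_scope = "subnetwork")

#' Algorithm configuration
#'
#' Builds a validated configuration for the pipeline. Every parameter has
#' an explicit default; where the underlying protocol states a value, the
#' default is that value.
#'
#' @param ... named overrides of the defaults. Recognised keys:
#' \describe{
#'   \item{edge_fraction}{fraction of strongest network edges kept (0.05).}
#'   \item{k_sub}{Dijkstra subnetwork size (30 closest neighbors).}
#'   \item{k_neighbors}{ranked neighbors contributing features (10).}
#'   \item{restart_alpha}{random-walk restart probability (0.5).}
#'   \item{walk_tol, walk_max_iter}{walk convergence control.}
#'   \item{copies_per_cnv}{training copies representing each CNV (1000).}
#'   \item{dgv_threshold}{minimal benign-region overlap fraction (0.5).}
#'   \item{dgv_type_match}{match DUP/DEL type in benign overlap (FALSE).}
#'   \item{feature_weighting}{"network-weighted" or "network-uniform".}
#'   \item{gene_weighting}{"phenotype-weighted" or "phenotype-uniform".}
#'   \item{cnv_features}{subset of c("gene", "length", "dgv").}
#'   \item{regime}{"balanced" or "unbalanced" split protocol.}
#'   \item{runs, seeds}{number of evaluation runs (20); run i uses
#'     seeds[i], default 1..runs.}
#'   \item{rf_trees, rf_mtry}{Random Forest size (100) and per-split
#'     feature count (default sqrt of feature count).}
#'   \item{permute_labels, permutation_seed}{null-model control: permute
#'     CNV labels once before all runs.}
#'   \item{symmetrize_similarity}{symmetrize the set similarity (FALSE;
#'     the printed asymmetric form is the default).}
#'   \item{fallback_scope}{"subnetwork" (all members) or "top_k" for the
#'     zero-relevance neighbor fallback.}
#' }
#' @return a validated named list of class `pathoCNVConfig`.
#' @export
runConfig <- function(...) {
  validateConfig(utils::modifyList(.configDefaults(), list(...),
                                   keep.null = TRUE))
}

#' Validate a configuration
#'
#' Rejects unknown keys and out-of-range values, naming the offender.
#'
#' @param config a named list of configuration values.
#' @return the validated config (class `pathoCNVConfig`).
#' @export
validateConfig <- function(config) {
  defaults <- .configDefaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  config <- utils::modifyList(defaults, config, keep.null = TRUE)
  chk <- function(ok, key, what)
    if (!ok) stop("invalid value for '", key, "': ", what)
  num1 <- function(v) is.numeric(v) && length(v) == 1L && is.finite(v)
  chk(num1(config$edge_fraction) && config$edge_fraction > 0 &&
        config$edge_fraction <= 1, "edge_fraction", "must be in (0, 1]")
  chk(num1(config$k_sub) && config$k_sub >= 1, "k_sub", "must be >= 1")
  chk(num1(config$k_neighbors) && config$k_neighbors >= 0,
      "k_neighbors", "must be >= 0")
  chk(num1(config$restart_alpha) && config$restart_alpha > 0 &&
        config$restart_alpha < 1, "restart_alpha", "must be in (0, 1)")
  chk(num1(config$walk_tol) && config$walk_tol > 0, "walk_tol",
      "must be positive")
  chk(num1(config$copies_per_cnv) && config$copies_per_cnv >= 1,
      "copies_per_cnv", "must be >= 1")
  chk(num1(config$dgv_threshold) && config$dgv_threshold >= 0 &&
        config$dgv_threshold <= 1, "dgv_threshold", "must be in [0, 1]")
  chk(config$feature_weighting %in% c("network-weighted", "network-uniform"),
      "feature_weighting", "must be network-weighted or network-uniform")
  chk(config$gene_weighting %in% c("phenotype-weighted", "phenotype-uniform"),
      "gene_weighting", "must be phenotype-weighted or phenotype-uniform")
  chk(length(config$cnv_features) >= 1L &&
        all(config$cnv_features %in% c("gene", "length", "dgv")),
      "cnv_features", "must be a non-empty subset of gene, length, dgv")
  chk(config$regime %in% c("balanced", "unbalanced"), "regime",
      "must be balanced or unbalanced")
  chk(num1(config$runs) && config$runs >= 1, "runs", "must be >= 1")
  chk(is.null(config$seeds) || (is.numeric(config$seeds) &&
        length(config$seeds) == config$runs), "seeds",
      "must be NULL or one seed per run")
  chk(num1(config$rf_trees) && config$rf_trees >= 1, "rf_trees",
      "must be >= 1")
  chk(config$fallback_scope %in% c("subnetwork", "top_k"), "fallback_scope",
      "must be subnetwork or top_k")
  for (k in c("k_sub", "k_neighbors", "walk_max_iter", "copies_per_cnv",
              "runs", "rf_trees"))
    config[[k]] <- as.integer(config[[k]])
  class(config) <- c("pathoCNVConfig", "list")
  config
}

#' Load a configuration from YAML
#'
#' Values merge flags-over-file-over-defaults: the YAML file overrides the
#' defaults, and `overrides` (e.g. parsed command-line flags) override the
#' file.
#'
#' @param path path to a YAML file, or NULL for defaults only.
#' @param overrides named list applied on top of the file.
#' @return a validated `pathoCNVConfig`.
#' @export
loadConfig <- function(path = NULL, overrides = list()) {
  cfg <- list()
  if (!is.null(path)) {
    cfg <- yaml::read_yaml(path)
    if (is.null(cfg)) cfg <- list()
    if (!is.null(cfg$cnv_features)) cfg$cnv_features <-
      as.character(cfg$cnv_features)
  }
  validateConfig(utils::modifyList(cfg, overrides, keep.null = TRUE))
}

#' Save a configuration to YAML
#'
#' Round-trips through [loadConfig()] to the identical configuration.
#'
#' @param config a `pathoCNVConfig`.
#' @param path destination YAML path.
#' @return `path`, invisibly.
#' @export
saveConfig <- function(config, path) {
  out <- unclass(config)
  out <- out[!vapply(out, is.null, logical(1))]
  yaml::write_yaml(out, path)
  invisible(path)
}
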