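resolve_network <- function(x) {
  if (inherits(x, "gene_network")) x else read_gene_network(x)
}

resolve_collections <- function(x) {
  if (inherits(x, "pathway_collection")) x <- list(x)
  x <- lapply(x, function(ci) {
    if (inherits(ci, "pathway_collection")) ci else read_gmt(ci)
  })
  names(x) <- vapply(x, `[[`, "", "source_label")
  x
}

resolve_seed_tables <- function(x) {
  out <- lapply(seq_along(x), function(i) {
    ti <- x[[i]]
    if (inherits(ti, "seed_table")) ti
    else read_seed_table(ti, cancer_type = names(x)[i])
  })
  names(out) <- vapply(out, attr, "", "cancer_type")
  if (!is.null(names(x)) && all(nzchar(names(x)))) names(out) <- names(x)
  out
}

# merge several collections into one, keeping a per-pathway label vector
merge_collections <- function(collections) {
  all_sets <- list(); labels <- character()
  for (ci in collections) {
    clash <- intersect(names(ci$sets), names(all_sets))
    if (length(clash))
      stop("pathway name(s) shared across collections: ",
           paste(head(clash, 5), collapse = ", "))
    all_sets <- c(all_sets, ci$sets)
    labels <- c(labels, rep(ci$source_label, length(ci$sets)))
  }
  list(pathways = pathway_collection(all_sets, source_label = "merged"),
       labels = labels)
}

#' Run the full disruption-analysis pipeline
#'
#' Per cancer type: build the initial activity vector from the seed table,
#' propagate it over the network, and score every pathway; then assemble
#' the pathway x cancer activity matrix, attach permutation p-values and
#' BH q-values, and select per-cancer, commonly and specifically disrupted
#' pathways. Optionally adds Z-scoring plus two-way clustering and
#' co-disruption correlation, overrepresentation baselines against a
#' census list, and network-view exports. All outputs are plain text and
#' byte-identical across reruns with the same inputs and seed.
#'
#' @param network path or \code{\link{gene_network}}.
#' @param collections path(s), \code{\link{pathway_collection}}(s) or a
#'   list thereof.
#' @param seed_tables named list of paths or \code{\link{seed_table}}s,
#'   one per cancer type.
#' @param out_dir output directory (created).
#' @param prop_cfg a \code{\link{propagation_config}}.
#' @param perm_cfg a \code{\link{permutation_config}}.
#' @param criteria a \code{\link{selection_criteria}}.
#' @param score_mode \code{"magnitude"} or \code{"signed"} (see
#'   \code{\link{initial_scores}}).
#' @param exclude_arm_level drop arm-level records before scoring.
#' @param min_members rankability threshold for pathways (default 3).
#' @param run_patterns compute Z-scores, clustering and co-disruption
#'   (default TRUE; skipped with a message when fewer than 3 cancers or
#'   pathways).
#' @param census optional path or character vector of known cancer genes;
#'   enables the census-fraction report on the common-pathway module.
#' @param netview_pathways optional character vector of pathway names to
#'   export as disruption neighborhoods (first cancer's seed table).
#' @param max_specific_cancers recurrence bound for cancer-specific calls
#'   (default 2).
#' @return (invisibly) a list with the activity matrix, selections and
#'   output paths; files are written under \code{out_dir}.
#' @export
run_pipeline <- function(network, collections, seed_tables, out_dir,
                         prop_cfg = propagation_config(),
                         perm_cfg = permutation_config(),
                         criteria = selection_criteria(),
                         score_mode = c("magnitude", "signed"),
                         exclude_arm_level = FALSE, min_members = 3,
                         run_patterns = TRUE, census = NULL,
                         netview_pathways = NULL,
                         max_specific_cancers = 2) {
  score_mode <- match.arg(score_mode)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  net <- resolve_network(network)
  colls <- resolve_collections(collections)
  merged <- merge_collections(colls)
  tables <- resolve_seed_tables(seed_tables)
  if (exclude_arm_level)
    tables <- lapply(tables, filter_arm_level, exclude = TRUE)

  gbar <- normalized_adjacency(net)
  g_list <- list(); gt_list <- list(); scores <- list()
  for (ck in names(tables)) {
    g <- initial_scores(tables[[ck]], net, mode = score_mode)
    gt <- propagate(gbar, g, prop_cfg)
    g_list[[ck]] <- g
    gt_list[[ck]] <- gt
    scores[[ck]] <- pathway_activity(gt, merged$pathways,
                                     min_members = min_members)
    write_scores(g, gt, file.path(out_dir, paste0("scores_", ck, ".tsv")))
  }
  mat <- assemble_matrix(scores, collection_labels = merged$labels)
  mat <- add_significance(mat, gbar, g_list, merged$pathways, perm_cfg,
                          prop_cfg, gtilde_list = gt_list)
  write_activity_matrix(mat, file.path(out_dir, "activity_matrix.tsv"),
                        coverage_path = file.path(out_dir, "coverage.tsv"))
  write.table(data.frame(cancer = rownames(mat$q_values), mat$q_values,
                         check.names = FALSE),
              file.path(out_dir, "q_values.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  per_cancer <- select_per_cancer(mat, criteria, perm_cfg$fdr_cutoffs)
  for (ck in names(per_cancer))
    write.table(per_cancer[[ck]],
                file.path(out_dir, paste0("selected_", ck, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  common <- select_common(mat, criteria, perm_cfg$fdr_cutoffs)
  write.table(common, file.path(out_dir, "common_pathways.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  specific <- select_specific(mat, criteria, perm_cfg$fdr_cutoffs,
                              max_cancer_types = max_specific_cancers)

  result <- list(matrix = mat, per_cancer = per_cancer, common = common,
                 specific = specific, out_dir = out_dir)

  if (run_patterns) {
    if (nrow(mat$scores) >= 3 && sum(colSums(is.na(mat$scores)) == 0) >= 3) {
      z <- zscore_by_cancer(mat)
      cl <- hierarchical_cluster(z, axis = "both")
      write_tree_newick(cl$row_tree, file.path(out_dir, "cancer_tree.nwk"))
      write_tree_newick(cl$column_tree, file.path(out_dir, "pathway_tree.nwk"))
      top_n <- min(30, sum(colSums(is.na(mat$scores)) == 0))
      cc <- codisruption_correlation(mat, top_n = top_n, criteria = criteria,
                                     fdr_cutoffs = perm_cfg$fdr_cutoffs)
      write.table(data.frame(pathway = rownames(cc), cc, check.names = FALSE),
                  file.path(out_dir, "codisruption.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      result$clustering <- cl
      result$codisruption <- cc
    } else message("patterns skipped: fewer than 3 cancers or rankable pathways")
  }

  if (!is.null(census)) {
    census_genes <- if (length(census) == 1 && file.exists(census))
      read_gene_list(census) else normalize_symbol(census)
    module <- unique(unlist(lapply(common$pathway, function(p)
      merged$pathways$sets[[p]]$members)))
    if (length(module)) {
      cf <- cancer_gene_fraction(module, census_genes, n_random = 1000,
                                 gene_pool = net$nodes,
                                 rng_seed = perm_cfg$rng_seed)
      jsonlite::write_json(cf[c("fraction", "n_module", "n_census_in_module",
                                "control_mean", "control_sd")],
                           file.path(out_dir, "census_fraction.json"),
                           auto_unbox = TRUE, digits = NA)
      result$census_fraction <- cf
    }
  }

  if (!is.null(netview_pathways)) {
    first <- tables[[1]]
    for (p in netview_pathways) {
      nb <- build_neighborhood(p, merged$pathways, net, first)
      export_neighborhood(nb, file.path(out_dir, paste0("netview_", p)),
                          format = "sif")
    }
  }

  manifest <- list(
    n_cancers = length(tables),
    cancers = names(tables),
    n_pathways = length(merged$pathways),
    collections = unname(vapply(colls, `[[`, "", "source_label")),
    network = list(nodes = length(net$nodes), edges = nrow(net$edges)),
    config = list(alpha = prop_cfg$alpha, method = prop_cfg$method,
                  score_mode = score_mode,
                  n_permutations = perm_cfg$n_permutations,
                  permutation_mode = perm_cfg$mode,
                  rng_seed = perm_cfg$rng_seed,
                  fdr_cutoffs = as.list(perm_cfg$fdr_cutoffs),
                  criteria = unclass(criteria)),
    n_selected_common = nrow(common),
    n_selected_per_cancer = vapply(per_cancer, function(d) sum(d$selected), 0))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(result)
}

#' Run the pipeline from a YAML configuration file
#'
#' The YAML file holds input paths (relative to its own directory) and
#' optional parameter overrides:
#' \preformatted{
#' network: network.tsv
#' collections:
#'   - {label: synthetic, path: pathways.gmt}
#' seed_tables:
#'   cancer01: seeds/cancer01.tsv
#' out_dir: results
#' alpha: 0.5
#' n_permutations: 1000
#' permutation_mode: membership
#' rng_seed: 1
#' fdr_default: 0.10
#' fdr_biocarta: 0.005
#' }
#'
#' @param config_path YAML path.
#' @param overrides named list overriding top-level config keys (e.g. from
#'   command-line flags).
#' @return see \code{\link{run_pipeline}}.
#' @export
run_pipeline_config <- function(config_path, overrides = list()) {
  cfg <- yaml::read_yaml(config_path)
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  base <- dirname(normalizePath(config_path))
  rel <- function(p) if (grepl("^/", p)) p else file.path(base, p)
  take <- function(nm, default) if (!is.null(cfg[[nm]])) cfg[[nm]] else default
  colls <- lapply(cfg$collections, function(ci)
    read_gmt(rel(ci$path), source_label = ci$label))
  seeds <- lapply(cfg$seed_tables, rel)
  cutoffs <- c(biocarta = as.numeric(take("fdr_biocarta", 0.005)),
               default = as.numeric(take("fdr_default", 0.10)))
  run_pipeline(
    network = rel(cfg$network), collections = colls, seed_tables = seeds,
    out_dir = take("out_dir", file.path(base, "results")),
    prop_cfg = propagation_config(alpha = take("alpha", 0.5)),
    perm_cfg = permutation_config(
      n_permutations = take("n_permutations", 10000),
      mode = take("permutation_mode", "both"),
      rng_seed = take("rng_seed", 1L), fdr_cutoffs = cutoffs),
    criteria = selection_criteria(
      per_cancer_top_fraction = take("top_percent", 20) / 100,
      common_top_fraction = take("common_top_percent", 10) / 100,
      min_cancer_types = take("min_cancers", 10)),
    score_mode = take("score_mode", "magnitude"),
    exclude_arm_level = isTRUE(cfg$exclude_arm_level),
    census = if (!is.null(cfg$census)) rel(cfg$census),
    netview_pathways = cfg$netview_pathways)
}

#' Command-line entry point
#'
#' Thin wrapper over \code{\link{run_pipeline_config}} for use from
#' \code{Rscript}; see \code{system.file("cli", "pathprop.R", package =
#' "pathprop")}. Flags override the corresponding YAML keys.
#'
#' @param args character vector of command-line arguments (default: the
#'   process arguments).
#' @return see \code{\link{run_pipeline}}.
#' @export
pathprop_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!requireNamespace("optparse", quietly = TRUE))
    stop("the command-line interface requires the 'optparse' package")
  parser <- optparse::OptionParser(
    usage = "pathprop --config config.yaml [overrides]",
    option_list = list(
      optparse::make_option("--config", type = "character"),
      optparse::make_option("--seed", type = "integer", default = NULL),
      optparse::make_option("--alpha", type = "double", default = NULL),
      optparse::make_option("--permutations", type = "integer", default = NULL),
      optparse::make_option("--mode", type = "character", default = NULL),
      optparse::make_option("--fdr-biocarta", type = "double", default = NULL),
      optparse::make_option("--fdr-default", type = "double", default = NULL),
      optparse::make_option("--top-percent", type = "double", default = NULL),
      optparse::make_option("--min-cancers", type = "integer", default = NULL),
      optparse::make_option("--out", type = "character", default = NULL)))
  opt <- optparse::parse_args(parser, args = args)
  if (is.null(opt$config)) stop("--config is required")
  ov <- list()
  map <- c(seed = "rng_seed", alpha = "alpha", permutations = "n_permutations",
           mode = "permutation_mode", `fdr-biocarta` = "fdr_biocarta",
           `fdr-default` = "fdr_default", `top-percent` = "top_percent",
           `min-cancers` = "min_cancers", out = "out_dir")
  for (flag in names(map))
    if (!is.null(opt[[flag]])) ov[[map[[flag]]]] <- opt[[flag]]
  run_pipeline_config(opt$config, overrides = ov)
}
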