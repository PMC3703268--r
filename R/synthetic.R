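#' Specification of a synthetic benchmark instance
#'
#' Describes a synthetic world for end-to-end testing: an interaction
#' network, a pathway collection, and per-cancer seed tables with planted
#' disruption. Defaults mirror the scale of the real resources the method
#' targets, reduced to desk scale: the reference interactome has ~9.7k
#' proteins with mean degree ~15.7, emulated here by 2,000 genes at mean
#' degree 16; 16 cancer types; 200 pathways of 10-40 genes
#' (curated-collection sizes); ~5\% of genes altered per cancer with mean
#' |log2 ratio| 1 (one copy gained/lost on average).
#'
#' @param n_genes number of genes (default 2000).
#' @param network_model \code{"erdos_renyi"}, \code{"preferential_attachment"}
#'   or \code{"community"} (planted-partition).
#' @param mean_degree target mean degree (default 16).
#' @param n_communities blocks for the community model (default 10).
#' @param n_pathways number of gene sets (default 200).
#' @param pathway_size_range inclusive size range (default c(10, 40)).
#' @param n_cancers number of cancer types (default 16).
#' @param scenario \code{"direct"} (altered genes planted inside target
#'   pathways, half the members on average), \code{"neighbor_only"}
#'   (altered genes planted exclusively among direct interactors of target
#'   members, zero member overlap) or \code{"null"} (uniform scatter).
#' @param effect_size mean |log2 ratio| of altered genes (default 1).
#' @param altered_fraction background fraction of genes altered per cancer
#'   (default 0.05).
#' @param n_planted_pathways number of target pathways (default 1).
#' @param n_planted_cancers cancers carrying the planted signal
#'   (default 12).
#' @param rng_seed integer seed.
#' @return list of class \code{scenario_spec}.
#' @export
scenario_spec <- function(n_genes = 2000,
                          network_model = c("erdos_renyi",
                                            "preferential_attachment",
                                            "community"),
                          mean_degree = 16, n_communities = 10,
                          n_pathways = 200, pathway_size_range = c(10, 40),
                          n_cancers = 16,
                          scenario = c("direct", "neighbor_only", "null"),
                          effect_size = 1.0, altered_fraction = 0.05,
                          n_planted_pathways = 1, n_planted_cancers = 12,
                          rng_seed = 1L) {
  network_model <- match.arg(network_model)
  scenario <- match.arg(scenario)
  stopifnot(n_genes > 0, n_pathways > 0, n_cancers > 0,
            altered_fraction > 0, altered_fraction < 1, effect_size > 0,
            length(pathway_size_range) == 2,
            pathway_size_range[1] >= 1,
            pathway_size_range[2] >= pathway_size_range[1])
  if (pathway_size_range[2] > n_genes)
    stop("pathway size range exceeds the number of genes")
  if (n_planted_cancers > n_cancers)
    stop("n_planted_cancers exceeds n_cancers")
  structure(list(n_genes = as.integer(n_genes), network_model = network_model,
                 mean_degree = mean_degree,
                 n_communities = as.integer(n_communities),
                 n_pathways = as.integer(n_pathways),
                 pathway_size_range = as.integer(pathway_size_range),
                 n_cancers = as.integer(n_cancers), scenario = scenario,
                 effect_size = effect_size,
                 altered_fraction = altered_fraction,
                 n_planted_pathways = as.integer(n_planted_pathways),
                 n_planted_cancers = as.integer(n_planted_cancers),
                 rng_seed = as.integer(rng_seed)),
            class = "scenario_spec")
}

synthetic_graph <- function(spec) {
  n <- spec$n_genes
  g <- switch(spec$network_model,
    erdos_renyi = igraph::sample_gnp(n, spec$mean_degree / (n - 1)),
    preferential_attachment =
      igraph::sample_pa(n, m = max(1, round(spec$mean_degree / 2)),
                        directed = FALSE),
    community = {
      sizes <- rep(n %/% spec$n_communities, spec$n_communities)
      sizes[1] <- sizes[1] + n - sum(sizes)
      # within-block edges 5x denser than between-block, calibrated so the
      # overall mean degree matches spec$mean_degree
      f_in <- mean(sizes) / n
      p_between <- spec$mean_degree / ((n - 1) * (1 + 4 * f_in))
      pm <- matrix(p_between, spec$n_communities, spec$n_communities)
      diag(pm) <- 5 * p_between
      igraph::sample_sbm(n, pref.matrix = pm, block.sizes = sizes)
    })
  genes <- sprintf("G%04d", seq_len(n))
  el <- igraph::as_edgelist(g, names = FALSE)
  gene_network(cbind(genes[el[, 1]], genes[el[, 2]]), nodes = genes)
}

# one seed record block for a set of altered genes
alteration_records <- function(genes, spec) {
  if (!length(genes)) return(NULL)
  magn <- rlnorm(length(genes), meanlog = log(spec$effect_size), sdlog = 0.3)
  is_amp <- runif(length(genes)) < 0.5
  data.frame(
    gene = genes,
    alteration = ifelse(is_amp, "amp", "del"),
    avg_log2_ratio = ifelse(is_amp, magn, -magn),
    q_value = 10^(-runif(length(genes), 1.5, 8)),
    frequency = runif(length(genes), 0.05, 0.6),
    arm_level = runif(length(genes)) < 0.1,
    stringsAsFactors = FALSE)
}

#' Generate a synthetic benchmark instance
#'
#' Builds a network, a pathway collection, per-cancer seed tables and
#' ground-truth labels from a \code{\link{scenario_spec}}. Deterministic
#' for a given \code{rng_seed}. In the \code{"direct"} scenario each
#' planted-pathway member is altered with probability 0.5 in the planted
#' cancers (half the members on average, at least one); in
#' \code{"neighbor_only"} the same rule is applied to the direct
#' interactors of planted members instead, and no planted member is ever
#' altered (background alterations exclude members too, so the
#' member/altered overlap is exactly zero); \code{"null"} plants nothing.
#'
#' @param spec a \code{\link{scenario_spec}}.
#' @return list with \code{network} (\code{gene_network}),
#'   \code{pathways} (\code{pathway_collection}, label
#'   \code{"synthetic"}), \code{seed_tables} (named list of
#'   \code{seed_table}s), and \code{truth} (list: \code{planted_pathways},
#'   \code{planted_cancers}, per-cancer \code{altered} gene lists).
#' @export
generate_instance <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  set.seed(spec$rng_seed)
  net <- synthetic_graph(spec)
  genes <- net$nodes
  n <- length(genes)

  sizes <- sample(seq(spec$pathway_size_range[1], spec$pathway_size_range[2]),
                  spec$n_pathways, replace = TRUE)
  connected <- genes[net$degrees > 0]
  sets <- vector("list", spec$n_pathways)
  planted_idx <- seq_len(min(spec$n_planted_pathways, spec$n_pathways))
  if (spec$scenario == "null") planted_idx <- integer()
  for (j in planted_idx) sets[[j]] <- sample(connected, sizes[j])
  planted_members <- unique(unlist(sets[planted_idx]))
  # the altered-interactor zone of the neighbor_only scenario emulates the
  # annotation gap: genes adjacent to the planted pathway carry the signal
  # but are absent from every other gene set, as most significantly altered
  # genes are absent from pathway databases
  bg_gene_pool <- genes
  if (spec$scenario == "neighbor_only" && length(planted_members)) {
    midx <- match(planted_members, genes)
    nbzone <- genes[unique(unlist(lapply(midx, function(i)
      which(net$adjacency[i, ] != 0))))]
    bg_gene_pool <- setdiff(genes, setdiff(nbzone, planted_members))
  }
  for (j in setdiff(seq_len(spec$n_pathways), planted_idx))
    sets[[j]] <- sample(bg_gene_pool, sizes[j])
  names(sets) <- sprintf("PW%03d", seq_len(spec$n_pathways))
  pathways <- pathway_collection(sets, source_label = "synthetic")
  planted_pathways <- names(sets)[planted_idx]

  cancers <- sprintf("cancer%02d", seq_len(spec$n_cancers))
  planted_cancers <- if (length(planted_idx))
    sort(sample(cancers, spec$n_planted_cancers)) else character()

  # genes never altered in this scenario
  forbidden <- if (spec$scenario == "neighbor_only") planted_members else character()
  bg_pool <- setdiff(genes, forbidden)
  n_bg <- round(spec$altered_fraction * n)

  plant_targets <- function() {
    if (spec$scenario == "direct") {
      alt <- planted_members[runif(length(planted_members)) < 0.5]
      if (!length(alt)) alt <- sample(planted_members, 1)
      alt
    } else if (spec$scenario == "neighbor_only") {
      midx <- match(planted_members, genes)
      nb <- unique(unlist(lapply(midx, function(i)
        which(net$adjacency[i, ] != 0))))
      nb <- setdiff(genes[nb], planted_members)
      alt <- nb[runif(length(nb)) < 0.5]
      if (!length(alt) && length(nb)) alt <- sample(nb, 1)
      alt
    } else character()
  }

  seed_tables <- list()
  altered <- list()
  for (ck in cancers) {
    alt <- sample(bg_pool, n_bg)
    if (ck %in% planted_cancers) alt <- unique(c(alt, plant_targets()))
    altered[[ck]] <- sort(alt)
    seed_tables[[ck]] <- seed_table(alteration_records(altered[[ck]], spec),
                                    cancer_type = ck)
  }
  list(network = net, pathways = pathways, seed_tables = seed_tables,
       truth = list(planted_pathways = planted_pathways,
                    planted_cancers = planted_cancers, altered = altered))
}

#' Generate size-matched decoy pathways
#'
#' Decoys are uniform random gene sets whose sizes are sampled (with
#' replacement) from the sizes of the real collection, serving as negative
#' controls for false-discovery evaluation.
#'
#' @param pathways the real \code{\link{pathway_collection}}.
#' @param n_decoys number of decoys.
#' @param gene_pool character vector to draw decoy members from.
#' @param rng_seed seed.
#' @return a \code{pathway_collection} labelled
#'   \code{"<source>_decoy"}; decoy names are \code{DECOY_###}.
#' @export
generate_decoys <- function(pathways, n_decoys, gene_pool, rng_seed = 1L) {
  stopifnot(inherits(pathways, "pathway_collection"), n_decoys >= 1)
  gene_pool <- unique(normalize_symbol(gene_pool))
  real_sizes <- lengths(lapply(pathways$sets, `[[`, "members"))
  if (max(real_sizes) > length(gene_pool))
    stop("gene pool smaller than the largest pathway size")
  set.seed(rng_seed)
  sizes <- sample(real_sizes, n_decoys, replace = TRUE)
  sets <- lapply(sizes, function(s) sample(gene_pool, s))
  names(sets) <- sprintf("DECOY_%03d", seq_len(n_decoys))
  pc <- pathway_collection(sets,
                           source_label = paste0(pathways$source_label, "_decoy"))
  attr(pc, "matched_sizes") <- unname(sizes)
  pc
}

#' Write a synthetic instance to disk in the pipeline's input formats
#'
#' Emits \code{network.tsv} (edge list), \code{pathways.gmt},
#' \code{seeds/<cancer>.tsv} seed tables and \code{manifest.yaml} listing
#' them, so generated fixtures double as documentation examples.
#'
#' @param instance result of \code{\link{generate_instance}}.
#' @param dir output directory (created if needed).
#' @return the manifest path.
#' @export
write_instance <- function(instance, dir) {
  dir.create(file.path(dir, "seeds"), recursive = TRUE, showWarnings = FALSE)
  write_edge_list(instance$network, file.path(dir, "network.tsv"))
  write_gmt(instance$pathways, file.path(dir, "pathways.gmt"))
  seed_paths <- character()
  for (ck in names(instance$seed_tables)) {
    p <- file.path(dir, "seeds", paste0(ck, ".tsv"))
    write.table(as.data.frame(instance$seed_tables[[ck]]), p, sep = "\t",
                quote = FALSE, row.names = FALSE)
    seed_paths[ck] <- file.path("seeds", paste0(ck, ".tsv"))
  }
  manifest <- list(network = "network.tsv",
                   collections = list(list(label = instance$pathways$source_label,
                                           path = "pathways.gmt")),
                   seed_tables = as.list(seed_paths))
  out <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(manifest, out)
  out
}
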