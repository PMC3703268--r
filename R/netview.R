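#' Build the disruption neighborhood of a pathway
#'
#' Collects all in-network members of the pathway (whatever their
#' alteration status) plus non-member direct interactors whose
#' GISTIC-style q-value ranks among the \code{top_n_qvalue} most
#' significant genes of the seed table. Per gene, the q-value used for
#' ranking is the more significant of its amp/del records; ties at the
#' boundary rank are all included. Node attributes carry alteration
#' status, population frequency and magnitude when available.
#'
#' @param pathway pathway name.
#' @param pathways a \code{\link{pathway_collection}}.
#' @param net a \code{\link{gene_network}}.
#' @param seed_table a \code{\link{seed_table}} with q-values.
#' @param top_n_qvalue rank cutoff for interactors (default 500).
#' @param include_interactor_edges also keep interactor-interactor edges
#'   (default TRUE).
#' @return object of class \code{pathway_neighborhood}: list with
#'   \code{nodes} (data.frame gene, layer, status, frequency, magnitude)
#'   and \code{edges} (data.frame from, to).
#' @export
build_neighborhood <- function(pathway, pathways, net, seed_table,
                               top_n_qvalue = 500,
                               include_interactor_edges = TRUE) {
  stopifnot(inherits(pathways, "pathway_collection"),
            inherits(net, "gene_network"),
            inherits(seed_table, "seed_table"))
  if (!pathway %in% names(pathways$sets))
    stop("unknown pathway: ", pathway)
  st <- as.data.frame(seed_table)
  if (!"q_value" %in% names(st))
    stop("seed table carries no q_value column (required for interactor ranking)")
  members <- intersect(pathways$sets[[pathway]]$members, net$nodes)

  # per-gene best (most significant) q-value, then rank ascending
  o <- order(st$gene, st$q_value)
  best <- st[o, ][!duplicated(st$gene[o]), ]
  rnk <- rank(best$q_value, ties.method = "min")
  top_genes <- best$gene[rnk <= top_n_qvalue]

  adj <- net$adjacency
  midx <- match(members, net$nodes)
  neigh <- if (length(midx)) {
    nb <- unique(unlist(lapply(midx, function(i) which(adj[i, ] != 0))))
    setdiff(net$nodes[nb], members)
  } else character()
  interactors <- intersect(neigh, top_genes)

  all_nodes <- c(members, interactors)
  layer <- c(rep("member", length(members)),
             rep("interactor", length(interactors)))
  # status / frequency / magnitude from the seed table (best record)
  srec <- best[match(all_nodes, best$gene), ]
  status <- ifelse(is.na(srec$alteration), "unchanged", srec$alteration)
  freq <- if ("frequency" %in% names(st)) srec$frequency else rep(NA_real_, length(all_nodes))
  magn <- srec$avg_log2_ratio
  nodes <- data.frame(gene = all_nodes, layer = layer, status = status,
                      frequency = freq, magnitude = magn,
                      stringsAsFactors = FALSE, row.names = NULL)

  keep <- net$edges$from %in% all_nodes & net$edges$to %in% all_nodes
  edges <- net$edges[keep, , drop = FALSE]
  if (!include_interactor_edges) {
    is_m <- function(g) g %in% members
    edges <- edges[is_m(edges$from) | is_m(edges$to), , drop = FALSE]
  }
  # drop interactors with no surviving edge to a member
  has_member_edge <- vapply(all_nodes, function(g) {
    if (g %in% members) return(TRUE)
    any((edges$from == g & edges$to %in% members) |
        (edges$to == g & edges$from %in% members))
  }, TRUE)
  nodes <- nodes[has_member_edge, , drop = FALSE]
  edges <- edges[edges$from %in% nodes$gene & edges$to %in% nodes$gene, ,
                 drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(pathway = pathway, nodes = nodes, edges = edges),
            class = "pathway_neighborhood")
}

#' Export a pathway neighborhood for visualization
#'
#' \code{"sif"} writes \code{<prefix>.sif} (edge list with relation
#' \code{pp}) and \code{<prefix>_nodes.tsv} (node attributes: gene, layer,
#' status, frequency, magnitude); \code{"graphml"} writes a single
#' \code{<prefix>.graphml} with the same attributes. In rendered views
#' node size is conventionally proportional to alteration frequency and
#' color encodes status (red = amplified, green = deleted, gray =
#' unchanged). Output is byte-stable for a fixed neighborhood.
#'
#' @param nb a \code{pathway_neighborhood}.
#' @param prefix output path prefix.
#' @param format \code{"sif"} or \code{"graphml"}.
#' @return character vector of files written.
#' @export
export_neighborhood <- function(nb, prefix, format = c("sif", "graphml")) {
  stopifnot(inherits(nb, "pathway_neighborhood"))
  format <- match.arg(format)
  if (format == "sif") {
    sif <- file.path(paste0(prefix, ".sif"))
    writeLines(paste(nb$edges$from, "pp", nb$edges$to, sep = "\t"), sif)
    attrs <- paste0(prefix, "_nodes.tsv")
    write.table(nb$nodes, attrs, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(c(sif, attrs))
  } else {
    g <- igraph::graph_from_data_frame(nb$edges, directed = FALSE,
                                       vertices = nb$nodes)
    out <- paste0(prefix, ".graphml")
    igraph::write_graph(g, out, format = "graphml")
    invisible(out)
  }
}
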