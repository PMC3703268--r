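#' @importFrom methods as is
#' @importFrom stats cor rnorm runif sd setNames rlnorm
#' @importFrom utils read.delim write.table head
NULL

normalize_symbol <- function(x) toupper(trimws(x))

#' Construct a gene interaction network
#'
#' Builds an undirected, simple (no self-loops, no multi-edges) gene network
#' from an edge table. Gene symbols are uppercased and whitespace-trimmed;
#' node order is lexicographic so that all derived matrices and output files
#' are reproducible for a given input.
#'
#' @param edges two-column character matrix or data.frame of gene pairs.
#' @param nodes optional character vector of node symbols to retain even when
#'   isolated (i.e. not covered by any edge).
#' @return an object of class \code{gene_network} with elements
#'   \code{nodes} (lexicographic symbol vector), \code{edges} (data.frame with
#'   columns \code{from}, \code{to}, canonicalized so \code{from < to}),
#'   \code{adjacency} (sparse symmetric 0/1 \code{Matrix} aligned to
#'   \code{nodes}) and \code{degrees} (named integer vector).
#' @export
gene_network <- function(edges, nodes = NULL) {
  if (is.null(edges)) edges <- matrix(character(), ncol = 2)
  edges <- as.matrix(edges)
  if (ncol(edges) != 2 && length(edges) > 0)
    stop("edge table must have exactly two columns")
  from <- normalize_symbol(edges[, 1])
  to <- if (ncol(edges) >= 2) normalize_symbol(edges[, 2]) else character()
  keep <- from != to                       # drop self-loops
  from <- from[keep]; to <- to[keep]
  a <- pmin(from, to); b <- pmax(from, to) # canonical orientation
  key <- paste(a, b, sep = "\r")
  dup <- duplicated(key)
  a <- a[!dup]; b <- b[!dup]
  all_nodes <- sort(unique(c(a, b, if (!is.null(nodes)) normalize_symbol(nodes))))
  n <- length(all_nodes)
  idx_a <- match(a, all_nodes); idx_b <- match(b, all_nodes)
  adj <- Matrix::sparseMatrix(
    i = c(idx_a, idx_b), j = c(idx_b, idx_a), x = 1,
    dims = c(n, n), dimnames = list(all_nodes, all_nodes)
  )
  ord <- order(a, b)
  structure(
    list(
      nodes = all_nodes,
      edges = data.frame(from = a[ord], to = b[ord], stringsAsFactors = FALSE),
      adjacency = adj,
      degrees = setNames(as.integer(Matrix::rowSums(adj)), all_nodes)
    ),
    class = "gene_network"
  )
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("gene_network: %d nodes, %d edges, mean degree %.2f\n",
              length(x$nodes), nrow(x$edges),
              if (length(x$nodes)) mean(x$degrees) else 0))
  invisible(x)
}

looks_like_header <- function(tokens) {
  any(grepl("^(gene|node|from|to|source|target|protein|interactor)", tolower(tokens)))
}

#' Read a gene network from an edge-list or SIF file
#'
#' Accepts a two-column tab-delimited edge list (\code{gene TAB gene}) or a
#' SIF file (\code{node TAB relation TAB node}; the relation is ignored).
#' A header line is detected heuristically by common column-name tokens.
#' Any extra columns (e.g. edge weights) are ignored with a warning, since
#' interactions are treated as binary.
#'
#' @param path path to the network file.
#' @param format \code{"auto"} (default: 3+ columns on the first data line is
#'   read as SIF), \code{"tsv"}, or \code{"sif"}.
#' @param node_file optional path to a one-symbol-per-line node file; listed
#'   nodes are retained even when isolated.
#' @return a \code{\link{gene_network}}.
#' @export
read_gene_network <- function(path, format = c("auto", "tsv", "sif"),
                              node_file = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("network file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0 && is.null(node_file)) stop("empty network file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  # fall back to whitespace splitting for space-separated files
  if (length(fields) && max(lengths(fields)) == 1)
    fields <- strsplit(lines, "[[:space:]]+")
  start <- 1L
  if (length(fields) && looks_like_header(fields[[1]])) start <- 2L
  fields <- fields[seq.int(start, length.out = max(0L, length(fields) - start + 1L))]
  line_no <- seq_along(lines)[seq.int(start, length.out = length(fields))]
  if (format == "auto")
    format <- if (length(fields) && length(fields[[1]]) >= 3) "sif" else "tsv"
  need <- if (format == "sif") 3L else 2L
  bad <- which(lengths(fields) < need)
  if (length(bad))
    stop(sprintf("malformed line %d in %s: expected >= %d fields, got %d",
                 line_no[bad[1]], path, need, length(fields[[bad[1]]])))
  if (format == "tsv" && any(lengths(fields) > 2))
    warning("extra columns beyond the two gene columns are ignored (binary edges)")
  edges <- if (length(fields)) {
    if (format == "sif")
      cbind(vapply(fields, `[`, "", 1L), vapply(fields, `[`, "", 3L))
    else
      cbind(vapply(fields, `[`, "", 1L), vapply(fields, `[`, "", 2L))
  } else matrix(character(), ncol = 2)
  nodes <- NULL
  if (!is.null(node_file)) {
    nodes <- trimws(readLines(node_file, warn = FALSE))
    nodes <- nodes[nzchar(nodes)]
  }
  gene_network(edges, nodes = nodes)
}

#' Write a network as a canonical two-column edge list
#'
#' Edges are written in canonical orientation (\code{from < to}),
#' lexicographically sorted, so that a write/read round trip is stable.
#'
#' @param net a \code{gene_network}.
#' @param path output path.
#' @param header write a \code{from TAB to} header (default TRUE).
#' @export
write_edge_list <- function(net, path, header = TRUE) {
  stopifnot(inherits(net, "gene_network"))
  write.table(net$edges, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = header)
  invisible(path)
}

#' Node-order manifest
#'
#' @param net a \code{gene_network}.
#' @return data.frame with columns \code{index}, \code{symbol}, \code{degree}
#'   in the canonical (lexicographic) node order used by all matrices.
#' @export
node_manifest <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  data.frame(index = seq_along(net$nodes), symbol = net$nodes,
             degree = unname(net$degrees), stringsAsFactors = FALSE)
}

#' Symmetric degree-normalized adjacency operator
#'
#' Computes the propagation operator \eqn{\bar{G} = D^{-1/2} G D^{-1/2}},
#' where \eqn{G} is the binary adjacency matrix and \eqn{D} the diagonal
#' degree matrix. Rows and columns of degree-zero nodes are identically
#' zero (their \eqn{D^{-1/2}} entry is set to 0), so an isolated node's
#' propagated score reduces to \eqn{(1-\alpha) g_i}. The operator is
#' symmetric with entries in [0, 1] and spectral radius at most 1.
#'
#' @param net a \code{gene_network}.
#' @return a sparse symmetric \code{Matrix} aligned to \code{net$nodes}.
#' @export
normalized_adjacency <- function(net) {
  stopifnot(inherits(net, "gene_network"))
  d <- as.numeric(net$degrees)
  inv_sqrt <- ifelse(d > 0, 1 / sqrt(d), 0)
  Dm <- Matrix::Diagonal(x = inv_sqrt)
  gbar <- Dm %*% net$adjacency %*% Dm
  dimnames(gbar) <- list(net$nodes, net$nodes)
  gbar
}
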