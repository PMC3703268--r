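#' Z-score transform pathway activity within each cancer type
#'
#' Each cancer row is centered and scaled to \eqn{(x - \bar{x})/s} using
#' the sample (n-1) standard deviation, so pathway activities become
#' comparable across cancer types with different overall alteration loads.
#' Missing (flagged) entries stay missing; a zero-variance row maps to all
#' zeros with a warning.
#'
#' @param mat a \code{pathway_activity_matrix}.
#' @return the matrix with \code{scores} replaced by row Z-scores.
#' @export
zscore_by_cancer <- function(mat) {
  stopifnot(inherits(mat, "pathway_activity_matrix"))
  z <- mat$scores
  for (k in seq_len(nrow(z))) {
    x <- z[k, ]
    ok <- !is.na(x)
    if (sum(ok) < 2)
      stop(sprintf("cancer row '%s' has fewer than 2 rankable pathways",
                   rownames(z)[k]))
    s <- sd(x[ok])
    if (s == 0) {
      warning(sprintf("zero-variance row '%s' mapped to zeros", rownames(z)[k]))
      z[k, ok] <- 0
    } else {
      z[k, ok] <- (x[ok] - mean(x[ok])) / s
    }
  }
  mat$scores <- z
  mat
}

# pairwise distances between rows of x
row_distances <- function(x, distance) {
  if (distance == "euclidean") as.matrix(stats::dist(x))
  else {
    d <- 1 - stats::cor(t(x))
    diag(d) <- 0
    d
  }
}

# agglomerative complete-linkage clustering with deterministic
# tie-breaking: among pairs at the minimal distance, merge the
# lexicographically smallest (by member label sets)
complete_linkage <- function(d, labels) {
  n <- nrow(d)
  if (n < 2) stop("need at least 2 items to cluster")
  active <- seq_len(n)
  members <- lapply(seq_len(n), identity)
  reps <- labels # lexicographically smallest label in each cluster
  id <- -seq_len(n) # hclust convention: negative = leaf
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  D <- d
  for (step in seq_len(n - 1)) {
    best <- NULL; best_d <- Inf
    for (ii in seq_along(active)) for (jj in seq_along(active)) {
      if (jj <= ii) next
      i <- active[ii]; j <- active[jj]
      dij <- D[i, j]
      if (dij < best_d - 1e-12) {
        best_d <- dij; best <- c(i, j)
      } else if (abs(dij - best_d) <= 1e-12 && !is.null(best)) {
        cand <- sort(c(reps[i], reps[j]))
        cur <- sort(c(reps[best[1]], reps[best[2]]))
        if (cand[1] < cur[1] || (cand[1] == cur[1] && cand[2] < cur[2]))
          best <- c(i, j)
      }
    }
    i <- best[1]; j <- best[2]
    merge[step, ] <- sort(c(id[i], id[j]))
    height[step] <- best_d
    # complete linkage: distance to the new cluster is the max
    for (k in active) if (k != i && k != j)
      D[i, k] <- D[k, i] <- max(D[i, k], D[j, k])
    # canonical within-merge order (smaller representative label first) so
    # the leaf order is independent of input row order
    members[[i]] <- if (reps[j] < reps[i]) c(members[[j]], members[[i]])
                    else c(members[[i]], members[[j]])
    reps[i] <- min(reps[i], reps[j])
    id[i] <- step
    active <- setdiff(active, j)
  }
  hc <- list(merge = merge, height = height,
             order = unlist(members[active]),
             labels = labels, method = "complete",
             call = match.call(), dist.method = "custom")
  class(hc) <- "hclust"
  hc
}

#' Two-way hierarchical clustering of the activity matrix
#'
#' Agglomerative complete-linkage clustering of cancer types (rows) and/or
#' pathways (columns). The default distance is 1 - Pearson correlation;
#' ties in the agglomeration are broken toward the lexicographically
#' smallest cluster pair so output is byte-stable.
#'
#' @param mat a \code{pathway_activity_matrix} (typically Z-scored);
#'   flagged pathways (any NA in their column) are dropped before
#'   clustering.
#' @param axis \code{"rows"}, \code{"columns"} or \code{"both"}.
#' @param distance \code{"correlation"} (1 - Pearson, default) or
#'   \code{"euclidean"}.
#' @return list of class \code{clustering_result} with \code{row_order},
#'   \code{column_order} (label vectors), \code{row_tree},
#'   \code{column_tree} (\code{hclust} objects or NULL), and provenance
#'   labels \code{distance_label}, \code{linkage_label}.
#' @export
hierarchical_cluster <- function(mat, axis = c("both", "rows", "columns"),
                                 distance = c("correlation", "euclidean")) {
  stopifnot(inherits(mat, "pathway_activity_matrix"))
  axis <- match.arg(axis)
  distance <- match.arg(distance)
  x <- mat$scores[, colSums(is.na(mat$scores)) == 0, drop = FALSE]
  res <- list(row_order = rownames(x), column_order = colnames(x),
              row_tree = NULL, column_tree = NULL,
              distance_label = distance, linkage_label = "complete")
  if (axis %in% c("rows", "both")) {
    hc <- complete_linkage(row_distances(x, distance), rownames(x))
    res$row_tree <- hc
    res$row_order <- rownames(x)[hc$order]
  }
  if (axis %in% c("columns", "both")) {
    hc <- complete_linkage(row_distances(t(x), distance), colnames(x))
    res$column_tree <- hc
    res$column_order <- colnames(x)[hc$order]
  }
  class(res) <- "clustering_result"
  res
}

#' Export a clustering tree in Newick format
#' @param tree an \code{hclust} object from
#'   \code{\link{hierarchical_cluster}}.
#' @param path output file.
#' @export
write_tree_newick <- function(tree, path) {
  stopifnot(inherits(tree, "hclust"))
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}

#' Pathway co-disruption correlation matrix
#'
#' Restricts to the top \code{top_n} pathways (ranked by recurrence in
#' qualifying cancers when q-values are available, otherwise by mean
#' activity score) and computes the Pearson correlation of each pathway
#' pair's activity profile across cancer types. Zero-variance profiles
#' yield NA correlations.
#'
#' @param mat a \code{pathway_activity_matrix}.
#' @param top_n number of top-ranked pathways to include (default 30).
#' @param criteria,fdr_cutoffs used for recurrence ranking when q-values
#'   are present.
#' @return top_n x top_n correlation matrix with unit diagonal.
#' @export
codisruption_correlation <- function(mat, top_n = 30,
                                     criteria = selection_criteria(),
                                     fdr_cutoffs = c(biocarta = 0.005,
                                                     default = 0.10)) {
  stopifnot(inherits(mat, "pathway_activity_matrix"))
  ok_cols <- colSums(is.na(mat$scores)) == 0
  x <- mat$scores[, ok_cols, drop = FALSE]
  if (top_n > ncol(x)) stop("top_n exceeds the number of rankable pathways")
  if (!is.null(mat$q_values)) {
    qual <- qualification_matrix(mat, criteria$common_top_fraction, fdr_cutoffs)
    key <- colSums(qual)[ok_cols]
  } else key <- rep(0, ncol(x))
  ord <- order(-key, -colMeans(x), colnames(x))
  x <- x[, ord[seq_len(top_n)], drop = FALSE]
  sds <- apply(x, 2, sd)
  cc <- suppressWarnings(stats::cor(x))
  cc[sds == 0, ] <- NA; cc[, sds == 0] <- NA
  diag(cc) <- 1
  cc
}
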