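#' Construct a pathway collection
#'
#' @param sets named list; each element is a list with \code{description}
#'   and \code{members} (character vector of gene symbols), or simply a
#'   character vector of members.
#' @param source_label collection label (e.g. \code{"biocarta"}); used to
#'   look up collection-specific FDR cutoffs.
#' @return object of class \code{pathway_collection} with elements
#'   \code{sets} and \code{source_label}.
#' @export
pathway_collection <- function(sets, source_label = "default") {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("all pathways must be named")
  if (anyDuplicated(names(sets)))
    stop("duplicate pathway name(s): ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "))
  sets <- lapply(sets, function(s) {
    if (is.character(s)) s <- list(description = "", members = s)
    s$members <- unique(normalize_symbol(s$members))
    if (!length(s$members)) stop("pathway with empty member list")
    s
  })
  structure(list(sets = sets, source_label = source_label),
            class = "pathway_collection")
}

#' @export
print.pathway_collection <- function(x, ...) {
  sizes <- lengths(lapply(x$sets, `[[`, "members"))
  cat(sprintf("pathway_collection '%s': %d gene sets, sizes %d-%d (median %d)\n",
              x$source_label, length(x$sets), min(sizes), max(sizes),
              as.integer(stats::median(sizes))))
  invisible(x)
}

#' @export
length.pathway_collection <- function(x) length(x$sets)

#' Read a GMT gene-set file
#'
#' Standard MSigDB dialect: one set per line, tab-separated
#' \code{name TAB description TAB member...}. Duplicate members within a
#' line are deduplicated; lines with fewer than three fields or duplicate
#' set names are rejected.
#'
#' @param path GMT file path.
#' @param source_label collection label; defaults to the file-name stem.
#' @return a \code{\link{pathway_collection}}.
#' @export
read_gmt <- function(path, source_label = NULL) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  if (is.null(source_label)) source_label <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad))
    stop(sprintf("malformed GMT line %d: fewer than 3 tab-separated fields",
                 bad[1]))
  sets <- lapply(fields, function(f)
    list(description = f[2], members = f[-(1:2)]))
  names(sets) <- vapply(fields, `[`, "", 1L)
  pathway_collection(sets, source_label = source_label)
}

#' Write a pathway collection as GMT
#' @param pathways a \code{\link{pathway_collection}}.
#' @param path output path.
#' @export
write_gmt <- function(pathways, path) {
  lines <- vapply(names(pathways$sets), function(nm) {
    s <- pathways$sets[[nm]]
    paste(c(nm, if (nzchar(s$description)) s$description else "na", s$members),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Pathway activity scores from propagated gene scores
#'
#' The activity of pathway \eqn{M_j} in one cancer type is the mean
#' propagated score of its member genes,
#' \eqn{M_{jk} = \sum_{i \in N_{M_j}} \tilde{g}_{ik} / |N_{M_j}|}.
#' By default the mean runs over members present in the network (absent
#' members reflect database coverage gaps, not biology); set
#' \code{all_members = TRUE} to count absent members as zeros instead.
#' Pathways with fewer than \code{min_members} in-network members are
#' flagged (score \code{NA}) and excluded from downstream ranking.
#'
#' @param gtilde propagated activity vector (names are gene symbols).
#' @param pathways a \code{\link{pathway_collection}}.
#' @param min_members minimum in-network members for a rankable score
#'   (default 3).
#' @param all_members if TRUE divide by annotated pathway size instead of
#'   in-network size.
#' @return data.frame with columns \code{pathway}, \code{score},
#'   \code{n_members}, \code{n_in_network}, \code{flagged}.
#' @export
pathway_activity <- function(gtilde, pathways, min_members = 3,
                             all_members = FALSE) {
  stopifnot(inherits(pathways, "pathway_collection"))
  if (!identical(attr(gtilde, "stage"), "propagated"))
    warning("scoring a vector not marked stage='propagated'")
  nms <- names(pathways$sets)
  score <- numeric(length(nms)); n_in <- integer(length(nms))
  n_mem <- integer(length(nms))
  for (i in seq_along(nms)) {
    mem <- pathways$sets[[i]]$members
    n_mem[i] <- length(mem)
    idx <- match(mem, names(gtilde))
    idx <- idx[!is.na(idx)]
    n_in[i] <- length(idx)
    score[i] <- if (length(idx) == 0) NA_real_
      else sum(gtilde[idx]) / if (all_members) length(mem) else length(idx)
  }
  flagged <- n_in < min_members
  score[flagged] <- NA_real_
  data.frame(pathway = nms, score = score, n_members = n_mem,
             n_in_network = n_in, flagged = flagged,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Assemble the pathway x cancer activity matrix
#'
#' @param per_cancer_scores named list (names are cancer-type labels) of
#'   \code{\link{pathway_activity}} data.frames computed against the same
#'   pathway collection.
#' @param collection_labels optional character vector (one per pathway, in
#'   collection order) recording which collection each pathway came from;
#'   a single label is recycled.
#' @return object of class \code{pathway_activity_matrix}: list with
#'   \code{scores} (cancers x pathways matrix, NA for flagged cells),
#'   \code{coverage} (same shape, in-network member counts),
#'   \code{collection} (per-pathway label vector), and slots
#'   \code{p_values} / \code{q_values} filled by
#'   \code{\link{add_significance}}.
#' @export
assemble_matrix <- function(per_cancer_scores, collection_labels = "default") {
  if (is.null(names(per_cancer_scores)))
    stop("per_cancer_scores must be a named list (cancer labels)")
  ref <- per_cancer_scores[[1]]$pathway
  for (k in seq_along(per_cancer_scores)) {
    if (!identical(per_cancer_scores[[k]]$pathway, ref))
      stop("inconsistent pathway sets across cancers (entry ",
           names(per_cancer_scores)[k], ")")
  }
  cancers <- names(per_cancer_scores)
  scores <- do.call(rbind, lapply(per_cancer_scores, function(d) d$score))
  coverage <- do.call(rbind, lapply(per_cancer_scores, function(d) d$n_in_network))
  dimnames(scores) <- dimnames(coverage) <- list(cancers, ref)
  collection <- rep_len(collection_labels, length(ref))
  names(collection) <- ref
  structure(list(scores = scores, coverage = coverage,
                 collection = collection, p_values = NULL, q_values = NULL),
            class = "pathway_activity_matrix")
}

#' @export
print.pathway_activity_matrix <- function(x, ...) {
  cat(sprintf("pathway_activity_matrix: %d cancer type(s) x %d pathway(s)%s\n",
              nrow(x$scores), ncol(x$scores),
              if (!is.null(x$q_values)) " (with p/q values)" else ""))
  invisible(x)
}

#' Write an activity matrix (and coverage) as TSV
#' @param mat a \code{pathway_activity_matrix}.
#' @param path score-matrix TSV path (cancers as rows).
#' @param coverage_path optional coverage TSV path.
#' @export
write_activity_matrix <- function(mat, path, coverage_path = NULL) {
  stopifnot(inherits(mat, "pathway_activity_matrix"))
  write.table(data.frame(cancer = rownames(mat$scores), mat$scores,
                         check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(coverage_path))
    write.table(data.frame(cancer = rownames(mat$coverage), mat$coverage,
                           check.names = FALSE),
                coverage_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
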