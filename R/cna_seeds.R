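#' Construct a seed-gene alteration table
#'
#' A seed table holds gene-level copy-number alteration summaries for one
#' cancer type: one record per (gene, alteration) pair with the average
#' log2 ratio across patients and, optionally, a GISTIC-style q-value, the
#' alteration frequency in the patient population, and an arm-level flag.
#'
#' @param records data.frame with columns \code{gene}, \code{alteration}
#'   (\code{"amp"} or \code{"del"}), \code{avg_log2_ratio} and optionally
#'   \code{q_value}, \code{frequency}, \code{arm_level}.
#' @param cancer_type label for the cancer type the table describes.
#' @return data.frame of class \code{seed_table} with attribute
#'   \code{cancer_type}.
#' @export
seed_table <- function(records, cancer_type = "unknown") {
  req <- c("gene", "alteration", "avg_log2_ratio")
  missing_cols <- setdiff(req, names(records))
  if (length(missing_cols))
    stop("seed table missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  records$gene <- normalize_symbol(records$gene)
  records$alteration <- tolower(trimws(records$alteration))
  bad_alt <- setdiff(unique(records$alteration), c("amp", "del"))
  if (length(bad_alt))
    stop("unknown alteration label(s): ", paste(bad_alt, collapse = ", "),
         " (expected 'amp' or 'del')")
  if (!is.numeric(records$avg_log2_ratio))
    stop("avg_log2_ratio must be numeric")
  key <- paste(records$gene, records$alteration)
  if (anyDuplicated(key)) {
    dups <- unique(records$gene[duplicated(key)])
    stop("duplicate (gene, alteration) record(s) for: ",
         paste(head(dups, 5), collapse = ", "))
  }
  if ("q_value" %in% names(records)) {
    q <- records$q_value
    if (any(!is.na(q) & (q < 0 | q > 1)))
      stop("q_value outside [0, 1]")
  }
  structure(records, class = c("seed_table", "data.frame"),
            cancer_type = cancer_type)
}

#' Read a gene-level seed table (GISTIC-style gene summary) from TSV
#'
#' Required columns: \code{gene}, \code{alteration}, \code{avg_log2_ratio};
#' optional: \code{q_value}, \code{frequency}, \code{arm_level} (logical).
#' The cancer-type label defaults to the file-name stem.
#'
#' @param path TSV path.
#' @param cancer_type optional explicit cancer-type label.
#' @return a \code{\link{seed_table}}.
#' @export
read_seed_table <- function(path, cancer_type = NULL) {
  if (!file.exists(path)) stop("seed table not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (is.null(cancer_type))
    cancer_type <- sub("\\.[^.]*$", "", basename(path))
  if ("avg_log2_ratio" %in% names(df) && !is.numeric(df$avg_log2_ratio)) {
    suppressWarnings(num <- as.numeric(df$avg_log2_ratio))
    if (anyNA(num)) {
      bad <- which(is.na(num))[1]
      stop(sprintf("non-numeric avg_log2_ratio on data line %d of %s", bad, path))
    }
    df$avg_log2_ratio <- num
  }
  if ("arm_level" %in% names(df) && !is.logical(df$arm_level))
    df$arm_level <- tolower(as.character(df$arm_level)) %in% c("true", "t", "1", "yes")
  seed_table(df, cancer_type = cancer_type)
}

#' Per-gene average log2 ratios from a patient-level matrix
#'
#' For each seed gene the initial score is the arithmetic mean of its log2
#' ratios over the m patient columns, i.e. \eqn{g_i = \sum_j S_{ij} / m}.
#'
#' @param mat gene x patient numeric matrix of log2 ratios (rownames are
#'   gene symbols).
#' @param amp_genes,del_genes character vectors of amplified / deleted seed
#'   genes; must be subsets of \code{rownames(mat)}.
#' @param cancer_type label for the resulting table.
#' @return a \code{\link{seed_table}} with one record per seed gene.
#' @export
averages_from_matrix <- function(mat, amp_genes, del_genes,
                                 cancer_type = "unknown") {
  mat <- as.matrix(mat)
  if (is.null(rownames(mat))) stop("matrix must carry gene rownames")
  rn <- normalize_symbol(rownames(mat))
  amp_genes <- normalize_symbol(amp_genes)
  del_genes <- normalize_symbol(del_genes)
  missing_genes <- setdiff(c(amp_genes, del_genes), rn)
  if (length(missing_genes))
    stop("seed gene(s) absent from matrix: ",
         paste(head(missing_genes, 10), collapse = ", "))
  rec <- function(genes, alt) {
    if (!length(genes)) return(NULL)
    data.frame(gene = genes, alteration = alt,
               avg_log2_ratio = rowMeans(mat[match(genes, rn), , drop = FALSE]),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  seed_table(rbind(rec(amp_genes, "amp"), rec(del_genes, "del")),
             cancer_type = cancer_type)
}

#' Drop whole-arm alteration records
#'
#' Arm-level gains and losses cover many passenger genes; excluding them is
#' a robustness option for sensitivity analysis.
#'
#' @param table a \code{\link{seed_table}}.
#' @param exclude if TRUE, remove records flagged \code{arm_level = TRUE};
#'   requires the \code{arm_level} column.
#' @return filtered \code{seed_table}.
#' @export
filter_arm_level <- function(table, exclude = FALSE) {
  stopifnot(inherits(table, "seed_table"))
  if (!exclude) return(table)
  if (!"arm_level" %in% names(table))
    stop("exclude = TRUE requires an arm_level column")
  keep <- !(table$arm_level %in% TRUE)
  if (!any(keep)) warning("all seed records are arm-level; table is now empty")
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  seed_table(as.data.frame(out), cancer_type = attr(table, "cancer_type"))
}

#' Initial gene activity vector
#'
#' Places each seed gene's average log2 ratio on the network node order;
#' all non-seed genes score 0. Under the default \code{"magnitude"} mode the
#' absolute value is used, so amplifications and deletions both contribute
#' positive disruption mass (signed scores would let them cancel within a
#' pathway); \code{"signed"} mode keeps the raw average for sensitivity
#' analysis. A gene carrying both an amp and a del record takes the record
#' with the larger |average| (tie broken toward amp). Seed genes absent from
#' the network cannot be propagated and are dropped with a warning count.
#'
#' @param table a \code{\link{seed_table}}.
#' @param net a \code{\link{gene_network}}.
#' @param mode \code{"magnitude"} (default) or \code{"signed"}.
#' @return named numeric vector aligned to \code{net$nodes} with attribute
#'   \code{stage = "initial"}.
#' @export
initial_scores <- function(table, net, mode = c("magnitude", "signed")) {
  stopifnot(inherits(table, "seed_table"), inherits(net, "gene_network"))
  mode <- match.arg(mode)
  df <- as.data.frame(table)
  if (nrow(df)) {
    # resolve amp+del conflicts: larger magnitude wins, ties go to amp
    pref <- order(df$gene, -abs(df$avg_log2_ratio),
                  match(df$alteration, c("amp", "del")))
    df <- df[pref, , drop = FALSE]
    df <- df[!duplicated(df$gene), , drop = FALSE]
  }
  g <- setNames(numeric(length(net$nodes)), net$nodes)
  present <- df$gene %in% net$nodes
  n_dropped <- sum(!present)
  if (n_dropped > 0)
    warning(sprintf("%d seed gene(s) absent from the network were dropped",
                    n_dropped))
  val <- df$avg_log2_ratio[present]
  if (mode == "magnitude") val <- abs(val)
  g[df$gene[present]] <- val
  attr(g, "stage") <- "initial"
  attr(g, "n_dropped") <- n_dropped
  g
}

#' Pathway-annotation coverage of the seed genes
#'
#' Fraction of the significantly altered (seed) genes that appear in at
#' least one pathway of a collection, and its complement. Low coverage is
#' the motivation for propagating scores through the interaction network
#' rather than restricting analysis to annotated genes.
#'
#' @param table a \code{\link{seed_table}}.
#' @param pathways a \code{\link{pathway_collection}}.
#' @return list with \code{n_seed}, \code{n_annotated},
#'   \code{annotated_fraction}, \code{unannotated_fraction}.
#' @export
annotation_coverage <- function(table, pathways) {
  stopifnot(inherits(table, "seed_table"))
  genes <- unique(as.data.frame(table)$gene)
  if (!length(genes)) stop("empty seed table")
  annotated <- unique(unlist(lapply(pathways$sets, `[[`, "members")))
  n_ann <- sum(genes %in% annotated)
  list(n_seed = length(genes), n_annotated = n_ann,
       annotated_fraction = n_ann / length(genes),
       unannotated_fraction = 1 - n_ann / length(genes))
}
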