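#' Gene significance table from a seed table
#'
#' Converts per-gene GISTIC-style q-values into \code{-log10(q)}
#' significance scores, one column per alteration type. q-values equal to
#' zero are clamped to the smallest positive q in the table (with a
#' warning) so the logarithm stays finite.
#'
#' @param table a \code{\link{seed_table}} with a \code{q_value} column.
#' @return data.frame of class \code{gene_significance} with columns
#'   \code{gene}, \code{neg_log10_q_amp}, \code{neg_log10_q_del} (NA when
#'   the gene has no record of that type).
#' @export
gene_significance <- function(table) {
  stopifnot(inherits(table, "seed_table"))
  df <- as.data.frame(table)
  if (!"q_value" %in% names(df)) stop("seed table carries no q_value column")
  q <- df$q_value
  if (any(q == 0, na.rm = TRUE)) {
    floor_q <- min(q[q > 0], na.rm = TRUE)
    warning(sprintf("clamping %d zero q-value(s) to %.3g",
                    sum(q == 0, na.rm = TRUE), floor_q))
    q[q == 0] <- floor_q
  }
  df$nlq <- -log10(q)
  genes <- sort(unique(df$gene))
  pick <- function(alt) {
    sub <- df[df$alteration == alt, ]
    sub$nlq[match(genes, sub$gene)]
  }
  structure(data.frame(gene = genes, neg_log10_q_amp = pick("amp"),
                       neg_log10_q_del = pick("del"),
                       stringsAsFactors = FALSE),
            class = c("gene_significance", "data.frame"))
}

# per-gene significance taking the more significant of amp/del
best_significance <- function(sig) {
  pmax(ifelse(is.na(sig$neg_log10_q_amp), 0, sig$neg_log10_q_amp),
       ifelse(is.na(sig$neg_log10_q_del), 0, sig$neg_log10_q_del))
}

rank_and_cut <- function(genes, values, top_fraction) {
  if (!length(genes)) stop("empty gene significance table")
  k <- ceiling(top_fraction * length(genes))
  ord <- order(-values, genes) # deterministic tie-break by symbol
  genes[ord[seq_len(k)]]
}

#' Pooled gene ranking
#'
#' Ranks genes of a single pooled-analysis significance table by
#' \code{-log10(q)}, taking the more significant of the amp/del q-values
#' for genes carrying both, and returns the top fraction.
#'
#' @param sig a \code{\link{gene_significance}} table from the pooled run.
#' @param top_fraction fraction of genes to select (e.g. 0.05).
#' @return character vector of selected gene symbols.
#' @export
gene_ranking_pooled <- function(sig, top_fraction) {
  stopifnot(inherits(sig, "gene_significance"))
  rank_and_cut(sig$gene, best_significance(sig), top_fraction)
}

#' Aggregated gene ranking across cancer types
#'
#' Sums the per-cancer (best-of-amp/del) \code{-log10(q)} values per gene
#' across all tables, treating a missing gene as contributing 0, then
#' selects the top fraction.
#'
#' @param sig_list list of \code{\link{gene_significance}} tables, one per
#'   cancer type.
#' @param top_fraction fraction of genes to select.
#' @return character vector of selected gene symbols.
#' @export
gene_ranking_aggregated <- function(sig_list, top_fraction) {
  if (!length(sig_list)) stop("need at least one significance table")
  genes <- sort(unique(unlist(lapply(sig_list, `[[`, "gene"))))
  total <- setNames(numeric(length(genes)), genes)
  for (sig in sig_list) {
    v <- best_significance(sig)
    total[sig$gene] <- total[sig$gene] + v
  }
  rank_and_cut(genes, unname(total), top_fraction)
}

#' Hypergeometric overrepresentation test
#'
#' Upper-tail probability of observing at least the actual overlap between
#' a selected gene set and a pathway when drawing \code{|selected|} genes
#' without replacement from the universe.
#'
#' @param selected character vector of selected genes (subset of
#'   \code{universe}).
#' @param pathway_members character vector of pathway genes (subset of
#'   \code{universe}).
#' @param universe character vector: the gene population.
#' @return p-value \eqn{P(X \ge |selected \cap pathway|)}.
#' @export
hypergeometric_enrichment <- function(selected, pathway_members, universe) {
  universe <- unique(normalize_symbol(universe))
  selected <- unique(normalize_symbol(selected))
  pathway_members <- unique(normalize_symbol(pathway_members))
  if (length(setdiff(selected, universe)))
    stop("selected genes must be a subset of the universe")
  if (length(setdiff(pathway_members, universe)))
    stop("pathway members must be a subset of the universe")
  k <- length(intersect(selected, pathway_members))
  K <- length(pathway_members)
  N <- length(universe)
  n <- length(selected)
  # P(X >= k); phyper's upper tail is strict, hence k - 1
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Enrichment of a gene-ranking baseline over a pathway collection
#'
#' Convenience wrapper: hypergeometric p-value and BH q for every pathway
#' against a selected gene set.
#'
#' @param selected selected gene set.
#' @param pathways a \code{\link{pathway_collection}}.
#' @param universe gene population. Pathway members outside the universe
#'   are ignored (the test population is the measured universe).
#' @return data.frame with columns \code{pathway}, \code{overlap},
#'   \code{p}, \code{q}.
#' @export
baseline_enrichment <- function(selected, pathways, universe) {
  universe <- unique(normalize_symbol(universe))
  p <- vapply(pathways$sets, function(s) {
    mem <- intersect(s$members, universe)
    if (!length(mem)) return(NA_real_)
    hypergeometric_enrichment(selected, mem, universe)
  }, 0)
  ov <- vapply(pathways$sets, function(s)
    length(intersect(normalize_symbol(selected), s$members)), 0L)
  data.frame(pathway = names(pathways$sets), overlap = ov, p = p,
             q = bh_adjust(p), stringsAsFactors = FALSE, row.names = NULL)
}

#' Fraction of known cancer genes in a functional module
#'
#' The functional module is typically the union of the member genes of the
#' commonly disrupted pathways; its census fraction
#' \eqn{|module \cap census| / |module|} measures enrichment for known
#' cancer drivers. Optionally compares against size-matched random gene
#' sets drawn from a gene pool.
#'
#' @param module_genes character vector (non-empty).
#' @param census character vector of known cancer genes.
#' @param n_random number of size-matched random control sets (0 disables).
#' @param gene_pool pool for the random controls (required when
#'   \code{n_random > 0}).
#' @param rng_seed seed for the resampling.
#' @return list with \code{fraction}, \code{n_module}, \code{n_census_in_module}
#'   and, when resampling, \code{control_fractions}, \code{control_mean},
#'   \code{control_sd}.
#' @export
cancer_gene_fraction <- function(module_genes, census, n_random = 0,
                                 gene_pool = NULL, rng_seed = 1L) {
  module_genes <- unique(normalize_symbol(module_genes))
  if (!length(module_genes)) stop("empty functional module")
  census <- unique(normalize_symbol(census))
  hit <- sum(module_genes %in% census)
  out <- list(fraction = hit / length(module_genes),
              n_module = length(module_genes), n_census_in_module = hit)
  if (n_random > 0) {
    if (is.null(gene_pool)) stop("gene_pool required for resampling controls")
    gene_pool <- unique(normalize_symbol(gene_pool))
    set.seed(rng_seed)
    ctrl <- vapply(seq_len(n_random), function(i) {
      s <- sample(gene_pool, length(module_genes))
      sum(s %in% census) / length(s)
    }, 0)
    out$control_fractions <- ctrl
    out$control_mean <- mean(ctrl)
    out$control_sd <- sd(ctrl)
  }
  out
}

#' Read a cancer-gene census list (one symbol per line)
#' @param path file path.
#' @return character vector of uppercased symbols.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  unique(normalize_symbol(x[nzchar(x)]))
}
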