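#' Permutation configuration
#'
#' Controls the construction of the empirical null for pathway activity
#' scores. The background shuffles both the initial gene scores (with
#' re-propagation) and the pathway member assignments; \code{mode} selects
#' which ingredient(s) to randomize. \code{"membership"} keeps the observed
#' propagated vector fixed and only draws random same-size member sets,
#' which is a fast approximation suitable for tests and exploration;
#' \code{"both"} (default) is the full scheme.
#'
#' @param n_permutations number of shuffles (default 10000).
#' @param mode \code{"both"}, \code{"membership"} or \code{"scores"}.
#' @param rng_seed integer seed making the null reproducible.
#' @param fdr_cutoffs named numeric vector of BH q-value cutoffs per
#'   collection label; the \code{"default"} entry applies to unlisted
#'   collections (defaults: biocarta 0.005, everything else 0.10).
#' @param share_nulls_by_size if TRUE, in membership mode all pathways
#'   share one size-nested null sample per permutation (large speedup;
#'   induces correlation between the p-values of different pathways but
#'   leaves each marginal p-value exact). Leave FALSE when independent
#'   p-values matter, e.g. for calibration studies.
#' @return list of class \code{permutation_config}.
#' @export
permutation_config <- function(n_permutations = 10000,
                               mode = c("both", "membership", "scores"),
                               rng_seed = 1L,
                               fdr_cutoffs = c(biocarta = 0.005, default = 0.10),
                               share_nulls_by_size = FALSE) {
  mode <- match.arg(mode)
  if (n_permutations < 1) stop("n_permutations must be at least 1")
  if (!"default" %in% names(fdr_cutoffs))
    fdr_cutoffs <- c(fdr_cutoffs, default = 0.10)
  if (any(fdr_cutoffs <= 0 | fdr_cutoffs >= 1))
    stop("fdr_cutoffs must lie in (0, 1)")
  structure(list(n_permutations = as.integer(n_permutations), mode = mode,
                 rng_seed = as.integer(rng_seed), fdr_cutoffs = fdr_cutoffs,
                 share_nulls_by_size = isTRUE(share_nulls_by_size)),
            class = "permutation_config")
}

#' Selection criteria for disrupted pathways
#'
#' @param per_cancer_top_fraction rank filter for per-cancer disrupted
#'   pathways (default 0.20: top 20\% by activity score).
#' @param common_top_fraction rank filter used when counting recurrence
#'   across cancers (default 0.10).
#' @param min_cancer_types minimum number of cancer types in which a
#'   pathway must qualify to be called commonly disrupted (default 10).
#' @param subnetwork_top_fraction stricter rank filter intended for large
#'   subnetwork-module collections (default 0.05).
#' @return list of class \code{selection_criteria}.
#' @export
selection_criteria <- function(per_cancer_top_fraction = 0.20,
                               common_top_fraction = 0.10,
                               min_cancer_types = 10,
                               subnetwork_top_fraction = 0.05) {
  stopifnot(per_cancer_top_fraction > 0, per_cancer_top_fraction <= 1,
            common_top_fraction > 0, common_top_fraction <= 1,
            min_cancer_types >= 1)
  structure(list(per_cancer_top_fraction = per_cancer_top_fraction,
                 common_top_fraction = common_top_fraction,
                 min_cancer_types = as.integer(min_cancer_types),
                 subnetwork_top_fraction = subnetwork_top_fraction),
            class = "selection_criteria")
}

# in-network member sizes for each pathway, given the gene universe
pathway_network_sizes <- function(pathways, genes) {
  vapply(pathways$sets, function(s) sum(s$members %in% genes), 0L)
}

# draw B random member sets of size s (without replacement) and return the
# null scores: colMeans of values over each set
random_set_means <- function(values, s, B) {
  n <- length(values)
  out <- numeric(B)
  for (b in seq_len(B)) out[b] <- sum(values[sample.int(n, s)]) / s
  out
}

#' Permutation null distribution of pathway scores
#'
#' Generates \code{cfg$n_permutations} null pathway scores per pathway.
#' Depending on \code{cfg$mode}, each permutation shuffles the initial gene
#' score vector uniformly over network nodes and re-propagates
#' (\code{"scores"}), replaces each pathway's in-network member set with a
#' uniform random gene set of equal size against the fixed observed
#' propagated vector (\code{"membership"}), or does both (\code{"both"}).
#' Deterministic given \code{cfg$rng_seed}.
#'
#' @param gbar normalized adjacency operator.
#' @param g initial activity vector (named, aligned to \code{gbar}).
#' @param pathways a \code{\link{pathway_collection}}.
#' @param cfg a \code{\link{permutation_config}}.
#' @param prop_cfg a \code{\link{propagation_config}}.
#' @param gtilde optional precomputed propagated vector (membership mode).
#' @return pathway x permutation matrix of null scores; rows of pathways
#'   with no in-network members are NA.
#' @export
permutation_null <- function(gbar, g, pathways, cfg = permutation_config(),
                             prop_cfg = propagation_config(), gtilde = NULL) {
  stopifnot(inherits(cfg, "permutation_config"))
  B <- cfg$n_permutations
  n <- length(g)
  sizes <- pathway_network_sizes(pathways, names(g))
  nms <- names(pathways$sets)
  nulls <- matrix(NA_real_, length(nms), B, dimnames = list(nms, NULL))
  set.seed(cfg$rng_seed)

  if (cfg$mode == "membership") {
    if (is.null(gtilde)) gtilde <- propagate(gbar, g, prop_cfg)
    gt <- as.numeric(gtilde)
    if (cfg$share_nulls_by_size) {
      # one partial permutation per draw serves every size: the first s
      # entries of a uniform permutation are a uniform random set, so the
      # running means give size-nested shared nulls (marginally exact)
      smax <- max(sizes)
      cs <- matrix(0, smax, B)
      for (b in seq_len(B)) cs[, b] <- cumsum(gt[sample.int(n, smax)])
      for (s in unique(sizes[sizes > 0]))
        nulls[sizes == s, ] <- rep(cs[s, ] / s, each = sum(sizes == s))
    } else {
      for (j in which(sizes > 0)) nulls[j, ] <- random_set_means(gt, sizes[j], B)
    }
    return(nulls)
  }

  # scores / both: re-propagate permuted initial vectors in chunks
  a <- prop_cfg$alpha
  solver <- propagation_solver(gbar, a)
  member_idx <- lapply(pathways$sets, function(s) {
    i <- match(s$members, names(g)); i[!is.na(i)]
  })
  chunk <- 500L
  done <- 0L
  while (done < B) {
    nb <- min(chunk, B - done)
    Gperm <- matrix(0, n, nb)
    for (b in seq_len(nb)) Gperm[, b] <- as.numeric(g)[sample.int(n, n)]
    X <- as.matrix(solver((1 - a) * Gperm))
    for (j in seq_along(member_idx)) {
      s <- sizes[j]
      if (s == 0) next
      if (cfg$mode == "scores") {
        nulls[j, done + seq_len(nb)] <- colMeans(X[member_idx[[j]], , drop = FALSE])
      } else { # both: random membership per permutation as well
        for (b in seq_len(nb))
          nulls[j, done + b] <- mean(X[sample.int(n, s), b])
      }
    }
    done <- done + nb
  }
  nulls
}

#' Empirical permutation p-values
#'
#' \eqn{p = (1 + \#\{x_b \ge s\}) / (B + 1)} for observed score \eqn{s}
#' against null samples \eqn{x_1..x_B}; the +1 correction keeps p strictly
#' positive. Pathways with NA observed scores get NA.
#'
#' @param observed named numeric vector of observed pathway scores.
#' @param nulls pathway x permutation null matrix from
#'   \code{\link{permutation_null}} (rownames must cover \code{observed}).
#' @return named p-value vector in (0, 1].
#' @export
empirical_pvalues <- function(observed, nulls) {
  if (is.null(names(observed)) || is.null(rownames(nulls)))
    stop("observed scores and null matrix must carry pathway names")
  missing_rows <- setdiff(names(observed), rownames(nulls))
  if (length(missing_rows))
    stop("missing null samples for pathway(s): ",
         paste(head(missing_rows, 5), collapse = ", "))
  B <- ncol(nulls)
  p <- vapply(names(observed), function(nm) {
    s <- observed[[nm]]
    if (is.na(s)) return(NA_real_)
    x <- nulls[nm, ]
    if (all(is.na(x))) return(NA_real_)
    (1 + sum(x >= s, na.rm = TRUE)) / (B + 1)
  }, 0)
  p
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up FDR adjustment: sort p ascending,
#' \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} n / j}, capped at 1, restored to
#' input order. NAs propagate and do not count toward the family size.
#'
#' @param pvalues numeric vector in [0, 1] (NAs allowed).
#' @return adjusted q-values in the input order.
#' @export
bh_adjust <- function(pvalues) {
  ok <- !is.na(pvalues)
  p <- pvalues[ok]
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  n <- length(p)
  q <- rep(NA_real_, length(pvalues))
  if (n > 0) {
    o <- order(p)
    qq <- pmin(1, cummin(rev(p[o] * n / seq_len(n)))[n:1])
    q[ok][o] <- qq
  }
  q
}

#' Attach permutation p-values and BH q-values to an activity matrix
#'
#' For each cancer type, builds the permutation null (seeded from
#' \code{cfg$rng_seed} plus the cancer index), computes empirical p-values,
#' and applies BH within each (cancer, collection) family.
#'
#' @param mat a \code{pathway_activity_matrix}.
#' @param gbar normalized adjacency operator.
#' @param g_list named list of initial activity vectors, one per cancer row
#'   of \code{mat}.
#' @param pathways the \code{\link{pathway_collection}} used to score
#'   \code{mat}.
#' @param cfg a \code{\link{permutation_config}}.
#' @param prop_cfg a \code{\link{propagation_config}}.
#' @param gtilde_list optional named list of precomputed propagated vectors.
#' @return the matrix with \code{p_values} and \code{q_values} filled.
#' @export
add_significance <- function(mat, gbar, g_list, pathways,
                             cfg = permutation_config(),
                             prop_cfg = propagation_config(),
                             gtilde_list = NULL) {
  stopifnot(inherits(mat, "pathway_activity_matrix"))
  cancers <- rownames(mat$scores)
  missing_g <- setdiff(cancers, names(g_list))
  if (length(missing_g))
    stop("missing initial vectors for cancer(s): ",
         paste(missing_g, collapse = ", "))
  P <- matrix(NA_real_, nrow(mat$scores), ncol(mat$scores),
              dimnames = dimnames(mat$scores))
  for (k in seq_along(cancers)) {
    ck <- cancers[k]
    cfg_k <- cfg
    cfg_k$rng_seed <- cfg$rng_seed + k
    nulls <- permutation_null(gbar, g_list[[ck]], pathways, cfg_k, prop_cfg,
                              gtilde = gtilde_list[[ck]])
    P[k, ] <- empirical_pvalues(
      setNames(mat$scores[k, ], colnames(mat$scores)), nulls)
  }
  Q <- P
  for (k in seq_len(nrow(P)))
    for (lab in unique(mat$collection)) {
      cols <- mat$collection == lab
      Q[k, cols] <- bh_adjust(P[k, cols])
    }
  mat$p_values <- P
  mat$q_values <- Q
  mat
}

fdr_cutoff_for <- function(fdr_cutoffs, label) {
  if (label %in% names(fdr_cutoffs)) fdr_cutoffs[[label]]
  else fdr_cutoffs[["default"]]
}

# logical cancers x pathways matrix: significant AND within the top
# `fraction` of ranked (non-NA) scores in that cancer; ranking by
# descending score with lexicographic pathway-name tie-break
qualification_matrix <- function(mat, fraction, fdr_cutoffs) {
  if (is.null(mat$q_values)) stop("activity matrix carries no q-values; run add_significance() first")
  cutoffs <- vapply(mat$collection, function(l) fdr_cutoff_for(fdr_cutoffs, l), 0)
  qual <- matrix(FALSE, nrow(mat$scores), ncol(mat$scores),
                 dimnames = dimnames(mat$scores))
  for (k in seq_len(nrow(mat$scores))) {
    sc <- mat$scores[k, ]
    ranked <- which(!is.na(sc))
    if (!length(ranked)) next
    ord <- ranked[order(-sc[ranked], colnames(mat$scores)[ranked])]
    top_k <- ceiling(fraction * length(ranked))
    in_top <- colnames(mat$scores) %in% colnames(mat$scores)[ord[seq_len(top_k)]]
    sig <- !is.na(mat$q_values[k, ]) & mat$q_values[k, ] <= cutoffs
    qual[k, ] <- in_top & sig
  }
  qual
}

#' Per-cancer disrupted pathway selection
#'
#' A pathway is called disrupted in a cancer type when its BH q-value is at
#' or below the collection-specific FDR cutoff and its activity score ranks
#' within the top \code{per_cancer_top_fraction} of rankable pathways in
#' that cancer (descending score, ties broken by pathway name).
#'
#' @param mat a \code{pathway_activity_matrix} with q-values.
#' @param criteria a \code{\link{selection_criteria}}.
#' @param fdr_cutoffs named cutoff vector (see
#'   \code{\link{permutation_config}}).
#' @return named list (per cancer) of data.frames with columns
#'   \code{pathway}, \code{score}, \code{rank}, \code{p}, \code{q},
#'   \code{selected}.
#' @export
select_per_cancer <- function(mat, criteria = selection_criteria(),
                              fdr_cutoffs = c(biocarta = 0.005, default = 0.10)) {
  qual <- qualification_matrix(mat, criteria$per_cancer_top_fraction, fdr_cutoffs)
  out <- list()
  for (k in seq_len(nrow(mat$scores))) {
    sc <- mat$scores[k, ]
    rk <- rep(NA_integer_, length(sc))
    ranked <- which(!is.na(sc))
    ord <- ranked[order(-sc[ranked], colnames(mat$scores)[ranked])]
    rk[ord] <- seq_along(ord)
    out[[rownames(mat$scores)[k]]] <- data.frame(
      pathway = colnames(mat$scores), score = sc, rank = rk,
      p = mat$p_values[k, ], q = mat$q_values[k, ],
      selected = qual[k, ], stringsAsFactors = FALSE, row.names = NULL)
  }
  out
}

#' Commonly disrupted pathways across cancer types
#'
#' A pathway is commonly disrupted when it is significant (BH q at or below
#' the collection cutoff) and ranked within the top
#' \code{common_top_fraction} of pathways in at least
#' \code{min_cancer_types} cancer types.
#'
#' @inheritParams select_per_cancer
#' @param top_fraction override for the rank filter (defaults to
#'   \code{criteria$common_top_fraction}; use
#'   \code{criteria$subnetwork_top_fraction} for subnetwork collections).
#' @return data.frame with columns \code{pathway}, \code{n_cancers},
#'   \code{mean_score}, \code{cancers} (comma-joined labels), sorted by
#'   recurrence then mean score.
#' @export
select_common <- function(mat, criteria = selection_criteria(),
                          fdr_cutoffs = c(biocarta = 0.005, default = 0.10),
                          top_fraction = NULL) {
  if (is.null(top_fraction)) top_fraction <- criteria$common_top_fraction
  qual <- qualification_matrix(mat, top_fraction, fdr_cutoffs)
  counts <- colSums(qual)
  keep <- which(counts >= criteria$min_cancer_types)
  mean_score <- colMeans(mat$scores, na.rm = TRUE)
  res <- data.frame(
    pathway = colnames(mat$scores)[keep],
    n_cancers = counts[keep],
    mean_score = mean_score[keep],
    cancers = vapply(keep, function(j)
      paste(rownames(mat$scores)[qual[, j]], collapse = ","), ""),
    stringsAsFactors = FALSE, row.names = NULL)
  res[order(-res$n_cancers, -res$mean_score, res$pathway), , drop = FALSE]
}

#' Cancer-type-specific disrupted pathways
#'
#' Pathways qualifying (significant and top-ranked, as in
#' \code{\link{select_common}}) in at least one and at most
#' \code{max_cancer_types} cancer types, keyed by the cancers where they
#' qualify.
#'
#' @inheritParams select_common
#' @param max_cancer_types upper bound on recurrence (default 2).
#' @return named list: cancer label -> character vector of specific
#'   pathways.
#' @export
select_specific <- function(mat, criteria = selection_criteria(),
                            fdr_cutoffs = c(biocarta = 0.005, default = 0.10),
                            max_cancer_types = 2) {
  qual <- qualification_matrix(mat, criteria$common_top_fraction, fdr_cutoffs)
  counts <- colSums(qual)
  specific <- which(counts >= 1 & counts <= max_cancer_types)
  out <- setNames(vector("list", nrow(mat$scores)), rownames(mat$scores))
  for (k in seq_len(nrow(mat$scores)))
    out[[k]] <- colnames(mat$scores)[specific[qual[k, specific]]]
  out[lengths(out) > 0]
}
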