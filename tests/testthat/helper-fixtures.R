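# Shared fixture builders. Everything is generated in code; no stored data.

# tiny named edge-list networks
toy_net <- function(edges) gene_network(do.call(rbind, edges))

path_net <- function() toy_net(list(c("A", "B"), c("B", "C")))
triangle_net <- function() toy_net(list(c("A", "B"), c("B", "C"), c("A", "C")))
star_net <- function() toy_net(list(c("HUB", "L1"), c("HUB", "L2"),
                                    c("HUB", "L3"), c("HUB", "L4")))

# random Erdos-Renyi gene network for property tests
random_net <- function(n, p = 0.05, seed = 1) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  genes <- sprintf("G%03d", seq_len(n))
  el <- igraph::as_edgelist(g, names = FALSE)
  gene_network(cbind(genes[el[, 1]], genes[el[, 2]]), nodes = genes)
}

# activity vector aligned to a network, marked with a stage
av <- function(net, values, stage = "initial") {
  g <- setNames(values, net$nodes)
  attr(g, "stage") <- stage
  g
}

# seed table from compact arguments
st <- function(genes, alt, avg, q = NULL, cancer = "test", ...) {
  df <- data.frame(gene = genes, alteration = alt, avg_log2_ratio = avg,
                   stringsAsFactors = FALSE)
  if (!is.null(q)) df$q_value <- q
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  seed_table(df, cancer_type = cancer)
}

# hand-built pathway_activity_matrix with given scores and q-values
toy_pam <- function(scores, q = NULL, p = NULL, collection = "default") {
  stopifnot(is.matrix(scores))
  coverage <- matrix(5L, nrow(scores), ncol(scores), dimnames = dimnames(scores))
  coll <- setNames(rep_len(collection, ncol(scores)), colnames(scores))
  structure(list(scores = scores, coverage = coverage, collection = coll,
                 p_values = p, q_values = q),
            class = "pathway_activity_matrix")
}

# truncated Neumann-series propagation oracle: sum_k alpha^k Gbar^k (1-a) g
neumann_oracle <- function(gbar, g, alpha, K = 200) {
  acc <- term <- (1 - alpha) * as.numeric(g)
  for (k in seq_len(K)) {
    term <- alpha * as.numeric(gbar %*% term)
    acc <- acc + term
  }
  acc
}

# brute-force BH oracle: explicit min over j >= i of p_(j) * n / j
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  for (i in seq_len(n)) {
    vals <- vapply(i:n, function(j) p[o[j]] * n / j, 0)
    q[o[i]] <- min(1, min(vals))
  }
  q
}

# exhaustive hypergeometric oracle: enumerate all draws of size n
hyper_oracle <- function(k, K, N, n) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K) # first K elements are the "successes"
  mean(hits >= k)
}
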