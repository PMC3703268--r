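test_that("configs validate", {
  expect_error(permutation_config(n_permutations = 0), "n_permutations")
  expect_error(permutation_config(fdr_cutoffs = c(default = 1.5)), "fdr")
  expect_equal(permutation_config(fdr_cutoffs = c(kegg = 0.2))$fdr_cutoffs[["default"]],
               0.10)
  expect_error(selection_criteria(per_cancer_top_fraction = 0))
  expect_equal(selection_criteria()$min_cancer_types, 10L)
})

test_that("permutation nulls are deterministic and handle the whole-network set", {
  net <- random_net(40, 0.1, seed = 10)
  gb <- normalized_adjacency(net)
  set.seed(11); g <- av(net, runif(40))
  pc <- pathway_collection(list(P1 = net$nodes[1:5], ALL = net$nodes))
  cfg <- permutation_config(n_permutations = 50, mode = "membership",
                            rng_seed = 42)
  n1 <- permutation_null(gb, g, pc, cfg)
  n2 <- permutation_null(gb, g, pc, cfg)
  expect_identical(n1, n2)
  # a pathway spanning the whole network has a constant null: the mean of
  # the fixed propagated vector
  gt <- propagate(gb, g)
  expect_equal(unname(n1["ALL", ]), rep(mean(gt), 50))

  # scores and both modes run and are seeded
  for (m in c("scores", "both")) {
    cfg_m <- permutation_config(n_permutations = 20, mode = m, rng_seed = 7)
    a <- permutation_null(gb, g, pc, cfg_m)
    b <- permutation_null(gb, g, pc, cfg_m)
    expect_identical(a, b)
    expect_false(anyNA(a))
  }

  # share_nulls_by_size gives same-size pathways identical null rows
  pc2 <- pathway_collection(list(A = net$nodes[1:5], B = net$nodes[6:10]))
  ns <- permutation_null(gb, g, pc2,
                         permutation_config(50, "membership", 1,
                                            share_nulls_by_size = TRUE))
  expect_identical(ns["A", ], ns["B", ])
})

test_that("empirical p-values follow the +1-corrected counting formula", {
  nulls <- matrix(1:9, 1, dimnames = list("P", NULL)) # B = 9
  expect_equal(unname(empirical_pvalues(c(P = 7.5), nulls)), 0.3) # 2 of 9 >= obs
  expect_equal(unname(empirical_pvalues(c(P = 100), nulls)), 0.1) # beats all
  expect_equal(unname(empirical_pvalues(c(P = 0), nulls)), 1)     # beats none
  B999 <- matrix(runif(999), 1, dimnames = list("P", NULL))
  expect_equal(unname(empirical_pvalues(c(P = 2), B999)), 1 / 1000)
  expect_error(empirical_pvalues(c(Q = 1), nulls), "Q")
  # monotone: larger observed score never raises p
  obs <- sort(runif(20))
  ps <- vapply(obs, function(s)
    unname(empirical_pvalues(c(P = s), B999)), 0)
  expect_true(all(diff(ps) <= 0))
  expect_true(all(ps > 0 & ps <= 1))
})

test_that("bh_adjust matches hand cases and the brute-force oracle", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.1, 1.2)), "p-values")
  # NA handling: NAs pass through, family size excludes them
  expect_equal(bh_adjust(c(0.02, NA)), c(0.02, NA))
  set.seed(13)
  for (i in 1:50) {
    p <- runif(sample(3:40, 1))
    expect_equal(bh_adjust(p), bh_oracle(p))
  }
  # agreement with stats::p.adjust as a second, independent reference
  p <- runif(200)
  expect_equal(bh_adjust(p), p.adjust(p, "BH"))
})

test_that("per-cancer selection applies both the FDR and the rank filter", {
  scores <- rbind(ca = c(P01 = 10, P02 = 9, P03 = 8, P04 = 7, P05 = 6,
                         P06 = 5, P07 = 4, P08 = 3, P09 = 2, P10 = 1))
  q <- scores; q[1, ] <- c(0.001, 0.5, 0.001, 0.2, 0.2, 0.2, 0.2, 0.2, 0.2, 0.001)
  p <- q / 2
  mat <- toy_pam(scores, q = q, p = p)
  sel <- select_per_cancer(mat, selection_criteria(per_cancer_top_fraction = 0.2),
                           fdr_cutoffs = c(default = 0.05))
  d <- sel$ca
  # top 20% of 10 = 2 pathways by score: P01, P02; only P01 is also significant
  expect_equal(d$pathway[d$selected], "P01")
  expect_equal(d$rank[d$pathway == "P03"], 3)
  # q = 0.5 under a 0.005 cutoff is excluded regardless of rank
  sel2 <- select_per_cancer(mat, selection_criteria(),
                            fdr_cutoffs = c(default = 0.005))
  expect_false(sel2$ca$selected[sel2$ca$pathway == "P02"])
  expect_error(select_per_cancer(toy_pam(scores)), "q-values")
})

test_that("rank ties break lexicographically for determinism", {
  scores <- rbind(ca = c(PB = 5, PA = 5, PC = 1))
  q <- rbind(ca = c(0.01, 0.01, 0.01))
  dimnames(q) <- dimnames(scores)
  mat <- toy_pam(scores, q = q, p = q)
  d <- select_per_cancer(mat, selection_criteria(per_cancer_top_fraction = 1 / 3),
                         fdr_cutoffs = c(default = 0.05))$ca
  expect_equal(d$pathway[d$selected], "PA") # tie PA/PB -> PA first
})

test_that("common and specific selection follow the recurrence rules", {
  # 16 cancers x 20 pathways; plant PW01 in 11 cancers, PW02 in 9, PW03 in 2
  set.seed(14)
  cancers <- sprintf("c%02d", 1:16)
  paths <- sprintf("PW%02d", 1:20)
  scores <- matrix(runif(320), 16, 20, dimnames = list(cancers, paths))
  q <- matrix(0.9, 16, 20, dimnames = list(cancers, paths))
  boost <- function(m, pw, k) { m[1:k, pw] <- NA; m }
  scores[1:11, "PW01"] <- 10; q[1:11, "PW01"] <- 0.001
  scores[1:9, "PW02"] <- 9; q[1:9, "PW02"] <- 0.001
  scores[15:16, "PW03"] <- 8; q[15:16, "PW03"] <- 0.001
  mat <- toy_pam(scores, q = q, p = q)
  crit <- selection_criteria(common_top_fraction = 0.10, min_cancer_types = 10)
  common <- select_common(mat, crit, fdr_cutoffs = c(default = 0.05))
  expect_equal(common$pathway, "PW01") # 11 >= 10 in; 9 of 16 out
  expect_equal(common$n_cancers, 11)
  expect_equal(strsplit(common$cancers, ",")[[1]], cancers[1:11])

  # monotone in the threshold: relaxing min_cancer_types only adds pathways
  c1 <- select_common(mat, selection_criteria(min_cancer_types = 1),
                      fdr_cutoffs = c(default = 0.05))
  expect_true(all(common$pathway %in% c1$pathway))
  expect_true(all(c("PW02", "PW03") %in% c1$pathway))

  # specific: qualifying in <= 2 cancers, keyed by those cancers
  spec <- select_specific(mat, crit, fdr_cutoffs = c(default = 0.05),
                          max_cancer_types = 2)
  expect_true("PW03" %in% spec$c15 && "PW03" %in% spec$c16)
  expect_false("PW01" %in% unlist(spec))
  expect_false("PW02" %in% unlist(spec)) # 9 cancers > max 2
})

test_that("add_significance fills p and q per (cancer, collection) family", {
  net <- random_net(60, 0.1, seed = 15)
  gb <- normalized_adjacency(net)
  pc <- pathway_collection(list(P1 = net$nodes[1:6], P2 = net$nodes[7:12],
                                P3 = net$nodes[13:18], P4 = net$nodes[19:24]))
  set.seed(16)
  g_list <- list(ca = av(net, runif(60)), cb = av(net, runif(60)))
  acts <- lapply(g_list, function(g)
    pathway_activity(propagate(gb, g), pc))
  mat <- assemble_matrix(acts, collection_labels = c("x", "x", "y", "y"))
  mat <- add_significance(mat, gb, g_list, pc,
                          permutation_config(99, "membership", rng_seed = 5))
  expect_equal(dim(mat$p_values), dim(mat$scores))
  expect_true(all(mat$p_values > 0 & mat$p_values <= 1))
  # q within each collection family matches bh on that family's p
  expect_equal(unname(mat$q_values["ca", c("P1", "P2")]),
               bh_adjust(unname(mat$p_values["ca", c("P1", "P2")])))
  expect_equal(unname(mat$q_values["cb", c("P3", "P4")]),
               bh_adjust(unname(mat$p_values["cb", c("P3", "P4")])))
})
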