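test_that("seed tables parse, validate and reject malformed input", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\talteration\tavg_log2_ratio\tq_value",
               "MYC\tamp\t1.3\t1e-6"), f)
  tab <- read_seed_table(f, cancer_type = "colorectal")
  expect_s3_class(tab, "seed_table")
  expect_equal(attr(tab, "cancer_type"), "colorectal")
  expect_equal(tab$gene, "MYC")
  expect_equal(tab$alteration, "amp")

  # duplicate (gene, alteration) named in the error
  expect_error(st(c("MYC", "MYC"), c("amp", "amp"), c(1, 2)), "MYC")
  # same gene with amp and del is fine
  expect_silent(st(c("MYC", "MYC"), c("amp", "del"), c(1, -1)))
  # unknown alteration label
  expect_error(st("MYC", "gain", 1), "gain")
  # missing required column
  expect_error(seed_table(data.frame(gene = "A", alteration = "amp")),
               "avg_log2_ratio")
  # q outside [0,1]
  expect_error(st("A", "amp", 1, q = 1.5), "q_value")

  # non-numeric score -> parse error with line number
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\talteration\tavg_log2_ratio", "A\tamp\t0.5",
               "B\tdel\toops"), bad)
  expect_error(read_seed_table(bad), "line 2")

  # arm_level column parses to logical and is preserved
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\talteration\tavg_log2_ratio\tarm_level",
               "A\tamp\t1.0\ttrue", "B\tdel\t-0.5\tfalse"), f2)
  tab2 <- read_seed_table(f2)
  expect_identical(tab2$arm_level, c(TRUE, FALSE))
})

test_that("averages_from_matrix computes patient means and checks coverage", {
  m <- rbind(A = c(0.8, 1.2), B = c(-0.6, -1.0))
  tab <- averages_from_matrix(m, amp_genes = "A", del_genes = "B")
  expect_equal(tab$avg_log2_ratio[tab$gene == "A"], 1.0)
  expect_equal(tab$avg_log2_ratio[tab$gene == "B"], -0.8)

  set.seed(11)
  m2 <- matrix(rnorm(12), 3, 4, dimnames = list(c("X", "Y", "Z"), NULL))
  tab2 <- averages_from_matrix(m2, amp_genes = c("X", "Y"), del_genes = "Z")
  expect_equal(tab2$avg_log2_ratio[match(c("X", "Y", "Z"), tab2$gene)],
               unname(rowMeans(m2))) # independent row-mean oracle
  expect_error(averages_from_matrix(m, amp_genes = "NOPE", del_genes = "B"),
               "NOPE")
})

test_that("filter_arm_level removes flagged records only on request", {
  tab <- st(LETTERS[1:5], rep("amp", 5), 1:5,
            arm_level = c(TRUE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(nrow(filter_arm_level(tab, exclude = TRUE)), 3)
  expect_equal(filter_arm_level(tab, exclude = FALSE), tab)
  all_arm <- st("A", "amp", 1, arm_level = TRUE)
  expect_warning(out <- filter_arm_level(all_arm, exclude = TRUE), "empty")
  expect_equal(nrow(out), 0)
  no_col <- st("A", "amp", 1)
  expect_error(filter_arm_level(no_col, exclude = TRUE), "arm_level")
})

test_that("initial_scores aligns to the network and honors the score mode", {
  net <- path_net() # A-B-C
  tab <- st(c("A", "C"), c("amp", "del"), c(1.3, -0.8))
  g <- initial_scores(tab, net)
  expect_equal(as.numeric(g), c(1.3, 0, 0.8)) # magnitude: del flipped
  expect_equal(attr(g, "stage"), "initial")
  gs <- initial_scores(tab, net, mode = "signed")
  expect_equal(as.numeric(gs), c(1.3, 0, -0.8))
  # non-seed gene scores 0
  expect_equal(unname(g["B"]), 0)
  # seed gene absent from the network: dropped with a warning
  tab2 <- st(c("A", "ZZZ"), c("amp", "amp"), c(1, 2))
  expect_warning(g2 <- initial_scores(tab2, net), "absent")
  expect_equal(attr(g2, "n_dropped"), 1)
  expect_equal(as.numeric(g2), c(1, 0, 0))
})

test_that("amp+del conflicts take the larger magnitude, ties go to amp", {
  net <- path_net()
  both <- st(c("A", "A"), c("amp", "del"), c(0.5, -1.2))
  expect_equal(unname(initial_scores(both, net, "signed")["A"]), -1.2)
  tie <- st(c("A", "A"), c("amp", "del"), c(0.7, -0.7))
  expect_equal(unname(initial_scores(tie, net, "signed")["A"]), 0.7)
})

test_that("initial_scores invariants: homogeneity and support size", {
  net <- random_net(50, 0.1, seed = 2)
  set.seed(5)
  genes <- sample(net$nodes, 12)
  vals <- runif(12, 0.2, 2)
  tab <- st(genes, sample(c("amp", "del"), 12, TRUE),
            vals * sample(c(-1, 1), 12, TRUE))
  g1 <- initial_scores(tab, net)
  expect_equal(sum(g1 != 0), 12) # distinct in-network seed genes
  tab3 <- tab
  tab3$avg_log2_ratio <- 3 * tab3$avg_log2_ratio
  expect_equal(as.numeric(initial_scores(tab3, net)), as.numeric(3 * g1))
  # matrix route and precomputed-average route agree
  m <- matrix(rep(vals, 4), nrow = 12, dimnames = list(genes, NULL))
  tabm <- averages_from_matrix(m, amp_genes = genes, del_genes = character())
  tab_direct <- st(genes, rep("amp", 12), vals)
  expect_equal(initial_scores(tabm, net), initial_scores(tab_direct, net))
})

test_that("annotation coverage counts seed genes found in any pathway", {
  pc <- pathway_collection(list(P1 = c("A", "B"), P2 = c("B", "C")))
  tab <- st(sprintf("X%02d", 1:7), rep("amp", 7), rep(1, 7))
  tab2 <- st(c("A", "B", "C", sprintf("X%02d", 1:7)), rep("amp", 10), rep(1, 10))
  cov <- annotation_coverage(tab2, pc)
  expect_equal(cov$annotated_fraction, 0.3)
  expect_equal(cov$unannotated_fraction, 0.7)
  expect_equal(annotation_coverage(st(c("A", "B"), c("amp", "amp"), c(1, 1)),
                                   pc)$annotated_fraction, 1.0)
  expect_equal(annotation_coverage(tab, pc)$annotated_fraction, 0)
  expect_error(annotation_coverage(st(character(), character(), numeric()), pc),
               "empty")
})
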