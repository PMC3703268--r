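test_that("scenario specs validate and instances are deterministic", {
  expect_error(scenario_spec(pathway_size_range = c(10, 5000), n_genes = 100),
               "size range")
  expect_error(scenario_spec(n_cancers = 4, n_planted_cancers = 5),
               "n_planted_cancers")
  spec <- scenario_spec(n_genes = 150, n_pathways = 12, n_cancers = 3,
                        n_planted_cancers = 2, pathway_size_range = c(5, 10),
                        rng_seed = 5)
  i1 <- generate_instance(spec)
  i2 <- generate_instance(spec)
  expect_identical(i1$network$edges, i2$network$edges)
  expect_identical(lapply(i1$pathways$sets, `[[`, "members"),
                   lapply(i2$pathways$sets, `[[`, "members"))
  expect_identical(lapply(i1$seed_tables, as.data.frame),
                   lapply(i2$seed_tables, as.data.frame))
  expect_equal(length(i1$seed_tables), 3)
  expect_equal(length(i1$pathways), 12)
  expect_s3_class(i1$seed_tables[[1]], "seed_table")
})

test_that("the three network models hit the requested scale", {
  for (model in c("erdos_renyi", "preferential_attachment", "community")) {
    spec <- scenario_spec(n_genes = 400, network_model = model,
                          mean_degree = 10, n_pathways = 5, n_cancers = 1,
                          n_planted_cancers = 1, rng_seed = 2)
    net <- generate_instance(spec)$network
    expect_equal(length(net$nodes), 400)
    expect_gt(mean(net$degrees), 5)
    expect_lt(mean(net$degrees), 15)
  }
})

test_that("scenarios plant what they claim", {
  # null: no truth labels
  null_spec <- scenario_spec(n_genes = 200, n_pathways = 10, n_cancers = 2,
                             scenario = "null", rng_seed = 3,
                             n_planted_cancers = 2)
  expect_length(generate_instance(null_spec)$truth$planted_pathways, 0)

  # direct: altered genes overlap the planted pathway in planted cancers
  d_spec <- scenario_spec(n_genes = 300, n_pathways = 20, n_cancers = 4,
                          n_planted_cancers = 3, scenario = "direct",
                          pathway_size_range = c(6, 6), rng_seed = 7)
  di <- generate_instance(d_spec)
  members <- di$pathways$sets[[di$truth$planted_pathways]]$members
  for (ck in di$truth$planted_cancers) {
    ov <- intersect(di$truth$altered[[ck]], members)
    expect_gte(length(ov), 1)
  }

  # neighbor_only: zero member overlap, but altered direct neighbors exist
  n_spec <- scenario_spec(n_genes = 300, n_pathways = 20, n_cancers = 4,
                          n_planted_cancers = 4, scenario = "neighbor_only",
                          rng_seed = 8)
  ni <- generate_instance(n_spec)
  mem <- ni$pathways$sets[[ni$truth$planted_pathways]]$members
  adj <- ni$network$adjacency
  neighbors <- setdiff(
    ni$network$nodes[unique(unlist(lapply(match(mem, ni$network$nodes),
                                          function(i) which(adj[i, ] != 0))))],
    mem)
  for (ck in names(ni$seed_tables)) {
    alt <- ni$truth$altered[[ck]]
    expect_length(intersect(alt, mem), 0)
    if (ck %in% ni$truth$planted_cancers)
      expect_gt(length(intersect(alt, neighbors)), 0)
  }
})

test_that("alteration magnitudes center on the requested effect size", {
  spec <- scenario_spec(n_genes = 500, n_pathways = 5, n_cancers = 6,
                        n_planted_cancers = 1, effect_size = 1.2,
                        altered_fraction = 0.2, rng_seed = 9)
  inst <- generate_instance(spec)
  mags <- abs(unlist(lapply(inst$seed_tables, function(t) t$avg_log2_ratio)))
  # lognormal(meanlog = log(1.2), sd 0.3): median 1.2
  expect_lt(abs(median(mags) - 1.2), 0.1)
  amps <- unlist(lapply(inst$seed_tables, function(t) t$alteration))
  expect_gt(mean(amps == "amp"), 0.4)
  expect_lt(mean(amps == "amp"), 0.6)
})

test_that("decoys are size-matched, seeded and fail on a small pool", {
  pc <- pathway_collection(list(P1 = sprintf("A%02d", 1:8),
                                P2 = sprintf("B%02d", 1:15)))
  pool <- sprintf("G%03d", 1:100)
  d1 <- generate_decoys(pc, 20, pool, rng_seed = 4)
  d2 <- generate_decoys(pc, 20, pool, rng_seed = 4)
  expect_identical(lapply(d1$sets, `[[`, "members"),
                   lapply(d2$sets, `[[`, "members"))
  sizes <- lengths(lapply(d1$sets, `[[`, "members"))
  expect_true(all(sizes %in% c(8, 15)))
  expect_equal(d1$source_label, "default_decoy")
  expect_true(all(grepl("^DECOY_", names(d1$sets))))
  expect_error(generate_decoys(pc, 5, pool[1:10], rng_seed = 1), "pool")
})

test_that("decoy mean activity approximates the network mean propagated score", {
  spec <- scenario_spec(n_genes = 400, n_pathways = 10, n_cancers = 1,
                        n_planted_cancers = 1, scenario = "direct",
                        rng_seed = 12)
  inst <- generate_instance(spec)
  gbar <- normalized_adjacency(inst$network)
  g <- initial_scores(inst$seed_tables[[1]], inst$network)
  gt <- propagate(gbar, g)
  decoys <- generate_decoys(inst$pathways, 300, inst$network$nodes,
                            rng_seed = 13)
  act <- pathway_activity(gt, decoys, min_members = 1)
  expect_lt(abs(mean(act$score) - mean(gt)), 3 * sd(gt) / sqrt(100))
})

test_that("write_instance emits the formats the pipeline reads", {
  spec <- scenario_spec(n_genes = 120, n_pathways = 6, n_cancers = 2,
                        n_planted_cancers = 1, pathway_size_range = c(4, 8),
                        rng_seed = 6)
  inst <- generate_instance(spec)
  dir <- withr::local_tempdir()
  manifest <- write_instance(inst, dir)
  expect_true(file.exists(manifest))
  net2 <- read_gene_network(file.path(dir, "network.tsv"))
  expect_equal(net2$edges, inst$network$edges)
  pc2 <- read_gmt(file.path(dir, "pathways.gmt"))
  expect_equal(lapply(pc2$sets, `[[`, "members"),
               lapply(inst$pathways$sets, `[[`, "members"))
  m <- yaml::read_yaml(manifest)
  expect_equal(length(m$seed_tables), 2)
  tab <- read_seed_table(file.path(dir, m$seed_tables[[1]]))
  expect_equal(tab$gene, inst$seed_tables[[1]]$gene)
})
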