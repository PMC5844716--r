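test_that("a null, noise-free simulation has identical group means", {
  cfg <- sim_config(n_genes = 50L, de_fraction = 0, noise_sd_log2 = 0,
                    hub_spec = list(), n_random_edges = 0L, seed = 5L)
  sim <- simulate_expression(cfg)
  ctrl <- as.matrix(sim$expr[sprintf("ctrl_%d", 1:3)])
  expp <- as.matrix(sim$expr[sprintf("exp_%d", 1:3)])
  expect_equal(exp(rowMeans(log(expp))), exp(rowMeans(log(ctrl))),
               tolerance = 1e-12)
  expect_equal(nrow(sim$truth$de_genes), 0)
})

test_that("the same seed reproduces the simulation bit-identically", {
  cfg <- sim_config(n_genes = 300L, de_fraction = 0.1, seed = 7L,
                    hub_spec = list(list(gene = NA, n_spokes = 5L,
                                         strength = 0.9)))
  a <- simulate_expression(cfg)
  b <- simulate_expression(cfg)
  expect_identical(a$expr, b$expr)
  expect_identical(a$truth, b$truth)
})

test_that("a planted fold change reproduces a printed intensity pair", {
  # the printed fold (47.26) is itself rounded; planting the exact
  # intensity ratio reproduces both printed geometric means
  fold <- 2650.31 / 56.08
  cfg <- sim_config(n_genes = 1L, de_fraction = 1, up_fraction = 1,
                    fold_change_range = c(fold, fold), noise_sd_log2 = 0,
                    baseline_log2_mean = log2(56.08), baseline_log2_sd = 0,
                    hub_spec = list(), n_random_edges = 0L, seed = 1L)
  sim <- simulate_expression(cfg)
  geo <- function(x) exp(mean(log(x)))
  ctrl <- geo(unlist(sim$expr[1, sprintf("ctrl_%d", 1:3)]))
  expp <- geo(unlist(sim$expr[1, sprintf("exp_%d", 1:3)]))
  expect_equal(ctrl, 56.08, tolerance = 1e-9)
  expect_equal(expp, 2650.31, tolerance = 1e-6)
  expect_equal(round(expp / ctrl, 2), 47.26)
})

test_that("config validation names the offending field", {
  expect_error(sim_config(de_fraction = 1.3), "de_fraction",
               class = "hubgene_config_error")
  expect_error(sim_config(fold_change_range = c(0.5, 3)),
               "fold_change_range", class = "hubgene_config_error")
  expect_error(sim_config(noise_sd_log2 = -1), "noise_sd_log2",
               class = "hubgene_config_error")
  expect_error(sim_config(n_genes = 10L,
                          hub_spec = list(list(gene = NA, n_spokes = 10L,
                                               strength = 0.9))),
               "n_spokes", class = "hubgene_config_error")
})

test_that("hub blocks carry the planted latent correlation", {
  cfg <- sim_config(n_genes = 400L, de_fraction = 0.3,
                    n_samples_per_group = 30L,
                    hub_spec = list(list(gene = NA, n_spokes = 8L,
                                         strength = 0.9)),
                    seed = 23L)
  sim <- simulate_expression(cfg)
  block <- sim$truth$hub_blocks[[1]]
  mat <- log2(as.matrix(sim$expr[match(block, sim$expr$gene_id),
                                 sprintf("ctrl_%d", 1:30)]))
  cm <- cor(t(mat))
  off <- cm[upper.tri(cm)]
  # mean sample correlation near the planted strength at n = 30
  expect_gt(mean(off), 0.8)
})

test_that("annotation generation is deterministic and GMT round-trips", {
  cfg <- sim_config(n_genes = 200L, de_fraction = 0.2, n_terms = 10L,
                    enriched_terms = 2L, hub_spec = list(), seed = 13L)
  sim <- simulate_expression(cfg)
  a <- simulate_annotations(cfg, sim$truth)
  b <- simulate_annotations(cfg, sim$truth)
  expect_identical(a$gene_sets, b$gene_sets)

  f1 <- withr::local_tempfile(fileext = ".gmt")
  f2 <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(a$gene_sets, f1)
  write_gmt(a$gene_sets, f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_gmt(f1, category = "GO")
  expect_equal(dplyr::arrange(back, term_id, gene_id),
               dplyr::arrange(a$gene_sets, term_id, gene_id) |>
                 dplyr::select("term_id", "name", "category", "gene_id"))
})

test_that("interaction edges give the planted hub maximal betweenness", {
  cfg <- sim_config(n_genes = 300L, de_fraction = 0.3,
                    hub_spec = list(list(gene = NA, n_spokes = 16L,
                                         strength = 0.9)),
                    n_random_edges = 40L, seed = 31L)
  sim <- simulate_expression(cfg)
  edges <- simulate_interaction_edges(cfg, sim$truth)
  net <- gene_network(edges, directed = TRUE)
  hub <- sim$truth$hub_genes[1]
  b <- betweenness_stats(net)
  expect_equal(b$node[which.max(b$betweenness)], hub)
  # cross-check the hub's value against the geodesic oracle on this graph
  oracle <- oracle_betweenness(as.data.frame(net$edges), net$nodes$node,
                               directed = TRUE)
  expect_equal(max(b$betweenness), unname(oracle[hub]), tolerance = 1e-12)

  # hub participates in at least n_spokes edges
  expect_gte(sum(edges$from == hub | edges$to == hub), 16)
})

test_that("no hubs and no random edges give an empty edge list", {
  cfg <- sim_config(n_genes = 100L, de_fraction = 0.2, hub_spec = list(),
                    n_random_edges = 0L, seed = 3L)
  sim <- simulate_expression(cfg)
  edges <- simulate_interaction_edges(cfg, sim$truth)
  expect_equal(nrow(edges), 0)
  expect_identical(edges, simulate_interaction_edges(cfg, sim$truth))
})

test_that("Ct tables encode planted folds exactly when noise-free", {
  ct <- simulate_ct_table(c(geneA = 1, geneB = 4, geneC = 0.5),
                          noise_sd = 0, seed = 2L)
  r <- ddct_ratios(ct)
  expect_equal(r$ratio[r$gene == "geneA"], 1)
  expect_equal(r$ratio[r$gene == "geneB"], 4)
  expect_equal(r$ratio[r$gene == "geneC"], 0.5)
})

test_that("noisy Ct replicates recover the planted fold approximately", {
  ct <- simulate_ct_table(c(geneA = 8), n_replicates = 3L, noise_sd = 0.2,
                          seed = 4L)
  r <- ddct_ratio(ct, "geneA")
  expect_lt(abs(log2(r$ratio) - 3), 0.6)  # within ~3 pooled noise SDs
})

test_that("simulated files round-trip through the package readers", {
  cfg <- sim_config(n_genes = 120L, de_fraction = 0.2, n_terms = 8L,
                    enriched_terms = 2L,
                    hub_spec = list(list(gene = NA, n_spokes = 4L,
                                         strength = 0.9)),
                    n_random_edges = 10L, seed = 29L)
  ds <- simulate_dataset(cfg)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)

  expr2 <- read_expression_tsv(file.path(dir, "expression.tsv"))
  expect_equal(as.data.frame(expr2), as.data.frame(ds$expr),
               tolerance = 1e-12)
  expect_equal(read_groups_tsv(file.path(dir, "groups.tsv")), ds$groups)
  edges2 <- read_interaction_tsv(file.path(dir, "interactions.tsv"))
  expect_equal(edges2, ds$interaction_edges)
  ct2 <- read_ct_csv(file.path(dir, "ct.csv"))
  expect_equal(ct2$ct, ds$ct_table$ct, tolerance = 1e-12)
  truth2 <- read_truth_json(file.path(dir, "truth.json"))
  expect_equal(truth2$de_genes$gene_id, ds$truth$de_genes$gene_id)
  expect_equal(truth2$de_genes$fold_change, ds$truth$de_genes$fold_change,
               tolerance = 1e-12)
  expect_equal(unlist(truth2$hub_genes), ds$truth$hub_genes)
})
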