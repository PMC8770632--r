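test_that("two-shell networks place planted genes at distance one", {
  cfg <- small_config(seed = 4)
  sim <- simulate_network(cfg)
  g <- igraph::graph_from_data_frame(
    sim$edges[sim$edges$combined_score >= 905, 1:2], directed = FALSE)
  d <- igraph::distances(g, v = paste0("9606.SYN_", cfg$focal_gene))
  expect_true(all(d[1, paste0("9606.SYN_", sim$planted)] == 1))
  expect_length(sim$planted, cfg$n_planted)

  again <- simulate_network(cfg)
  expect_identical(sim$edges, again$edges)
  expect_identical(sim$aliases, again$aliases)
  expect_error(sim_config(n_shell1 = 3, n_planted = 5), "planted")
})

test_that("preferential attachment grows connected heavy-tailed graphs", {
  for (seed in 1:20) {
    cfg <- sim_config(n_genes = 200, topology = "preferential_attachment",
                      n_planted = 2, seed = seed)
    sim <- simulate_network(cfg)
    g <- igraph::graph_from_data_frame(sim$edges[, 1:2], directed = FALSE)
    expect_true(igraph::is_connected(g))
    deg <- igraph::degree(g)
    expect_gte(max(deg), 3 * stats::median(deg))
  }
})

test_that("expression marginals, graph correlation and missingness behave", {
  # degenerate: no cell-to-cell variation leaves the baseline vector
  cfg0 <- small_config(seed = 6, expr_noise_sd = 0)
  net0 <- simulate_network(cfg0)
  ex0 <- simulate_expression(net0, cfg0)
  expect_equal(max(apply(ex0$expr, 2, stats::sd)), 0)
  expect_true(all(ex0$expr >= 0))

  # adjacent genes correlate more than non-adjacent ones on average
  adj_gap <- vapply(1:3, function(seed) {
    cfg <- sim_config(n_genes = 120, n_cells = 500, n_shell1 = 20,
                      n_planted = 3, n_extra_genes = 10,
                      n_decoy_genes = 20, low_expr_frac = 0, seed = seed)
    net <- simulate_network(cfg)
    ex <- simulate_expression(net, cfg)
    hi <- net$edges$combined_score >= 905
    ga <- sub("^9606\\.SYN_", "", net$edges$protein1[hi])
    gb <- sub("^9606\\.SYN_", "", net$edges$protein2[hi])
    adj <- mean(vapply(seq_along(ga), function(i) {
      stats::cor(ex$expr[, ga[i]], ex$expr[, gb[i]])
    }, numeric(1)))
    set.seed(seed)
    genes <- net$genes
    ra <- sample(genes, 300, TRUE); rb <- sample(genes, 300, TRUE)
    key <- paste(pmin(ra, rb), pmax(ra, rb))
    non <- !(key %in% paste(pmin(ga, gb), pmax(ga, gb))) & ra != rb
    nonadj <- mean(vapply(which(non), function(i) {
      stats::cor(ex$expr[, ra[i]], ex$expr[, rb[i]])
    }, numeric(1)))
    adj - nonadj
  }, numeric(1))
  expect_true(all(adj_gap > 0.05))

  # missing-value injection hits about the requested fraction
  cfgm <- sim_config(n_genes = 400, n_cells = 500, n_shell1 = 40,
                     missing_frac = 0.01, seed = 2)
  netm <- simulate_network(cfgm)
  exm <- simulate_expression(netm, cfgm)
  frac <- mean(is.na(exm$expr))
  expect_gt(frac, 0.005)
  expect_lt(frac, 0.015)
})

test_that("dependency construction encodes the planted signal and sign", {
  cfg <- small_config(seed = 7, n_planted = 1, effect_weights = -1,
                      target_r2 = 1, mutation_effect = 0)
  net <- simulate_network(cfg)
  ex <- simulate_expression(net, cfg)
  dep <- simulate_dependency(ex$expr, net, cfg)
  y <- dep$gene_effect[, cfg$focal_gene]
  rho <- stats::cor(y, ex$expr[, net$planted], method = "spearman")
  expect_equal(abs(rho), 1)
  expect_equal(sign(rho), -1)  # higher expression -> more dependent
  expect_true(all(dep$dependency_prob >= 0 & dep$dependency_prob <= 1))
  # dependent tail: most-negative gene effects cross the 0.5 probability
  expect_true(all(dep$dependency_prob[y < mean(y), cfg$focal_gene] > 0.5))
  expect_equal(ncol(dep$gene_effect), 1L + length(dep$truth$marker_genes))
})

test_that("noise calibration yields the designed model recovery range", {
  cfg <- sim_config(n_genes = 60, n_cells = 200, n_shell1 = 10,
                    n_planted = 5, n_extra_genes = 45, n_decoy_genes = 10,
                    low_expr_frac = 0, mutation_effect = 0, seed = 8)
  b <- simulate_bundle(cfg)
  gt <- b$ground_truth
  noise_genes <- grep("^EXT", colnames(b$expression), value = TRUE)
  X <- as.matrix(b$expression[, c(gt$planted_genes, noise_genes)])
  y <- b$gene_effect[, cfg$focal_gene]
  ens <- run_ensemble(X, y, model_spec("lasso", nfolds = 5),
                      n_models = 50, seed = 9, keep_models = FALSE)
  # theoretical r at R^2 = 0.5 is sqrt(0.5) ~ 0.71, with sampling slack
  expect_gte(ens$r, 0.55)
  expect_lte(ens$r, 0.85)
})

test_that("mutation and copy-number generators honor their contracts", {
  cfg <- small_config(seed = 10)
  net <- simulate_network(cfg)
  cells <- sprintf("CL%04d", 1:60)

  none <- simulate_mutations_and_cn(
    net, small_config(seed = 10, mutation_rate = 0), cells)
  status <- classify_mutation_status(none$mutations, "KRAS", cells)
  expect_true(all(status == "wt"))

  mc <- simulate_mutations_and_cn(net, cfg, cells)
  rel <- vapply(cells, function(cl) {
    relative_copy_number(mc$cn[cl, ], "KRAS")
  }, numeric(1))
  expect_setequal(names(which(classify_amplified(rel))),
                  mc$amplified_lines)

  # deleterious-only decoys: wild-type yet (1,0,0)-encoded
  del_only <- setdiff(mc$mutations$cell_line[mc$mutations$is_deleterious],
                      mc$mutant_lines)
  expect_gt(length(del_only), 0L)
  status <- classify_mutation_status(mc$mutations, "KRAS", cells)
  enc <- encode_mutation_predictors(mc$mutations, "KRAS", cells)
  expect_true(all(status[del_only] == "wt"))
  expect_true(all(enc[del_only, "deleterious"] == 1L))
  expect_true(all(enc[mc$mutant_lines, "hotspot"] +
                    enc[mc$mutant_lines, "other"] >= 1L))
})

test_that("bundles round-trip through disk in the loader dialects", {
  cfg <- sim_config(n_genes = 50, n_cells = 50, n_shell1 = 8,
                    n_planted = 3, n_markers = 4, n_extra_genes = 10,
                    n_decoy_genes = 10, n_amplified = 4, seed = 12)
  b <- simulate_bundle(cfg)
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  expect_silent(l <- load_bundle(dir))
  expect_lt(max(abs(l$expression - b$expression)), 1e-9)
  expect_lt(max(abs(l$gene_effect - b$gene_effect)), 1e-9)
  expect_lt(max(abs(l$dependency_prob - b$dependency_prob)), 1e-9)
  expect_lt(max(abs(l$copy_number - b$copy_number)), 1e-9)
  expect_equal(l$mutations$cell_line, b$mutations$cell_line)
  expect_identical(sort(l$ground_truth$planted_genes),
                   sort(b$ground_truth$planted_genes))
  expect_identical(attr(l$edges, "score_scale"), "0-1000")
})
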