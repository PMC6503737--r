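test_that("generation is deterministic and honors the null scenario", {
  cfg <- synthetic_config(K = 5, G = 100, n_case = 5, n_control = 5,
                          pi_de = 0, seed = 1)
  a <- generate_collection(cfg)
  b <- generate_collection(cfg)
  expect_identical(a$collection$studies[[1]]$expr,
                   b$collection$studies[[1]]$expr)
  expect_identical(a$truth$genes, b$truth$genes)
  expect_equal(sum(a$truth$genes$is_de), 0)
  expect_true(all(a$truth$delta == 0))
  # different seed gives different data
  c2 <- generate_collection(synthetic_config(K = 5, G = 100, n_case = 5,
                                             n_control = 5, pi_de = 0,
                                             seed = 2))
  expect_false(identical(a$collection$studies[[1]]$expr,
                         c2$collection$studies[[1]]$expr))
})

test_that("HS_r plants the configured number of DE genes and carriers", {
  cfg <- synthetic_config(K = 5, G = 1000, n_case = 5, n_control = 5,
                          pi_de = 0.1, scenario = "HS_r", r_frac = 0.7,
                          seed = 3)
  sim <- generate_collection(cfg)
  de <- sim$truth$genes$is_de
  expect_equal(sum(de), 100)
  carriers <- rowSums(sim$truth$delta != 0)
  expect_true(all(carriers[de] == ceiling(0.7 * 5)))
  expect_true(all(carriers[!de] == 0))
  # HS_A: every DE gene carried in all studies
  sim_a <- generate_collection(synthetic_config(K = 4, G = 200, pi_de = 0.1,
                                                scenario = "HS_A", seed = 4,
                                                n_case = 5, n_control = 5))
  expect_true(all(rowSums(sim_a$truth$delta != 0)[sim_a$truth$genes$is_de] == 4))
  # HS_B: between 1 and K carriers
  sim_b <- generate_collection(synthetic_config(K = 4, G = 200, pi_de = 0.2,
                                                scenario = "HS_B", seed = 5,
                                                n_case = 5, n_control = 5))
  cb <- rowSums(sim_b$truth$delta != 0)[sim_b$truth$genes$is_de]
  expect_true(all(cb >= 1 & cb <= 4))
})

test_that("planted effects respect the effect model (mean mu when tau2 = 0)", {
  cfg <- synthetic_config(K = 3, G = 4000, n_case = 20, n_control = 20,
                          pi_de = 0.5, scenario = "HS_A", mu = 1, tau2 = 0,
                          sigma = 1, seed = 6)
  sim <- generate_collection(cfg)
  de <- sim$truth$genes$is_de
  # direction-aligned standardized case-control difference over DE genes
  aligned <- sapply(sim$collection$studies, function(s) {
    d <- rowMeans(s$expr[, s$group == "case"]) -
      rowMeans(s$expr[, s$group == "control"])
    mean(d[de] * sim$truth$genes$direction[de])
  })
  # per-study SE of the mean over 2000 DE genes: sqrt(2/40) / sqrt(2000)
  se <- sqrt(2 / 40) / sqrt(sum(de))
  expect_true(all(abs(aligned - 1) < 3 * se + 0.01))
})

test_that("null per-study t-test p-values are uniform", {
  sim <- generate_collection(synthetic_config(K = 1, G = 2000, n_case = 10,
                                              n_control = 10, pi_de = 0,
                                              seed = 7))
  s <- sim$collection$studies[[1]]
  p <- apply(s$expr, 1, function(x) {
    t.test(x[s$group == "case"], x[s$group == "control"],
           var.equal = TRUE)$p.value
  })
  expect_gt(ks.test(p, "punif")$p.value, 0.01)
})

test_that("planted outlier samples lose inter-sample correlation", {
  sim <- generate_collection(synthetic_config(K = 2, G = 300, n_case = 8,
                                              n_control = 8, pi_de = 0,
                                              seed = 8))
  # n = 0 leaves the collection unchanged
  un <- plant_outlier_samples(sim$collection, sim$truth, 0, seed = 1)
  expect_identical(un$collection$studies[[1]]$expr,
                   sim$collection$studies[[1]]$expr)

  out <- plant_outlier_samples(sim$collection, sim$truth, 1, seed = 2)
  flagged <- out$truth$samples[out$truth$samples$is_outlier, ]
  expect_equal(nrow(flagged), 1)
  rep <- compute_iac(out$collection$studies[[flagged$study_id]])
  expect_equal(names(which.min(rep$mean_iac)), flagged$sample)

  # different seeds pick different samples
  out2 <- plant_outlier_samples(sim$collection, sim$truth, 1, seed = 3)
  flagged2 <- out2$truth$samples[out2$truth$samples$is_outlier, ]
  expect_false(identical(flagged$sample, flagged2$sample))

  expect_error(plant_outlier_samples(sim$collection, sim$truth, 16, seed = 1),
               "smaller")
})

test_that("corrupted studies lose co-expression and DE signal", {
  sim <- generate_collection(synthetic_config(K = 3, G = 500, n_case = 10,
                                              n_control = 10, pi_de = 0.2,
                                              scenario = "HS_A", mu = 1.5,
                                              seed = 9))
  un <- plant_corrupted_study(sim$collection, sim$truth, 0, seed = 1)
  expect_identical(un$collection$studies[[2]]$expr,
                   sim$collection$studies[[2]]$expr)

  out <- plant_corrupted_study(sim$collection, sim$truth, 1, seed = 4)
  bad <- out$truth$studies$study_id[out$truth$studies$is_corrupted]
  expect_length(bad, 1)

  mean_abs_cor <- function(s) {
    v <- apply(s$expr, 1, var)
    top <- order(-v)[1:50]
    C <- cor(t(s$expr[top, ]))
    mean(abs(C[upper.tri(C)]))
  }
  vals <- sapply(out$collection$studies, mean_abs_cor)
  # the corrupted study's top-variance genes decorrelate relative to clean
  # studies that carry shared DE structure
  expect_lt(vals[bad], min(vals[setdiff(names(vals), bad)]))

  # case-vs-control t statistics in the corrupted study are null-distributed
  s <- out$collection$studies[[bad]]
  tt <- apply(s$expr, 1, function(x) {
    t.test(x[s$group == "case"], x[s$group == "control"],
           var.equal = TRUE)$statistic
  })
  expect_gt(ks.test(tt, pt, df = ncol(s$expr) - 2)$p.value, 0.01)

  expect_error(plant_corrupted_study(sim$collection, sim$truth, 3, seed = 1),
               "smaller")
})

test_that("generated gene sets carry planted enrichment", {
  sim <- generate_collection(synthetic_config(K = 2, G = 1000, pi_de = 0.1,
                                              n_case = 5, n_control = 5,
                                              seed = 10))
  gs0 <- generate_gene_sets(sim$truth, n_sets = 20, n_enriched = 0, seed = 1)
  expect_false(any(gs0$truth$gene_sets$is_enriched))

  gs <- generate_gene_sets(sim$truth, n_sets = 30, set_size_range = c(20, 20),
                           n_enriched = 4, enrich_frac = 1, seed = 2)
  de_genes <- sim$truth$genes$gene[sim$truth$genes$is_de]
  for (nm in gs$truth$gene_sets$set[gs$truth$gene_sets$is_enriched])
    expect_true(all(gs$sets[[nm]] %in% de_genes))

  # hypergeometric evidence: enriched set beats the median random set
  gs2 <- generate_gene_sets(sim$truth, n_sets = 30,
                            set_size_range = c(20, 20), n_enriched = 5,
                            enrich_frac = 0.8, seed = 3)
  res <- ora_test(de_genes, sim$truth$genes$gene, gs2$sets)
  enr <- gs2$truth$gene_sets$is_enriched
  expect_lt(max(res$p[enr]), median(res$p[!enr]))

  expect_error(generate_gene_sets(sim$truth, n_sets = 2,
                                  set_size_range = c(200, 200),
                                  n_enriched = 1, enrich_frac = 1, seed = 1),
               "exceeds")
})

test_that("generated compound libraries plant reversal structure", {
  universe <- sprintf("G%05d", 1:800)
  up <- universe[1:100]; down <- universe[101:200]
  truth <- list(genes = data.frame(gene = universe))
  cl0 <- generate_compound_library(up, down, universe, n_reversal = 0,
                                   truth = truth, seed = 1)
  expect_false(any(cl0$truth$compounds$is_reversal))

  cl <- generate_compound_library(up, down, universe, n_compounds = 6,
                                  n_reversal = 2, overlap_frac = 1,
                                  set_size = 40, truth = truth, seed = 2)
  rev_cmpds <- cl$truth$compounds$compound[cl$truth$compounds$is_reversal]
  inst <- cl$library$instances
  for (id in inst$instance[inst$compound %in% rev_cmpds]) {
    expect_true(all(cl$library$up[[id]] %in% down))
    expect_true(all(cl$library$down[[id]] %in% up))
  }
  expect_error(generate_compound_library(up, down, universe,
                                         overlap_frac = 1.5),
               "overlap_frac")
  expect_error(generate_compound_library(character(0), down, universe),
               "non-empty")
})
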