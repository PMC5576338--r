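test_that("simulation is deterministic under a fixed seed", {
  cfg <- simulation_config(n_genes = 80, seed = 81)
  a <- simulate_expression(cfg)
  b <- simulate_expression(cfg)
  expect_identical(a$expr, b$expr)
  expect_identical(a$truth, b$truth)

  sets_a <- simulate_pathways(a$truth, cfg)
  sets_b <- simulate_pathways(b$truth, cfg)
  expect_identical(sets_a$genes, sets_b$genes)

  genes <- a$truth$gene[1:5]
  expect_identical(simulate_ct(a$expr, genes, cfg),
                   simulate_ct(a$expr, genes, cfg))

  # GMT output is byte-identical too
  p1 <- withr::local_tempfile(fileext = ".gmt")
  p2 <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets_a, p1); write_gmt(sets_b, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("zero effect fractions give an all-null truth", {
  cfg <- simulation_config(n_genes = 50, f_genotype = 0, f_oxygen = 0,
                           f_interaction = 0, seed = 82)
  sim <- simulate_expression(cfg)
  expect_true(all(sim$truth$class == "null"))
})

test_that("invalid configs fail with all violated fields listed", {
  err <- tryCatch(simulation_config(noise_sd = -1, replicates_per_group = 1,
                                    f_oxygen = 2),
                  error = function(e) conditionMessage(e))
  expect_match(err, "noise_sd")
  expect_match(err, "replicates_per_group")
  expect_match(err, "fractions")
  expect_error(simulation_config(pathway_size = 100, n_genes = 50),
               "pathway_size")
})

test_that("planted oxygen effects have the configured mean log2 difference", {
  cfg <- simulation_config(n_genes = 2000, beta_oxygen = 4, noise_sd = 0.5,
                           f_oxygen = 0.1, f_genotype = 0, f_interaction = 0,
                           seed = 83)
  sim <- simulate_expression(cfg)
  m <- expr_matrix(sim$expr)
  grp <- sim$design$group
  oxy <- toupper(sim$truth$gene[sim$truth$class == "oxygen"])
  diffs <- rowMeans(m[oxy, grp %in% c("WT_HO", "KO_HO")]) -
    rowMeans(m[oxy, grp %in% c("WT_RA", "KO_RA")])
  # per-gene diff has sd sigma*sqrt(1/6+1/6); 3 standard errors of the mean
  se <- 0.5 * sqrt(1 / 3) / sqrt(length(oxy))
  expect_lt(abs(mean(diffs) - 4), 3 * se)
})

test_that("pure planted pathways draw only from their class", {
  cfg <- simulation_config(n_genes = 200, f_oxygen = 0.5, f_genotype = 0,
                           f_interaction = 0, n_pathways = 10,
                           pathway_size = 15, enrichment_purity = 1,
                           planted_fraction = 1, seed = 84)
  sim <- simulate_expression(cfg)
  sets <- simulate_pathways(sim$truth, cfg)
  oxy <- sim$truth$gene[sim$truth$class == "oxygen"]
  for (i in seq_len(nrow(sets))) {
    expect_true(all(sets$genes[[i]] %in% toupper(oxy)))
  }
})

test_that("zero purity makes planted and null pathways indistinguishable", {
  overlaps <- purrr::map_dfr(1:50, function(seed) {
    cfg <- simulation_config(n_genes = 150, f_oxygen = 0.3, f_genotype = 0,
                             f_interaction = 0, n_pathways = 8,
                             pathway_size = 12, enrichment_purity = 0,
                             planted_fraction = 0.5, seed = seed)
    sim <- simulate_expression(cfg)
    sets <- simulate_pathways(sim$truth, cfg)
    oxy <- toupper(sim$truth$gene[sim$truth$class == "oxygen"])
    tibble::tibble(
      planted = sets$planted_class != "null",
      overlap = vapply(sets$genes, function(g) sum(g %in% oxy), integer(1))
    )
  })
  p <- wilcox.test(overlap ~ planted, data = overlaps, exact = FALSE)$p.value
  expect_gt(p, 0.01)
})

test_that("noisy Ct recovers the planted fold change on average", {
  cfg0 <- simulation_config(n_genes = 20, pathway_size = 10, f_oxygen = 0.5,
                            f_genotype = 0, f_interaction = 0, beta_oxygen = 1,
                            noise_sd = 1e-9, ct_sd = 0.2, seed = 85)
  sim <- simulate_expression(cfg0)
  genes <- sim$truth$gene[sim$truth$class == "oxygen"][1:3]
  fcs <- vapply(1:200, function(r) {
    cfg <- simulation_config(n_genes = 20, pathway_size = 10, f_oxygen = 0.5,
                             f_genotype = 0, f_interaction = 0, beta_oxygen = 1,
                             noise_sd = 1e-9, ct_sd = 0.2, seed = 85 + r)
    ct <- simulate_ct(sim$expr, genes, cfg)
    rel <- ddct_fold_change(ct, sim$design)
    mean(rel$fold_change[rel$group == "WT_HO"])
  }, numeric(1))
  expect_lt(abs(mean(fcs) - 2) / 2, 0.05)
})

test_that("configs round-trip through YAML and JSON", {
  cfg <- simulation_config(n_genes = 33, seed = 86, beta_oxygen = 1.5)
  yml <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg[names(cfg)], yml)
  back <- read_simulation_config(yml)
  expect_equal(back$n_genes, 33)
  expect_equal(back$beta_oxygen, 1.5)

  js <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(cfg[names(cfg)], js, auto_unbox = TRUE, digits = NA)
  expect_equal(read_simulation_config(js)$beta_oxygen, 1.5)
})
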