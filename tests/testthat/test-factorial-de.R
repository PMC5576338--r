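test_that("balanced ANOVA matches the least-squares oracle on the worked example", {
  design <- balanced_design(3)
  y <- c(1, 2, 3, 5, 6, 7, 1, 2, 3, 1, 2, 3)  # WT_RA, WT_HO, KO_RA, KO_HO
  fit <- anova_two_way(y, design)
  oracle <- anova_lm_oracle(y, design$genotype, design$oxygen)
  expect_equal(fit$ss[1:3],
               unname(oracle$ss[c("genotype", "oxygen", "interaction")]),
               tolerance = 1e-9)
  expect_equal(fit$statistic[1:3],
               unname(oracle$f[c("genotype", "oxygen", "interaction")]),
               tolerance = 1e-9)
  # the oxygen response exists only in WT: a large interaction
  expect_gt(fit$statistic[fit$term == "interaction"], 10)

  # swapping the two factor labels jointly swaps the main effects only
  design_swapped <- as_sample_design(tibble::tibble(
    sample = design$sample,
    genotype = ifelse(design$oxygen == "HO", "KO", "WT"),
    oxygen = ifelse(design$genotype == "KO", "HO", "RA")
  ))
  fit_swapped <- anova_two_way(y, design_swapped)
  expect_equal(fit_swapped$ss[c(2, 1, 3)], fit$ss[1:3], tolerance = 1e-9)
  expect_equal(fit_swapped$statistic[3], fit$statistic[3], tolerance = 1e-9)
})

test_that("sums of squares decompose exactly and degenerate data are flagged", {
  design <- balanced_design(3)
  set.seed(31)
  for (i in 1:20) {
    y <- rnorm(12)
    fit <- anova_two_way(y, design)
    expect_equal(sum(fit$ss), sum((y - mean(y))^2), tolerance = 1e-9)
  }
  flat <- anova_two_way(rep(4.2, 12), design)
  expect_equal(flat$ss, rep(0, 4))
  expect_true(attr(flat, "degenerate"))
})

test_that("F statistics are invariant to affine transforms of the data", {
  design <- balanced_design(3)
  set.seed(32)
  y <- rnorm(12, 5)
  f0 <- anova_two_way(y, design)$statistic[1:3]
  expect_equal(anova_two_way(y + 100, design)$statistic[1:3], f0,
               tolerance = 1e-9)
  expect_equal(anova_two_way(y * 3.5, design)$statistic[1:3], f0,
               tolerance = 1e-9)
})

test_that("unbalanced designs reproduce Type-II least-squares sums of squares", {
  skip_if_not_installed("car")
  set.seed(33)
  design <- as_sample_design(tibble::tibble(
    sample = paste0("s", 1:14),
    genotype = rep(c("WT", "KO"), c(8, 6)),
    oxygen = c(rep(c("RA", "HO"), c(3, 5)), rep(c("RA", "HO"), c(4, 2)))
  ))
  for (i in 1:10) {
    y <- rnorm(14)
    fit <- anova_two_way(y, design)
    g <- factor(design$genotype, c("WT", "KO"))
    o <- factor(design$oxygen, c("RA", "HO"))
    ref <- car::Anova(stats::lm(y ~ g * o), type = 2)
    expect_equal(fit$ss[1:3], ref[c("g", "o", "g:o"), "Sum Sq"],
                 tolerance = 1e-9)
  }
})

test_that("LSD contrasts match the textbook formula and closed forms", {
  cc <- lsd_contrast(5, 3, 3, 3, 1.5, 8)
  t_ref <- 2 / sqrt(1.5 * (1 / 3 + 1 / 3))
  expect_equal(cc$statistic, t_ref, tolerance = 1e-9)
  expect_equal(cc$p.value, 2 * pt(t_ref, 8, lower.tail = FALSE),
               tolerance = 1e-9)
  expect_equal(cc$fold_change, 4)

  expect_equal(lsd_contrast(7, 6, 3, 3, 2, 8)$delta, 1)
  expect_equal(lsd_contrast(7, 6, 3, 3, 2, 8)$fold_change, 2)
  same <- lsd_contrast(4, 4, 3, 3, 2, 8)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  expect_equal(same$fold_change, 1)

  degen <- lsd_contrast(4, 3, 3, 3, 0, 8)
  expect_true(is.infinite(degen$statistic) && degen$p.value == 0 &&
                degen$degenerate)
  expect_equal(lsd_contrast(4, 4, 3, 3, 0, 8)$p.value, 1)
})

test_that("BH adjustment reproduces hand-computed and brute-force values", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.5), 0.5)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(34)
  for (i in 1:200) {
    p <- runif(sample(1:6, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_brute(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
    expect_true(all(diff(q[order(p)]) >= -1e-15))  # monotone in p
  }
})

test_that("the gene-wise pipeline is order-invariant with coherent flags and fold changes", {
  cfg <- simulation_config(n_genes = 120, seed = 35)
  sim <- simulate_expression(cfg)
  de <- run_factorial_de(sim$expr, sim$design)

  res <- de$results
  for (e in c("genotype", "oxygen", "interaction")) {
    expect_true(all(res[[paste0("q_", e)]] >= res[[paste0("p_", e)]] - 1e-15,
                    na.rm = TRUE))
    expect_equal(de$flags[[e]],
                 !is.na(res[[paste0("q_", e)]]) &
                   res[[paste0("q_", e)]] < 0.05)
  }
  # reciprocal fold changes multiply to one
  expect_equal(res$fc_WT_HO_vs_WT_RA * 2^(-res$delta_WT_HO_vs_WT_RA),
               rep(1, nrow(res)), tolerance = 1e-12)

  perm <- sample(ncol(sim$expr) - 1) + 1
  expr_perm <- sim$expr[, c(1, perm)]
  attr(expr_perm, "scale_tag") <- "log2"
  de_perm <- run_factorial_de(expr_perm, sim$design)
  expect_equal(de_perm$results, de$results, tolerance = 1e-12)

  gperm <- sample(nrow(sim$expr))
  expr_gperm <- sim$expr[gperm, ]
  attr(expr_gperm, "scale_tag") <- "log2"
  de_gperm <- run_factorial_de(expr_gperm, sim$design)
  expect_equal(de_gperm$results, de$results, tolerance = 1e-12)
})

test_that("a strong planted oxygen effect is recovered almost completely", {
  cfg <- simulation_config(n_genes = 600, f_genotype = 0, f_interaction = 0,
                           f_oxygen = 0.2, beta_oxygen = 3, noise_sd = 0.5,
                           seed = 36)
  sim <- simulate_expression(cfg)
  de <- run_factorial_de(sim$expr, sim$design)
  oxy_genes <- sim$truth$gene[sim$truth$class == "oxygen"]
  called <- de$flags$gene[de$flags$oxygen]
  expect_gte(mean(oxy_genes %in% called), 0.95)
})

test_that("zero-variance genes are excluded from the BH family", {
  design <- balanced_design(3)
  set.seed(37)
  m <- rbind(matrix(rnorm(5 * 12), 5), rep(1, 12))
  de <- run_factorial_de(expr_from_matrix(m, design), design)
  expect_true(de$results$degenerate[de$results$gene == "G0006"])
  expect_true(is.na(de$results$q_oxygen[de$results$gene == "G0006"]))
  live <- de$results[!de$results$degenerate, ]
  expect_equal(live$q_oxygen, bh_brute(live$p_oxygen), tolerance = 1e-12)
})

test_that("tidy and glance expose the fit as tibbles", {
  cfg <- simulation_config(n_genes = 50, seed = 38)
  sim <- simulate_expression(cfg)
  de <- run_factorial_de(sim$expr, sim$design)
  expect_identical(tidy(de), de$results)
  g <- glance(de)
  expect_equal(g$n_genes, 50L)
  expect_s3_class(autoplot(de), "ggplot")
})
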