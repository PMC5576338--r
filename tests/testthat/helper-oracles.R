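# Independent brute-force oracles, kept deliberately naive and separate from
# the package implementations they check.

# BH step-up by definition: q_(i) = min_{j >= i} p_(j) * m / j, capped at 1
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  sp <- p[o]
  q_sorted <- vapply(seq_len(m), function(i) {
    min(1, min(sp[i:m] * m / (i:m)))
  }, numeric(1))
  out <- numeric(m)
  out[o] <- q_sorted
  out
}

# upper-tail hypergeometric by direct enumeration over overlap counts
hyper_tail_brute <- function(N, K, n, k) {
  j <- max(0, k):min(K, n)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# per-response two-way ANOVA through R's least-squares machinery
anova_lm_oracle <- function(values, genotype, oxygen) {
  g <- factor(genotype, levels = c("WT", "KO"))
  o <- factor(oxygen, levels = c("RA", "HO"))
  a <- stats::anova(stats::lm(values ~ g * o))
  list(
    ss = c(genotype = a["g", "Sum Sq"], oxygen = a["o", "Sum Sq"],
           interaction = a["g:o", "Sum Sq"], error = a["Residuals", "Sum Sq"]),
    f = c(genotype = a["g", "F value"], oxygen = a["o", "F value"],
          interaction = a["g:o", "F value"])
  )
}

# balanced 2x2 design with n replicates per cell
balanced_design <- function(n = 3) {
  as_sample_design(tibble::tibble(
    sample = paste0("s", seq_len(4 * n)),
    genotype = rep(c("WT", "WT", "KO", "KO"), each = n),
    oxygen = rep(c("RA", "HO", "RA", "HO"), each = n)
  ))
}

# random gene-set tibble over a small universe
random_sets <- function(n_sets, universe, min_size = 3, max_size = 8) {
  tibble::tibble(
    set_id = sprintf("S%02d", seq_len(n_sets)),
    description = "random",
    genes = lapply(seq_len(n_sets), function(i) {
      sample(universe, sample(min_size:max_size, 1))
    })
  )
}

expr_from_matrix <- function(m, design, scale_tag = "log2") {
  colnames(m) <- design$sample
  rownames(m) <- sprintf("G%04d", seq_len(nrow(m)))
  expr_tibble(m, scale_tag = scale_tag)
}
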