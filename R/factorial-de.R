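#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up control of the false discovery rate: sort p ascending,
#' take running minima of p(j) * m / j from the largest rank down, cap at 1,
#' and map back to input order. Delegates to [stats::p.adjust()] after
#' validating the input.
#'
#' @param p Numeric vector of p-values in \[0, 1\]. `NA`s are preserved and do
#'   not count toward the family size.
#' @return q-values in input order.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop("p must be numeric", call. = FALSE)
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

# Vectorised two-way ANOVA over a genes x samples matrix.
# Balanced designs use the closed-form factorial (moment) decomposition;
# unbalanced designs fall back to Type-II least-squares sums of squares
# computed through projection matrices shared across genes.
anova_matrix <- function(m, design) {
  grp <- factor(design$group, levels = group_levels())
  n_cell <- as.integer(table(grp))
  if (any(n_cell < 2L)) stop("each group needs >=2 replicates", call. = FALSE)
  if (any(!is.finite(m))) stop("expression values must be finite", call. = FALSE)
  N <- ncol(m)
  df_e <- N - 4L

  geno <- factor(design$genotype, levels = c("WT", "KO"))
  oxy <- factor(design$oxygen, levels = c("RA", "HO"))
  grand <- rowMeans(m)
  ss_total <- rowSums((m - grand)^2)

  if (length(unique(n_cell)) == 1L) {
    n <- n_cell[[1L]]
    cell_mean <- vapply(levels(grp), function(g) {
      rowMeans(m[, grp == g, drop = FALSE])
    }, numeric(nrow(m)))
    cell_mean <- matrix(cell_mean, nrow = nrow(m),
                        dimnames = list(rownames(m), levels(grp)))
    mean_wt <- (cell_mean[, "WT_RA"] + cell_mean[, "WT_HO"]) / 2
    mean_ko <- (cell_mean[, "KO_RA"] + cell_mean[, "KO_HO"]) / 2
    mean_ra <- (cell_mean[, "WT_RA"] + cell_mean[, "KO_RA"]) / 2
    mean_ho <- (cell_mean[, "WT_HO"] + cell_mean[, "KO_HO"]) / 2
    ss_g <- 2 * n * ((mean_wt - grand)^2 + (mean_ko - grand)^2)
    ss_o <- 2 * n * ((mean_ra - grand)^2 + (mean_ho - grand)^2)
    # interaction: cell deviation from the additive fit
    a_eff <- cbind(mean_wt, mean_wt, mean_ko, mean_ko)
    b_eff <- cbind(mean_ra, mean_ho, mean_ra, mean_ho)
    ss_i <- n * rowSums((cell_mean - a_eff - b_eff + grand)^2)
    ss_e <- pmax(ss_total - ss_g - ss_o - ss_i, 0)
  } else {
    rss <- function(formula_terms) {
      X <- stats::model.matrix(formula_terms, data.frame(geno = geno, oxy = oxy))
      Q <- diag(N) - X %*% solve(crossprod(X), t(X))
      rowSums((m %*% Q) * m)
    }
    rss_b <- rss(~oxy)
    rss_a <- rss(~geno)
    rss_ab <- rss(~geno + oxy)
    rss_full <- rss(~geno * oxy)
    ss_g <- rss_b - rss_ab
    ss_o <- rss_a - rss_ab
    ss_i <- rss_ab - rss_full
    ss_e <- rss_full
  }

  ms_e <- ss_e / df_e
  f_of <- function(ss) {
    f <- ss / ms_e
    f[ms_e == 0 & ss > 0] <- Inf
    f[ms_e == 0 & ss == 0] <- NaN
    f
  }
  f_g <- f_of(ss_g); f_o <- f_of(ss_o); f_i <- f_of(ss_i)
  p_of <- function(f) {
    p <- stats::pf(f, 1, df_e, lower.tail = FALSE)
    p[is.infinite(f)] <- 0
    p
  }
  list(
    ss = cbind(genotype = ss_g, oxygen = ss_o, interaction = ss_i, error = ss_e),
    f = cbind(genotype = f_g, oxygen = f_o, interaction = f_i),
    p = cbind(genotype = p_of(f_g), oxygen = p_of(f_o), interaction = p_of(f_i)),
    ms_e = ms_e, df_e = df_e, ss_total = ss_total,
    degenerate = ms_e == 0
  )
}

#' Two-way ANOVA for a single response vector
#'
#' Gene-wise F tests for the genotype and oxygen main effects and their
#' interaction. Balanced 2x2 designs use the exact factorial decomposition
#' (the moment estimator, which coincides with least squares when cells are
#' balanced); unbalanced designs use Type-II least-squares sums of squares.
#'
#' @param values Numeric response, one value per sample.
#' @param design Sample design tibble (see [as_sample_design()]); rows must
#'   align with `values`.
#' @return A tibble with one row per term (`genotype`, `oxygen`,
#'   `interaction`, `residual`): sum of squares, df, mean square, F and p.
#'   The attribute `"degenerate"` flags zero residual variance.
#' @export
anova_two_way <- function(values, design) {
  design <- as_sample_design(design)
  stopifnot(length(values) == nrow(design))
  m <- matrix(as.numeric(values), nrow = 1L)
  fit <- anova_matrix(m, design)
  effects <- c("genotype", "oxygen", "interaction")
  ss <- unname(c(fit$ss[1L, effects], fit$ss[1L, "error"]))
  df <- c(1L, 1L, 1L, fit$df_e)
  out <- tibble::tibble(
    term = c(effects, "residual"),
    ss = ss,
    df = df,
    ms = ss / df,
    statistic = unname(c(fit$f[1L, effects], NA_real_)),
    p.value = unname(c(fit$p[1L, effects], NA_real_))
  )
  attr(out, "degenerate") <- unname(fit$degenerate[1L])
  out
}

#' Fisher's LSD contrast between two groups
#'
#' Pairwise comparison using the pooled residual mean square from the
#' two-way ANOVA: `t = (mean_u - mean_v) / sqrt(MS_E * (1/n_u + 1/n_v))`
#' with the residual degrees of freedom, plus the fold change
#' `2^(mean_u - mean_v)` (log2-scale input assumed).
#'
#' @param mean_u,mean_v Group means (log2 scale).
#' @param n_u,n_v Group sizes.
#' @param ms_e Pooled residual mean square.
#' @param df_e Residual degrees of freedom.
#' @return One-row tibble: `delta` (log2 difference), `statistic`, `p.value`,
#'   `fold_change`, `degenerate`.
#' @export
lsd_contrast <- function(mean_u, mean_v, n_u, n_v, ms_e, df_e) {
  stopifnot(ms_e >= 0, n_u >= 1, n_v >= 1)
  delta <- mean_u - mean_v
  se <- sqrt(ms_e * (1 / n_u + 1 / n_v))
  degenerate <- se == 0
  t_stat <- ifelse(degenerate, ifelse(delta == 0, 0, sign(delta) * Inf),
                   delta / se)
  p <- ifelse(is.infinite(t_stat), 0,
              ifelse(degenerate, 1,
                     2 * stats::pt(abs(t_stat), df_e, lower.tail = FALSE)))
  tibble::tibble(delta = delta, statistic = t_stat, p.value = p,
                 fold_change = 2^delta, degenerate = degenerate)
}

lsd_pairs <- function() {
  g <- group_levels()
  pairs <- utils::combn(g, 2L)
  # orient each pair so the fold change reads treatment vs baseline
  tibble::tibble(u = pairs[2L, ], v = pairs[1L, ])
}

#' Gene-wise factorial differential expression
#'
#' Runs the two-way ANOVA (genotype x oxygen) for every gene, attaches LSD
#' pairwise contrasts with signed fold changes, and controls the FDR with
#' Benjamini-Hochberg, by default separately within each effect family.
#' Genes with zero total variance have undefined F statistics; they are
#' flagged and excluded from the BH family size.
#'
#' @param expr Expression tibble (log2 scale).
#' @param design Sample design.
#' @param q_threshold FDR cut-off for significance flags (default 0.05).
#' @param bh_family `"per_effect"` (default) adjusts each of the three effect
#'   families separately; `"pooled"` adjusts all three together.
#' @return An object of class `factorial_de` with elements `results` (one row
#'   per gene: SS/F/p/q per effect plus delta/t/p/FC per group pair), `flags`
#'   (logical significance per effect), and the run parameters. `tidy()`,
#'   `glance()` and `autoplot()` methods are provided.
#' @export
run_factorial_de <- function(expr, design, q_threshold = 0.05,
                             bh_family = c("per_effect", "pooled")) {
  bh_family <- match.arg(bh_family)
  stopifnot(q_threshold > 0, q_threshold <= 1)
  design <- check_design(expr, design)
  if (!identical(expr_scale(expr), "log2")) {
    warning("expression matrix not tagged log2; fold changes assume log2 input",
            call. = FALSE)
  }
  m <- expr_matrix(expr)
  ord <- order(rownames(m), method = "radix")
  m <- m[ord, , drop = FALSE]
  genes <- expr$gene[ord]

  fit <- anova_matrix(m, design)
  effects <- c("genotype", "oxygen", "interaction")

  pmat <- fit$p
  usable <- !fit$degenerate  # zero-variance genes leave the BH family
  qmat <- matrix(NA_real_, nrow(pmat), 3L, dimnames = dimnames(pmat))
  if (bh_family == "per_effect") {
    for (e in effects) {
      qmat[usable, e] <- bh_adjust(pmat[usable, e])
    }
  } else {
    qmat[usable, ] <- matrix(bh_adjust(as.vector(pmat[usable, ])),
                             ncol = 3L)
  }

  results <- tibble::tibble(gene = genes)
  for (e in effects) {
    results[[paste0("ss_", e)]] <- unname(fit$ss[, e])
    results[[paste0("f_", e)]] <- unname(fit$f[, e])
    results[[paste0("p_", e)]] <- unname(pmat[, e])
    results[[paste0("q_", e)]] <- unname(qmat[, e])
  }
  results$ms_error <- unname(fit$ms_e)
  results$df_error <- fit$df_e
  results$degenerate <- unname(fit$degenerate)

  grp <- factor(design$group, levels = group_levels())
  n_cell <- as.integer(table(grp))
  names(n_cell) <- group_levels()
  cell_mean <- vapply(group_levels(), function(g) {
    rowMeans(m[, grp == g, drop = FALSE])
  }, numeric(nrow(m)))
  cell_mean <- matrix(cell_mean, nrow = nrow(m),
                      dimnames = list(rownames(m), group_levels()))
  pairs <- lsd_pairs()
  for (i in seq_len(nrow(pairs))) {
    u <- pairs$u[[i]]; v <- pairs$v[[i]]
    lab <- paste0(u, "_vs_", v)
    cc <- lsd_contrast(cell_mean[, u], cell_mean[, v],
                       n_cell[[u]], n_cell[[v]], fit$ms_e, fit$df_e)
    results[[paste0("delta_", lab)]] <- unname(cc$delta)
    results[[paste0("t_", lab)]] <- unname(cc$statistic)
    results[[paste0("p_", lab)]] <- unname(cc$p.value)
    results[[paste0("fc_", lab)]] <- unname(cc$fold_change)
  }

  sig <- function(e) {
    unname(!is.na(qmat[, e]) & qmat[, e] < q_threshold)
  }
  flags <- tibble::tibble(
    gene = genes,
    genotype = sig("genotype"),
    oxygen = sig("oxygen"),
    interaction = sig("interaction")
  )

  structure(
    list(results = results, flags = flags,
         params = list(q_threshold = q_threshold, bh_family = bh_family,
                       n_per_group = n_cell, df_error = fit$df_e)),
    class = "factorial_de"
  )
}

#' @export
print.factorial_de <- function(x, ...) {
  cat("Factorial differential expression (genotype x oxygen)\n")
  cat("  genes tested: ", nrow(x$results), "\n", sep = "")
  cat("  replicates per group: ",
      paste(x$params$n_per_group, collapse = "/"), "\n", sep = "")
  for (e in c("genotype", "oxygen", "interaction")) {
    cat(sprintf("  significant %-11s (q < %.3g): %d\n", e,
                x$params$q_threshold, sum(x$flags[[e]])))
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname run_factorial_de
#' @param x A `factorial_de` object.
#' @param ... Unused.
#' @export
tidy.factorial_de <- function(x, ...) x$results

#' @rdname run_factorial_de
#' @export
glance.factorial_de <- function(x, ...) {
  tibble::tibble(
    n_genes = nrow(x$results),
    n_sig_genotype = sum(x$flags$genotype),
    n_sig_oxygen = sum(x$flags$oxygen),
    n_sig_interaction = sum(x$flags$interaction),
    n_degenerate = sum(x$results$degenerate),
    q_threshold = x$params$q_threshold,
    bh_family = x$params$bh_family
  )
}

#' Volcano-style plot of a factorial DE fit
#'
#' One panel per effect: -log10 q against the most relevant LSD log2 fold
#' change (KO_RA vs WT_RA for genotype, WT_HO vs WT_RA for oxygen, KO_HO vs
#' WT_HO for interaction), colored by significance.
#'
#' @param object A `factorial_de` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.factorial_de <- function(object, ...) {
  res <- object$results
  panels <- list(
    genotype = "delta_KO_RA_vs_WT_RA",
    oxygen = "delta_WT_HO_vs_WT_RA",
    interaction = "delta_KO_HO_vs_WT_HO"
  )
  long <- purrr::map_dfr(names(panels), function(e) {
    tibble::tibble(
      effect = e, gene = res$gene,
      delta = res[[panels[[e]]]],
      q = res[[paste0("q_", e)]],
      significant = object$flags[[e]]
    )
  })
  long$effect <- factor(long$effect, levels = names(panels))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$delta,
                                     y = -log10(pmax(.data$q, 1e-300)),
                                     color = .data$significant)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::facet_wrap(~effect, scales = "free") +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey60",
                                           `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change (LSD contrast)",
                  y = expression(-log[10]~q)) +
    ggplot2::theme_minimal(base_size = 9)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
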