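#' Relative expression by the 2^-ddCt method
#'
#' Normalizes each target Ct to the reference gene within the same sample
#' (`dCt = target_ct - reference_ct`), then to the mean dCt of the reference
#' group (`ddCt = dCt - mean dCt(reference group)`), and exponentiates:
#' per-sample relative expression `2^-ddCt`. The group fold change is
#' `2^-(mean group ddCt)`, i.e. the geometric mean of the per-sample ratios;
#' it is exactly 1 in the reference group.
#'
#' @param ct Ct tibble (see [read_ct_table()]).
#' @param design Sample design.
#' @param reference_group Baseline group (default `"WT_RA"`).
#' @return A tibble with one row per (gene, group): `gene`, `group`,
#'   `fold_change`, `mean_ddct`, `n_samples`, plus the per-sample values in
#'   the `samples` list-column.
#' @export
ddct_fold_change <- function(ct, design, reference_group = "WT_RA") {
  ct <- as_ct_table(ct)
  design <- as_sample_design(design)
  stopifnot(reference_group %in% group_levels())
  miss <- setdiff(ct$sample, design$sample)
  if (length(miss)) {
    stop("Ct samples missing from design: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ct$group <- design$group[match(ct$sample, design$sample)]
  ct$dct <- ct$target_ct - ct$reference_ct

  ref <- dplyr::filter(ct, .data$group == reference_group)
  ref_mean <- dplyr::summarise(dplyr::group_by(ref, .data$gene),
                               ref_dct = mean(.data$dct), .groups = "drop")
  missing_ref <- setdiff(unique(ct$gene), ref_mean$gene)
  if (length(missing_ref)) {
    stop("gene(s) missing from reference group: ",
         paste(missing_ref, collapse = ", "), call. = FALSE)
  }
  ct <- dplyr::left_join(ct, ref_mean, by = "gene")
  ct$ddct <- ct$dct - ct$ref_dct
  ct$rel_expr <- 2^(-ct$ddct)

  out <- ct |>
    dplyr::group_by(.data$gene, .data$group) |>
    dplyr::summarise(
      mean_ddct = mean(.data$ddct),
      n_samples = dplyr::n(),
      samples = list(tibble::tibble(sample, rel_expr)),
      .groups = "drop"
    )
  out$fold_change <- 2^(-out$mean_ddct)
  out$group <- factor(out$group, levels = group_levels())
  out <- dplyr::arrange(out, .data$gene, .data$group)
  out$group <- as.character(out$group)
  out[c("gene", "group", "fold_change", "mean_ddct", "n_samples", "samples")]
}

#' Direction call from a fold change
#'
#' Classifies a fold change as `up`, `down` or `no-change` relative to a
#' symmetric no-change band of half-width `delta` in log2 units around 1.
#'
#' @param fold_change Positive fold change(s).
#' @param delta Half-width of the no-change band in log2 units (default 0:
#'   any departure from 1 counts as a direction).
#' @return Character vector in `{"up", "down", "no-change"}`.
#' @export
direction <- function(fold_change, delta = 0) {
  if (any(!is.finite(fold_change)) || any(fold_change <= 0)) {
    stop("fold changes must be positive and finite", call. = FALSE)
  }
  stopifnot(delta >= 0)
  lfc <- log2(fold_change)
  dplyr::case_when(lfc > delta ~ "up", lfc < -delta ~ "down",
                   .default = "no-change")
}

#' Microarray vs qPCR direction concordance
#'
#' Compares fold-change directions between the two platforms gene by gene and
#' group by group ("vectorial" agreement): a (gene, group) pair is concordant
#' when both platforms call the same direction with the no-change band
#' `delta`. Pairs present on only one platform are excluded and logged, never
#' imputed.
#'
#' @param microarray,qpcr Tibbles with columns `gene`, `group`,
#'   `fold_change` (the reference group may be present; fold change 1 rows in
#'   the reference group are skipped).
#' @param delta No-change band half-width in log2 units (default 0).
#' @param reference_group Group excluded from comparison (its fold change is
#'   1 by construction).
#' @return An object of class `concordance`: per-pair calls plus the
#'   `per_gene` attribute (gene concordant in every evaluated group) and the
#'   overall fraction via `glance()`.
#' @export
concordance <- function(microarray, qpcr, delta = 0,
                        reference_group = "WT_RA") {
  ma <- tibble::as_tibble(microarray)[c("gene", "group", "fold_change")]
  qp <- tibble::as_tibble(qpcr)[c("gene", "group", "fold_change")]
  ma <- ma[ma$group != reference_group, ]
  qp <- qp[qp$group != reference_group, ]
  merged <- dplyr::inner_join(ma, qp, by = c("gene", "group"),
                              suffix = c("_microarray", "_qpcr"))
  n_dropped <- nrow(ma) + nrow(qp) - 2L * nrow(merged)
  if (n_dropped > 0L) {
    message(n_dropped, " (gene, group) pair(s) present on one platform only ",
            "were excluded")
  }
  if (!nrow(merged)) stop("no comparable (gene, group) pairs", call. = FALSE)
  merged$direction_microarray <- direction(merged$fold_change_microarray, delta)
  merged$direction_qpcr <- direction(merged$fold_change_qpcr, delta)
  merged$concordant <- merged$direction_microarray == merged$direction_qpcr
  merged <- dplyr::arrange(merged, .data$gene, .data$group)

  per_gene <- merged |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(n_groups = dplyr::n(),
                     all_concordant = all(.data$concordant),
                     .groups = "drop")
  structure(merged,
            per_gene = per_gene, delta = delta,
            class = c("concordance", class(merged)))
}

#' @rdname concordance
#' @param x A `concordance` object.
#' @param ... Unused.
#' @export
glance.concordance <- function(x, ...) {
  per_gene <- attr(x, "per_gene")
  tibble::tibble(
    n_pairs = nrow(x),
    n_concordant = sum(x$concordant),
    fraction_concordant = mean(x$concordant),
    n_genes = nrow(per_gene),
    n_genes_all_concordant = sum(per_gene$all_concordant),
    delta = attr(x, "delta")
  )
}

#' Paired t test between two groups
#'
#' Classical paired t on the within-pair differences, two-sided. When every
#' difference is zero the statistic is 0 with p = 1; when the differences are
#' constant but non-zero the statistic is infinite with p = 0 and the
#' degenerate flag set.
#'
#' @param values_u,values_v Equal-length paired measurements, n >= 2.
#' @return One-row tibble: `estimate` (mean difference), `statistic`,
#'   `p.value`, `df`, `degenerate`.
#' @export
paired_t_test <- function(values_u, values_v) {
  if (length(values_u) != length(values_v)) {
    stop("paired samples must have equal length", call. = FALSE)
  }
  n <- length(values_u)
  if (n < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- values_u - values_v
  md <- mean(d)
  sdd <- stats::sd(d)
  if (sdd == 0) {
    if (md == 0) {
      return(tibble::tibble(estimate = 0, statistic = 0, p.value = 1,
                            df = n - 1L, degenerate = TRUE))
    }
    return(tibble::tibble(estimate = md, statistic = sign(md) * Inf,
                          p.value = 0, df = n - 1L, degenerate = TRUE))
  }
  t_stat <- md / (sdd / sqrt(n))
  tibble::tibble(
    estimate = md, statistic = t_stat,
    p.value = 2 * stats::pt(abs(t_stat), n - 1L, lower.tail = FALSE),
    df = n - 1L, degenerate = FALSE
  )
}

#' Fold-change comparison plot across platforms
#'
#' @param object A `concordance` object.
#' @param ... Unused.
#' @return A ggplot object: log2 fold changes on both platforms, concordant
#'   pairs in blue, discordant in red.
#' @export
autoplot.concordance <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = log2(.data$fold_change_microarray),
                               y = log2(.data$fold_change_qpcr),
                               color = .data$concordant)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, color = "grey70") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, color = "grey70") +
    ggplot2::geom_abline(slope = 1, intercept = 0, color = "grey80") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_color_manual(values = c(`TRUE` = "steelblue",
                                           `FALSE` = "firebrick")) +
    ggplot2::labs(x = "microarray log2 fold change",
                  y = "qPCR log2 fold change", color = "concordant") +
    ggplot2::theme_minimal(base_size = 9)
}
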