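#' Quantile-normalize an expression matrix across samples
#'
#' Forces every sample (column) onto the same empirical distribution: the
#' per-rank mean across samples. Ties within a column receive the mean of
#' their tied ranks' target values, which makes the operation deterministic
#' and idempotent.
#'
#' @param expr Expression tibble (`gene` column plus >=2 sample columns).
#' @return Expression tibble of the same shape, quantile-normalized.
#' @export
quantile_normalize <- function(expr) {
  m <- expr_matrix(expr)
  if (ncol(m) < 2L) stop("quantile normalization needs >=2 samples", call. = FALSE)
  if (any(!is.finite(m))) stop("matrix must be complete and finite", call. = FALSE)
  target <- rowMeans(apply(m, 2L, sort, method = "radix"))
  norm <- apply(m, 2L, function(col) {
    o <- order(col)
    t <- numeric(length(col))
    t[o] <- target
    # tied values share the mean of their ranks' target values
    stats::ave(t, match(col, col), FUN = mean)
  })
  dimnames(norm) <- dimnames(m)
  out <- expr_tibble(norm, scale_tag = expr_scale(expr))
  out$gene <- expr$gene
  out
}

#' Log2-transform a linear-scale expression matrix
#'
#' @param expr Expression tibble tagged `linear` or `unknown`.
#' @param pseudocount Non-negative value added before taking logs.
#' @return Expression tibble on the log2 scale (`scale_tag = "log2"`).
#' @export
log2_transform <- function(expr, pseudocount = 0) {
  if (identical(expr_scale(expr), "log2")) {
    stop("matrix is already tagged log2; refusing to transform again",
         call. = FALSE)
  }
  stopifnot(pseudocount >= 0)
  m <- expr_matrix(expr)
  if (any(m + pseudocount <= 0)) {
    stop("non-positive values; use a pseudocount > 0", call. = FALSE)
  }
  out <- expr_tibble(log2(m + pseudocount), scale_tag = "log2")
  out$gene <- expr$gene
  out
}

#' Per-gene z-scores for heatmap display
#'
#' Standardizes each selected gene row to mean 0 and sample (n-1) standard
#' deviation 1. Constant rows are mapped to all zeros with a warning. Exported
#' values are never clipped; the +/-2 bound applies only to rendered colors in
#' [plot_heatmap()].
#'
#' @param expr Expression tibble.
#' @param genes Genes to standardize (default all). Matching is
#'   case-insensitive.
#' @return Tibble of per-gene z-scores for the selected genes.
#' @export
zscore_rows <- function(expr, genes = NULL) {
  m <- expr_matrix(expr)
  if (is.null(genes)) genes <- expr$gene
  if (!length(genes)) stop("empty gene list", call. = FALSE)
  idx <- match(toupper(genes), rownames(m))
  if (anyNA(idx)) {
    stop("genes not in matrix: ",
         paste(genes[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  sub <- m[idx, , drop = FALSE]
  mu <- rowMeans(sub)
  sdv <- apply(sub, 1L, stats::sd)
  z <- (sub - mu) / sdv
  if (any(sdv == 0)) {
    warning(sum(sdv == 0), " constant row(s) mapped to zeros", call. = FALSE)
    z[sdv == 0, ] <- 0
  }
  out <- expr_tibble(z, scale_tag = "zscore")
  out$gene <- expr$gene[idx]
  out
}

#' Group-mean z-score matrix for heatmap export
#'
#' Averages per-sample z-scores within each of the four design groups, the
#' usual genes-by-groups display for small factorial studies. Both the
#' per-sample and per-group views can be exported since published heatmaps do
#' not always say which they show.
#'
#' @param zexpr Z-score tibble from [zscore_rows()].
#' @param design Sample design.
#' @return Tibble with columns `gene`, `WT_RA`, `WT_HO`, `KO_RA`, `KO_HO`.
#' @export
group_mean_zscores <- function(zexpr, design) {
  design <- check_design(zexpr, design)
  m <- expr_matrix(zexpr)
  grp <- split(design$sample, factor(design$group, levels = group_levels()))
  out <- vapply(grp, function(s) rowMeans(m[, s, drop = FALSE]), numeric(nrow(m)))
  out <- matrix(out, nrow = nrow(m), dimnames = list(rownames(m), names(grp)))
  res <- tibble::as_tibble(as.data.frame(out, check.names = FALSE))
  tibble::add_column(res, gene = zexpr$gene, .before = 1L)
}

#' Heatmap of z-scored expression
#'
#' Renders a genes-by-samples (or genes-by-groups) tile heatmap of z-scores
#' with the color scale clipped at +/-2. Clipping affects only the fill
#' mapping, never the underlying numbers.
#'
#' @param z Tibble from [zscore_rows()] or [group_mean_zscores()].
#' @param clip Color-scale clip bound (display only).
#' @return A ggplot object.
#' @export
plot_heatmap <- function(z, clip = 2) {
  long <- tidyr::pivot_longer(z, -"gene", names_to = "sample",
                              values_to = "z")
  long$sample <- factor(long$sample, levels = setdiff(names(z), "gene"))
  long$gene <- factor(long$gene, levels = rev(unique(z$gene)))
  long$z_disp <- pmin(pmax(long$z, -clip), clip)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample, y = .data$gene,
                                     fill = .data$z_disp)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "darkblue", mid = "white",
                                  high = "darkred", limits = c(-clip, clip),
                                  name = "z-score") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal(base_size = 9)
}
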