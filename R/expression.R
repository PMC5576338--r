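#' Convert an expression tibble to a numeric matrix
#'
#' @param expr Expression tibble (`gene` column plus sample columns).
#' @return Numeric matrix, genes in rows (rownames are uppercased gene ids).
#' @export
expr_matrix <- function(expr) {
  stopifnot("gene" %in% names(expr))
  m <- as.matrix(expr[setdiff(names(expr), "gene")])
  storage.mode(m) <- "double"
  rownames(m) <- toupper(expr$gene)
  m
}

#' Convert a numeric matrix back to an expression tibble
#'
#' @param m Numeric matrix with gene rownames and sample colnames.
#' @param scale_tag Scale attribute for the result.
#' @return Expression tibble.
#' @export
expr_tibble <- function(m, scale_tag = "log2") {
  out <- tibble::as_tibble(as.data.frame(m, check.names = FALSE))
  out <- tibble::add_column(out, gene = rownames(m), .before = 1L)
  attr(out, "scale_tag") <- scale_tag
  out
}

expr_scale <- function(expr) {
  tag <- attr(expr, "scale_tag")
  if (is.null(tag)) "unknown" else tag
}

#' Write an expression tibble as delimited text
#'
#' @param expr Expression tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(expr, path) {
  out <- expr
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) formatC(x, digits = 15, format = "g"))
  readr::write_tsv(out, path)
  invisible(path)
}

# check expr/design agreement; returns design reordered to expr columns
check_design <- function(expr, design) {
  design <- as_sample_design(design)
  samples <- setdiff(names(expr), "gene")
  if (!setequal(samples, design$sample)) {
    stop("design samples do not match expression matrix columns", call. = FALSE)
  }
  design[match(samples, design$sample), , drop = FALSE]
}
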