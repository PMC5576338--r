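#' Hypergeometric over-representation of gene sets
#'
#' Tests each gene set for over-representation in a query list of
#' differential genes within a stated universe, using the exact upper-tail
#' hypergeometric probability `P(X >= k)` for overlap `k`, set size `K`,
#' query size `n` and universe size `N`. Results are ranked by ascending p
#' with deterministic lexicographic tie-breaking on `set_id`, and BH q-values
#' are attached across the collection.
#'
#' Sets are intersected with the universe before testing; the universe is by
#' convention all genes tested in the ANOVA, not the union of the collection.
#'
#' @param query Character vector of query gene ids (must lie in `universe`).
#' @param sets Gene-set tibble from [read_gmt()] or [simulate_pathways()].
#' @param universe Character vector of all testable gene ids.
#' @return An `enrichment` tibble: `set_id`, `universe_size`, `set_size`,
#'   `query_size`, `overlap`, `p.value`, `q.value`, `rank`.
#' @export
hypergeom_enrich <- function(query, sets, universe) {
  universe <- unique(toupper(universe))
  query <- unique(toupper(query))
  if (!length(universe)) stop("empty universe", call. = FALSE)
  if (!length(query)) stop("empty query list", call. = FALSE)
  if (!all(query %in% universe)) {
    stop("query genes outside the universe: ",
         paste(utils::head(setdiff(query, universe), 5L), collapse = ", "),
         call. = FALSE)
  }
  N <- length(universe)
  n <- length(query)
  res <- tibble::tibble(
    set_id = sets$set_id,
    universe_size = N,
    set_size = vapply(sets$genes, function(g) {
      sum(unique(toupper(g)) %in% universe)
    }, integer(1)),
    query_size = n,
    overlap = vapply(sets$genes, function(g) {
      sum(unique(toupper(g)) %in% query)
    }, integer(1))
  )
  # P(X >= k) for X ~ Hypergeometric(N, K, n)
  res$p.value <- stats::phyper(res$overlap - 1L, res$set_size,
                               N - res$set_size, n, lower.tail = FALSE)
  res$q.value <- bh_adjust(res$p.value)
  ord <- order(res$p.value, res$set_id, method = "radix")
  res <- res[ord, , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  structure(res, class = c("enrichment", class(res)))
}

#' Keep the top K enriched pathways
#'
#' @param results Ranked `enrichment` tibble from [hypergeom_enrich()].
#' @param k Number of top pathways to keep (default 50, the usual cut for
#'   pathway-map ontologies).
#' @return The first `k` rows by rank; all rows (with a message) if fewer
#'   exist.
#' @export
top_k <- function(results, k = 50) {
  if (k <= 0) stop("k must be positive", call. = FALSE)
  if (nrow(results) < k) {
    message("only ", nrow(results), " pathways available (requested ", k, ")")
    return(results)
  }
  results[seq_len(k), , drop = FALSE]
}

#' @rdname hypergeom_enrich
#' @param x An `enrichment` tibble.
#' @param ... Unused.
#' @export
glance.enrichment <- function(x, ...) {
  tibble::tibble(
    n_sets = nrow(x),
    n_significant = sum(x$q.value < 0.05),
    min_p = min(x$p.value),
    universe_size = x$universe_size[[1L]],
    query_size = x$query_size[[1L]]
  )
}

#' Dot plot of enrichment results
#'
#' @param object An `enrichment` tibble.
#' @param k Show the top `k` sets.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.enrichment <- function(object, k = 20, ...) {
  d <- utils::head(object[order(object$rank), ], k)
  d$set_id <- factor(d$set_id, levels = rev(d$set_id))
  ggplot2::ggplot(d, ggplot2::aes(x = -log10(.data$p.value), y = .data$set_id,
                                  size = .data$overlap)) +
    ggplot2::geom_point(color = "steelblue") +
    ggplot2::labs(x = expression(-log[10]~p), y = NULL, size = "overlap") +
    ggplot2::theme_minimal(base_size = 9)
}
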