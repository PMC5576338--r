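#' Jaccard distance between two gene sets
#'
#' `d = 1 - |A ∩ B| / |A ∪ B|`: 0 for identical sets, 1 for disjoint sets.
#'
#' @param a,b Non-empty character vectors of gene ids.
#' @return Dissimilarity in \[0, 1\].
#' @export
jaccard_distance <- function(a, b) {
  a <- unique(toupper(a)); b <- unique(toupper(b))
  if (!length(a) || !length(b)) stop("empty gene set", call. = FALSE)
  inter <- length(intersect(a, b))
  1 - inter / (length(a) + length(b) - inter)
}

jaccard_matrix <- function(genes) {
  n <- length(genes)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i)) {
      if (i != j) d[i, j] <- d[j, i] <- jaccard_distance(genes[[i]], genes[[j]])
    }
  }
  d
}

#' Collapse redundant pathways into mega pathways
#'
#' Agglomerative complete-linkage clustering on the Jaccard distance between
#' the complete gene sets of enriched pathways, cut so that clusters are the
#' maximal groups whose merge height is at most `cutoff` (closed threshold).
#' Each resulting cluster is a "mega pathway" whose redundant members describe
#' sub-segments of the same biology. Ties in merge distance are broken by the
#' lexicographically smallest pair of cluster labels (a cluster is labelled by
#' its smallest member set id), which makes the output deterministic across
#' platforms.
#'
#' @param sets Gene-set tibble (`set_id`, `genes` list-column), usually the
#'   sets corresponding to the top enriched pathways, in enrichment-rank
#'   order.
#' @param cutoff Dissimilarity cut in \[0, 1\]; default 0.6.
#' @return An object of class `pathway_clusters`: a tibble with one row per
#'   mega pathway (`cluster_id`, `members` list-column, `n_members`, `height`
#'   = max within-cluster pairwise distance, `genes` = union of member sets),
#'   ordered by the first member's position in the input. The full merge
#'   sequence is kept in attributes for dendrogram export.
#' @export
complete_linkage_cluster <- function(sets, cutoff = 0.6) {
  if (cutoff < 0 || cutoff > 1) stop("cutoff must lie in [0, 1]", call. = FALSE)
  n <- nrow(sets)
  if (n < 1L) stop("need at least one pathway", call. = FALSE)
  d <- jaccard_matrix(sets$genes)

  # agglomerate with explicit lexicographic tie-breaking on cluster labels
  clusters <- as.list(seq_len(n))
  labels <- sets$set_id
  active <- rep(TRUE, n)
  cd <- d                      # complete-linkage distances between clusters
  merges <- list()
  while (sum(active) > 1L) {
    idx <- which(active)
    best <- NULL
    for (ii in seq_along(idx)) {
      for (jj in seq_len(ii - 1L)) {
        i <- idx[[jj]]; j <- idx[[ii]]
        lab <- sort(c(labels[[i]], labels[[j]]))
        cand <- list(dist = cd[i, j], lab = lab, i = i, j = j)
        if (is.null(best) || cand$dist < best$dist ||
            (cand$dist == best$dist &&
             (cand$lab[[1L]] < best$lab[[1L]] ||
              (cand$lab[[1L]] == best$lab[[1L]] &&
               cand$lab[[2L]] < best$lab[[2L]])))) {
          best <- cand
        }
      }
    }
    i <- best$i; j <- best$j
    merges[[length(merges) + 1L]] <-
      list(i = i, j = j, height = best$dist,
           members_i = clusters[[i]], members_j = clusters[[j]])
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    labels[[i]] <- min(labels[[i]], labels[[j]])
    active[[j]] <- FALSE
    for (k in which(active)) {
      if (k != i) cd[i, k] <- cd[k, i] <- max(cd[i, k], cd[j, k])
    }
  }

  # cut: undo nothing, just replay merges with height <= cutoff
  assignment <- seq_len(n)
  for (mg in merges) {
    if (mg$height <= cutoff) {
      assignment[assignment %in% assignment[c(mg$members_i, mg$members_j)]] <-
        min(assignment[c(mg$members_i, mg$members_j)])
    }
  }
  groups <- unname(split(seq_len(n), assignment))
  first <- vapply(groups, min, integer(1))
  groups <- groups[order(first)]

  out <- tibble::tibble(
    cluster_id = seq_along(groups),
    members = lapply(groups, function(g) sets$set_id[g]),
    n_members = lengths(groups),
    height = vapply(groups, function(g) {
      if (length(g) == 1L) 0 else max(d[g, g])
    }, numeric(1)),
    genes = lapply(groups, function(g) {
      sort(unique(toupper(unlist(sets$genes[g]))))
    })
  )
  structure(out, merges = merges, set_ids = sets$set_id, distances = d,
            cutoff = cutoff, class = c("pathway_clusters", class(out)))
}

#' Pool a mega pathway's differential genes
#'
#' Union of the member pathways' gene sets intersected with the genes flagged
#' differential for the configured effect — the gene list behind each mega
#' pathway's heatmap.
#'
#' @param clusters A `pathway_clusters` object.
#' @param flags Significance flags tibble (from [run_factorial_de()]).
#' @param effect Which effect family defines "differential"
#'   (default `"interaction"`).
#' @return `clusters` with a `pooled_genes` list-column and `n_pooled` count.
#' @export
pool_cluster_genes <- function(clusters, flags, effect = "interaction") {
  stopifnot(effect %in% c("genotype", "oxygen", "interaction"))
  de <- toupper(flags$gene[flags[[effect]]])
  pooled <- lapply(clusters$genes, function(g) sort(intersect(g, de)))
  if (all(lengths(pooled) == 0L)) {
    warning("no differential genes in any cluster", call. = FALSE)
  }
  clusters$pooled_genes <- pooled
  clusters$n_pooled <- lengths(pooled)
  clusters
}

#' Newick export of the pathway dendrogram
#'
#' @param clusters A `pathway_clusters` object.
#' @return Single newick string with merge heights as branch lengths.
#' @export
cluster_newick <- function(clusters) {
  merges <- attr(clusters, "merges")
  ids <- attr(clusters, "set_ids")
  if (!length(merges)) return(paste0(ids, ";"))
  node <- as.list(ids)          # newick fragment per original slot
  depth <- rep(0, length(ids))  # height of each fragment's root
  for (mg in merges) {
    bl_i <- mg$height - depth[[mg$i]]
    bl_j <- mg$height - depth[[mg$j]]
    node[[mg$i]] <- sprintf("(%s:%g,%s:%g)", node[[mg$i]], bl_i,
                            node[[mg$j]], bl_j)
    depth[[mg$i]] <- mg$height
  }
  paste0(node[[merges[[length(merges)]]$i]], ";")
}

#' @rdname complete_linkage_cluster
#' @param x A `pathway_clusters` object.
#' @param ... Unused.
#' @export
glance.pathway_clusters <- function(x, ...) {
  tibble::tibble(
    n_pathways = sum(x$n_members),
    n_clusters = nrow(x),
    cutoff = attr(x, "cutoff"),
    max_height = max(x$height),
    largest_cluster = max(x$n_members)
  )
}

#' Dendrogram-style plot of pathway clusters
#'
#' Displays member pathways grouped by mega pathway with their merge heights.
#'
#' @param object A `pathway_clusters` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pathway_clusters <- function(object, ...) {
  d <- tidyr::unnest(
    tibble::tibble(cluster_id = object$cluster_id,
                   height = object$height,
                   set_id = object$members),
    "set_id"
  )
  d$set_id <- factor(d$set_id, levels = rev(d$set_id))
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$cluster_id),
                                  y = .data$set_id,
                                  fill = .data$height)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "#2c7bb6", high = "#d7191c",
                                 limits = c(0, 1), name = "merge height") +
    ggplot2::labs(x = "mega pathway", y = NULL) +
    ggplot2::theme_minimal(base_size = 9)
}
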