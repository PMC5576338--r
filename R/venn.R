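venn_regions <- function() {
  c("genotype_only", "oxygen_only", "interaction_only",
    "genotype_oxygen", "genotype_interaction", "oxygen_interaction",
    "genotype_oxygen_interaction", "none")
}

#' Partition genes into the seven Venn regions of the three effects
#'
#' Every tested gene falls in exactly one of the seven disjoint regions of
#' the genotype / oxygen / interaction Venn diagram according to its 3-bit
#' significance pattern, or in the triple-negative remainder.
#'
#' @param flags Tibble with columns `gene`, `genotype`, `oxygen`,
#'   `interaction` (logical), one row per tested gene (e.g. the `flags`
#'   element of a [run_factorial_de()] fit).
#' @return An object of class `venn_partition`: a tibble of region counts
#'   (`region`, `n`) with region membership lists in the `"members"`
#'   attribute.
#' @export
venn_partition <- function(flags) {
  flags <- tibble::as_tibble(flags)
  stopifnot(all(c("gene", "genotype", "oxygen", "interaction") %in% names(flags)))
  if (anyDuplicated(toupper(flags$gene))) {
    stop("duplicate genes in flags", call. = FALSE)
  }
  pattern <- dplyr::case_when(
    flags$genotype & !flags$oxygen & !flags$interaction ~ "genotype_only",
    !flags$genotype & flags$oxygen & !flags$interaction ~ "oxygen_only",
    !flags$genotype & !flags$oxygen & flags$interaction ~ "interaction_only",
    flags$genotype & flags$oxygen & !flags$interaction ~ "genotype_oxygen",
    flags$genotype & !flags$oxygen & flags$interaction ~ "genotype_interaction",
    !flags$genotype & flags$oxygen & flags$interaction ~ "oxygen_interaction",
    flags$genotype & flags$oxygen & flags$interaction ~
      "genotype_oxygen_interaction",
    .default = "none"
  )
  members <- split(flags$gene, factor(pattern, levels = venn_regions()))
  counts <- tibble::tibble(region = venn_regions(),
                           n = as.integer(lengths(members)))
  structure(counts, members = members, n_genes = nrow(flags),
            class = c("venn_partition", class(counts)))
}

#' Assemble a Venn partition directly from region counts
#'
#' Useful when only the printed region counts of a published diagram are
#' available, without gene lists.
#'
#' @param counts Named numeric vector or tibble (`region`, `n`) covering the
#'   seven regions (missing regions count 0); names as in
#'   `venn_partition()` output.
#' @return A `venn_partition` object with empty membership lists.
#' @export
venn_from_counts <- function(counts) {
  if (is.data.frame(counts)) {
    counts <- stats::setNames(counts$n, counts$region)
  }
  unknown <- setdiff(names(counts), venn_regions())
  if (length(unknown)) {
    stop("unknown region name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  full <- stats::setNames(integer(length(venn_regions())), venn_regions())
  full[names(counts)] <- as.integer(counts)
  out <- tibble::tibble(region = venn_regions(), n = unname(full))
  structure(out, members = NULL, n_genes = sum(full),
            class = c("venn_partition", class(out)))
}

#' Total gene count of one Venn circle
#'
#' The circle for an effect is the union of the four regions that include it,
#' e.g. genotype = genotype_only + genotype_oxygen + genotype_interaction +
#' genotype_oxygen_interaction.
#'
#' @param partition A `venn_partition` object.
#' @param effect One of `"genotype"`, `"oxygen"`, `"interaction"`.
#' @return Integer count.
#' @export
circle_total <- function(partition, effect) {
  if (!effect %in% c("genotype", "oxygen", "interaction")) {
    stop("unknown effect: ", effect, call. = FALSE)
  }
  counts <- stats::setNames(partition$n, partition$region)
  regions <- switch(effect,
    genotype = c("genotype_only", "genotype_oxygen", "genotype_interaction",
                 "genotype_oxygen_interaction"),
    oxygen = c("oxygen_only", "genotype_oxygen", "oxygen_interaction",
               "genotype_oxygen_interaction"),
    interaction = c("interaction_only", "genotype_interaction",
                    "oxygen_interaction", "genotype_oxygen_interaction")
  )
  sum(counts[regions])
}

#' Gene membership of one Venn region
#'
#' @param partition A `venn_partition` built from gene flags.
#' @param region Region name (see `venn_partition()` output).
#' @return Character vector of gene ids.
#' @export
venn_members <- function(partition, region) {
  members <- attr(partition, "members")
  if (is.null(members)) {
    stop("partition was built from counts only; no membership lists",
         call. = FALSE)
  }
  if (!region %in% venn_regions()) {
    stop("unknown region: ", region, call. = FALSE)
  }
  members[[region]]
}

#' @rdname venn_partition
#' @param x A `venn_partition`.
#' @param ... Unused.
#' @export
glance.venn_partition <- function(x, ...) {
  tibble::tibble(
    n_genes = attr(x, "n_genes"),
    genotype_total = circle_total(x, "genotype"),
    oxygen_total = circle_total(x, "oxygen"),
    interaction_total = circle_total(x, "interaction"),
    n_triple_negative = x$n[x$region == "none"]
  )
}
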