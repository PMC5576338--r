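#' Published example data: Venn region counts and platform fold changes
#'
#' Two small worked-example tables transcribed from a published microarray
#' study of SphK1-knockout neonatal mice exposed to hyperoxia (a
#' bronchopulmonary-dysplasia model with the same 2x2 genotype-by-oxygen
#' design this package analyses):
#'
#' * `bpd_example_venn()` — the seven disjoint region counts of the
#'   study's genotype/oxygen/interaction Venn diagram, ready for
#'   [venn_from_counts()] and [circle_total()].
#' * `bpd_example_fold_changes()` — the study's 24-gene microarray vs
#'   RT-PCR validation panel: per-group fold changes relative to the
#'   wild-type normoxia group on both platforms, in long (gene, group,
#'   platform) form ready for [concordance()].
#'
#' @return A tibble (see above).
#' @name bpd_examples
NULL

#' @rdname bpd_examples
#' @export
bpd_example_venn <- function() {
  readr::read_tsv(
    system.file("extdata", "bpd_venn_regions.tsv", package = "factorex",
                mustWork = TRUE),
    show_col_types = FALSE
  )
}

#' @rdname bpd_examples
#' @export
bpd_example_fold_changes <- function() {
  wide <- readr::read_tsv(
    system.file("extdata", "bpd_platform_fold_changes.tsv",
                package = "factorex", mustWork = TRUE),
    show_col_types = FALSE
  )
  tidyr::pivot_longer(wide, cols = c("WT_RA", "WT_HO", "KO_RA", "KO_HO"),
                      names_to = "group", values_to = "fold_change")
}
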