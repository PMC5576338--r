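#' Configuration for a full pipeline run
#'
#' Collects the input paths and the analysis parameters of one end-to-end
#' run: ingest, optional quantile normalization, gene-wise factorial ANOVA,
#' Venn partition, over-representation, mega-pathway clustering, z-score
#' heatmap export and (when a Ct table is given) qPCR concordance.
#'
#' @param matrix_path Expression matrix file.
#' @param design_path Sample design file.
#' @param gmt_path Gene-set collection (GMT).
#' @param ct_path Optional qPCR Ct table.
#' @param output_dir Directory for all outputs (created if missing).
#' @param dialect Expression matrix dialect (see [read_expression_matrix()]).
#' @param scale_tag Declared scale of the matrix values.
#' @param quantile_normalize Quantile-normalize across samples before the
#'   ANOVA (default TRUE).
#' @param q_threshold FDR cut-off (default 0.05).
#' @param top_k Number of top enriched pathways to cluster (default 50).
#' @param cluster_cutoff Jaccard dissimilarity cut for mega pathways
#'   (default 0.6).
#' @param query_region Which genes form the enrichment query:
#'   `"interaction"`, `"genotype"` or `"oxygen"` selects that effect's whole
#'   Venn circle.
#' @param no_change_band log2 half-width of the qPCR no-change band.
#' @param seed RNG seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(matrix_path, design_path, gmt_path,
                            ct_path = NULL, output_dir,
                            dialect = "delimited", scale_tag = "log2",
                            quantile_normalize = TRUE,
                            q_threshold = 0.05, top_k = 50,
                            cluster_cutoff = 0.6,
                            query_region = c("interaction", "genotype",
                                             "oxygen"),
                            no_change_band = 0, seed = 1L) {
  query_region <- match.arg(query_region)
  stopifnot(q_threshold > 0, q_threshold <= 1,
            cluster_cutoff >= 0, cluster_cutoff <= 1,
            top_k >= 1, no_change_band >= 0)
  for (p in c(matrix_path, design_path, gmt_path, ct_path)) {
    if (!file.exists(p)) stop("input path does not exist: ", p, call. = FALSE)
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full factorial expression pipeline
#'
#' Stages run in a fixed order; every artifact is written under
#' `output_dir` and listed with its md5 checksum in `manifest.json`, so a
#' rerun with identical inputs and seed reproduces identical checksums.
#'
#' @param config A `pipeline_config`.
#' @return The manifest, invisibly, as a list (`params`, `files`, `summary`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(config$output_dir, name)
  files <- character(0)
  emit <- function(path) files <<- c(files, path)
  log_stage <- function(stage, ...) {
    message(sprintf("[%s] %s", stage, paste0(...)))
  }

  expr <- read_expression_matrix(config$matrix_path, dialect = config$dialect,
                                 scale_tag = config$scale_tag)
  design <- read_sample_design(config$design_path)
  sets <- read_gmt(config$gmt_path)
  log_stage("ingest", nrow(expr), " genes x ", ncol(expr) - 1L, " samples, ",
            nrow(sets), " gene sets")

  if (identical(expr_scale(expr), "linear")) {
    expr <- log2_transform(expr, pseudocount = 1)
    log_stage("preprocess", "log2 transform applied (linear input)")
  }
  if (config$quantile_normalize) {
    expr <- quantile_normalize(expr)
    log_stage("preprocess", "quantile normalization applied")
  }

  de <- run_factorial_de(expr, design, q_threshold = config$q_threshold)
  write_results_table(de$results, out("de_results.tsv"))
  emit(out("de_results.tsv"))
  log_stage("de", sum(de$flags$interaction), " interaction-significant genes")

  venn <- venn_partition(de$flags)
  venn_summary <- c(
    stats::setNames(as.list(venn$n), venn$region),
    list(genotype_total = circle_total(venn, "genotype"),
         oxygen_total = circle_total(venn, "oxygen"),
         interaction_total = circle_total(venn, "interaction"))
  )
  jsonlite::write_json(venn_summary, out("venn.json"), auto_unbox = TRUE)
  emit(out("venn.json"))
  log_stage("venn", "circle totals G/O/I = ",
            venn_summary$genotype_total, "/", venn_summary$oxygen_total,
            "/", venn_summary$interaction_total)

  query <- de$flags$gene[de$flags[[config$query_region]]]
  manifest_summary <- list(n_query_genes = length(query))
  if (length(query)) {
    enr <- hypergeom_enrich(query, sets, universe = de$flags$gene)
    write_results_table(enr, out("enrichment.tsv"))
    emit(out("enrichment.tsv"))
    top <- top_k(enr, k = min(config$top_k, nrow(enr)))
    top_sets <- sets[match(top$set_id, sets$set_id), , drop = FALSE]
    clusters <- complete_linkage_cluster(top_sets,
                                         cutoff = config$cluster_cutoff)
    clusters <- pool_cluster_genes(clusters, de$flags,
                                   effect = config$query_region)
    cluster_tbl <- tibble::tibble(
      cluster_id = clusters$cluster_id,
      members = vapply(clusters$members, paste, character(1), collapse = ";"),
      n_members = clusters$n_members,
      height = clusters$height,
      n_pooled = clusters$n_pooled,
      pooled_genes = vapply(clusters$pooled_genes, paste, character(1),
                            collapse = ";")
    )
    readr::write_tsv(cluster_tbl, out("mega_pathways.tsv"))
    emit(out("mega_pathways.tsv"))
    readr::write_lines(cluster_newick(clusters), out("dendrogram.nwk"))
    emit(out("dendrogram.nwk"))
    log_stage("cluster", nrow(clusters), " mega pathways from ",
              nrow(top_sets), " enriched pathways")

    de_genes <- unique(unlist(clusters$pooled_genes))
    if (length(de_genes)) {
      z <- zscore_rows(expr, de_genes)
      write_results_table(z, out("heatmap_zscores_per_sample.tsv"))
      emit(out("heatmap_zscores_per_sample.tsv"))
      zg <- group_mean_zscores(z, design)
      write_results_table(zg, out("heatmap_zscores_group_mean.tsv"))
      emit(out("heatmap_zscores_group_mean.tsv"))
      log_stage("heatmap", length(de_genes), " pooled differential genes")
    }
    manifest_summary$n_mega_pathways <- nrow(clusters)
    manifest_summary$n_enriched_sets_tested <- nrow(enr)
  } else {
    log_stage("enrich", "skipped: no significant genes in query region")
  }

  if (!is.null(config$ct_path)) {
    ct <- read_ct_table(config$ct_path)
    rel <- ddct_fold_change(ct, design)
    write_results_table(rel[setdiff(names(rel), "samples")],
                        out("qpcr_fold_changes.tsv"))
    emit(out("qpcr_fold_changes.tsv"))
    ma_fc <- microarray_fold_changes(de, genes = unique(ct$gene))
    conc <- concordance(ma_fc, rel, delta = config$no_change_band)
    write_results_table(tibble::as_tibble(conc), out("concordance.tsv"))
    emit(out("concordance.tsv"))
    manifest_summary$fraction_concordant <- glance(conc)$fraction_concordant
    log_stage("qpcr", "concordant fraction ",
              round(manifest_summary$fraction_concordant, 3))
  }

  manifest <- list(
    params = config[c("q_threshold", "top_k", "cluster_cutoff",
                      "query_region", "no_change_band", "seed",
                      "quantile_normalize")],
    files = lapply(stats::setNames(files, basename(files)), function(f) {
      list(path = f, md5 = unname(tools::md5sum(f)))
    }),
    summary = c(venn_summary, manifest_summary)
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  log_stage("done", length(files), " artifacts + manifest")
  invisible(manifest)
}

#' Microarray fold changes versus the reference group
#'
#' Extracts, for each gene, the LSD fold changes of the three non-reference
#' groups against `WT_RA` from a factorial DE fit, in the same layout as
#' [ddct_fold_change()] output so the two platforms can be compared directly.
#'
#' @param de A `factorial_de` object.
#' @param genes Genes to extract (default all).
#' @return Tibble with `gene`, `group`, `fold_change`.
#' @export
microarray_fold_changes <- function(de, genes = NULL) {
  res <- de$results
  if (!is.null(genes)) {
    res <- res[toupper(res$gene) %in% toupper(genes), , drop = FALSE]
  }
  groups <- c("WT_HO", "KO_RA", "KO_HO")
  purrr::map_dfr(groups, function(g) {
    tibble::tibble(gene = res$gene, group = g,
                   fold_change = res[[paste0("fc_", g, "_vs_WT_RA")]])
  }) |>
    dplyr::arrange(.data$gene, .data$group)
}

#' Generate and analyse a self-contained synthetic demo study
#'
#' Simulates a complete factorial study (expression, pathways, Ct table)
#' with planted ground truth, writes the inputs to disk, runs the full
#' pipeline on them, and reports how well each stage recovered the truth.
#'
#' @param dir Output directory.
#' @param config A `sim_config`; defaults to [simulation_config()] defaults.
#' @param ... Passed to [pipeline_config()] (e.g. `q_threshold`). Unless
#'   overridden, the demo runs with `quantile_normalize = FALSE`: the
#'   generator emulates an already-summarized matrix with no technical
#'   between-sample effects, and re-normalizing data in which a sizeable
#'   gene fraction shifts in one direction redistributes part of the
#'   planted signal onto null genes.
#' @return A list with the pipeline `manifest` and a `recovery` tibble
#'   juxtaposing planted truth and recovered calls per effect (sensitivity
#'   and realized false discovery rate).
#' @export
make_demo <- function(dir, config = simulation_config(), ...) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_expression(config)
  sets <- simulate_pathways(sim$truth, config)
  assay_genes <- utils::head(sim$truth$gene[sim$truth$class != "null"], 24L)
  if (!length(assay_genes)) assay_genes <- utils::head(sim$truth$gene, 24L)
  ct <- simulate_ct(sim$expr, assay_genes, config)

  inputs <- file.path(dir, "inputs")
  dir.create(inputs, showWarnings = FALSE)
  write_expression_matrix(sim$expr, file.path(inputs, "expression.tsv"))
  readr::write_tsv(sim$design[c("sample", "genotype", "oxygen")],
                   file.path(inputs, "design.tsv"))
  write_gmt(sets, file.path(inputs, "pathways.gmt"))
  readr::write_tsv(ct, file.path(inputs, "ct.tsv"))
  readr::write_tsv(sim$truth, file.path(inputs, "truth.tsv"))

  extra <- list(...)
  if (!"quantile_normalize" %in% names(extra)) {
    extra$quantile_normalize <- FALSE
  }
  cfg <- do.call(pipeline_config, c(list(
    matrix_path = file.path(inputs, "expression.tsv"),
    design_path = file.path(inputs, "design.tsv"),
    gmt_path = file.path(inputs, "pathways.gmt"),
    ct_path = file.path(inputs, "ct.tsv"),
    output_dir = file.path(dir, "results"),
    seed = config$seed
  ), extra))
  manifest <- run_pipeline(cfg)

  de <- run_factorial_de(
    if (cfg$quantile_normalize) {
      quantile_normalize(sim$expr)
    } else sim$expr,
    sim$design, q_threshold = cfg$q_threshold
  )
  recovery <- purrr::map_dfr(
    c("genotype", "oxygen", "interaction"),
    function(e) effect_recovery(de$flags, sim$truth, e)
  )
  readr::write_tsv(recovery, file.path(dir, "results", "recovery.tsv"))
  list(manifest = manifest, recovery = recovery)
}

#' Sensitivity and realized FDR of one effect's calls against planted truth
#'
#' Because the planted interaction acts on the KO-hyperoxia cell alone, an
#' interaction-class gene also has genuine non-zero marginal means for both
#' factors; such genes therefore count as true positives for the main
#' effects as well as for the interaction.
#'
#' @param flags Significance flags from [run_factorial_de()].
#' @param truth Ground-truth tibble (`gene`, `class`).
#' @param effect Effect class to evaluate.
#' @return One-row tibble: `effect`, `n_true`, `n_called`, `sensitivity`,
#'   `fdr`.
#' @export
effect_recovery <- function(flags, truth, effect) {
  true_classes <- if (effect == "interaction") "interaction" else {
    c(effect, "interaction")
  }
  truth_genes <- toupper(truth$gene[truth$class %in% true_classes])
  called <- toupper(flags$gene[flags[[effect]]])
  tp <- length(intersect(called, truth_genes))
  tibble::tibble(
    effect = effect,
    n_true = length(truth_genes),
    n_called = length(called),
    sensitivity = if (length(truth_genes)) tp / length(truth_genes)
                  else NA_real_,
    fdr = if (length(called)) 1 - tp / length(called) else 0
  )
}
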