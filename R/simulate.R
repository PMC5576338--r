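#' Configuration for the synthetic factorial study
#'
#' Defines the generative model of the synthetic study: a 2x2 (genotype x
#' oxygen) design with `replicates_per_group` lungs per group, log2-scale
#' baselines `Normal(baseline_mean, baseline_sd)`, additive log2 effects of
#' magnitude `beta_*` planted in disjoint fractions `f_*` of genes, Gaussian
#' measurement noise `noise_sd`, pathway sets of size `pathway_size` drawing
#' a fraction `enrichment_purity` of members from their target effect class,
#' and Ct values derived from the expression values with noise `ct_sd`.
#'
#' One global `seed` governs every sub-generator: each generator draws from a
#' sub-stream derived as `(seed * 1103 + stream_offset) mod (2^31 - 1)`, with
#' offsets 1 (expression), 2 (pathways), 3 (Ct).
#'
#' @param n_genes Number of genes.
#' @param replicates_per_group Replicates per group (default 3, the typical
#'   per-group lung count in neonatal mouse hyperoxia studies).
#' @param baseline_mean,baseline_sd Log2 baseline distribution (defaults 7
#'   and 1.5, typical of RMA-summarized arrays).
#' @param noise_sd Residual log2 noise (default 0.5).
#' @param f_genotype,f_oxygen,f_interaction Fractions of genes carrying each
#'   effect (disjoint classes; must sum to <= 1).
#' @param beta_genotype,beta_oxygen,beta_interaction Effect magnitudes in
#'   log2 units. Main effects default to 2 (4-fold). The interaction term
#'   defaults to 4 because it enters only the KO-hyperoxia cell: its
#'   interaction contrast carries a quarter of the noncentrality of an
#'   equal-magnitude main effect, so a detectable interaction at 3
#'   replicates per group needs roughly twice the log2 magnitude.
#' @param n_pathways,pathway_size Gene-set collection shape.
#' @param planted_fraction Fraction of pathways planted on an effect class.
#' @param enrichment_purity Fraction of a planted set's members drawn from
#'   its target class.
#' @param redundant_fraction Fraction of planted pathways that also emit a
#'   redundant companion set (a sub-segment sharing most of the parent's
#'   genes), emulating the overlapping pathway-map entries that make
#'   mega-pathway clustering necessary in curated ontologies.
#' @param ct_intercept,ct_reference,ct_sd Ct generation: target Ct is
#'   `ct_intercept - expression + Normal(0, ct_sd)`; reference Ct is
#'   `ct_reference + Normal(0, ct_sd)` per sample.
#' @param seed Global RNG seed.
#' @return A validated `sim_config` list.
#' @export
simulation_config <- function(n_genes = 2000,
                              replicates_per_group = 3,
                              baseline_mean = 7,
                              baseline_sd = 1.5,
                              noise_sd = 0.5,
                              f_genotype = 0.05,
                              f_oxygen = 0.10,
                              f_interaction = 0.05,
                              beta_genotype = 2,
                              beta_oxygen = 2,
                              beta_interaction = 4,
                              n_pathways = 40,
                              pathway_size = 25,
                              planted_fraction = 0.5,
                              enrichment_purity = 0.8,
                              redundant_fraction = 0.2,
                              ct_intercept = 35,
                              ct_reference = 12,
                              ct_sd = 0.15,
                              seed = 1L) {
  cfg <- as.list(environment())
  problems <- character(0)
  chk <- function(ok, msg) if (!ok) problems <<- c(problems, msg)
  chk(n_genes >= 1, "n_genes must be >= 1")
  chk(replicates_per_group >= 2, "replicates_per_group must be >= 2")
  chk(baseline_sd > 0, "baseline_sd must be > 0")
  chk(noise_sd > 0, "noise_sd must be > 0")
  chk(all(c(f_genotype, f_oxygen, f_interaction) >= 0),
      "effect fractions must be non-negative")
  chk(f_genotype + f_oxygen + f_interaction <= 1,
      "effect fractions must sum to <= 1")
  chk(n_pathways >= 1, "n_pathways must be >= 1")
  chk(pathway_size >= 1 && pathway_size <= n_genes,
      "pathway_size must lie in [1, n_genes]")
  chk(planted_fraction >= 0 && planted_fraction <= 1,
      "planted_fraction must lie in [0, 1]")
  chk(enrichment_purity >= 0 && enrichment_purity <= 1,
      "enrichment_purity must lie in [0, 1]")
  chk(redundant_fraction >= 0 && redundant_fraction <= 1,
      "redundant_fraction must lie in [0, 1]")
  chk(ct_sd >= 0, "ct_sd must be >= 0")
  if (length(problems)) {
    stop("invalid simulation config:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Read a simulation config from YAML or JSON
#'
#' @param path Path to a YAML/JSON file with `simulation_config()` fields.
#' @return A validated `sim_config`.
#' @export
read_simulation_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(simulation_config, cfg)
}

split_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1103 + stream) %% (2^31 - 1))
}

sim_gene_ids <- function(n) sprintf("GENE%05d", seq_len(n))

#' Simulate a factorial expression study with planted effects
#'
#' Generates a log2 expression matrix under the additive model
#' `x(g, s) = mu_g + beta_G * KO(s) + beta_O * HO(s) + beta_I * KO(s)*HO(s)
#' + eps`, where each effect term is present only for genes of that class,
#' `mu_g ~ Normal(baseline_mean, baseline_sd)` and
#' `eps ~ Normal(0, noise_sd)`. Gene classes (`null`, `genotype`, `oxygen`,
#' `interaction`) are assigned to a random disjoint split of the genes in the
#' configured fractions.
#'
#' @param config A `sim_config` from [simulation_config()].
#' @return A list with `expr` (expression tibble, tagged log2), `design`
#'   (sample design) and `truth` (tibble `gene`, `class`).
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::local_seed(split_seed(config$seed, 1L))
  n <- config$n_genes
  genes <- sim_gene_ids(n)

  n_g <- round(config$f_genotype * n)
  n_o <- round(config$f_oxygen * n)
  n_i <- round(config$f_interaction * n)
  class <- rep("null", n)
  picked <- sample.int(n, n_g + n_o + n_i)
  class[picked] <- rep(c("genotype", "oxygen", "interaction"),
                       times = c(n_g, n_o, n_i))

  reps <- config$replicates_per_group
  design <- tibble::tibble(
    sample = unlist(lapply(group_levels(), function(g) {
      paste0(g, "_", seq_len(reps))
    })),
    genotype = rep(c("WT", "WT", "KO", "KO"), each = reps),
    oxygen = rep(c("RA", "HO", "RA", "HO"), each = reps)
  )
  design <- as_sample_design(design)

  ko <- as.numeric(design$genotype == "KO")
  ho <- as.numeric(design$oxygen == "HO")
  mu <- stats::rnorm(n, config$baseline_mean, config$baseline_sd)
  effect <- matrix(0, n, nrow(design))
  plant <- function(cls, beta, indicator) {
    k <- sum(class == cls)
    if (k > 0) {
      effect[class == cls, ] <<- beta * matrix(indicator, k, nrow(design),
                                               byrow = TRUE)
    }
  }
  plant("genotype", config$beta_genotype, ko)
  plant("oxygen", config$beta_oxygen, ho)
  plant("interaction", config$beta_interaction, ko * ho)
  noise <- matrix(stats::rnorm(n * nrow(design), 0, config$noise_sd),
                  n, nrow(design))
  m <- mu + effect + noise
  dimnames(m) <- list(genes, design$sample)

  list(
    expr = expr_tibble(m, scale_tag = "log2"),
    design = design,
    truth = tibble::tibble(gene = genes, class = class)
  )
}

#' Simulate a gene-set collection with planted enrichment
#'
#' A configurable fraction of pathways is planted on an effect class: a
#' planted set draws `enrichment_purity` of its members from that class
#' (without replacement, topping up from the remainder when the class is
#' small) and the rest uniformly from the remaining genes. Null sets draw
#' uniformly from all genes. Planted classes cycle over the effect classes
#' that actually contain genes. A fraction `redundant_fraction` of the
#' planted pathways additionally emits a companion sub-segment set (id
#' suffix `"R"`) that keeps most of its parent's genes, so the collection
#' shows the redundancy that mega-pathway clustering is meant to collapse.
#'
#' @param truth Ground-truth tibble from [simulate_expression()].
#' @param config A `sim_config`.
#' @return A gene-set tibble (`set_id`, `description`, `genes`, `n_genes`)
#'   with the planted class in the `planted_class` column (`"null"` for
#'   unplanted sets).
#' @export
simulate_pathways <- function(truth, config) {
  stopifnot(inherits(config, "sim_config"), nrow(truth) > 0)
  if (config$pathway_size > nrow(truth)) {
    stop("pathway_size exceeds number of genes", call. = FALSE)
  }
  withr::local_seed(split_seed(config$seed, 2L))
  classes <- intersect(c("genotype", "oxygen", "interaction"),
                       unique(truth$class))
  n_planted <- if (length(classes)) {
    round(config$planted_fraction * config$n_pathways)
  } else 0L
  planted_class <- c(
    if (n_planted > 0) rep(classes, length.out = n_planted),
    rep("null", config$n_pathways - n_planted)
  )
  size <- config$pathway_size
  rho <- config$enrichment_purity
  genes_by_class <- split(truth$gene, truth$class)

  draw_set <- function(cls) {
    if (cls == "null") return(sample(truth$gene, size))
    pool <- genes_by_class[[cls]]
    n_in <- min(round(rho * size), length(pool))
    inside <- sample(pool, n_in)
    # remainder drawn uniformly from all not-yet-chosen genes, so rho = 0
    # reduces exactly to a null (uniform) set
    outside <- sample(setdiff(truth$gene, inside), size - n_in)
    sample(c(inside, outside))
  }
  out <- tibble::tibble(
    set_id = sprintf("PW%03d", seq_len(config$n_pathways)),
    description = paste0("synthetic pathway (planted: ", planted_class, ")"),
    genes = lapply(planted_class, draw_set),
    n_genes = size,
    planted_class = planted_class
  )

  parents <- which(out$planted_class != "null")
  n_red <- min(length(parents),
               round(config$redundant_fraction * config$n_pathways))
  if (n_red > 0) {
    companions <- purrr::map_dfr(parents[seq_len(n_red)], function(i) {
      keep <- sample(out$genes[[i]], round(0.7 * size))
      cls <- out$planted_class[[i]]
      pool <- setdiff(genes_by_class[[cls]], keep)
      n_fill <- size - length(keep)
      n_in <- min(round(rho * n_fill), length(pool))
      inside <- sample(pool, n_in)
      fill <- c(inside,
                sample(setdiff(truth$gene, c(keep, inside)), n_fill - n_in))
      tibble::tibble(
        set_id = paste0(out$set_id[[i]], "R"),
        description = paste0("synthetic pathway (redundant sub-segment of ",
                             out$set_id[[i]], ")"),
        genes = list(sample(c(keep, fill))),
        n_genes = size,
        planted_class = cls
      )
    })
    out <- dplyr::bind_rows(out, companions)
  }
  out
}

#' Simulate a qPCR Ct table consistent with the expression matrix
#'
#' Target Ct decreases linearly with log2 expression
#' (`target_ct = ct_intercept - x(g, s) + Normal(0, ct_sd)`); the reference
#' gene's Ct is constant per sample up to the same noise. With `ct_sd = 0`,
#' downstream 2^-ddCt group fold changes equal `2^(group mean log2
#' difference)` exactly.
#'
#' @param expr Expression tibble from [simulate_expression()].
#' @param genes Genes to assay (subset of the matrix's gene ids).
#' @param config A `sim_config`.
#' @return A validated Ct tibble.
#' @export
simulate_ct <- function(expr, genes, config) {
  stopifnot(inherits(config, "sim_config"))
  m <- expr_matrix(expr)
  idx <- match(toupper(genes), rownames(m))
  if (anyNA(idx)) {
    stop("unknown gene(s): ", paste(genes[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  withr::local_seed(split_seed(config$seed, 3L))
  samples <- colnames(m)
  grid <- expand.grid(gene = genes, sample = samples,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  x <- m[cbind(match(toupper(grid$gene), rownames(m)),
               match(grid$sample, samples))]
  ref_ct <- stats::setNames(
    config$ct_reference + stats::rnorm(length(samples), 0, config$ct_sd),
    samples
  )
  ct <- tibble::tibble(
    gene = grid$gene,
    sample = grid$sample,
    target_ct = config$ct_intercept - x +
      stats::rnorm(nrow(grid), 0, config$ct_sd),
    reference_ct = unname(ref_ct[grid$sample])
  )
  as_ct_table(ct, ct_range = c(-Inf, Inf))
}
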