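#' Read a genes-by-samples expression matrix
#'
#' Ingests a wide expression table: one row per gene, one column per sample,
#' values on the log2 (or linear) scale. Two dialects are supported:
#'
#' * `"delimited"` — plain tab- or comma-delimited text with one header row of
#'   sample ids and gene ids in the first column;
#' * `"geo_series_matrix"` — the GEO Series Matrix flavour, where metadata
#'   lines start with `!` and the value block sits between
#'   `!series_matrix_table_begin` and `!series_matrix_table_end`.
#'
#' Rows containing any missing value are dropped (the count is recorded in the
#' `"n_dropped_na"` attribute). Duplicate gene ids (after uppercase
#' normalisation) are resolved by keeping the row with the highest mean; each
#' such event is recorded in the `"dedup_events"` attribute and messaged.
#'
#' @param path Path to the file.
#' @param dialect One of `"delimited"`, `"geo_series_matrix"`.
#' @param scale_tag Declared scale of the values: `"log2"`, `"linear"` or
#'   `"unknown"`. Stored as an attribute; downstream log transforms consult it.
#' @return A tibble with column `gene` followed by one numeric column per
#'   sample, carrying attributes `scale_tag`, `n_dropped_na` and
#'   `dedup_events`.
#' @export
read_expression_matrix <- function(path,
                                   dialect = c("delimited", "geo_series_matrix"),
                                   scale_tag = c("log2", "linear", "unknown")) {
  dialect <- match.arg(dialect)
  scale_tag <- match.arg(scale_tag)
  if (!file.exists(path)) {
    stop("expression matrix file does not exist: ", path, call. = FALSE)
  }
  lines <- readr::read_lines(path)
  if (dialect == "geo_series_matrix") {
    begin <- which(trimws(lines) == "!series_matrix_table_begin")
    end <- which(trimws(lines) == "!series_matrix_table_end")
    if (length(begin) != 1L || length(end) != 1L || end <= begin + 1L) {
      stop("malformed GEO series matrix: table sentinels missing or empty block",
           call. = FALSE)
    }
    lines <- lines[(begin + 1L):(end - 1L)]
  } else {
    lines <- lines[!startsWith(lines, "#")]
  }
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("empty expression matrix: ", path, call. = FALSE)

  sep <- if (grepl("\t", lines[[1L]])) "\t" else ","
  fields <- strsplit(lines, sep, fixed = TRUE)
  header <- fields[[1L]]
  if (length(header) < 2L) {
    stop("malformed header at line 1: expected gene column plus >=1 sample",
         call. = FALSE)
  }
  sample_ids <- unquote_geo(header[-1L])
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids in header: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }

  body <- fields[-1L]
  bad <- which(vapply(body, length, integer(1)) != length(header))
  if (length(bad)) {
    stop("malformed row at line ", bad[[1L]] + 1L, ": wrong field count",
         call. = FALSE)
  }
  genes <- unquote_geo(vapply(body, `[[`, character(1), 1L))
  vals <- matrix(NA_real_, nrow = length(body), ncol = length(sample_ids),
                 dimnames = list(NULL, sample_ids))
  for (j in seq_along(sample_ids)) {
    raw <- vapply(body, `[[`, character(1), j + 1L)
    raw[raw %in% c("", "NA", "null", "NULL")] <- NA
    v <- suppressWarnings(as.numeric(raw))
    broken <- which(!is.na(raw) & is.na(v))
    if (length(broken)) {
      stop("non-numeric value for gene '", genes[broken[[1L]]],
           "', sample '", sample_ids[[j]], "'", call. = FALSE)
    }
    vals[, j] <- v
  }

  keep <- stats::complete.cases(vals)
  n_dropped <- sum(!keep)
  if (n_dropped > 0L) {
    message(n_dropped, " gene row(s) with missing values dropped")
    vals <- vals[keep, , drop = FALSE]
    genes <- genes[keep]
  }
  if (nrow(vals) == 0L) stop("empty expression matrix after filtering", call. = FALSE)

  key <- toupper(genes)
  dedup_events <- character(0)
  if (anyDuplicated(key)) {
    means <- rowMeans(vals)
    ord <- order(match(key, unique(key)), -means)
    first <- !duplicated(key[ord])
    dropped_keys <- unique(key[ord][!first])
    dedup_events <- dropped_keys
    message(length(ord) - sum(first), " duplicate gene row(s) collapsed ",
            "(kept highest-mean row): ", paste(dropped_keys, collapse = ", "))
    sel <- sort(ord[first])
    vals <- vals[sel, , drop = FALSE]
    genes <- genes[sel]
  }

  out <- tibble::as_tibble(as.data.frame(vals, check.names = FALSE))
  out <- tibble::add_column(out, gene = genes, .before = 1L)
  attr(out, "scale_tag") <- scale_tag
  attr(out, "n_dropped_na") <- n_dropped
  attr(out, "dedup_events") <- dedup_events
  out
}

# GEO series matrix files quote their identifiers
unquote_geo <- function(x) gsub('^"|"$', "", trimws(x))

#' Read a sample design table
#'
#' The design assigns every sample to one genotype level (`WT`/`KO`) and one
#' oxygen level (`RA` for room air / `HO` for hyperoxia), defining the four
#' groups of the 2x2 factorial.
#'
#' @param path Delimited text with columns `sample`, `genotype`, `oxygen`.
#' @return A tibble with columns `sample`, `genotype`, `oxygen`, `group`
#'   (e.g. `WT_RA`).
#' @export
read_sample_design <- function(path) {
  d <- readr::read_delim(path, delim = guess_sep(path), show_col_types = FALSE,
                         trim_ws = TRUE)
  names(d) <- tolower(names(d))
  required <- c("sample", "genotype", "oxygen")
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols)) {
    stop("design table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  as_sample_design(d[required])
}

#' Build and validate a sample design tibble
#'
#' @param design A data frame with columns `sample`, `genotype` (`WT`/`KO`) and
#'   `oxygen` (`RA`/`HO`).
#' @return A validated design tibble with a derived `group` column.
#' @export
as_sample_design <- function(design) {
  design <- tibble::as_tibble(design)
  stopifnot(all(c("sample", "genotype", "oxygen") %in% names(design)))
  design$sample <- as.character(design$sample)
  design$genotype <- as.character(design$genotype)
  design$oxygen <- as.character(design$oxygen)
  if (anyDuplicated(design$sample)) {
    stop("duplicate sample ids in design", call. = FALSE)
  }
  if (!all(design$genotype %in% c("WT", "KO"))) {
    stop("genotype must be 'WT' or 'KO'", call. = FALSE)
  }
  if (!all(design$oxygen %in% c("RA", "HO"))) {
    stop("oxygen must be 'RA' or 'HO'", call. = FALSE)
  }
  design$group <- paste(design$genotype, design$oxygen, sep = "_")
  counts <- table(factor(design$group, levels = group_levels()))
  if (any(counts == 0L)) {
    stop("all four groups must be non-empty; missing: ",
         paste(names(counts)[counts == 0L], collapse = ", "), call. = FALSE)
  }
  design
}

group_levels <- function() c("WT_RA", "WT_HO", "KO_RA", "KO_HO")

#' Read a gene-set collection in GMT format
#'
#' Each line holds at least three tab-separated fields: set id, description,
#' then member gene ids. Member ids are uppercased so they match expression
#' gene ids; duplicates within a line are collapsed.
#'
#' @param path Path to the GMT file.
#' @return A tibble with columns `set_id`, `description`, `genes`
#'   (list-column of character vectors) and `n_genes`, preserving file order.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file does not exist: ", path, call. = FALSE)
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty GMT file: ", path, call. = FALSE)
    return(tibble::tibble(set_id = character(), description = character(),
                          genes = list(), n_genes = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, integer(1)) < 3L)
  if (length(short)) {
    stop("GMT parse error at line ", short[[1L]],
         ": fewer than 3 tab-separated fields", call. = FALSE)
  }
  out <- tibble::tibble(
    set_id = vapply(fields, `[[`, character(1), 1L),
    description = vapply(fields, `[[`, character(1), 2L),
    genes = lapply(fields, function(f) unique(toupper(f[-(1:2)])))
  )
  if (anyDuplicated(out$set_id)) {
    stop("duplicate set ids in GMT: ",
         paste(unique(out$set_id[duplicated(out$set_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(lengths(out$genes) == 0L)) stop("empty gene set in GMT", call. = FALSE)
  out$n_genes <- lengths(out$genes)
  out
}

#' Write a gene-set collection to GMT
#'
#' @param sets Tibble as returned by [read_gmt()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- purrr::pmap_chr(
    list(sets$set_id, sets$description, sets$genes),
    function(id, desc, genes) paste(c(id, desc, genes), collapse = "\t")
  )
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a qPCR Ct table
#'
#' @param path Delimited text with columns `gene`, `sample`, `target_ct`,
#'   `reference_ct` (threshold cycles for the target and the reference gene,
#'   e.g. 18S rRNA).
#' @param ct_range Plausible Ct range; values outside it are rejected.
#' @return A validated tibble of per-(gene, sample) Ct records.
#' @export
read_ct_table <- function(path, ct_range = c(0, 45)) {
  d <- readr::read_delim(path, delim = guess_sep(path), show_col_types = FALSE,
                         trim_ws = TRUE)
  names(d) <- tolower(names(d))
  as_ct_table(d, ct_range = ct_range)
}

#' Validate a Ct table
#'
#' @inheritParams read_ct_table
#' @param ct A data frame with columns `gene`, `sample`, `target_ct`,
#'   `reference_ct`.
#' @return The validated tibble.
#' @export
as_ct_table <- function(ct, ct_range = c(0, 45)) {
  ct <- tibble::as_tibble(ct)
  required <- c("gene", "sample", "target_ct", "reference_ct")
  missing_cols <- setdiff(required, names(ct))
  if (length(missing_cols)) {
    stop("Ct table missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  ct <- ct[required]
  ct$gene <- as.character(ct$gene)
  ct$sample <- as.character(ct$sample)
  for (col in c("target_ct", "reference_ct")) {
    v <- ct[[col]]
    if (!is.numeric(v) || any(!is.finite(v))) {
      stop("non-finite ", col, " values", call. = FALSE)
    }
    if (any(v < ct_range[[1L]] | v > ct_range[[2L]])) {
      stop(col, " outside plausible range [", ct_range[[1L]], ", ",
           ct_range[[2L]], "]", call. = FALSE)
    }
  }
  if (anyDuplicated(ct[c("gene", "sample")])) {
    stop("duplicate (gene, sample) pairs in Ct table", call. = FALSE)
  }
  ct
}

#' Write a results table deterministically
#'
#' Rows are sorted by gene id (or by the first column when no `gene` column
#' exists), columns keep their order, and numeric values are written with 15
#' significant digits so the table round-trips losslessly.
#'
#' @param records Data frame of results.
#' @param path Output path.
#' @param allow_empty Permit writing a header-only table.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(records, path, allow_empty = FALSE) {
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0L && !allow_empty) {
    stop("refusing to write empty results table (set allow_empty = TRUE)",
         call. = FALSE)
  }
  key <- if ("gene" %in% names(records)) records$gene else records[[1L]]
  records <- records[order(key, method = "radix"), , drop = FALSE]
  num <- vapply(records, is.numeric, logical(1))
  records[num] <- lapply(records[num], function(x) formatC(x, digits = 15, format = "g"))
  readr::write_tsv(records, path)
  invisible(path)
}

#' Read a results table written by [write_results_table()]
#'
#' @param path Path to the TSV.
#' @return A tibble with numeric columns restored.
#' @export
read_results_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

guess_sep <- function(path) {
  first <- readr::read_lines(path, n_max = 1L)
  if (length(first) && grepl("\t", first)) "\t" else ","
}
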