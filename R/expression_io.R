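#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
NULL

#' Genotype tokens of the reference design
#'
#' The three TGFb3 alleles in display order: `hom` (TGFb3-/-, knockout with
#' cleft phenotype), `het` (TGFb3+/-, phenotypically normal), `wt` (wildtype).
#' @export
GENOTYPE_LEVELS <- c("hom", "het", "wt")

#' Default palatogenesis stage order
#'
#' E14.5 (palatal shelf elevation/growth), E15.5 (adhesion, midline epithelial
#' seam formation), E16.5 (fusion). Stage order is configuration, never a
#' lexical sort.
#' @export
DEFAULT_STAGES <- c("E14.5", "E15.5", "E16.5")

#' Normalize a gene symbol for identity comparison
#'
#' Symbols are compared case-insensitively after whitespace trimming, because
#' curated panels mix mouse title-case and human upper-case forms of the same
#' gene. The display form is always preserved alongside.
#'
#' @param x character vector of gene symbols.
#' @return character vector of normalized (trimmed, upper-cased) keys.
#' @export
norm_symbol <- function(x) toupper(trimws(x))

pm_abort <- function(msg, class = "palmotif_validation_error") {
  rlang::abort(msg, class = class)
}

#' Construct a validated expression matrix
#'
#' The canonical container of the pipeline: a non-negative FPKM matrix
#' (genes x samples) plus per-sample design metadata, modelled on the
#' matrix-plus-samples lists used throughout expression analysis.
#'
#' @param values numeric matrix of FPKM, rownames = gene symbols (display
#'   form), colnames = sample ids.
#' @param samples data frame with columns `sample_id`, `genotype`
#'   (`hom`/`het`/`wt`), `stage`, `bio_rep`, `tech_rep`; one row per matrix
#'   column, in column order.
#' @param stage_order character vector giving the developmental ordering of
#'   stage labels.
#' @return an object of class `ExpressionMatrix`: a list with elements
#'   `values`, `samples` (tibble) and `stage_order`.
#' @export
expression_matrix <- function(values, samples,
                              stage_order = DEFAULT_STAGES) {
  if (!is.matrix(values) || !is.numeric(values)) {
    pm_abort("`values` must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    pm_abort("`values` must carry gene rownames and sample colnames")
  }
  samples <- as_tibble(samples)
  needed <- c("sample_id", "genotype", "stage", "bio_rep", "tech_rep")
  missing_cols <- setdiff(needed, names(samples))
  if (length(missing_cols)) {
    pm_abort(paste0("sample sheet lacks column(s): ",
                    paste(missing_cols, collapse = ", ")))
  }
  samples$bio_rep <- as.integer(samples$bio_rep)
  samples$tech_rep <- as.integer(samples$tech_rep)

  bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    g <- rownames(values)[bad[1, "row"]]
    s <- colnames(values)[bad[1, "col"]]
    pm_abort(sprintf(
      "FPKM values must be finite and non-negative; first offender: gene '%s', sample '%s' (value %s)",
      g, s, format(values[bad[1, "row"], bad[1, "col"]])))
  }
  key <- norm_symbol(rownames(values))
  if (anyDuplicated(key)) {
    dups <- unique(rownames(values)[key %in% key[duplicated(key)]])
    pm_abort(paste0("duplicate gene symbol(s) after case normalization: ",
                    paste(dups, collapse = ", ")))
  }
  if (anyDuplicated(samples$sample_id)) {
    pm_abort(paste0("duplicate sample_id in sample sheet: ",
                    paste(unique(samples$sample_id[duplicated(samples$sample_id)]),
                          collapse = ", ")))
  }
  design_key <- with(samples, paste(genotype, stage, bio_rep, tech_rep))
  if (anyDuplicated(design_key)) {
    pm_abort(paste0("duplicate (genotype, stage, bio_rep, tech_rep) design cell: ",
                    paste(unique(design_key[duplicated(design_key)]), collapse = "; ")))
  }
  unknown_gt <- setdiff(unique(samples$genotype), GENOTYPE_LEVELS)
  if (length(unknown_gt)) {
    pm_abort(paste0("unknown genotype token(s): ",
                    paste(unknown_gt, collapse = ", "),
                    " (expected hom|het|wt)"))
  }
  unknown_stage <- setdiff(unique(samples$stage), stage_order)
  if (length(unknown_stage)) {
    pm_abort(paste0("stage token(s) not in configured stage order: ",
                    paste(unknown_stage, collapse = ", ")))
  }
  if (!setequal(colnames(values), samples$sample_id) ||
      ncol(values) != nrow(samples)) {
    only_m <- setdiff(colnames(values), samples$sample_id)
    only_s <- setdiff(samples$sample_id, colnames(values))
    pm_abort(paste0(
      "matrix columns and sample sheet disagree",
      if (length(only_m)) paste0("; matrix-only: ", paste(only_m, collapse = ", ")) else "",
      if (length(only_s)) paste0("; sheet-only: ", paste(only_s, collapse = ", ")) else ""))
  }
  samples <- samples[match(colnames(values), samples$sample_id), , drop = FALSE]

  structure(list(values = values, samples = samples,
                 stage_order = stage_order),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  cat("  genotypes:", paste(intersect(GENOTYPE_LEVELS, unique(x$samples$genotype)),
                            collapse = ", "), "\n")
  cat("  stages:   ", paste(x$stage_order, collapse = " < "), "\n")
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Load an expression matrix and its sample sheet from TSV
#'
#' The matrix file is tab-separated with header `gene_id` followed by one
#' column per sample; the sample sheet has columns `sample_id`, `genotype`,
#' `stage`, `bio_rep`, `tech_rep`. Lines starting with `#` are ignored in
#' both files. Every matrix column must have exactly one sheet row.
#'
#' @param path_matrix path to the FPKM matrix TSV.
#' @param path_samples path to the sample sheet TSV.
#' @param stage_order developmental ordering of stage labels.
#' @param fill_zero if `TRUE`, empty FPKM cells are substituted with 0.0 (a
#'   message is emitted); by default an empty cell is an error.
#' @return an [expression_matrix()].
#' @export
load_expression <- function(path_matrix, path_samples,
                            stage_order = DEFAULT_STAGES,
                            fill_zero = FALSE) {
  for (p in c(path_matrix, path_samples)) {
    if (!file.exists(p)) pm_abort(paste0("input file not found: ", p))
  }
  raw <- readr::read_tsv(path_matrix, comment = "#",
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (names(raw)[1] != "gene_id") {
    pm_abort("matrix TSV must start with a 'gene_id' column")
  }
  genes <- trimws(raw$gene_id)
  sample_ids <- names(raw)[-1]
  if (!length(sample_ids)) pm_abort("matrix TSV has no sample columns")

  vals <- matrix(NA_real_, nrow = length(genes), ncol = length(sample_ids),
                 dimnames = list(genes, sample_ids))
  for (j in seq_along(sample_ids)) {
    col <- raw[[j + 1L]]
    empty <- is.na(col) | !nzchar(trimws(col))
    num <- suppressWarnings(as.numeric(col))
    bad <- which(!empty & is.na(num))
    if (length(bad)) {
      pm_abort(sprintf("non-numeric FPKM '%s' for gene '%s', sample '%s'",
                       col[bad[1]], genes[bad[1]], sample_ids[j]))
    }
    if (any(empty)) {
      if (fill_zero) {
        message(sprintf("filling %d empty cell(s) in sample '%s' with 0.0",
                        sum(empty), sample_ids[j]))
        num[empty] <- 0
      } else {
        pm_abort(sprintf("empty FPKM cell for gene '%s', sample '%s' (use fill_zero = TRUE to substitute 0)",
                         genes[which(empty)[1]], sample_ids[j]))
      }
    }
    neg <- which(num < 0)
    if (length(neg)) {
      pm_abort(sprintf("negative FPKM %s for gene '%s', sample '%s'",
                       format(num[neg[1]]), genes[neg[1]], sample_ids[j]))
    }
    vals[, j] <- num
  }

  sheet <- readr::read_tsv(path_samples, comment = "#",
                           col_types = readr::cols(
                             sample_id = readr::col_character(),
                             genotype = readr::col_character(),
                             stage = readr::col_character(),
                             bio_rep = readr::col_integer(),
                             tech_rep = readr::col_integer()),
                           progress = FALSE)
  expression_matrix(vals, sheet, stage_order = stage_order)
}

#' Write an expression matrix and sample sheet back to TSV
#'
#' Inverse of [load_expression()]; `load(write(x))` is the identity on
#' content.
#'
#' @param em an `ExpressionMatrix`.
#' @param path_matrix,path_samples output paths.
#' @export
write_expression <- function(em, path_matrix, path_samples) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  df <- as_tibble(em$values, rownames = "gene_id")
  write_table(df, path_matrix)
  write_table(em$samples, path_samples)
  invisible(NULL)
}

#' Write a tabular result as TSV
#'
#' Tab-separated, UTF-8, '.' decimal separator, header always written (an
#' empty result yields a header-only file).
#'
#' @param rows data frame of results.
#' @param path output path.
#' @export
write_table <- function(rows, path) {
  rows <- as.data.frame(rows)
  if (!ncol(rows)) pm_abort("cannot write a table with no columns")
  readr::write_tsv(rows, path, progress = FALSE)
  invisible(NULL)
}

#' Read a TSV table written by [write_table()]
#'
#' @param path input path.
#' @return a tibble; `#`-prefixed lines are ignored.
#' @export
load_table <- function(path) {
  if (!file.exists(path)) pm_abort(paste0("input file not found: ", path))
  readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
}
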