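#' Construct a gene panel
#'
#' @param entries tibble with columns `symbol`, `source`
#'   (`mouse`/`human`/`common`) and optionally `ortholog_symbol`, `notes`.
#' @param name short panel name.
#' @param provenance free-text description of where the entries came from.
#' @return an object of class `GenePanel`.
#' @export
gene_panel <- function(entries, name = "panel", provenance = "") {
  entries <- tibble::as_tibble(entries)
  if (!all(c("symbol", "source") %in% names(entries))) {
    pm_abort("panel entries need columns 'symbol' and 'source'")
  }
  if (!"ortholog_symbol" %in% names(entries)) entries$ortholog_symbol <- NA_character_
  entries$symbol <- trimws(entries$symbol)
  if (any(!nzchar(entries$symbol))) pm_abort("panel contains an empty gene symbol")
  bad_src <- setdiff(unique(entries$source), c("mouse", "human", "common"))
  if (length(bad_src)) {
    pm_abort(paste0("unknown panel source token(s): ",
                    paste(bad_src, collapse = ", ")))
  }
  key <- norm_symbol(entries$symbol)
  if (anyDuplicated(key)) {
    coll <- unique(entries$symbol[key %in% key[duplicated(key)]])
    pm_abort(paste0("duplicate panel symbol(s) after case normalization: ",
                    paste(coll, collapse = ", ")))
  }
  structure(list(entries = entries, name = name, provenance = provenance),
            class = "GenePanel")
}

#' @export
print.GenePanel <- function(x, ...) {
  cat(sprintf("GenePanel '%s': %d genes (%s)\n", x$name, nrow(x$entries),
              paste(sprintf("%s %d", names(table(x$entries$source)),
                            as.integer(table(x$entries$source))),
                    collapse = ", ")))
  invisible(x)
}

#' @export
length.GenePanel <- function(x) nrow(x$entries)

#' Load a gene panel from TSV
#'
#' Expects columns `symbol`, `source` and optionally `ortholog_symbol`,
#' `notes`; `#` lines are comments. Duplicate symbols (case-insensitive) are
#' rejected.
#'
#' @param path panel TSV path.
#' @param name,provenance passed to [gene_panel()].
#' @return a `GenePanel`.
#' @export
load_panel <- function(path, name = basename(path),
                       provenance = paste0("loaded from ", path)) {
  if (!file.exists(path)) pm_abort(paste0("panel file not found: ", path))
  entries <- readr::read_tsv(path, comment = "#",
                             col_types = readr::cols(.default = readr::col_character()),
                             progress = FALSE)
  gene_panel(entries, name = name, provenance = provenance)
}

#' The packaged 322-gene cleft-palate panel
#'
#' Genes whose disruption causes cleft palate in mouse (MGI-derived) or human
#' (OMIM-derived), shipped with the package as `cp_panel_table2.tsv`. Source
#' tags are heuristic (by symbol typography) and flagged as such in the
#' provenance.
#'
#' @return a `GenePanel` with 322 entries.
#' @export
cp_panel <- function() {
  path <- system.file("extdata", "cp_panel_table2.tsv", package = "palmotif",
                      mustWork = TRUE)
  load_panel(path, name = "cleft-palate panel (n = 322)",
             provenance = "packaged MGI/OMIM cleft-palate gene list; source tags heuristic by symbol case")
}

#' Merge mouse and human disease-gene lists through an ortholog map
#'
#' Human symbols are first mapped into mouse symbol space through a
#' user-supplied one-to-one ortholog map. Genes present (post-mapping) in
#' both lists become `common`; mouse-only genes `mouse`; mapped human-only
#' genes `human`. Unmapped human genes are excluded from the panel but
#' counted as non-orthologs in the report.
#'
#' @param mouse_list character vector of mouse gene symbols.
#' @param human_list character vector of human gene symbols.
#' @param ortholog_map data frame with columns `human_symbol`,
#'   `mouse_symbol`; human keys must be unique (ambiguous maps are rejected,
#'   not resolved).
#' @param name panel name.
#' @return list with elements `panel` (a `GenePanel`) and `report`, the
#'   latter carrying counts `n_mouse_input`, `n_human_input`, `n_common`,
#'   `n_human_only`, `n_non_ortholog`, `n_panel`.
#' @export
merge_species_lists <- function(mouse_list, human_list, ortholog_map,
                                name = "merged panel") {
  ortholog_map <- tibble::as_tibble(ortholog_map)
  if (!all(c("human_symbol", "mouse_symbol") %in% names(ortholog_map))) {
    pm_abort("ortholog map needs columns 'human_symbol' and 'mouse_symbol'")
  }
  mouse_list <- unique(trimws(mouse_list))
  human_list <- unique(trimws(human_list))
  hkey <- norm_symbol(ortholog_map$human_symbol)
  if (anyDuplicated(hkey)) {
    pm_abort(paste0("ambiguous ortholog map: duplicate human key(s) ",
                    paste(unique(ortholog_map$human_symbol[duplicated(hkey)]),
                          collapse = ", ")))
  }
  mouse_key <- norm_symbol(mouse_list)

  idx <- match(norm_symbol(human_list), hkey)
  mapped <- !is.na(idx)
  mapped_mouse <- ortholog_map$mouse_symbol[idx[mapped]]
  mapped_human <- human_list[mapped]
  is_common <- norm_symbol(mapped_mouse) %in% mouse_key

  common_mouse_key <- norm_symbol(mapped_mouse[is_common])
  mouse_entries <- tibble::tibble(
    symbol = mouse_list,
    source = ifelse(mouse_key %in% common_mouse_key, "common", "mouse"),
    ortholog_symbol = mapped_human[is_common][match(mouse_key,
                                                    common_mouse_key)])
  human_entries <- tibble::tibble(
    symbol = as.character(mapped_mouse[!is_common]),
    source = rep("human", sum(!is_common)),
    ortholog_symbol = as.character(mapped_human[!is_common]))

  entries <- dplyr::bind_rows(mouse_entries, human_entries)
  report <- list(
    n_mouse_input = length(mouse_list),
    n_human_input = length(human_list),
    n_common = sum(is_common),
    n_human_only = sum(!is_common),
    n_non_ortholog = sum(!mapped),
    n_panel = nrow(entries),
    non_ortholog = sort(human_list[!mapped]))
  panel <- gene_panel(entries, name = name,
                      provenance = "merged mouse/human lists via ortholog map")
  list(panel = panel, report = report)
}

#' Restrict an expression matrix to panel genes
#'
#' Gene identity is case-insensitive; panel genes absent from the matrix are
#' reported, not fatal. The operation is idempotent.
#'
#' @param em an `ExpressionMatrix`.
#' @param panel a `GenePanel`.
#' @return list with `matrix` (the restricted `ExpressionMatrix`) and
#'   `absent` (panel symbols not found in the matrix, sorted).
#' @export
panel_subset <- function(em, panel) {
  stopifnot(inherits(em, "ExpressionMatrix"), inherits(panel, "GenePanel"))
  pkey <- norm_symbol(panel$entries$symbol)
  gkey <- norm_symbol(rownames(em$values))
  keep <- gkey %in% pkey
  absent <- sort(panel$entries$symbol[!(pkey %in% gkey)])
  out <- expression_matrix(em$values[keep, , drop = FALSE], em$samples,
                           stage_order = em$stage_order)
  list(matrix = out, absent = absent)
}
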