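#' Render a pattern-grouped expression heatmap for one genotype
#'
#' Rows are genes grouped by pattern code (alphabetical within a group, gaps
#' between groups; empty groups are skipped), columns are that genotype's
#' samples in stage-then-replicate order, cell values are the rounded
#' log10(FPKM+1) of each replicate, drawn with a red-to-yellow ramp
#' (increasing intensity toward yellow = higher expression). The exact
#' plotted matrix is always written to a companion TSV: the figure is
#' advisory, the table is the record.
#'
#' @param em the `ExpressionMatrix` the pattern table was computed from.
#' @param table a pattern table from [classify_all()].
#' @param genotype genotype token to render.
#' @param path output image path (`.png`).
#' @param companion_tsv path for the plotted-values TSV; default derived
#'   from `path`.
#' @return invisibly, the plotted tibble (gene, pattern, one column per
#'   sample), or `NULL` when there is nothing to plot.
#' @export
render_pattern_heatmap <- function(em, table, genotype, path,
                                   companion_tsv = sub("\\.[A-Za-z]+$", ".tsv", path)) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  sub <- table[table$genotype == genotype, ]
  if (!nrow(sub)) {
    warning(sprintf("no genes to plot for genotype '%s'; no image written", genotype))
    return(invisible(NULL))
  }
  cfg <- attr(table, "threshold_config")
  decimals <- if (is.null(cfg)) 2L else cfg$decimals
  sub <- sub[order(sub$pattern, sub$gene), ]
  sel <- em$samples$genotype == genotype
  s <- em$samples[sel, ]
  ord <- order(match(s$stage, em$stage_order), s$bio_rep, s$tech_rep)
  cols <- s$sample_id[ord]
  mat <- em$values[match(sub$gene, rownames(em$values)), cols, drop = FALSE]
  mat <- matrix(transform_value(mat, decimals), nrow = nrow(mat),
                dimnames = list(sub$gene, cols))

  group_sizes <- table(factor(sub$pattern, names(PATTERN_CODES)))
  gaps <- cumsum(group_sizes[group_sizes > 0])
  pheatmap::pheatmap(
    mat, cluster_rows = FALSE, cluster_cols = FALSE,
    gaps_row = utils::head(unname(gaps), -1),
    color = grDevices::colorRampPalette(c("red", "yellow"))(100),
    main = sprintf("%s: %d genes in %d patterns", genotype, nrow(mat),
                   sum(group_sizes > 0)),
    filename = path, silent = TRUE)
  companion <- dplyr::bind_cols(
    tibble::tibble(gene = sub$gene, pattern = sub$pattern),
    tibble::as_tibble(mat))
  write_table(companion, companion_tsv)
  invisible(companion)
}

venn_region_xy <- function(k) {
  if (k == 2L) {
    list(centers = cbind(x = c(-0.45, 0.45), y = c(0, 0)), r = 0.85,
         regions = rbind("10" = c(-0.85, 0), "01" = c(0.85, 0),
                         "11" = c(0, 0)))
  } else {
    list(centers = cbind(x = c(0, -0.5, 0.5), y = c(0.5, -0.37, -0.37)),
         r = 0.85,
         regions = rbind("100" = c(0, 1.0), "010" = c(-0.95, -0.75),
                         "001" = c(0.95, -0.75), "110" = c(-0.55, 0.2),
                         "101" = c(0.55, 0.2), "011" = c(0, -0.65),
                         "111" = c(0, 0)))
  }
}

#' Render a Venn diagram for a set comparison
#'
#' Circles are schematic (not area-proportional); the counts printed in each
#' region are exactly the [venn_partition()] region counts.
#'
#' @param comparison a `SetComparison` from [venn_partition()].
#' @param path output image path (`.png`).
#' @param width,height image size in pixels.
#' @return invisibly, the region tibble that was drawn.
#' @export
render_venn <- function(comparison, path, width = 640, height = 640) {
  stopifnot(inherits(comparison, "SetComparison"))
  labels <- attr(comparison, "labels")
  k <- length(labels)
  geo <- venn_region_xy(k)
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off(), add = TRUE)
  graphics::plot.new()
  graphics::plot.window(xlim = c(-1.7, 1.7), ylim = c(-1.7, 1.9), asp = 1)
  th <- seq(0, 2 * pi, length.out = 200)
  for (i in seq_len(k)) {
    graphics::polygon(geo$centers[i, "x"] + geo$r * cos(th),
                      geo$centers[i, "y"] + geo$r * sin(th),
                      border = c("firebrick", "steelblue", "darkgreen")[i],
                      lwd = 2)
  }
  lab_xy <- geo$centers * 1.9
  for (i in seq_len(k)) {
    graphics::text(lab_xy[i, "x"], lab_xy[i, "y"], labels[i], font = 2)
  }
  sig <- apply(as.matrix(comparison[, labels]), 1L,
               function(m) paste(as.integer(m), collapse = ""))
  for (i in seq_len(nrow(comparison))) {
    xy <- geo$regions[sig[i], ]
    graphics::text(xy[1], xy[2], comparison$n[i], cex = 1.3)
  }
  invisible(comparison)
}

#' Run the full motif pipeline on files
#'
#' Executes QC, pattern classification, differential tabulation, set
#' comparison, and report rendering, writing every result as TSV/JSON (plus
#' advisory figures) under `out_dir`, together with a manifest recording the
#' configuration, package version, completed stages, and a content hash per
#' output file. Deterministic: re-running on identical inputs reproduces all
#' non-figure outputs.
#'
#' @param path_expr,path_samples expression matrix and sample sheet TSVs.
#' @param out_dir output directory (created if needed).
#' @param path_panel optional panel TSV; `panel = cp_panel()` style objects
#'   can be passed via `panel` instead.
#' @param panel optional `GenePanel` object (overrides `path_panel`).
#' @param cfg a [fc_config()].
#' @param scheme replicate aggregation scheme.
#' @param stage_order stage ordering.
#' @param min_r QC gate threshold.
#' @param unique_pattern,target_genotype,reference_genotype the
#'   unique-pattern extraction to report (defaults: p1 unique to `hom` vs
#'   `het`).
#' @param figures render heatmaps and Venn images (`TRUE` by default).
#' @return invisibly, a list with the in-memory results (`qc`, `patterns`,
#'   `counts`, `diff`, `unique_genes`, `manifest`).
#' @export
run_pipeline <- function(path_expr, path_samples, out_dir,
                         path_panel = NULL, panel = NULL,
                         cfg = fc_config(), scheme = "mean_all",
                         stage_order = DEFAULT_STAGES, min_r = 0.9,
                         unique_pattern = "p1", target_genotype = "hom",
                         reference_genotype = "het", figures = TRUE) {
  for (p in c(path_expr, path_samples, path_panel)) {
    if (!is.null(p) && !file.exists(p)) {
      pm_abort(paste0("input file not found: ", p))
    }
  }
  if (is.null(panel) && !is.null(path_panel)) panel <- load_panel(path_panel)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fig_dir <- file.path(out_dir, "figures")
  unique_dir <- file.path(out_dir, "unique_sets")
  if (figures) dir.create(fig_dir, showWarnings = FALSE)
  dir.create(unique_dir, showWarnings = FALSE)
  stages_done <- character()
  run_stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      pm_abort(sprintf("pipeline stage '%s' failed: %s", name,
                       conditionMessage(e)), class = "palmotif_stage_error")
    })
    stages_done <<- c(stages_done, name)
    res
  }

  em <- run_stage("load", load_expression(path_expr, path_samples,
                                          stage_order = stage_order))
  qc <- run_stage("qc", {
    conc <- replicate_concordance(em)
    gate <- qc_gate(conc, min_r = min_r)
    write_table(gate$pairs, file.path(out_dir, "qc.tsv"))
    gate
  })
  patterns <- run_stage("classify", {
    tab <- classify_all(em, cfg = cfg, panel = panel, scheme = scheme)
    write_table(tab, file.path(out_dir, "patterns.tsv"))
    write_table(pattern_counts(tab), file.path(out_dir, "pattern_counts.tsv"))
    tab
  })
  diffs <- run_stage("diff", {
    ds <- differential_sets(em, cfg = cfg, scheme = scheme)
    jsonlite::write_json(
      list(counts = diff_counts(ds)), file.path(out_dir, "table1.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    flat <- ds
    flat$genes <- vapply(flat$genes, paste, "", collapse = ",")
    write_table(flat, file.path(out_dir, "diff_sets.tsv"))
    ds
  })
  unique_genes <- run_stage("compare", {
    ug <- unique_pattern_genes(patterns, target_genotype, unique_pattern,
                               reference_genotype)
    writeLines(ug, file.path(unique_dir,
                             sprintf("%s_%s_not_%s.txt", unique_pattern,
                                     target_genotype,
                                     paste(reference_genotype, collapse = "_"))))
    ug
  })
  if (figures) {
    run_stage("render", {
      for (gt in intersect(GENOTYPE_LEVELS, unique(patterns$genotype))) {
        render_pattern_heatmap(em, patterns, gt,
                               file.path(fig_dir, paste0("heatmap_", gt, ".png")))
      }
      p_sets <- lapply(intersect(GENOTYPE_LEVELS, unique(patterns$genotype)),
                       function(gt) patterns$gene[patterns$genotype == gt &
                                                    patterns$pattern == unique_pattern])
      names(p_sets) <- intersect(GENOTYPE_LEVELS, unique(patterns$genotype))
      if (length(p_sets) >= 2) {
        comp <- venn_partition(p_sets)
        flat <- comp
        flat$genes <- vapply(flat$genes, paste, "", collapse = ",")
        write_table(tibble::as_tibble(flat),
                    file.path(fig_dir, paste0("venn_", unique_pattern, ".tsv")))
        render_venn(comp, file.path(fig_dir, paste0("venn_", unique_pattern, ".png")))
      }
      NULL
    })
  }

  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    package = "palmotif",
    version = as.character(utils::packageVersion("palmotif")),
    config = list(fc = cfg$fc, decimals = cfg$decimals,
                  log_delta = cfg$log_delta, inclusive = cfg$inclusive,
                  on_raw = cfg$on_raw, scheme = scheme,
                  stage_order = stage_order, min_r = min_r,
                  unique_pattern = unique_pattern,
                  target_genotype = target_genotype,
                  reference_genotype = reference_genotype),
    stages_complete = stages_done,
    qc_overall_pass = qc$overall_pass,
    outputs = lapply(stats::setNames(files, basename(files)), function(f) {
      list(path = f, md5 = unname(tools::md5sum(f)))
    }))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(qc = qc, patterns = patterns,
                 counts = pattern_counts(patterns), diff = diffs,
                 unique_genes = unique_genes, manifest = manifest))
}
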