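#' Differential gene sets per genotype and stage pair
#'
#' For every genotype and every ordered stage pair (in the reference design:
#' E14.5-E15.5, E14.5-E16.5, E15.5-E16.5), the genes whose transition is
#' called `up` or `down` on the aggregated transformed values; `all` is the
#' disjoint union of the two. Calls are fold-change-only (no significance
#' test), so "differential" here means FC-significant.
#'
#' @param em an `ExpressionMatrix` with >= 2 stages.
#' @param cfg a [fc_config()].
#' @param scheme replicate aggregation scheme.
#' @return tibble with columns `genotype`, `stage_from`, `stage_to`,
#'   `direction` (`up`/`down`/`all`), `n` and a `genes` list-column (sorted
#'   symbols).
#' @export
differential_sets <- function(em, cfg = fc_config(), scheme = "mean_all") {
  stopifnot(inherits(em, "ExpressionMatrix"))
  stages <- em$stage_order
  if (length(stages) < 2L) pm_abort("differential sets require >= 2 stages")
  agg <- aggregate_replicates(em, scheme = scheme)
  agg$t <- transform_value(agg$fpkm, cfg$decimals)
  wide <- tidyr::pivot_wider(agg[, c("gene", "genotype", "stage", "t")],
                             names_from = "stage", values_from = "t")
  pairs <- utils::combn(stages, 2L)
  rows <- list()
  for (gt in intersect(GENOTYPE_LEVELS, unique(wide$genotype))) {
    sub <- wide[wide$genotype == gt, ]
    for (k in seq_len(ncol(pairs))) {
      s_from <- pairs[1, k]; s_to <- pairs[2, k]
      d <- call_direction(sub[[s_from]], sub[[s_to]], cfg)
      up <- sort(sub$gene[d == "up"])
      down <- sort(sub$gene[d == "down"])
      for (dir in c("all", "up", "down")) {
        genes <- switch(dir, up = up, down = down, all = sort(c(up, down)))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          genotype = gt, stage_from = s_from, stage_to = s_to,
          direction = dir, n = length(genes), genes = list(genes))
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Differential-set counts in report shape
#'
#' @param sets tibble from [differential_sets()].
#' @return tibble of counts: one row per (direction, genotype), one column
#'   per stage pair.
#' @export
diff_counts <- function(sets) {
  sets$pair <- paste(sets$stage_from, sets$stage_to, sep = "-")
  tidyr::pivot_wider(sets[, c("direction", "genotype", "pair", "n")],
                     names_from = "pair", values_from = "n")
}

#' Venn-style partition of 2 or 3 named gene sets
#'
#' Complete disjoint region decomposition: every gene of the union lies in
#' exactly one region, so region counts sum to the union size.
#'
#' @param sets named list of 2 or 3 character vectors.
#' @return an object of class `SetComparison`: a tibble with one row per
#'   region (all 2^k - 1 membership signatures, including empty ones), with
#'   logical membership columns, a `region` label, `n`, and a `genes`
#'   list-column; set names and the union size are attached as attributes.
#' @export
venn_partition <- function(sets) {
  if (!is.list(sets) || is.null(names(sets)) || any(!nzchar(names(sets)))) {
    pm_abort("`sets` must be a named list")
  }
  k <- length(sets)
  if (k < 2L || k > 3L) {
    pm_abort(sprintf("venn partition supports 2 or 3 sets, got %d", k))
  }
  sets <- lapply(sets, function(s) unique(as.character(s)))
  universe <- sort(unique(unlist(sets)))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  member <- matrix(member, ncol = k, dimnames = list(universe, names(sets)))

  sig_grid <- expand.grid(rep(list(c(TRUE, FALSE)), k))[-2^k, , drop = FALSE]
  names(sig_grid) <- names(sets)
  rows <- lapply(seq_len(nrow(sig_grid)), function(i) {
    sig <- unlist(sig_grid[i, ])
    in_region <- apply(member, 1L, function(m) all(m == sig))
    genes <- universe[in_region]
    lab <- paste(names(sets)[sig], collapse = "&")
    tibble::tibble(region = lab, n = length(genes), genes = list(genes))
  })
  out <- dplyr::bind_cols(tibble::as_tibble(sig_grid), dplyr::bind_rows(rows))
  attr(out, "labels") <- names(sets)
  attr(out, "union_size") <- length(universe)
  class(out) <- c("SetComparison", class(out))
  out
}

#' Genes with the first-up-then-down motif
#'
#' Exactly the genes classified p4 (upregulated over the first transition,
#' downregulated over the second) for the given genotype — the motif flagged
#' as marking transcripts needed around the adhesion stage.
#'
#' @param table a pattern table from [classify_all()].
#' @param genotype genotype token present in the table.
#' @return sorted character vector of gene symbols.
#' @export
first_up_then_down <- function(table, genotype) {
  if (!genotype %in% table$genotype) {
    pm_abort(paste0("genotype not present in pattern table: ", genotype))
  }
  sort(table$gene[table$genotype == genotype & table$pattern == "p4"])
}

#' Genes holding a pattern uniquely in a target genotype
#'
#' The set `{g : pattern(g, target) = pattern and pattern(g, reference) !=
#' pattern}` — with target `hom`, pattern `p1`, reference `het` this is the
#' candidate cleft-palate extraction (genes flat in the knockout but
#' regulated in the phenotypically normal heterozygote).
#'
#' @param table a pattern table from [classify_all()].
#' @param target_genotype,reference_genotype genotype tokens present in the
#'   table; `reference_genotype` may be a vector, in which case a gene
#'   qualifies only if it differs from ALL references.
#' @param pattern a pattern code `p1`..`p9`.
#' @return sorted character vector of gene symbols.
#' @export
unique_pattern_genes <- function(table, target_genotype, pattern,
                                 reference_genotype) {
  for (gt in c(target_genotype, reference_genotype)) {
    if (!gt %in% table$genotype) {
      pm_abort(paste0("genotype not present in pattern table: ", gt))
    }
  }
  if (!pattern %in% names(PATTERN_CODES)) {
    pm_abort(paste0("unknown pattern code: ", pattern))
  }
  target_set <- table$gene[table$genotype == target_genotype &
                             table$pattern == pattern]
  for (ref in reference_genotype) {
    ref_set <- table$gene[table$genotype == ref & table$pattern == pattern]
    target_set <- setdiff(target_set, ref_set)
  }
  sort(target_set)
}

#' Overlap of one pattern's gene sets between two genotypes
#'
#' Both directed fractions are reported because the natural denominator is
#' ambiguous: `fraction_a` = |shared| / |pattern set of a|, and symmetrically
#' `fraction_b`.
#'
#' @param table a pattern table from [classify_all()].
#' @param pattern a pattern code.
#' @param genotype_a,genotype_b genotype tokens present in the table.
#' @return list with `shared` (sorted symbols), `n_a`, `n_b`, `fraction_a`,
#'   `fraction_b`; a fraction is `NA` when its denominator set is empty.
#' @export
pattern_overlap <- function(table, pattern, genotype_a, genotype_b) {
  for (gt in c(genotype_a, genotype_b)) {
    if (!gt %in% table$genotype) {
      pm_abort(paste0("genotype not present in pattern table: ", gt))
    }
  }
  set_a <- table$gene[table$genotype == genotype_a & table$pattern == pattern]
  set_b <- table$gene[table$genotype == genotype_b & table$pattern == pattern]
  shared <- sort(intersect(set_a, set_b))
  list(shared = shared, n_a = length(set_a), n_b = length(set_b),
       fraction_a = if (length(set_a)) length(shared) / length(set_a) else NA_real_,
       fraction_b = if (length(set_b)) length(shared) / length(set_b) else NA_real_)
}
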