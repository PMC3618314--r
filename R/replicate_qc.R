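#' Transform FPKM for replicate QC
#'
#' `log10(fpkm + 1)`, unrounded: rounding is a classifier concern, not a QC
#' concern.
#'
#' @param fpkm non-negative numeric vector.
#' @return transformed values.
#' @export
transform_for_qc <- function(fpkm) {
  if (any(!is.finite(fpkm) | fpkm < 0)) {
    pm_abort("FPKM values must be finite and non-negative")
  }
  log10(fpkm + 1)
}

#' Replicate concordance of an expression matrix
#'
#' Enumerates replicate pairs within each (genotype, stage) design cell:
#' columns differing in `bio_rep` form biological pairs, columns sharing
#' `bio_rep` but differing in `tech_rep` form technical pairs. For each pair
#' the Pearson correlation of `log10(FPKM+1)` over all shared genes is
#' computed, with a two-tailed p-value from the t distribution on
#' `n_genes - 2` degrees of freedom. Cross-stage and cross-genotype
#' correlations are not QC and are not enumerated.
#'
#' @param em an `ExpressionMatrix`.
#' @return tibble with columns `sample_a`, `sample_b`, `genotype`, `stage`,
#'   `kind` (`biological`/`technical`), `r`, `n_genes`, `p_two_tail`, sorted
#'   by (genotype, stage, kind). A zero-variance column yields `r = NA`;
#'   cells with fewer than 3 genes are skipped with a warning.
#' @export
replicate_concordance <- function(em) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  tv <- log10(em$values + 1)
  s <- em$samples
  rows <- list()
  for (gt in intersect(GENOTYPE_LEVELS, unique(s$genotype))) {
    for (st in intersect(em$stage_order, unique(s$stage[s$genotype == gt]))) {
      idx <- which(s$genotype == gt & s$stage == st)
      if (length(idx) < 2L) next
      if (nrow(tv) < 3L) {
        warning(sprintf("cell (%s, %s): fewer than 3 genes, pairs skipped",
                        gt, st))
        next
      }
      for (a in seq_along(idx)[-length(idx)]) {
        for (b in seq((a + 1L), length(idx))) {
          ia <- idx[a]; ib <- idx[b]
          kind <- if (s$bio_rep[ia] != s$bio_rep[ib]) "biological"
                  else "technical"
          x <- tv[, ia]; y <- tv[, ib]
          n <- length(x)
          r <- if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_
               else stats::cor(x, y)
          p <- if (is.na(r)) NA_real_
               else if (abs(r) >= 1) 0
               else 2 * stats::pt(-abs(r) * sqrt((n - 2) / (1 - r^2)), n - 2)
          rows[[length(rows) + 1L]] <- tibble::tibble(
            sample_a = s$sample_id[ia], sample_b = s$sample_id[ib],
            genotype = gt, stage = st, kind = kind,
            r = r, n_genes = n, p_two_tail = p)
        }
      }
    }
  }
  if (!length(rows)) pm_abort("matrix contains no replicate pairs")
  out <- dplyr::bind_rows(rows)
  out[order(match(out$genotype, GENOTYPE_LEVELS),
            match(out$stage, em$stage_order), out$kind), ]
}

#' Gate replicate concordance results against a minimum correlation
#'
#' Purely advisory: the QC contract of the source design reports r but
#' prescribes no threshold, so the default gate of 0.9 is a conservative
#' pipeline guard.
#'
#' @param results tibble from [replicate_concordance()].
#' @param min_r minimum acceptable Pearson r (default 0.9).
#' @return list with `pairs` (the input plus a logical `pass` column; an
#'   undefined r fails) and `overall_pass` (all pairs pass).
#' @export
qc_gate <- function(results, min_r = 0.9) {
  pairs <- dplyr::mutate(results, pass = !is.na(.data$r) & .data$r >= min_r)
  list(pairs = pairs, overall_pass = all(pairs$pass), min_r = min_r)
}
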