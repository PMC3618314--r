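#' The nine stage-transition motif codes
#'
#' Each code is an ordered pair of direction calls over the two consecutive
#' stage transitions (first E14.5 to E15.5, then E15.5 to E16.5 in the
#' reference design):
#' p1 unchanged-unchanged, p2 up-unchanged, p3 unchanged-up, p4 up-down,
#' p5 up-up, p6 down-unchanged, p7 down-up, p8 unchanged-down, p9 down-down.
#' @export
PATTERN_CODES <- c(p1 = "unchanged/unchanged", p2 = "up/unchanged",
                   p3 = "unchanged/up",        p4 = "up/down",
                   p5 = "up/up",               p6 = "down/unchanged",
                   p7 = "down/up",             p8 = "unchanged/down",
                   p9 = "down/down")

#' Map a pair of direction calls to its pattern code
#'
#' Total over the 3 x 3 direction space: every (d1, d2) pair receives exactly
#' one of the nine codes.
#'
#' @param d1,d2 direction calls (`"up"`, `"down"`, `"unchanged"`), recycled.
#' @return character vector of pattern codes `p1`..`p9`.
#' @export
pattern_from_directions <- function(d1, d2) {
  key <- paste(d1, d2, sep = "/")
  out <- names(PATTERN_CODES)[match(key, PATTERN_CODES)]
  if (anyNA(out)) {
    pm_abort(paste0("invalid direction pair(s): ",
                    paste(unique(key[is.na(out)]), collapse = ", ")))
  }
  out
}

#' Recover the direction pair encoded by a pattern code
#'
#' @param pattern character vector of codes `p1`..`p9`.
#' @return tibble with columns `pattern`, `d1`, `d2`.
#' @export
directions_from_pattern <- function(pattern) {
  pair <- PATTERN_CODES[match(pattern, names(PATTERN_CODES))]
  if (anyNA(pair)) {
    pm_abort(paste0("unknown pattern code(s): ",
                    paste(unique(pattern[is.na(pair)]), collapse = ", ")))
  }
  parts <- strsplit(unname(pair), "/", fixed = TRUE)
  tibble::tibble(pattern = pattern,
                 d1 = vapply(parts, `[`, "", 1L),
                 d2 = vapply(parts, `[`, "", 2L))
}

#' Fold-change threshold configuration
#'
#' The fold-change threshold FC is applied on the transformed scale as a
#' difference of rounded log10(FPKM+1) values: a transition is a regulation
#' event when |b - a| >= `log_delta`, where `log_delta = round(log10(fc),
#' decimals)` (0.30 at the default FC of 2 and 2 decimals). Because both the
#' values and the threshold are rounded to the same precision, calls are
#' exact in hundredths. `on_raw = TRUE` switches to thresholding the raw
#' FPKM ratio instead (non-default; zero denominators are treated as
#' regulation whenever the numerator is positive).
#'
#' @param fc fold-change threshold, > 1 (default 2.0).
#' @param decimals rounding precision of the transformed values (default 2).
#' @param inclusive if `TRUE` (default) a difference exactly equal to
#'   `log_delta` counts as regulated (FC >= 2.0 semantics).
#' @param on_raw threshold the raw FPKM ratio rather than the transformed
#'   difference.
#' @return an object of class `FoldChangeConfig`.
#' @export
fc_config <- function(fc = 2.0, decimals = 2L, inclusive = TRUE,
                      on_raw = FALSE) {
  if (!is.numeric(fc) || length(fc) != 1L || fc <= 1) {
    pm_abort("`fc` must be a single number > 1")
  }
  decimals <- as.integer(decimals)
  if (decimals < 0) pm_abort("`decimals` must be >= 0")
  log_delta <- round_half_away(log10(fc), decimals)
  if (log_delta <= 0) pm_abort("`fc` too close to 1 for the chosen precision")
  structure(list(fc = fc, decimals = decimals, log_delta = log_delta,
                 inclusive = inclusive, on_raw = on_raw),
            class = "FoldChangeConfig")
}

#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (2.5 -> 3, -2.5 -> -3),
#' as opposed to the round-half-even rule of [base::round()].
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 2L) {
  m <- 10^digits
  # small eps absorbs binary representation error just below a .5 boundary
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Transform an FPKM value to the classification scale
#'
#' `round(log10(fpkm + 1), decimals)` with half-away-from-zero rounding; the
#' pseudocount keeps zero-FPKM genes well-defined and the rounding fixes the
#' working precision of the whole motif analysis.
#'
#' @param fpkm non-negative numeric vector.
#' @param decimals rounding precision (default 2).
#' @return transformed values.
#' @export
transform_value <- function(fpkm, decimals = 2L) {
  if (any(!is.finite(fpkm) | fpkm < 0)) {
    pm_abort("FPKM values must be finite and non-negative")
  }
  round_half_away(log10(fpkm + 1), decimals)
}

#' Call the direction of one stage transition
#'
#' Given transformed (rounded) values `a` at the earlier and `b` at the later
#' stage: `up` when `b - a >= log_delta`, `down` when `a - b >= log_delta`,
#' else `unchanged` (boundary handling per `cfg$inclusive`).
#'
#' @param a,b transformed expression values (recycled).
#' @param cfg a [fc_config()].
#' @return character vector of `"up"`, `"down"`, `"unchanged"`.
#' @export
call_direction <- function(a, b, cfg = fc_config()) {
  stopifnot(inherits(cfg, "FoldChangeConfig"))
  diff <- b - a
  eps <- 1e-9   # rounded values differ by exact hundredths up to fp error
  if (cfg$inclusive) {
    up <- diff >= cfg$log_delta - eps
    down <- -diff >= cfg$log_delta - eps
  } else {
    up <- diff > cfg$log_delta + eps
    down <- -diff > cfg$log_delta + eps
  }
  ifelse(up, "up", ifelse(down, "down", "unchanged"))
}

call_direction_raw <- function(a, b, cfg) {
  up <- (a == 0 & b > 0) | (a > 0 & b / a >= cfg$fc)
  down <- (b == 0 & a > 0) | (b > 0 & a / b >= cfg$fc)
  ifelse(up, "up", ifelse(down, "down", "unchanged"))
}

#' Classify one stage profile into a pattern code
#'
#' @param values ordered transformed expression values, one per stage;
#'   exactly 3 in the reference design (two transitions).
#' @param cfg a [fc_config()].
#' @return a single pattern code `p1`..`p9`.
#' @export
classify_pattern <- function(values, cfg = fc_config()) {
  if (length(values) != 3L) {
    pm_abort(sprintf("a stage profile must have exactly 3 values, got %d",
                     length(values)))
  }
  pattern_from_directions(call_direction(values[1], values[2], cfg),
                          call_direction(values[2], values[3], cfg))
}

#' Aggregate replicate FPKM into per-(gene, genotype, stage) means
#'
#' `mean_all` (default) averages all replicate columns of a design cell;
#' `mean_bio_of_tech` averages technical replicates within each biological
#' replicate first, then the biological means. The two schemes coincide for
#' balanced designs.
#'
#' @param em an `ExpressionMatrix`.
#' @param scheme aggregation scheme.
#' @return tibble with columns `gene`, `genotype`, `stage`, `fpkm`; stages
#'   ordered per the matrix stage order, genotypes per `hom < het < wt`.
#' @export
aggregate_replicates <- function(em, scheme = c("mean_all", "mean_bio_of_tech")) {
  stopifnot(inherits(em, "ExpressionMatrix"))
  scheme <- match.arg(scheme)
  genotypes <- intersect(GENOTYPE_LEVELS, unique(em$samples$genotype))
  out <- vector("list", length(genotypes) * length(em$stage_order))
  k <- 0L
  for (gt in genotypes) {
    for (st in em$stage_order) {
      sel <- em$samples$genotype == gt & em$samples$stage == st
      if (!any(sel)) {
        pm_abort(sprintf("design cell (%s, %s) has no samples", gt, st))
      }
      sub <- em$values[, sel, drop = FALSE]
      if (scheme == "mean_all") {
        m <- rowMeans(sub)
      } else {
        bio <- em$samples$bio_rep[sel]
        bio_means <- vapply(unique(bio), function(b) {
          rowMeans(sub[, bio == b, drop = FALSE])
        }, numeric(nrow(sub)))
        m <- rowMeans(matrix(bio_means, nrow = nrow(sub)))
      }
      k <- k + 1L
      out[[k]] <- tibble::tibble(gene = rownames(em$values), genotype = gt,
                                 stage = st, fpkm = unname(m))
    }
  }
  dplyr::bind_rows(out)
}

#' Classify every (gene, genotype) of a matrix into a pattern
#'
#' Aggregates replicates, transforms to rounded log10(FPKM+1), calls the two
#' transition directions at the configured threshold, and assigns one of the
#' nine pattern codes. Deterministic given inputs and configuration.
#'
#' @param em an `ExpressionMatrix` with exactly 3 stages.
#' @param cfg a [fc_config()].
#' @param panel optional `GenePanel`; if given the matrix is restricted to
#'   panel genes first.
#' @param scheme replicate aggregation scheme, see [aggregate_replicates()].
#' @return a pattern table: tibble with columns `gene`, `genotype`, `t1`,
#'   `t2`, `t3` (transformed stage values), `d1`, `d2` (direction calls) and
#'   `pattern`; the `FoldChangeConfig` and stage order are attached as
#'   attributes `threshold_config` and `stages`.
#' @export
classify_all <- function(em, cfg = fc_config(), panel = NULL,
                         scheme = "mean_all") {
  stopifnot(inherits(em, "ExpressionMatrix"))
  if (length(em$stage_order) != 3L) {
    pm_abort("pattern classification requires exactly 3 stages")
  }
  if (!is.null(panel)) em <- panel_subset(em, panel)$matrix
  agg <- aggregate_replicates(em, scheme = scheme)
  wide <- tidyr::pivot_wider(agg, names_from = "stage", values_from = "fpkm")
  raw <- as.matrix(wide[, em$stage_order, drop = FALSE])
  tv <- matrix(transform_value(raw, cfg$decimals), nrow = nrow(raw))
  if (cfg$on_raw) {
    d1 <- call_direction_raw(raw[, 1], raw[, 2], cfg)
    d2 <- call_direction_raw(raw[, 2], raw[, 3], cfg)
  } else {
    d1 <- call_direction(tv[, 1], tv[, 2], cfg)
    d2 <- call_direction(tv[, 2], tv[, 3], cfg)
  }
  tab <- tibble::tibble(gene = wide$gene, genotype = wide$genotype,
                        t1 = tv[, 1], t2 = tv[, 2], t3 = tv[, 3],
                        d1 = d1, d2 = d2,
                        pattern = pattern_from_directions(d1, d2))
  tab <- tab[order(match(tab$genotype, GENOTYPE_LEVELS), tab$gene), ]
  attr(tab, "threshold_config") <- cfg
  attr(tab, "stages") <- em$stage_order
  tab
}

#' Tabulate pattern membership per genotype
#'
#' @param table a pattern table from [classify_all()].
#' @return tibble with columns `genotype`, `pattern`, `n`, `fraction`; all
#'   nine codes are reported per genotype (zeros included) and fractions sum
#'   to 1 within each genotype.
#' @export
pattern_counts <- function(table) {
  genotypes <- intersect(GENOTYPE_LEVELS, unique(table$genotype))
  grid <- tidyr::expand_grid(genotype = genotypes,
                             pattern = names(PATTERN_CODES))
  counts <- dplyr::count(table, .data$genotype, .data$pattern)
  out <- dplyr::left_join(grid, counts, by = c("genotype", "pattern"))
  out$n[is.na(out$n)] <- 0L
  out <- dplyr::group_by(out, .data$genotype)
  out <- dplyr::mutate(out, fraction = .data$n / sum(.data$n))
  dplyr::ungroup(out)
}
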