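# Build an ExpressionMatrix from per-(gene, genotype) FPKM stage profiles,
# replicated identically over n_bio x n_tech columns (zero replicate noise).
# profiles: data frame with columns gene, genotype, s1, s2, s3 (FPKM).
em_from_profiles <- function(profiles, stages = DEFAULT_STAGES,
                             n_bio = 2L, n_tech = 1L) {
  genes <- unique(profiles$gene)
  genotypes <- intersect(GENOTYPE_LEVELS, unique(profiles$genotype))
  cols <- list(); values <- NULL
  for (gt in genotypes) {
    sub <- profiles[profiles$genotype == gt, ]
    sub <- sub[match(genes, sub$gene), ]
    for (si in seq_along(stages)) {
      fpkm <- sub[[paste0("s", si)]]
      for (bi in seq_len(n_bio)) for (ti in seq_len(n_tech)) {
        cols[[length(cols) + 1L]] <- data.frame(
          sample_id = sprintf("%s_%s_b%d_t%d", gt, stages[si], bi, ti),
          genotype = gt, stage = stages[si], bio_rep = bi, tech_rep = ti)
        values <- cbind(values, fpkm)
      }
    }
  }
  samples <- do.call(rbind, cols)
  dimnames(values) <- list(genes, samples$sample_id)
  expression_matrix(values, samples, stage_order = stages)
}

# FPKM whose transformed (rounded log10(FPKM+1)) value is exactly t
fpkm_for_t <- function(t) 10^t - 1

# single-genotype profile matrix from transformed stage targets
em_from_transformed <- function(t_profiles, genotype = "wt", ...) {
  profiles <- data.frame(gene = rownames(t_profiles), genotype = genotype,
                         s1 = fpkm_for_t(t_profiles[, 1]),
                         s2 = fpkm_for_t(t_profiles[, 2]),
                         s3 = fpkm_for_t(t_profiles[, 3]))
  em_from_profiles(profiles, ...)
}

# minimal pattern table (only the columns the set operations consume)
make_pattern_table <- function(gene, genotype, pattern) {
  tibble::tibble(gene = gene, genotype = genotype, pattern = pattern)
}

# independent direction oracle, working in integer hundredths
oracle_direction <- function(a, b, delta = 0.30) {
  ai <- round(a * 100); bi <- round(b * 100); di <- round(delta * 100)
  if (bi - ai >= di) "up" else if (ai - bi >= di) "down" else "unchanged"
}

# independent pattern lookup written out by hand
oracle_pattern <- function(d1, d2) {
  tab <- c("unchanged.unchanged" = "p1", "up.unchanged" = "p2",
           "unchanged.up" = "p3", "up.down" = "p4", "up.up" = "p5",
           "down.unchanged" = "p6", "down.up" = "p7",
           "unchanged.down" = "p8", "down.down" = "p9")
  unname(tab[paste(d1, d2, sep = ".")])
}

write_em_tsvs <- function(em, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  paths <- list(expr = file.path(dir, "expr.tsv"),
                samples = file.path(dir, "samples.tsv"))
  write_expression(em, paths$expr, paths$samples)
  paths
}
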