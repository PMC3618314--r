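test_that("rounding is half away from zero at fixed decimals", {
  expect_equal(round_half_away(0.305, 2), 0.31)
  expect_equal(round_half_away(-0.305, 2), -0.31)
  expect_equal(round_half_away(2.5, 0), 3)
  expect_equal(round_half_away(-2.5, 0), -3)
  expect_equal(round_half_away(log10(2), 2), 0.30)
})

test_that("the classification transform is rounded log10(FPKM + 1)", {
  expect_equal(transform_value(0), 0)
  expect_equal(transform_value(99), 2)
  expect_equal(transform_value(1.0), 0.30)
  expect_equal(transform_value(9999, decimals = 3), 4)
  expect_error(transform_value(-2), "non-negative")
})

test_that("direction calls threshold the transformed difference inclusively", {
  cfg <- fc_config()
  expect_equal(cfg$log_delta, 0.30)
  expect_equal(call_direction(1.00, 1.30, cfg), "up")
  expect_equal(call_direction(1.00, 1.29, cfg), "unchanged")
  expect_equal(call_direction(1.30, 1.00, cfg), "down")
  # binary float subtraction must not break exact-boundary calls
  expect_equal(call_direction(0.30, 0.60, cfg), "up")
  expect_equal(call_direction(0.60, 0.30, cfg), "down")
  for (x in c(0, 0.47, 2.13)) {
    expect_equal(call_direction(x, x, cfg), "unchanged")
  }
  strict <- fc_config(inclusive = FALSE)
  expect_equal(call_direction(1.00, 1.30, strict), "unchanged")
  expect_equal(call_direction(1.00, 1.31, strict), "up")
  expect_error(fc_config(fc = 1), "> 1")
})

test_that("profiles map to single pattern codes", {
  expect_equal(classify_pattern(c(1.00, 1.00, 1.00)), "p1")
  expect_equal(classify_pattern(c(0.50, 1.00, 0.40)), "p4")
  expect_error(classify_pattern(c(1, 2)), "exactly 3")
  expect_error(classify_pattern(c(1, 2, 3, 4)), "exactly 3")
})

test_that("classifier agrees with brute-force enumeration on all 27 grids", {
  lv <- c(0.00, 0.30, 0.60)
  grids <- expand.grid(v1 = lv, v2 = lv, v3 = lv)
  seen <- character()
  for (i in seq_len(nrow(grids))) {
    v <- as.numeric(grids[i, ])
    expected <- oracle_pattern(oracle_direction(v[1], v[2]),
                               oracle_direction(v[2], v[3]))
    got <- classify_pattern(v)
    expect_equal(got, expected,
                 label = sprintf("profile (%.2f, %.2f, %.2f)", v[1], v[2], v[3]))
    seen <- c(seen, got)
  }
  expect_setequal(unique(seen), paste0("p", 1:9))
})

test_that("reversing stage order flips and swaps the transition directions", {
  # reversal maps (d1, d2) -> (flip d2, flip d1); composed over the codes:
  # p1<->p1, p2<->p8, p3<->p6, p4<->p4, p5<->p9, p7<->p7
  flip <- function(d) c(up = "down", down = "up", unchanged = "unchanged")[d]
  lv <- c(0.00, 0.30, 0.60)
  grids <- expand.grid(v1 = lv, v2 = lv, v3 = lv)
  for (i in seq_len(nrow(grids))) {
    v <- as.numeric(grids[i, ])
    p_fwd <- classify_pattern(v)
    d <- c(oracle_direction(v[1], v[2]), oracle_direction(v[2], v[3]))
    expected_rev <- oracle_pattern(unname(flip(d[2])), unname(flip(d[1])))
    expect_equal(classify_pattern(rev(v)), expected_rev)
  }
  # and the induced involution on codes, checked on one witness per code
  witness <- list(p1 = c(0, 0, 0), p2 = c(0, .3, .3), p3 = c(0, 0, .3),
                  p4 = c(0, .3, 0), p5 = c(0, .3, .6), p6 = c(.3, 0, 0),
                  p7 = c(.3, 0, .3), p8 = c(.3, .3, 0), p9 = c(.6, .3, 0))
  mapped <- vapply(witness, function(v) classify_pattern(rev(v)), "")
  expect_equal(unname(mapped),
               c("p1", "p8", "p6", "p4", "p9", "p3", "p7", "p2", "p5"))
})

test_that("replicate aggregation schemes average as specified", {
  profiles <- data.frame(gene = "g1", genotype = "wt",
                         s1 = 10, s2 = 30, s3 = 50)
  em1 <- em_from_profiles(profiles, n_bio = 1L, n_tech = 1L)
  agg1 <- aggregate_replicates(em1)
  expect_equal(agg1$fpkm, c(10, 30, 50))

  # 2x2 cell holding (10, 20, 40, 50): bio groups {10,20} and {40,50}
  vals <- matrix(c(10, 20, 40, 50), nrow = 1)
  samples <- data.frame(sample_id = paste0("s", 1:4), genotype = "wt",
                        stage = "E14.5",
                        bio_rep = c(1L, 1L, 2L, 2L), tech_rep = c(1L, 2L, 1L, 2L))
  dimnames(vals) <- list("g1", samples$sample_id)
  em2 <- expression_matrix(vals, samples, stage_order = "E14.5")
  expect_equal(aggregate_replicates(em2, "mean_all")$fpkm, 30)
  expect_equal(aggregate_replicates(em2, "mean_bio_of_tech")$fpkm, 30)

  # unbalanced cell: bio1 {10}, bio2 {20, 40} -- schemes now differ
  vals3 <- matrix(c(10, 20, 40), nrow = 1)
  samples3 <- data.frame(sample_id = paste0("s", 1:3), genotype = "wt",
                         stage = "E14.5",
                         bio_rep = c(1L, 2L, 2L), tech_rep = c(1L, 1L, 2L))
  dimnames(vals3) <- list("g1", samples3$sample_id)
  em3 <- expression_matrix(vals3, samples3, stage_order = "E14.5")
  expect_equal(aggregate_replicates(em3, "mean_all")$fpkm, 70 / 3)
  expect_equal(aggregate_replicates(em3, "mean_bio_of_tech")$fpkm, 20)
})

test_that("classify_all recovers planted patterns and reproduces the printed codes", {
  # one gene per pattern, zero noise, effect twice the threshold
  truth9 <- expand.grid(gene = 1:9, genotype = GENOTYPE_LEVELS,
                        stringsAsFactors = FALSE)
  truth9$pattern <- paste0("p", truth9$gene)
  cfg9 <- sim_config(n_genes = 9, noise_sd = 0, effect_delta = 0.60,
                     pattern_assignment = truth9, seed = 1)
  sim <- simulate_experiment(cfg9)
  tab <- classify_all(sim$matrix)
  expect_equal(recovery_score(sim$truth, tab)$accuracy, 1.0)

  # single constant gene -> p1 in every genotype, totality of the partition
  em1 <- em_from_profiles(data.frame(gene = "g1", genotype = "wt",
                                     s1 = 5, s2 = 5, s3 = 5))
  tab1 <- classify_all(em1)
  expect_equal(tab1$pattern, "p1")

  # published per-genotype codes for the 8 candidate genes
  fx <- plant_table3_fixture()
  tab3 <- classify_all(fx$matrix)
  joined <- merge(fx$expected, tab3[, c("gene", "genotype", "pattern")],
                  by = c("gene", "genotype"))
  expect_equal(nrow(joined), nrow(fx$expected))
  expect_equal(joined$pattern.y, joined$pattern.x)
})

test_that("every (gene, genotype) gets exactly one code; counts partition genes", {
  sim <- simulate_experiment(sim_config(n_genes = 120, seed = 17))
  tab <- classify_all(sim$matrix)
  expect_equal(nrow(tab), 120L * 3L)
  expect_equal(anyDuplicated(tab[, c("gene", "genotype")]), 0L)
  expect_true(all(tab$pattern %in% paste0("p", 1:9)))

  counts <- pattern_counts(tab)
  sums <- tapply(counts$n, counts$genotype, sum)
  expect_true(all(sums == 120L))
  fracs <- tapply(counts$fraction, counts$genotype, sum)
  expect_equal(as.numeric(fracs), rep(1, 3))

  # counts invariant under gene reordering
  perm <- tab[rev(seq_len(nrow(tab))), ]
  expect_equal(dplyr::arrange(pattern_counts(perm), genotype, pattern),
               dplyr::arrange(counts, genotype, pattern))
})

test_that("a global 10x FPKM rescaling leaves direction calls unchanged", {
  # effects away from the rounding boundary (>= 0.32 or <= 0.28)
  set.seed(31)
  steps <- c(-0.6, -0.32, -0.28, 0, 0.28, 0.32, 0.6)
  # keep all profile values high enough (>= 2.2) that the pseudocount
  # perturbation from the rescaling stays within a rounding hundredth
  t1 <- round(stats::runif(60, 3.4, 4.5), 2)
  d1 <- sample(steps, 60, TRUE); d2 <- sample(steps, 60, TRUE)
  tmat <- cbind(t1, t1 + d1, t1 + d1 + d2)
  rownames(tmat) <- sprintf("g%02d", 1:60)
  em <- em_from_transformed(tmat)
  em10 <- expression_matrix(em$values * 10, em$samples, em$stage_order)
  tab <- classify_all(em)
  tab10 <- classify_all(em10)
  expect_equal(tab10$pattern, tab$pattern)
})

test_that("the raw-ratio threshold mode is available and differs where it should", {
  cfg_raw <- fc_config(on_raw = TRUE)
  # raw ratio 20/10 = 2 -> up; pseudocounted 21/11 < 2 -> unchanged
  em <- em_from_profiles(data.frame(gene = "g1", genotype = "wt",
                                    s1 = 10, s2 = 20, s3 = 20))
  expect_equal(classify_all(em, cfg_raw)$pattern, "p2")
  expect_equal(classify_all(em, fc_config())$pattern, "p1")
  # zero-FPKM endpoints are well-defined in both modes
  em0 <- em_from_profiles(data.frame(gene = "g1", genotype = "wt",
                                     s1 = 0, s2 = 9, s3 = 0))
  expect_equal(classify_all(em0, cfg_raw)$pattern, "p4")
  expect_equal(classify_all(em0, fc_config())$pattern, "p4")
})
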