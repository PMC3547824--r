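# small reference configs used across simulation tests
quiet_config <- function(...) {
  args <- list(n_chrom = 2, snps_per_chrom = 30, n_transcripts = 60,
               n_drivers = 5, n_de_only = 5,
               segment_map = data.frame(chrom = 1L, start_snp = 11L,
                                        end_snp = 20L, group = "met",
                                        shift = 0.5))
  over <- list(...)
  do.call(sim_config, c(over, args[!names(args) %in% names(over)]))
}

test_that("same seed gives bit-identical cohorts, different seeds differ", {
  cfg <- quiet_config(seed = 42)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  c <- simulate_cohort(quiet_config(seed = 43))
  expect_false(identical(a$cn, c$cn))
})

test_that("no segments and no noise gives an all-zero log-ratio matrix", {
  cfg <- sim_config(n_chrom = 2, snps_per_chrom = 10, n_transcripts = 10,
                    n_drivers = 0, n_de_only = 0,
                    segment_map = NULL, noise_sd_cn = 0, seed = 1)
  g <- generate_genomes(cfg)
  expect_true(all(g$cn == 0))
  # positions strictly increasing within chromosome
  for (ch in unique(g$panel$chrom))
    expect_true(all(diff(g$panel$pos[g$panel$chrom == ch]) > 0))
})

test_that("in-segment metastatic mean recovers the configured shift", {
  cfg <- quiet_config(n_primary = 20, n_met = 20, noise_sd_cn = 0.1, seed = 5)
  g <- generate_genomes(cfg)
  in_seg <- g$truth$differential_snp
  met <- g$samples$group == "met"
  vals <- g$cn[in_seg, met]
  se <- 0.1 / sqrt(length(vals))
  expect_lt(abs(mean(vals) - 0.5), 3 * se)
  # primary samples unshifted at the same probes
  vals_p <- g$cn[in_seg, !met]
  expect_lt(abs(mean(vals_p)), 3 * 0.1 / sqrt(length(vals_p)))
})

test_that("overlapping same-group segments are rejected, cross-group allowed", {
  bad <- data.frame(chrom = c(1L, 1L), start_snp = c(5L, 8L),
                    end_snp = c(10L, 12L), group = c("met", "met"),
                    shift = c(0.5, 0.3))
  expect_error(quiet_config(segment_map = bad), "overlapping")
  ok <- data.frame(chrom = c(1L, 1L), start_snp = c(5L, 8L),
                   end_snp = c(10L, 12L), group = c("met", "primary"),
                   shift = c(0.5, 0.3))
  expect_s3_class(quiet_config(segment_map = ok), "sim_config")
})

test_that("null expression has no group effects and noiseless drivers are exactly linear", {
  cfg <- quiet_config(driver_beta = 0, de_nondriver_effect = 0,
                      noise_sd_expr = 0.3, n_primary = 25, n_met = 25, seed = 9)
  g <- generate_genomes(cfg)
  e <- generate_expression(g, cfg)
  met <- g$samples$group == "met"
  diffs <- rowMeans(e$expr[, met]) - rowMeans(e$expr[, !met])
  se <- 0.3 * sqrt(1 / sum(met) + 1 / sum(!met))
  expect_lt(abs(mean(diffs)), 3 * se / sqrt(nrow(e$expr)))
  expect_gt(mean(abs(diffs) < 3 * se), 0.95)

  # noiseless linear coupling: correlation with window copy number exactly 1
  cfg2 <- quiet_config(driver_beta = 1, noise_sd_expr = 0, seed = 9)
  g2 <- generate_genomes(cfg2)
  e2 <- generate_expression(g2, cfg2)
  for (id in e2$truth$driver_ids) {
    x <- e2$expr[id, ]
    ann <- e2$annotation[e2$annotation$transcript_id == id, ]
    snps <- map_snps(ann, g2$panel, cfg2$window_bp)
    truecn <- ifelse(g2$samples$group == "met",
                     mean(g2$truth$shift_tracks[g2$panel$probe_id %in% snps, "met"]),
                     mean(g2$truth$shift_tracks[g2$panel$probe_id %in% snps, "primary"]))
    expect_gt(stats::sd(truecn), 0)
    expect_equal(stats::cor(x, truecn), 1)
  }
})

test_that("DE-only transcripts carry the configured group shift", {
  cfg <- quiet_config(de_nondriver_effect = 1.0, noise_sd_expr = 0.2,
                      n_primary = 20, n_met = 20, seed = 13)
  g <- generate_genomes(cfg)
  e <- generate_expression(g, cfg)
  met <- g$samples$group == "met"
  se <- 0.2 * sqrt(1 / 20 + 1 / 20)
  for (id in e$truth$de_only_ids) {
    d <- mean(e$expr[id, met]) - mean(e$expr[id, !met])
    expect_lt(abs(d - 1.0), 3.5 * se)
  }
})

test_that("planted truth ids all exist in the emitted matrices", {
  cfg <- quiet_config(seed = 3)
  co <- simulate_cohort(cfg)
  ids <- c(co$truth$driver_ids, co$truth$de_only_ids, co$truth$null_ids)
  expect_setequal(ids, rownames(co$expr))
  expect_setequal(ids, co$annotation$transcript_id)
  expect_length(intersect(co$truth$driver_ids, co$truth$de_only_ids), 0)
  # every driver lies inside a group-differential segment window
  diff_probes <- co$truth$differential_snp_ids
  for (id in co$truth$driver_ids) {
    ann <- co$annotation[co$annotation$transcript_id == id, ]
    anchor <- co$panel$probe_id[co$panel$chrom == ann$chrom &
                                  co$panel$pos >= ann$start &
                                  co$panel$pos <= ann$end]
    expect_gt(length(intersect(anchor, diff_probes)), 0)
  }
})

test_that("driver demand beyond differential segment capacity is rejected", {
  expect_error(
    simulate_cohort(quiet_config(n_drivers = 11, n_transcripts = 60)),
    "exceeds SNPs")
})

test_that("survival generator honours hazards, censoring and the null", {
  cfg <- sim_config(hazard_disease = c(0.1, 0.1), hazard_other = c(0.05, 0.05),
                    hazard_censor = 0.05, seed = 21)
  cl <- rep(c(1L, 2L), each = 250)
  pts <- generate_survival(cl, cfg)
  fit <- survival::coxph(survival::Surv(time, status > 0) ~ cluster, data = pts)
  expect_gt(exp(coef(fit)), 0.8)
  expect_lt(exp(coef(fit)), 1.25)

  # zero censoring hazard forces events everywhere
  cfg2 <- sim_config(hazard_censor = 0, seed = 22)
  pts2 <- generate_survival(rep(1L, 200), cfg2)
  expect_true(all(pts2$status != 0))

  # 3:1 cause hazard ratio gives ~75% cause-1 deaths
  cfg3 <- sim_config(hazard_disease = c(0.3, 0.3), hazard_other = c(0.1, 0.1),
                     hazard_censor = 0, seed = 23)
  pts3 <- generate_survival(rep(1L, 400), cfg3)
  frac1 <- mean(pts3$status == 1)
  expect_lt(abs(frac1 - 0.75), 3 * sqrt(0.75 * 0.25 / 400))

  expect_error(sim_config(hazard_disease = c(0, 0.1)), "positive")
  expect_error(generate_survival(c(1, 3), cfg), "clusters")
})

test_that("screen generator: noise-free plates are exact, planted effects recover", {
  eff <- matrix(1, nrow = 2, ncol = 3,
                dimnames = list(c("gA", "gB"), NULL))
  cfg <- sim_config(n_lines = 3, replicate_cv = 0, suppression_effects = eff,
                    seed = 31)
  scr <- generate_screen(cfg)
  viab <- normalize_viability(scr$screen)
  expect_equal(viab$viability, rep(1, nrow(viab)))

  eff2 <- matrix(1, nrow = 2, ncol = 3, dimnames = list(c("gA", "gB"), NULL))
  eff2["gA", 2] <- 0.6
  cfg2 <- sim_config(n_lines = 3, n_replicates = 9, replicate_cv = 0.05,
                     suppression_effects = eff2, seed = 32)
  scr2 <- generate_screen(cfg2)
  viab2 <- normalize_viability(scr2$screen)
  hitrows <- viab2$gene == "gA" & viab2$cell_line == "line2"
  m <- mean(viab2$viability[hitrows])
  expect_lt(abs(m - 0.6), 3 * 0.6 * 0.05 / sqrt(9))

  expect_identical(generate_screen(cfg2), generate_screen(cfg2))
  eff_bad <- eff2; eff_bad["gB", 1] <- -0.2
  expect_error(sim_config(n_lines = 3, suppression_effects = eff_bad),
               "non-negative")
})
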