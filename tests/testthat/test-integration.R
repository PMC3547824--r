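test_that("cis-window mapping uses closed 250 kb boundaries", {
  panel <- data.frame(probe_id = c("a", "b", "c"),
                      chrom = "chr1",
                      pos = c(250000L, 760000L, 760001L),
                      stringsAsFactors = FALSE)
  tr <- list(chrom = "chr1", start = 500000L, end = 510000L)
  ids <- map_snps(tr, panel, 250000)
  expect_true("a" %in% ids)   # exactly at start - window
  expect_true("b" %in% ids)   # exactly at end + window
  expect_false("c" %in% ids)  # one bp outside
  # absent chromosome: empty with unmapped flag
  ids2 <- map_snps(list(chrom = "chrX", start = 1, end = 2), panel, 250000)
  expect_length(ids2, 0)
  expect_true(attr(ids2, "unmapped"))
})

test_that("cis-window mapping matches a brute-force interval scan", {
  set.seed(17)
  panel <- data.frame(probe_id = paste0("p", 1:30),
                      chrom = sample(c("chr1", "chr2"), 30, replace = TRUE),
                      pos = sample.int(2e6, 30),
                      stringsAsFactors = FALSE)
  for (i in 1:10) {
    st <- sample.int(2e6, 1)
    tr <- list(chrom = sample(c("chr1", "chr2"), 1), start = st,
               end = st + 10000)
    w <- sample(c(0, 50000, 250000), 1)
    got <- sort(map_snps(tr, panel, w))
    want <- sort(panel$probe_id[vapply(seq_len(30), function(j)
      panel$chrom[j] == tr$chrom && panel$pos[j] >= tr$start - w &&
        panel$pos[j] <= tr$end + w, logical(1))])
    expect_equal(got, want)
  }
})

test_that("transcript copy-number summary is the window mean", {
  prof <- matrix(c(0.2, 0.4, 9, 0.2, 0.4, 9), nrow = 3,
                 dimnames = list(c("s1", "s2", "s3"), c("A", "B")))
  expect_equal(transcript_cn(prof, c("s1", "s2")), c(A = 0.3, B = 0.3))
  expect_equal(transcript_cn(prof, "s1"), c(A = 0.2, B = 0.2))
  expect_equal(transcript_cn(prof, c("s2", "s1")),
               transcript_cn(prof, c("s1", "s2")))
  expect_error(transcript_cn(prof, character(0)), "empty")
})

test_that("robust correlation: noiseless slope, outlier resistance, constant guard", {
  cn <- seq(-0.5, 0.5, length.out = 10)
  r <- robust_corr_test(cn, 2 * cn)
  expect_lt(abs(r$slope - 2), 1e-6)
  expect_lt(r$p, 1e-6)

  # gross outlier: Huber slope beats least squares
  cn2 <- c(seq(0, 0.8, length.out = 9), 1)
  expr2 <- 3 * cn2; expr2[10] <- -20
  rh <- robust_corr_test(cn2, expr2)
  ols <- coef(stats::lm(expr2 ~ cn2))[2]
  expect_lt(abs(rh$slope - 3), abs(ols - 3))

  rc <- robust_corr_test(rep(0.3, 10), rnorm(10))
  expect_false(rc$ok)
  expect_equal(rc$reason, "constant_cn")
  expect_false(robust_corr_test(1:3, 1:3)$ok)
})

test_that("robust correlation p-values are calibrated under permutation", {
  set.seed(23)
  cn <- rnorm(20)
  expr <- rnorm(20)
  ps <- vapply(1:200, function(i)
    robust_corr_test(cn, sample(expr))$p, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 1e-3)
})

test_that("Wilcoxon engine: exact enumeration, ties, and symmetry", {
  # {1,2,3} vs {4,5,6}: 2 of 20 assignments as extreme -> p = 0.1
  lab <- factor(rep(c("primary", "met"), each = 3),
                levels = c("primary", "met"))
  r <- group_cn_difference(c(1, 2, 3, 4, 5, 6), lab)
  expect_true(r$exact)
  expect_equal(r$p, 0.1)
  expect_equal(r$p, wilcox_enum_p(c(1, 2, 3), c(4, 5, 6)))
  expect_gt(r$z, 0)  # higher CN in metastatic

  # identical multisets: no signal
  r2 <- group_cn_difference(c(1, 2, 3, 1, 2, 3), lab)
  expect_equal(r2$z, 0)
  expect_equal(r2$p, 1)

  # exact path agrees with wilcox.test on random tie-free fixtures
  set.seed(41)
  for (i in 1:10) {
    n1 <- sample(3:8, 1); n2 <- sample(3:12, 1)
    x <- sample(seq_len(50), n1 + n2)  # distinct -> no ties
    lab <- factor(rep(c("a", "b"), c(n1, n2)), levels = c("a", "b"))
    mine <- group_cn_difference(x, lab)
    ref <- stats::wilcox.test(x[lab == "b"], x[lab == "a"], exact = TRUE)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  }

  # tied data: normal approximation matches wilcox.test's corrected formula
  set.seed(43)
  x <- sample(1:8, 30, replace = TRUE)
  lab <- factor(rep(c("a", "b"), each = 15), levels = c("a", "b"))
  mine <- group_cn_difference(x, lab)
  expect_false(mine$exact)
  ref <- suppressWarnings(stats::wilcox.test(x[lab == "b"], x[lab == "a"],
                                             exact = FALSE, correct = TRUE))
  expect_equal(mine$p, ref$p.value, tolerance = 1e-10)

  # and is close to a Monte-Carlo permutation estimate
  mu_perm <- replicate(20000, {
    xp <- sample(x)
    abs(sum(rank(xp)[16:30]) - 15 * 16 / 2 - 112.5)
  })
  obs <- abs(mine$u - 112.5)
  expect_lt(abs(mean(mu_perm >= obs - 1e-9) - mine$p), 0.015)

  # swapping labels flips the sign, keeps p
  swapped <- group_cn_difference(x, factor(lab, levels = c("b", "a")))
  expect_equal(swapped$z, -mine$z)
  expect_equal(swapped$p, mine$p)
})

test_that("cascade gates nest and tighten monotonically", {
  cfg <- sim_config(n_chrom = 2, snps_per_chrom = 50, n_transcripts = 200,
                    n_drivers = 10, n_de_only = 10,
                    segment_map = data.frame(chrom = 1:2,
                                             start_snp = c(11L, 21L),
                                             end_snp = c(25L, 35L),
                                             group = "met",
                                             shift = c(0.5, -0.5)),
                    seed = 8)
  co <- simulate_cohort(cfg)
  pc <- pipeline_config()
  prof <- segment_profiles(co$cn, co$panel, pc$lam1, pc$lam2)
  lab <- factor(co$samples$group, levels = c("primary", "met"))
  res <- run_cascade(co$expr, prof, co$annotation, co$panel, lab, pc)

  # nesting: signature within correlated within DE
  cnt <- res$counts
  expect_lte(cnt[["signature"]], cnt[["correlated"]])
  expect_lte(cnt[["correlated"]], cnt[["mapped"]])
  expect_lte(cnt[["mapped"]], cnt[["de_selected"]])
  sig_ids <- res$signature$transcript_id
  corr_ids <- res$records$transcript_id[!is.na(res$records$corr_q) &
                                          res$records$corr_q < pc$corr_fdr]
  expect_true(all(sig_ids %in% corr_ids))

  # loosening the correlation gate can only grow the signature
  loose <- run_cascade(co$expr, prof, co$annotation, co$panel, lab,
                       pipeline_config(corr_fdr = 0.05))
  expect_gte(loose$counts[["signature"]], cnt[["signature"]])
  expect_true(all(sig_ids %in% loose$signature$transcript_id))
})

test_that("planted drivers are recovered with high precision and recall", {
  scores <- vapply(c(301, 302), function(s) {
    co <- simulate_cohort(sim_config(seed = s))
    pc <- pipeline_config()
    prof <- segment_profiles(co$cn, co$panel, pc$lam1, pc$lam2)
    lab <- factor(co$samples$group, levels = c("primary", "met"))
    res <- run_cascade(co$expr, prof, co$annotation, co$panel, lab, pc)
    sig <- res$signature$transcript_id
    tp <- length(intersect(sig, co$truth$driver_ids))
    c(tp / max(length(sig), 1), tp / length(co$truth$driver_ids))
  }, numeric(2))
  expect_gte(mean(scores[1, ]), 0.8)  # precision
  expect_gte(mean(scores[2, ]), 0.8)  # recall
})
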