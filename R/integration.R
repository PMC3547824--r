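#' Analysis pipeline configuration
#'
#' Central container for the cascade's constants: the +/- 250 kb cis window,
#' the stage-wise FDR gates (5% for differential expression, 1% for the
#' copy-number/expression correlation and for the group copy-number
#' difference), the gain/loss ratio thresholds 1.07/0.93, the screen
#' suppression threshold (30% viability loss), the number of principal
#' components and clusters for patient stratification, and the fused-lasso
#' penalties.
#'
#' @param window_bp cis-window half-width in bp (default 250000).
#' @param de_fdr,corr_fdr,diff_fdr FDR thresholds of the three gates.
#' @param t_loss,t_gain CNA call ratio thresholds.
#' @param suppression_threshold minimum fractional viability loss defining a
#'   screen hit.
#' @param n_pcs,k_clusters principal components and cluster count for
#'   patient stratification.
#' @param lam1,lam2 fused-lasso penalties for segmentation.
#' @param cn_summary how to summarize window SNPs into one transcript-level
#'   copy number: \code{"mean"} (default) or \code{"median"}.
#' @param seed integer seed for any randomized downstream step.
#' @return object of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(window_bp = 250000, de_fdr = 0.05,
                            corr_fdr = 0.01, diff_fdr = 0.01,
                            t_loss = 0.93, t_gain = 1.07,
                            suppression_threshold = 0.30,
                            n_pcs = 3, k_clusters = 2,
                            lam1 = 0.1, lam2 = 1,
                            cn_summary = c("mean", "median"),
                            seed = 1) {
  if (window_bp < 0) stop("window_bp must be >= 0")
  fdrs <- c(de_fdr, corr_fdr, diff_fdr)
  if (any(fdrs <= 0 | fdrs >= 1)) stop("FDR thresholds must lie in (0, 1)")
  if (!(t_loss > 0 && t_loss < 1 && t_gain > 1))
    stop("thresholds must satisfy 0 < t_loss < 1 < t_gain")
  if (suppression_threshold <= 0 || suppression_threshold >= 1)
    stop("suppression_threshold must lie in (0, 1)")
  cfg <- list(window_bp = window_bp, de_fdr = de_fdr, corr_fdr = corr_fdr,
              diff_fdr = diff_fdr, t_loss = t_loss, t_gain = t_gain,
              suppression_threshold = suppression_threshold,
              n_pcs = n_pcs, k_clusters = k_clusters,
              lam1 = lam1, lam2 = lam2,
              cn_summary = match.arg(cn_summary), seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Map SNPs to a transcript's cis window
#'
#' Returns the probes on the transcript's chromosome whose position lies in
#' the closed interval \[start - window_bp, end + window_bp\] (boundaries
#' inclusive). A transcript on a chromosome absent from the panel, or with
#' no SNP in its window, yields an empty vector flagged unmapped.
#'
#' @param transcript list or one-row data.frame with \code{chrom},
#'   \code{start}, \code{end} (1-based bp).
#' @param panel SNP panel data.frame (probe_id, chrom, pos).
#' @param window_bp window half-width in bp.
#' @return character vector of probe ids, with attribute \code{unmapped}
#'   (TRUE when empty).
#' @export
map_snps <- function(transcript, panel, window_bp = 250000) {
  if (window_bp < 0) stop("window_bp must be >= 0")
  hit <- panel$chrom == transcript$chrom &
    panel$pos >= transcript$start - window_bp &
    panel$pos <= transcript$end + window_bp
  ids <- panel$probe_id[hit]
  attr(ids, "unmapped") <- length(ids) == 0L
  ids
}

#' Transcript-level copy-number summary
#'
#' Summarizes the smoothed log2 copy-number estimates of the SNPs in a
#' transcript's cis window into one value per sample (arithmetic mean by
#' default, median optionally).
#'
#' @param profiles matrix of smoothed log2 estimates, probes x samples, with
#'   probe ids as rownames.
#' @param snp_ids probe ids in the transcript's window (non-empty).
#' @param summary \code{"mean"} or \code{"median"}.
#' @return numeric vector, one value per sample.
#' @export
transcript_cn <- function(profiles, snp_ids, summary = c("mean", "median")) {
  summary <- match.arg(summary)
  if (length(snp_ids) == 0L) stop("empty snp_ids: transcript has no window SNPs")
  sub <- profiles[snp_ids, , drop = FALSE]
  if (summary == "mean") colMeans(sub) else apply(sub, 2L, stats::median)
}

#' Robust copy-number/expression correlation test
#'
#' Huber M-estimated regression of expression on transcript-level copy
#' number (MAD-based scale, via \code{MASS::rlm}); the p-value is a
#' two-sided test of zero slope using the M-estimator's asymptotic standard
#' error with a normal reference.
#'
#' @param cn per-sample transcript copy-number vector.
#' @param expr per-sample expression vector.
#' @return list with \code{slope}, \code{se}, \code{p}, \code{ok} (logical)
#'   and \code{reason} (why the test was not performed, or NA).
#' @export
robust_corr_test <- function(cn, expr) {
  if (length(cn) != length(expr)) stop("cn and expr must have equal length")
  if (length(cn) < 4L)
    return(list(slope = NA_real_, se = NA_real_, p = NA_real_,
                ok = FALSE, reason = "too_few_samples"))
  if (stats::sd(cn) == 0)
    return(list(slope = NA_real_, se = NA_real_, p = NA_real_,
                ok = FALSE, reason = "constant_cn"))
  fit <- tryCatch(MASS::rlm(expr ~ cn, maxit = 100),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(fit))
    return(list(slope = NA_real_, se = NA_real_, p = NA_real_,
                ok = FALSE, reason = "rlm_failure"))
  cf <- stats::coef(summary(fit))
  slope <- cf["cn", "Value"]
  se <- cf["cn", "Std. Error"]
  tval <- if (se > 0) slope / se else sign(slope) * Inf
  list(slope = slope, se = se, p = 2 * stats::pnorm(-abs(tval)),
       ok = TRUE, reason = NA_character_)
}

#' Wilcoxon rank-sum test of group copy-number difference
#'
#' Midranks handle ties. When both groups have at least two samples, the
#' p-value is exact (null Mann-Whitney distribution) if the smaller group
#' has at most eight samples and there are no ties; otherwise a normal
#' approximation with tie correction and continuity correction is used. The
#' z statistic is signed so that positive means higher copy number in the
#' second factor level (metastatic by the package's convention).
#'
#' @param cn per-sample transcript copy-number vector.
#' @param labels two-level factor (or coercible); level 2 is the metastatic
#'   group.
#' @return list with \code{z}, \code{p}, \code{u} (Mann-Whitney U of the
#'   second group) and \code{exact} (logical).
#' @export
group_cn_difference <- function(cn, labels) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) stop("labels must have exactly two levels")
  g2 <- labels == levels(labels)[2L]
  n1 <- sum(!g2); n2 <- sum(g2)
  if (min(n1, n2) < 1L) stop("both groups must be non-empty")
  if (min(n1, n2) < 2L) stop("need at least two samples per group")
  r <- rank(cn)
  u <- sum(r[g2]) - n2 * (n2 + 1) / 2      # Mann-Whitney U of group 2
  ties <- table(cn)
  has_ties <- any(ties > 1L)
  mu <- n1 * n2 / 2
  n <- n1 + n2
  sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  sigma <- sqrt(sigma2)
  cc <- sign(u - mu) * 0.5                  # continuity correction
  z <- if (sigma > 0) (u - mu - cc) / sigma else 0
  exact <- !has_ties && min(n1, n2) <= 8L
  if (exact) {
    p <- if (u > mu) {
      2 * stats::pwilcox(u - 1, n2, n1, lower.tail = FALSE)
    } else {
      2 * stats::pwilcox(u, n2, n1)
    }
    p <- min(p, 1)
  } else {
    p <- if (sigma > 0) 2 * stats::pnorm(-abs(z)) else 1
  }
  list(z = z, p = p, u = u, exact = exact)
}

#' Run the integrative CNA/expression cascade
#'
#' Applies the three gates in order: (1) differential expression between
#' non-metastatic primary and metastatic samples at \code{de_fdr}; (2) within
#' the DE set, Huber-regression correlation between transcript-level copy
#' number and expression at \code{corr_fdr} (BH recomputed within the set);
#' (3) within the correlated set, Wilcoxon rank-sum test of the group
#' copy-number difference at \code{diff_fdr} (BH within the set). Survivors
#' of all three gates form the signature, partitioned into transcripts with
#' higher copy number and expression in metastatic samples (up_amplified),
#' lower in both (down_deleted), or discordant directions (retained,
#' flagged).
#'
#' @param expr expression matrix, transcripts x samples.
#' @param profiles smoothed copy-number matrix from [segment_profiles()],
#'   probes x samples.
#' @param annotation transcript annotation data.frame (transcript_id, gene,
#'   chrom, start, end).
#' @param panel SNP panel data.frame.
#' @param labels two-level factor; level 2 = metastatic.
#' @param config a [pipeline_config()].
#' @return list of class \code{"cascade_result"} with \code{records} (one
#'   row per DE-selected transcript with all statistics), \code{signature}
#'   (subset passing all gates), \code{de} (full DE table) and \code{counts}
#'   (named vector of stage sizes).
#' @export
run_cascade <- function(expr, profiles, annotation, panel, labels, config) {
  stopifnot(inherits(config, "pipeline_config"))
  labels <- as.factor(labels)
  if (ncol(expr) != length(labels)) stop("one label per expression column")
  if (!all(rownames(expr) %in% annotation$transcript_id))
    stop("annotation missing transcripts present in expression matrix")

  de <- de_screen(expr, labels, fdr = config$de_fdr)
  de_sel <- de$transcript_id[de$selected]

  ann <- annotation[match(de_sel, annotation$transcript_id), , drop = FALSE]
  snp_sets <- lapply(seq_len(nrow(ann)), function(i)
    map_snps(ann[i, ], panel, config$window_bp))
  mapped <- vapply(snp_sets, length, integer(1L)) > 0L

  nsel <- length(de_sel)
  rec <- data.frame(
    transcript_id = de_sel,
    gene = ann$gene,
    chrom = ann$chrom,
    n_snps = vapply(snp_sets, length, integer(1L)),
    de_effect = de$effect[match(de_sel, de$transcript_id)],
    de_q = de$q[match(de_sel, de$transcript_id)],
    corr_slope = rep(NA_real_, nsel), corr_p = rep(NA_real_, nsel),
    corr_q = rep(NA_real_, nsel),
    wilcoxon_z = rep(NA_real_, nsel), wilcoxon_p = rep(NA_real_, nsel),
    wilcoxon_q = rep(NA_real_, nsel),
    expr_up_met = de$effect[match(de_sel, de$transcript_id)] > 0,
    cn_up_met = rep(NA, nsel), discordant = rep(NA, nsel),
    in_signature = rep(FALSE, nsel),
    direction = rep(NA_character_, nsel),
    stringsAsFactors = FALSE
  )

  # gate 2: CN-expression correlation within the mapped DE set
  cn_list <- vector("list", nrow(rec))
  for (i in which(mapped)) {
    cn_list[[i]] <- transcript_cn(profiles, snp_sets[[i]],
                                  summary = config$cn_summary)
    ct <- robust_corr_test(cn_list[[i]], expr[rec$transcript_id[i], ])
    if (ct$ok) {
      rec$corr_slope[i] <- ct$slope
      rec$corr_p[i] <- ct$p
    }
  }
  testable <- which(!is.na(rec$corr_p))
  corr_pass <- integer()
  if (length(testable) > 0L) {
    sel <- bh_select(rec$corr_p[testable], config$corr_fdr)
    rec$corr_q[testable] <- sel$q
    corr_pass <- testable[sel$selected]
  }

  # gate 3: group CN difference within the correlated set
  if (length(corr_pass) > 0L) {
    for (i in corr_pass) {
      wt <- group_cn_difference(cn_list[[i]], labels)
      rec$wilcoxon_z[i] <- wt$z
      rec$wilcoxon_p[i] <- wt$p
    }
    sel <- bh_select(rec$wilcoxon_p[corr_pass], config$diff_fdr)
    rec$wilcoxon_q[corr_pass] <- sel$q
    sig_idx <- corr_pass[sel$selected]
    rec$in_signature[sig_idx] <- TRUE
    rec$cn_up_met[corr_pass] <- rec$wilcoxon_z[corr_pass] > 0
    rec$discordant <- rec$in_signature &
      (rec$expr_up_met != rec$cn_up_met)
    rec$direction[rec$in_signature] <- ifelse(
      rec$discordant[rec$in_signature], "discordant",
      ifelse(rec$expr_up_met[rec$in_signature], "up_amplified", "down_deleted"))
  }

  counts <- c(transcripts = nrow(expr), de_tested = nrow(de),
              de_selected = length(de_sel), mapped = sum(mapped),
              correlated = length(corr_pass),
              signature = sum(rec$in_signature))
  out <- list(records = rec,
              signature = rec[rec$in_signature, , drop = FALSE],
              de = de, counts = counts, config = config)
  class(out) <- "cascade_result"
  out
}

#' @export
print.cascade_result <- function(x, ...) {
  cat("Integrative CNA/expression cascade\n")
  cat(sprintf("  transcripts tested:   %d (of %d)\n",
              x$counts[["de_tested"]], x$counts[["transcripts"]]))
  cat(sprintf("  DE-selected (q<%g):   %d\n", x$config$de_fdr,
              x$counts[["de_selected"]]))
  cat(sprintf("  CN-correlated (q<%g): %d\n", x$config$corr_fdr,
              x$counts[["correlated"]]))
  cat(sprintf("  signature (q<%g):     %d\n", x$config$diff_fdr,
              x$counts[["signature"]]))
  invisible(x)
}
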