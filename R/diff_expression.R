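#' Pre-filter expression probes by variation and magnitude
#'
#' Removes probe sets that show no variation across samples or that are
#' expressed at very low magnitude, reducing the multiple-testing burden of
#' the downstream screen. A transcript is kept when its SD across samples
#' exceeds \code{min_sd} and its maximum value reaches \code{min_mag}.
#'
#' @param expr matrix of normalized log2 expression, transcripts x samples.
#' @param min_sd keep rows with SD strictly greater than this (default 0:
#'   drop exactly-constant rows only).
#' @param min_mag keep rows whose maximum is at least this; default the 25th
#'   percentile of the whole matrix.
#' @return character vector of kept transcript ids (rownames).
#' @export
filter_probes <- function(expr, min_sd = 0,
                          min_mag = stats::quantile(expr, 0.25)) {
  if (is.null(dim(expr)) || nrow(expr) == 0L || ncol(expr) == 0L)
    stop("empty expression matrix")
  if (min_sd < 0) stop("min_sd must be >= 0")
  sds <- apply(expr, 1L, stats::sd)
  maxs <- apply(expr, 1L, max)
  keep <- sds > min_sd & maxs >= min_mag
  rownames(expr)[keep]
}

#' Two-group differential-expression test with robust variance
#'
#' Per-transcript two-group linear model: the effect is the difference of
#' group means (second factor level minus first), its standard error the
#' heteroskedasticity-robust (HC0 sandwich) estimate
#' \eqn{\sqrt{\hat\sigma^2_1/n_1 + \hat\sigma^2_2/n_2}} with maximum-likelihood
#' group variances, and the p-value a two-sided normal tail for
#' z = effect / SE.
#'
#' @param x numeric vector of expression values for one transcript.
#' @param labels factor (or coercible) with exactly two levels; the effect is
#'   level 2 minus level 1.
#' @return list with \code{effect}, \code{z}, \code{p}.
#' @export
de_test <- function(x, labels) {
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) stop("labels must have exactly two levels")
  g2 <- labels == levels(labels)[2L]
  n1 <- sum(!g2); n2 <- sum(g2)
  if (min(n1, n2) < 2L) stop("need at least two samples per group")
  m1 <- mean(x[!g2]); m2 <- mean(x[g2])
  v1 <- sum((x[!g2] - m1)^2) / n1^2   # HC0: MLE variance / n
  v2 <- sum((x[g2] - m2)^2) / n2^2
  se <- sqrt(v1 + v2)
  effect <- m2 - m1
  z <- if (se > 0) effect / se else ifelse(effect == 0, 0, sign(effect) * Inf)
  list(effect = effect, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Benjamini-Hochberg selection
#'
#' Step-up FDR control: q-values are the monotone-adjusted \eqn{p \cdot m /
#' \mathrm{rank}}; a hypothesis is selected when its q-value is below the
#' threshold.
#'
#' @param pvals numeric vector of p-values in \[0, 1\].
#' @param q_threshold FDR level (default 0.05).
#' @return list with logical \code{selected} and numeric \code{q}.
#' @export
bh_select <- function(pvals, q_threshold = 0.05) {
  if (anyNA(pvals)) stop("NaN/NA p-value")
  if (any(pvals < 0 | pvals > 1)) stop("p-values must lie in [0, 1]")
  q <- stats::p.adjust(pvals, method = "BH")
  list(selected = q < q_threshold, q = q)
}

#' Differential-expression screen over a whole matrix
#'
#' Applies [filter_probes()], then [de_test()] per kept transcript
#' (vectorized), then [bh_select()] at the given FDR.
#'
#' @inheritParams filter_probes
#' @inheritParams de_test
#' @param fdr FDR threshold for selection (default 0.05).
#' @param min_sd,min_mag passed to [filter_probes()].
#' @return data.frame: transcript_id, effect, z, p, q, selected; one row per
#'   kept transcript.
#' @export
de_screen <- function(expr, labels, fdr = 0.05, min_sd = 0,
                      min_mag = stats::quantile(expr, 0.25)) {
  keep <- filter_probes(expr, min_sd = min_sd, min_mag = min_mag)
  sub <- expr[keep, , drop = FALSE]
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) stop("labels must have exactly two levels")
  g2 <- labels == levels(labels)[2L]
  n1 <- sum(!g2); n2 <- sum(g2)
  if (min(n1, n2) < 2L) stop("need at least two samples per group")
  m1 <- rowMeans(sub[, !g2, drop = FALSE])
  m2 <- rowMeans(sub[, g2, drop = FALSE])
  v1 <- rowSums((sub[, !g2, drop = FALSE] - m1)^2) / n1^2
  v2 <- rowSums((sub[, g2, drop = FALSE] - m2)^2) / n2^2
  se <- sqrt(v1 + v2)
  effect <- m2 - m1
  z <- ifelse(se > 0, effect / se,
              ifelse(effect == 0, 0, sign(effect) * Inf))
  p <- 2 * stats::pnorm(-abs(z))
  sel <- bh_select(p, fdr)
  data.frame(transcript_id = keep, effect = effect, z = z, p = p,
             q = sel$q, selected = sel$selected,
             stringsAsFactors = FALSE, row.names = NULL)
}
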