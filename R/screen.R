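#' Normalize siRNA screen readings to plate controls
#'
#' Divides every raw reading by the mean of the control wells (transfection
#' reagent only) of the same cell line/plate, producing relative viability
#' with 1 = control.
#'
#' @param raw data.frame with columns \code{gene}, \code{cell_line},
#'   \code{replicate}, \code{reading}, and \code{is_control} (logical) or a
#'   \code{control_gene} label identifying control wells.
#' @param control_gene gene label marking control wells when
#'   \code{is_control} is absent (default \code{"CONTROL"}).
#' @return the input data.frame with a \code{viability} column added;
#'   control rows retained (their mean viability is 1 by construction).
#' @export
normalize_viability <- function(raw, control_gene = "CONTROL") {
  need <- c("gene", "cell_line", "replicate", "reading")
  if (!all(need %in% names(raw))) stop("missing screen columns")
  if (any(raw$reading < 0)) stop("raw readings must be non-negative")
  is_ctrl <- if ("is_control" %in% names(raw)) raw$is_control
             else raw$gene == control_gene
  if (!any(is_ctrl)) stop("no control wells")
  ctrl_mean <- tapply(raw$reading[is_ctrl], raw$cell_line[is_ctrl], mean)
  if (any(is.na(ctrl_mean[unique(raw$cell_line)])))
    stop("a cell line has no control wells")
  if (any(ctrl_mean == 0)) stop("control mean is zero")
  raw$viability <- as.numeric(raw$reading / ctrl_mean[raw$cell_line])
  raw
}

#' Call growth-suppression hits
#'
#' A gene is a hit when its mean relative viability over replicates is at or
#' below \code{1 - threshold} in at least one cell line, i.e. knockdown
#' suppresses growth by at least \code{threshold} (default 30%) in at least
#' one line.
#'
#' @param viability data.frame from [normalize_viability()] (columns gene,
#'   cell_line, viability); control rows are ignored.
#' @param threshold minimum fractional viability loss (default 0.30).
#' @param control_gene control label to exclude.
#' @return data.frame: gene, min_viability (lowest per-line mean), hit
#'   (logical), plus one column of per-line mean viability per cell line.
#' @export
call_hits <- function(viability, threshold = 0.30, control_gene = "CONTROL") {
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)")
  drop_ctrl <- viability$gene == control_gene
  if ("is_control" %in% names(viability))
    drop_ctrl <- drop_ctrl | viability$is_control
  v <- viability[!drop_ctrl, , drop = FALSE]
  if (nrow(v) == 0L) stop("no gene readings")
  means <- tapply(v$viability, list(v$gene, v$cell_line), mean)
  if (anyNA(means)) stop("gene with no readings in some cell line")
  min_v <- apply(means, 1L, min)
  out <- data.frame(gene = rownames(means),
                    min_viability = as.numeric(min_v),
                    hit = as.numeric(min_v) <= 1 - threshold,
                    stringsAsFactors = FALSE, row.names = NULL)
  cbind(out, as.data.frame(means)[match(out$gene, rownames(means)), ,
                                  drop = FALSE])
}

#' Fisher exact enrichment of screen hits
#'
#' Two-sided Fisher's exact test comparing the hit proportion of the
#' signature gene set against a background set, by summing hypergeometric
#' probabilities of all tables (fixed margins) no more likely than the
#' observed one.
#'
#' @param hits_sig,n_sig hit count and size of the signature set.
#' @param hits_bg,n_bg hit count and size of the background set.
#' @return list with \code{p}, \code{odds_ratio} (conditional MLE) and
#'   \code{table} (the 2x2 matrix).
#' @export
fisher_enrichment <- function(hits_sig, n_sig, hits_bg, n_bg) {
  if (n_sig < 1 || n_bg < 1) stop("zero-size gene set")
  if (hits_sig < 0 || hits_sig > n_sig || hits_bg < 0 || hits_bg > n_bg)
    stop("hit counts must lie within set sizes")
  tab <- matrix(c(hits_sig, n_sig - hits_sig, hits_bg, n_bg - hits_bg),
                nrow = 2L,
                dimnames = list(c("hit", "no_hit"),
                                c("signature", "background")))
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  list(p = ft$p.value, odds_ratio = unname(ft$estimate), table = tab)
}
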