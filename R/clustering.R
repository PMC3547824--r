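#' Principal-component summary of signature expression
#'
#' Projects patients onto the leading principal components of the (centered,
#' unscaled) signature-transcript expression matrix, reporting per-component
#' and cumulative variance fractions.
#'
#' @param expr_subset expression matrix restricted to the signature
#'   transcripts, transcripts x patients.
#' @param n_pcs number of components to retain (default 3).
#' @return list of class \code{"pca_summary"}: \code{scores} (patients x
#'   n_pcs), \code{var_frac}, \code{cum_var_frac}.
#' @export
pca_scores <- function(expr_subset, n_pcs = 3) {
  x <- t(expr_subset)                      # patients x transcripts
  if (nrow(x) < n_pcs || ncol(x) < n_pcs)
    stop("need at least n_pcs patients and transcripts")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  rank_x <- sum(pc$sdev > max(pc$sdev) * 1e-12)
  if (n_pcs > rank_x) stop("n_pcs exceeds the rank of the centered matrix")
  var_all <- pc$sdev^2 / sum(pc$sdev^2)
  out <- list(scores = pc$x[, seq_len(n_pcs), drop = FALSE],
              var_frac = var_all[seq_len(n_pcs)],
              cum_var_frac = cumsum(var_all)[seq_len(n_pcs)])
  class(out) <- "pca_summary"
  out
}

#' Cluster patients on principal-component scores
#'
#' Agglomerative hierarchical clustering (Euclidean distance, Ward linkage
#' by default) of the patients' top principal-component scores, cut into
#' \code{k} groups. When the signature's metastatic direction vector and the
#' signature expression matrix are supplied, clusters are renamed so that
#' cluster 2 is the signature-concordant one: the cluster whose mean
#' signature expression deviation from the overall mean correlates best with
#' the metastatic direction (ties broken toward the larger cluster).
#'
#' @param scores a [pca_scores()] result or a numeric patients x components
#'   matrix.
#' @param k number of clusters (default 2).
#' @param expr_subset optional signature expression matrix (transcripts x
#'   patients) for the orientation rule.
#' @param direction optional numeric vector, one entry per signature
#'   transcript: the sign/magnitude of the metastatic expression change
#'   (e.g. the DE effect of each signature transcript).
#' @param method hclust linkage (default \code{"ward.D2"};
#'   \code{"complete"} available).
#' @return list of class \code{"cluster_assignment"}: \code{cluster}
#'   (integer vector), \code{concordance} (per-cluster correlation with the
#'   metastatic direction, NA when no direction given), \code{method}.
#' @export
cluster_patients <- function(scores, k = 2, expr_subset = NULL,
                             direction = NULL, method = c("ward.D2", "complete")) {
  method <- match.arg(method)
  if (inherits(scores, "pca_summary")) scores <- scores$scores
  scores <- as.matrix(scores)
  if (k < 2) stop("k must be >= 2")
  if (nrow(scores) < k) stop("need at least k patients")
  if (all(stats::dist(scores) == 0)) stop("all points identical: degenerate input")
  hc <- stats::hclust(stats::dist(scores), method = method)
  cl <- stats::cutree(hc, k = k)

  concord <- rep(NA_real_, k)
  if (!is.null(direction) && !is.null(expr_subset) && k == 2L) {
    overall <- rowMeans(expr_subset)
    concord <- vapply(seq_len(k), function(g) {
      dev <- rowMeans(expr_subset[, cl == g, drop = FALSE]) - overall
      if (stats::sd(dev) == 0 || stats::sd(direction) == 0) return(0)
      stats::cor(dev, direction)
    }, numeric(1L))
    # cluster 2 = signature-concordant; ties toward the larger cluster
    ord <- order(concord, tabulate(cl, k))
    relabel <- integer(k)
    relabel[ord] <- seq_len(k)
    cl <- relabel[cl]
    concord <- concord[ord]
  }
  out <- list(cluster = cl, concordance = concord, method = method)
  class(out) <- "cluster_assignment"
  out
}
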