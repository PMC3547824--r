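#' Exact 1-D total-variation denoising
#'
#' Computes the exact minimizer of
#' \deqn{\frac{1}{2}\sum_i (y_i - \beta_i)^2 + \lambda \sum_{i>1} |\beta_i - \beta_{i-1}|}
#' by Condat's direct (non-iterative) algorithm. This is the fusion-only
#' special case of the sparse fused-lasso signal approximator and the
#' workhorse for copy-number segmentation of ordered SNP log ratios.
#'
#' @param y numeric vector of noisy observations (finite).
#' @param lam non-negative fusion penalty.
#' @return numeric vector of the same length: the unique minimizer, a
#'   piecewise-constant signal.
#' @references Condat, L. (2013) A direct algorithm for 1-D total variation
#'   denoising. IEEE Signal Processing Letters 20(11), 1054-1057.
#' @export
tv_denoise <- function(y, lam) {
  if (length(y) == 0L) stop("empty input vector")
  if (!all(is.finite(y))) stop("input must be finite")
  if (!is.numeric(lam) || length(lam) != 1L || is.na(lam) || lam < 0)
    stop("lam must be a single non-negative number")
  n <- length(y)
  if (n == 1L || lam == 0) return(as.numeric(y))
  y <- as.numeric(y)
  x <- numeric(n)

  k <- k0 <- km <- kp <- 1L
  vmin <- y[1L] - lam
  vmax <- y[1L] + lam
  umin <- lam
  umax <- -lam

  repeat {
    if (k == n) {                       # last sample reached with no pending jump
      x[k0:n] <- vmin + umin            # boundary: x_n = vmin + umin
      break
    }
    if (y[k + 1L] + umin < vmin - lam) {        # negative jump is necessary
      x[k0:km] <- vmin
      k <- k0 <- km <- kp <- km + 1L
      vmin <- y[k]
      vmax <- y[k] + 2 * lam
      umin <- lam
      umax <- -lam
    } else if (y[k + 1L] + umax > vmax + lam) { # positive jump is necessary
      x[k0:kp] <- vmax
      k <- k0 <- km <- kp <- kp + 1L
      vmin <- y[k] - 2 * lam
      vmax <- y[k]
      umin <- lam
      umax <- -lam
    } else {                                    # no jump: extend the segment
      k <- k + 1L
      umin <- umin + y[k] - vmin
      umax <- umax + y[k] - vmax
      if (umin >= lam) {                        # update lower bound estimate
        vmin <- vmin + (umin - lam) / (k - k0 + 1L)
        umin <- lam
        km <- k
      }
      if (umax <= -lam) {                       # update upper bound estimate
        vmax <- vmax + (umax + lam) / (k - k0 + 1L)
        umax <- -lam
        kp <- k
      }
    }
    if (k < n) next
    # k == n: decide whether the final segment still needs to be split
    if (umin < 0) {                     # negative jump at the end
      x[k0:km] <- vmin
      k <- k0 <- km <- km + 1L
      vmin <- y[k]
      umin <- lam
      umax <- y[k] + lam - vmax
    } else if (umax > 0) {              # positive jump at the end
      x[k0:kp] <- vmax
      k <- k0 <- kp <- kp + 1L
      vmax <- y[k]
      umax <- -lam
      umin <- y[k] - lam - vmin
    } else {                            # flat finish
      x[k0:n] <- vmin + umin / (k - k0 + 1L)
      break
    }
  }
  x
}

#' Sparse fused-lasso signal approximator (exact)
#'
#' Solves
#' \deqn{\min_\beta \frac{1}{2}\sum_i (y_i-\beta_i)^2 + \lambda_1\sum_i|\beta_i|
#'       + \lambda_2\sum_{i>1}|\beta_i-\beta_{i-1}|}
#' exactly, via total-variation denoising at \code{lam2} followed by
#' soft-thresholding at \code{lam1} (the two-step solution is exact for this
#' objective). With both penalties zero the input is returned unchanged.
#' The sparsity penalty shrinks toward zero, the natural neutral point for
#' log2 tumor:reference copy-number ratios; the fusion penalty enforces the
#' piecewise-constant structure of segmental gains and losses.
#'
#' @param y numeric vector of log2 ratios along one chromosome, in genomic
#'   order.
#' @param lam1 non-negative sparsity penalty (shrinkage toward 0).
#' @param lam2 non-negative fusion penalty (smoothness between neighbours).
#' @return numeric vector: the unique minimizer.
#' @references Friedman, J., Hastie, T., Hoefling, H. and Tibshirani, R.
#'   (2007) Pathwise coordinate optimization. Annals of Applied Statistics
#'   1(2), 302-332.
#' @examples
#' y <- c(0, 0.1, -0.05, 0.6, 0.55, 0.62, 0.01)
#' fused_lasso_smooth(y, lam1 = 0.05, lam2 = 0.5)
#' @export
fused_lasso_smooth <- function(y, lam1, lam2) {
  if (length(y) == 0L) stop("empty input vector")
  if (!is.numeric(lam1) || length(lam1) != 1L || is.na(lam1) || lam1 < 0)
    stop("lam1 must be a single non-negative number")
  z <- tv_denoise(y, lam2)
  sign(z) * pmax(abs(z) - lam1, 0)
}
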