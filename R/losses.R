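# The three-term training objective. All terms operate in the whitened
# coordinate space: the frozen whitening/unwhitening layers live inside the
# model, so residuals are naturally whitened and reporting-level RMSD is
# computed after unwhitening.

#' Reconstruction loss: combined absolute and squared error
#'
#' Mean over the batch of the mean over output nodes of
#' `|x - xhat| + (x - xhat)^2`: the L1 part funnels reconstructions to the
#' target coordinates, the L2 part strongly discourages outliers.
#'
#' @param x target matrix (batch x nodes, whitened coordinates)
#' @param xhat reconstruction matrix of the same shape
#' @return nonnegative scalar
#' @export
reconLoss <- function(x, xhat) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (is.null(dim(xhat))) xhat <- matrix(xhat, nrow = 1)
  stopUnless(identical(dim(x), dim(xhat)), "x and xhat must have the same shape")
  e <- x - xhat
  mean(abs(e) + e^2)
}

#' Classification loss: binary cross-entropy with fractional targets
#'
#' Mean over the batch of `-[y log(yhat) + (1 - y) log(1 - yhat)]`.
#' Fractional targets (EM-refined labels) are supported, and the loss is
#' linear in `y`. Classifier outputs exactly at 0 or 1 are clamped to
#' `[eps, 1 - eps]`.
#'
#' @param y targets in `[0, 1]`
#' @param yhat classifier outputs in `(0, 1)`
#' @param eps clamp width (default 1e-7)
#' @return nonnegative scalar
#' @export
classLoss <- function(y, yhat, eps = 1e-7) {
  stopUnless(length(y) == length(yhat), "y and yhat must have equal length")
  stopUnless(all(y >= 0 & y <= 1), "targets must lie in [0, 1]")
  if (any(yhat <= 0 | yhat >= 1)) {
    yhat <- pmin(pmax(yhat, eps), 1 - eps)
  }
  -mean(y * log(yhat) + (1 - y) * log(1 - yhat))
}

#' Latent-decorrelation loss: squared off-diagonal covariance
#'
#' Sum over all ordered pairs `i != j` of the squared sample covariance
#' between latent variables over the batch (so each unordered pair counts
#' twice). The covariance uses the 1/N normalizer; the choice of normalizer
#' does not change the minimizer.
#'
#' @param z batch x latent matrix
#' @return nonnegative scalar
#' @export
corrLoss <- function(z) {
  if (is.null(dim(z))) z <- matrix(z, ncol = 1)
  if (nrow(z) < 2) stop("corr loss needs a batch of at least 2", call. = FALSE)
  zc <- sweep(z, 2, colMeans(z))
  C <- crossprod(zc) / nrow(z)
  diag(C) <- 0
  sum(C^2)
}

#' Weighted total training objective
#'
#' `w_recon * reconLoss + w_class * classLoss + w_corr * corrLoss`, all
#' weights 1 by default. A classification weight of 0 omits the
#' classification term entirely (the unsupervised-autoencoder baseline).
#'
#' @param batch list with `x`, `xhat` (whitened), `y`, `yhat`, `z`
#' @param weights nonnegative numeric length 3 (recon, class, corr)
#' @return scalar total loss and components as attribute `components`
#' @export
totalLoss <- function(batch, weights = c(1, 1, 1)) {
  stopUnless(length(weights) == 3 && all(weights >= 0),
             "weights must be three nonnegative numbers")
  lr <- reconLoss(batch$x, batch$xhat)
  lc <- if (weights[2] > 0) classLoss(batch$y, batch$yhat) else 0
  lz <- corrLoss(batch$z)
  total <- weights[1] * lr + weights[2] * lc + weights[3] * lz
  attr(total, "components") <- c(recon = lr, class = lc, corr = lz)
  total
}
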