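#' @include nn-layers.R
NULL

#' Element-wise binary cross-entropy loss
#'
#' Mean over voxels (and batch) of `-[t log p + (1 - t) log(1 - p)]` between a
#' predicted probability volume and a binary target volume. Predictions are
#' clipped to `[eps, 1 - eps]` for numerical safety; the loss is nonnegative
#' and (up to clipping) zero iff prediction equals target. Training uses the
#' mathematically equivalent fused logit formulation internally; this is the
#' probability-space evaluation form.
#'
#' @param pred probability volume(s) ([VoxelGrid] or array), values in \[0,1\]
#' @param target binary volume of the same shape
#' @param eps clipping constant
#' @return scalar loss (nats per voxel)
#' @export
ceLoss <- function(pred, target, eps = 1e-7) {
  p <- if (is(pred, "VoxelGrid")) pred@data else pred
  t <- if (is(target, "VoxelGrid")) target@data else target
  if (!identical(dim(p), dim(t)))
    uwStop("prediction and target shapes differ", "contractError")
  if (!isBinaryGrid(t))
    uwStop("target must be binary", "contractError")
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(t * log(p) + (1 - t) * log(1 - p))
}

#' Mean-squared error loss
#'
#' Mean of squared differences between predicted and true weights, in kg^2.
#'
#' @param pred,truth equal-length numeric vectors (kg)
#' @return scalar loss (kg^2)
#' @export
mseLoss <- function(pred, truth) {
  if (length(pred) != length(truth))
    uwStop("prediction and truth lengths differ", "contractError")
  if (length(pred) == 0) uwStop("empty batch", "contractError")
  mean((pred - truth)^2)
}
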