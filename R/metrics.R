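# Evaluation metrics over noise realisations: voxel-level bias / SD / NRMSE
# against a noise-free reference, and tumour-ROI TAC bias / SD / NRMSE.

#' Voxel-level bias, SD and NRMSE over noise realisations
#'
#' With `x_bar` the across-realisation mean image and `x_ref` the
#' noise-free reference, over the mask `omega`:
#' `Bias = 100 sqrt(sum (x_bar - x_ref)^2 / sum x_ref^2)`,
#' `SD = 100 sqrt((1/R) sum_r sum (x_bar - x_r)^2 / sum x_ref^2)`,
#' `NRMSE = sqrt(Bias^2 + SD^2)` (all in percent).
#'
#' @param images Array `R x J x T` (or a list of `J x T` matrices) of
#'   realisations.
#' @param reference `J x T` reference matrix.
#' @param mask Logical vector of length `J` (evaluation region); default all.
#' @param per_frame If `TRUE`, return one row per frame; otherwise pool all
#'   frames of the masked region into one summary.
#' @return Data frame with columns `frame` (`NA` for pooled), `bias`, `sd`,
#'   `nrmse` (percent).
#' @export
voxel_bias_sd_nrmse <- function(images, reference, mask = NULL,
                                per_frame = FALSE) {
  if (is.list(images)) {
    images <- aperm(simplify2array(images), c(3, 1, 2))
  }
  stopifnot(length(dim(images)) == 3)
  R <- dim(images)[1]
  stopifnot(R >= 2, dim(images)[2] == nrow(reference),
            dim(images)[3] == ncol(reference))
  if (any(reference < 0)) stop("reference must be nonnegative")
  if (is.null(mask)) mask <- rep(TRUE, nrow(reference))
  stopifnot(sum(mask) > 0)
  xbar <- apply(images, c(2, 3), mean)
  one <- function(cols) {
    ref <- reference[mask, cols, drop = FALSE]
    den <- sum(ref^2)
    if (den <= 0) stop("zero-norm reference over the evaluated region")
    xb <- xbar[mask, cols, drop = FALSE]
    bias2 <- sum((xb - ref)^2) / den
    sd2 <- sum(vapply(seq_len(R), function(r)
      sum((xb - images[r, mask, cols])^2), numeric(1))) / (R * den)
    c(bias = 100 * sqrt(bias2), sd = 100 * sqrt(sd2),
      nrmse = 100 * sqrt(bias2 + sd2))
  }
  if (per_frame) {
    out <- t(vapply(seq_len(ncol(reference)), one, numeric(3)))
    data.frame(frame = seq_len(ncol(reference)), out)
  } else {
    data.frame(frame = NA_integer_, t(one(seq_len(ncol(reference)))))
  }
}

#' Extract an ROI-mean TAC from a dynamic image
#'
#' @param dyn A [dynamic_image()] or `J x T` matrix.
#' @param roi_mask Logical vector of length `J` (non-empty).
#' @return Numeric vector of length `T`: frame-wise mean over the mask.
#' @export
extract_roi_tac <- function(dyn, roi_mask) {
  m <- if (inherits(dyn, "dynamic_image")) dyn$values else as.matrix(dyn)
  roi_mask <- as.logical(roi_mask)
  if (sum(roi_mask) == 0) stop("empty ROI mask")
  colMeans(m[roi_mask, , drop = FALSE])
}

#' ROI-TAC bias, SD and NRMSE over noise realisations
#'
#' Per frame, with `c_bar` the across-realisation mean and `c_ref` the
#' reference TAC: `Bias = 100 |c_bar - c_ref| / c_ref`,
#' `SD = 100 sqrt((1/R) sum_r (c_r - c_bar)^2) / c_ref`,
#' `NRMSE = sqrt(Bias^2 + SD^2)`. Frames with non-positive reference are
#' excluded (with a warning) and the aggregate is the unweighted mean over
#' the evaluated frames.
#'
#' @param tacs `R x T` matrix of realisation TACs (or list of vectors).
#' @param reference Reference TAC, length `T`.
#' @return List with `per_frame` (data frame: frame, bias, sd, nrmse) and
#'   `aggregate` (named vector of the frame means).
#' @export
roi_tac_nrmse <- function(tacs, reference) {
  if (is.list(tacs)) tacs <- do.call(rbind, tacs)
  stopifnot(nrow(tacs) >= 2, ncol(tacs) == length(reference))
  keep <- reference > 0
  if (!all(keep)) warning(sum(!keep), " frame(s) with non-positive reference excluded")
  cbar <- colMeans(tacs)
  R <- nrow(tacs)
  bias <- 100 * abs(cbar - reference) / reference
  sdv <- 100 * sqrt(colMeans((tacs - rep(cbar, each = R))^2)) / reference
  nrmse <- sqrt(bias^2 + sdv^2)
  per <- data.frame(frame = which(keep), bias = bias[keep], sd = sdv[keep],
                    nrmse = nrmse[keep])
  agg <- c(bias = mean(per$bias), sd = mean(per$sd), nrmse = mean(per$nrmse))
  list(per_frame = per, aggregate = agg)
}
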