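# Volume-level inference: slice-wise application of a trained network,
# optionally restricted to an ROI box (predictions are pasted back into a
# full-grid mask that is zero outside the box). The full-volume box reduces
# ROI-constrained inference to the plain full-size pipeline bit-for-bit.

#' Inference configuration
#'
#' @param input_size network input size `(h, w)`, divisible by 8.
#' @param threshold binarization threshold in (0, 1).
#' @param phase phase selector for single-phase networks.
#' @return list of class `infer_config`.
#' @export
infer_config <- function(input_size = c(256, 256), threshold = 0.5,
                         phase = 1) {
  if (length(input_size) == 1) input_size <- c(input_size, input_size)
  if (any(input_size < 8) || any(input_size %% 8 != 0))
    stopf("input_size must be >= 8 and divisible by 8")
  if (threshold <= 0 || threshold >= 1) stopf("threshold must be in (0, 1)")
  structure(list(input_size = as.integer(input_size), threshold = threshold,
                 phase = phase), class = "infer_config")
}

#' ROI-constrained segmentation of one case
#'
#' Crops both phases to the box, normalizes and resamples every slice of the
#' block to the network input size, applies the network per slice, resamples
#' the score maps back to the block slice size (bilinear, before
#' thresholding), binarizes, and pastes the stacked block into a full-grid
#' mask that is zero outside the box. Works with a fusion network (both
#' phases) or a single-phase network (phase selected by `cfg$phase`).
#'
#' @param net a trained `dfn` or `dcnn`.
#' @param case list with `phase1`, `phase2` (or `phase2_registered`) and a
#'   3D grid; a `phantom_case` works directly.
#' @param box a [roi_box()]; use [segment_case()] for the full volume.
#' @param cfg an [infer_config()].
#' @return full-grid binary mask (integer array), foreground strictly inside
#'   the box.
#' @export
segment_roi <- function(net, case, box, cfg) {
  dims <- dim(case$phase1)
  if (box$empty) stopf("cannot segment a degenerate ROI box")
  if (box$z[2] <= box$z[1]) stopf("ROI box contains no slices")
  p2 <- case$phase2_registered %||% case$phase2
  b1 <- crop_to_roi(case$phase1, box)
  b2 <- crop_to_roi(p2, box)
  bd <- dim(b1)
  prep <- function(block, z)
    normalize_intensity(resize2d(block[, , z], cfg$input_size[1],
                                 cfg$input_size[2]))
  x1 <- stack_slices(lapply(seq_len(bd[3]), function(z) prep(b1, z)))
  score <- if (inherits(net, "dfn")) {
    x2 <- stack_slices(lapply(seq_len(bd[3]), function(z) prep(b2, z)))
    dfn_forward(net, x1, x2)$out
  } else {
    xin <- if (cfg$phase == 1) x1
           else stack_slices(lapply(seq_len(bd[3]), function(z) prep(b2, z)))
    dcnn_forward(net, xin)
  }
  block <- array(0L, bd)
  for (z in seq_len(bd[3])) {
    sm <- resize2d(score[, , 1, z], bd[1], bd[2])
    block[, , z] <- binarize(sm, cfg$threshold)
  }
  out <- paste_from_roi(block, box, dims)
  array(as.integer(out), dims)
}

#' Full-volume segmentation of one case
#'
#' Equivalent to [segment_roi()] with a box covering the whole volume; this
#' is the full-size inference pipeline of the non-interactive models.
#'
#' @inheritParams segment_roi
#' @return full-grid binary mask.
#' @export
segment_case <- function(net, case, cfg) {
  segment_roi(net, case, full_box(dim(case$phase1)), cfg)
}
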