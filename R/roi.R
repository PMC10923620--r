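#' Axis-aligned 3D ROI box
#'
#' Coordinates are 0-based half-open voxel ranges `[lo, hi)` on the phase-1
#' grid, matching the convention used throughout the package for crops and
#' JSON interchange.
#'
#' @param x,y,z numeric pairs `c(lo, hi)` with `lo < hi`.
#' @param empty logical; a degenerate box (e.g. the bounding box of an empty
#'   mask) carries `empty = TRUE` and no usable ranges.
#' @return An object of class `roi_box`.
#' @export
roi_box <- function(x, y, z, empty = FALSE) {
  if (!empty) {
    for (r in list(x, y, z))
      if (length(r) != 2 || r[1] >= r[2])
        stopf("roi_box ranges must be c(lo, hi) with lo < hi")
  }
  structure(list(x = x, y = y, z = z, empty = empty), class = "roi_box")
}

#' @export
print.roi_box <- function(x, ...) {
  if (x$empty) cat("<roi_box: empty>\n")
  else cat(sprintf("<roi_box x:[%g,%g) y:[%g,%g) z:[%g,%g)>\n",
                   x$x[1], x$x[2], x$y[1], x$y[2], x$z[1], x$z[2]))
  invisible(x)
}

box_shape <- function(box) {
  if (box$empty) return(c(0L, 0L, 0L))
  c(box$x[2] - box$x[1], box$y[2] - box$y[1], box$z[2] - box$z[1])
}

full_box <- function(dims) roi_box(c(0, dims[1]), c(0, dims[2]), c(0, dims[3]))

# Tight 0-based half-open bounding box of a binary mask.
mask_bbox <- function(mask) {
  idx <- which(mask > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) return(roi_box(NULL, NULL, NULL, empty = TRUE))
  roi_box(c(min(idx[, 1]) - 1, max(idx[, 1])),
          c(min(idx[, 2]) - 1, max(idx[, 2])),
          c(min(idx[, 3]) - 1, max(idx[, 3])))
}

#' Planar rectangle on one of the three named planes
#'
#' The radiologist intervention is expressed as three rectangles dragged on
#' the x-y, x-z and y-z planes; each rectangle constrains two axes with
#' 0-based half-open ranges.
#'
#' @param plane one of `"xy"`, `"xz"`, `"yz"`.
#' @param a,b numeric pairs `c(lo, hi)`: the ranges along the first and second
#'   named axis of the plane.
#' @return An object of class `planar_rectangle`.
#' @export
planar_rectangle <- function(plane = c("xy", "xz", "yz"), a, b) {
  plane <- match.arg(plane)
  for (r in list(a, b))
    if (length(r) != 2 || r[1] >= r[2]) stopf("rectangle ranges must be nonempty")
  structure(list(plane = plane, a = a, b = b), class = "planar_rectangle")
}

#' Build a 3D ROI box from three planar rectangles
#'
#' Each axis is constrained by exactly two of the three rectangles; the box
#' range on that axis is the interval union of the two constraints (the
#' conservative reading of "the target lesion must be completely included"),
#' expanded by `margin` voxels per side and clipped to the volume bounds.
#' Consequently every voxel lying inside all three rectangles' constraints is
#' inside the box, and enlarging any rectangle never shrinks the box.
#'
#' @param rxy,rxz,ryz [planar_rectangle()]s on the three distinct planes.
#' @param margin voxels added on every side before clipping.
#' @param bounds volume shape (x, y, z) used for clipping.
#' @return A [roi_box()].
#' @export
box_from_rectangles <- function(rxy, rxz, ryz, margin = 2, bounds) {
  planes <- vapply(list(rxy, rxz, ryz), `[[`, "", "plane")
  if (!identical(planes, c("xy", "xz", "yz")))
    stopf("rectangles must be supplied on planes xy, xz, yz (got %s)",
          paste(planes, collapse = ", "))
  uni <- function(r1, r2) c(min(r1[1], r2[1]), max(r1[2], r2[2]))
  x <- uni(rxy$a, rxz$a); y <- uni(rxy$b, ryz$a); z <- uni(rxz$b, ryz$b)
  clip <- function(r, n) c(max(0, r[1] - margin), min(n, r[2] + margin))
  x <- clip(x, bounds[1]); y <- clip(y, bounds[2]); z <- clip(z, bounds[3])
  if (x[1] >= x[2] || y[1] >= y[2] || z[1] >= z[2])
    stopf("ROI box is empty after clipping to the volume bounds")
  roi_box(x, y, z)
}

#' Crop a volume or mask to an ROI box
#'
#' @param v 3D array.
#' @param box a non-degenerate [roi_box()] (clipped to the volume bounds).
#' @return The block; voxel (0,0,0) of the block is voxel
#'   (x.lo, y.lo, z.lo) of the source.
#' @export
crop_to_roi <- function(v, box) {
  if (box$empty) stopf("cannot crop to a degenerate ROI box")
  d <- dim(v)
  if (box$x[1] < 0 || box$y[1] < 0 || box$z[1] < 0 ||
      box$x[2] > d[1] || box$y[2] > d[2] || box$z[2] > d[3])
    stopf("ROI box exceeds volume bounds")
  v[(box$x[1] + 1):box$x[2], (box$y[1] + 1):box$y[2],
    (box$z[1] + 1):box$z[2], drop = FALSE]
}

#' Paste a block back into a zero volume at its ROI position
#'
#' @param block 3D array with the box extents.
#' @param box the [roi_box()] the block was cropped with.
#' @param dims full-volume shape.
#' @return Full-size array, zero outside the box.
#' @export
paste_from_roi <- function(block, box, dims) {
  out <- array(0, dims)
  out[(box$x[1] + 1):box$x[2], (box$y[1] + 1):box$y[2],
      (box$z[1] + 1):box$z[2]] <- block
  out
}

#' Jittered bounding-box ROI from a ground-truth mask
#'
#' Stand-in for a manually dragged rough ROI: the tight bounding box of the
#' mask with each face independently jittered by up to `jitter` voxels, then
#' expanded by `margin` and clipped. With `jitter = 0, margin = 0` this is the
#' tight bounding box.
#'
#' @param mask binary 3D array.
#' @param jitter maximum absolute per-face jitter, voxels.
#' @param margin voxels added per side after jittering.
#' @param seed integer seed for the jitter draw.
#' @return A [roi_box()]; degenerate (empty) if the mask is empty.
#' @export
roi_from_mask <- function(mask, jitter = 0, margin = 0, seed = 1L) {
  bb <- mask_bbox(mask)
  if (bb$empty) return(bb)
  d <- dim(mask)
  with_seed(seed, {
    j <- if (jitter > 0) sample(seq(-jitter, jitter), 6, replace = TRUE)
         else rep(0, 6)
    x <- c(bb$x[1] + j[1], bb$x[2] + j[2])
    y <- c(bb$y[1] + j[3], bb$y[2] + j[4])
    z <- c(bb$z[1] + j[5], bb$z[2] + j[6])
    clip <- function(r, n) c(max(0, r[1] - margin), min(n, r[2] + margin))
    x <- clip(x, d[1]); y <- clip(y, d[2]); z <- clip(z, d[3])
    # never let jitter collapse an axis
    if (x[1] >= x[2]) x <- c(max(0, bb$x[1] - margin), min(d[1], bb$x[2] + margin))
    if (y[1] >= y[2]) y <- c(max(0, bb$y[1] - margin), min(d[2], bb$y[2] + margin))
    if (z[1] >= z[2]) z <- c(max(0, bb$z[1] - margin), min(d[3], bb$z[2] + margin))
    roi_box(x, y, z)
  })
}

#' Read/write an ROI box as JSON
#'
#' The JSON schema stores either an explicit box or three planar rectangles,
#' a margin, and the coordinate convention string `"0-based half-open"`.
#'
#' @param box a [roi_box()].
#' @param path file path.
#' @name roi_json
#' @export
save_roi <- function(box, path) {
  jsonlite::write_json(list(convention = "0-based half-open",
                            x = box$x, y = box$y, z = box$z,
                            empty = box$empty),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname roi_json
#' @export
load_roi <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(j$convention, "0-based half-open"))
    stopf("ROI file %s does not declare the 0-based half-open convention", path)
  if (isTRUE(j$empty)) return(roi_box(NULL, NULL, NULL, empty = TRUE))
  roi_box(as.numeric(j$x), as.numeric(j$y), as.numeric(j$z))
}
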