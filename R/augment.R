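# Paired data augmentation: shared geometric transform (rotation, scaling,
# horizontal mirroring) across both phases and the mask; photometric
# transforms (contrast offset, additive noise) per phase, images only.

#' Augmentation parameters
#'
#' Default ranges follow the training protocol: rotation -20..20 degrees,
#' scaling 0.9..1.1, contrast adjustment -5..5 (read as an additive offset on
#' a 0-255 intensity scale, i.e. about +/-2% of the dynamic range; a
#' multiplicative variant is available via `contrast_mode`), additive
#' Gaussian noise, and horizontal mirroring.
#'
#' @param rotation_deg rotation range, degrees.
#' @param scale isotropic scale range.
#' @param contrast_shift offset range on a 0-255 scale.
#' @param contrast_mode `"additive"` (offset / 255) or `"multiplicative"`
#'   (1 + offset / 255 gain).
#' @param noise_sigma additive Gaussian noise s.d., fraction of range.
#' @param mirror allow horizontal mirroring.
#' @param multiplicity augmented copies per original pair.
#' @param include_originals append the unaugmented pairs to the output.
#' @param seed integer seed controlling all draws.
#' @return list of class `augment_params`.
#' @export
augment_params <- function(rotation_deg = c(-20, 20), scale = c(0.9, 1.1),
                           contrast_shift = c(-5, 5),
                           contrast_mode = c("additive", "multiplicative"),
                           noise_sigma = 0.01, mirror = TRUE,
                           multiplicity = 2L, include_originals = TRUE,
                           seed = 1L) {
  contrast_mode <- match.arg(contrast_mode)
  if (multiplicity < 0) stopf("multiplicity must be >= 0")
  structure(list(rotation_deg = rotation_deg, scale = scale,
                 contrast_shift = contrast_shift,
                 contrast_mode = contrast_mode,
                 noise_sigma = noise_sigma, mirror = mirror,
                 multiplicity = as.integer(multiplicity),
                 include_originals = include_originals,
                 seed = as.integer(seed)),
            class = "augment_params")
}

#' Sample one augmentation draw
#'
#' @param params an [augment_params()].
#' @return list with `rotation`, `scale`, `mirror`, per-phase `contrast` and
#'   `noise_seed` entries. Drawing consumes the current RNG stream.
#' @export
draw_augment <- function(params) {
  list(rotation = runif(1, params$rotation_deg[1], params$rotation_deg[2]),
       scale = runif(1, params$scale[1], params$scale[2]),
       mirror = params$mirror && runif(1) < 0.5,
       contrast = runif(2, params$contrast_shift[1], params$contrast_shift[2]),
       noise_sigma = params$noise_sigma,
       noise_seed = sample.int(2^30, 2))
}

#' The identity augmentation draw
#'
#' Rotation 0, scale 1, no mirror, zero contrast offset, no noise;
#' [augment_pair()] with this draw returns its input unchanged.
#'
#' @return a draw list as produced by [draw_augment()].
#' @export
identity_draw <- function() {
  list(rotation = 0, scale = 1, mirror = FALSE, contrast = c(0, 0),
       noise_sigma = 0, noise_seed = c(1, 1))
}

# Inverse-mapped affine resampling about the image centre. Exact identity for
# the identity draw (integer sample coordinates, zero fractional weights).
affine2d <- function(img, rotation_deg, scale, mirror,
                     method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  h <- nrow(img); w <- ncol(img)
  cx <- (h - 1) / 2; cy <- (w - 1) / 2
  xo <- rep(seq_len(h) - 1, times = w) - cx
  yo <- rep(seq_len(w) - 1, each = h) - cy
  th <- -rotation_deg * pi / 180  # inverse rotation
  xs <- (cos(th) * xo - sin(th) * yo) / scale
  ys <- (sin(th) * xo + cos(th) * yo) / scale
  if (mirror) xs <- -xs
  xs <- xs + cx; ys <- ys + cy
  inside <- xs >= -0.5 & xs <= h - 0.5 & ys >= -0.5 & ys <= w - 0.5
  out <- numeric(h * w)
  if (method == "nearest") {
    xi <- pmin(pmax(round(xs), 0), h - 1); yi <- pmin(pmax(round(ys), 0), w - 1)
    out <- img[cbind(xi + 1, yi + 1)]
  } else {
    x0 <- pmin(pmax(floor(xs), 0), h - 1); y0 <- pmin(pmax(floor(ys), 0), w - 1)
    x1 <- pmin(x0 + 1, h - 1); y1 <- pmin(y0 + 1, w - 1)
    fx <- pmin(pmax(xs - x0, 0), 1); fy <- pmin(pmax(ys - y0, 0), 1)
    out <- img[cbind(x0 + 1, y0 + 1)] * (1 - fx) * (1 - fy) +
      img[cbind(x1 + 1, y0 + 1)] * fx * (1 - fy) +
      img[cbind(x0 + 1, y1 + 1)] * (1 - fx) * fy +
      img[cbind(x1 + 1, y1 + 1)] * fx * fy
  }
  out[!inside] <- 0  # out-of-canvas pixels filled with background 0
  matrix(out, h, w)
}

#' Apply one augmentation draw to a slice pair
#'
#' The geometric transform (rotation, scale, mirror) is shared by phase 1,
#' phase 2 and the mask; photometric transforms (contrast offset, noise) are
#' applied to the images only, with independent draws per phase. The mask is
#' interpolated nearest-neighbour and stays binary.
#'
#' @param sp slice pair (`phase1`, `phase2`, `mask`, `case_id`, `slice`).
#' @param draw a draw from [draw_augment()] (or [identity_draw()]).
#' @param params optional [augment_params()] used to validate the draw
#'   against the configured ranges.
#' @return The augmented slice pair; the draw is recorded in `$draw`.
#' @export
augment_pair <- function(sp, draw, params = NULL) {
  if (!is.null(params)) {
    if (draw$rotation < params$rotation_deg[1] ||
        draw$rotation > params$rotation_deg[2] ||
        draw$scale < params$scale[1] || draw$scale > params$scale[2] ||
        any(draw$contrast < params$contrast_shift[1]) ||
        any(draw$contrast > params$contrast_shift[2]))
      stopf("augmentation draw lies outside the configured ranges")
  }
  geo <- function(m, mask) affine2d(m, draw$rotation, draw$scale, draw$mirror,
                                    method = if (mask) "nearest" else "bilinear")
  photo <- function(m, i, mode) {
    if (is.null(mode)) mode <- "additive"
    m <- if (mode == "multiplicative") m * (1 + draw$contrast[i] / 255)
         else m + draw$contrast[i] / 255
    if (draw$noise_sigma > 0)
      m <- m + with_seed(draw$noise_seed[i],
                         matrix(rnorm(length(m), sd = draw$noise_sigma),
                                nrow(m)))
    pmin(pmax(m, 0), 1)
  }
  mode <- if (!is.null(params)) params$contrast_mode else "additive"
  identity_photo <- all(draw$contrast == 0) && draw$noise_sigma == 0
  p1 <- geo(sp$phase1, FALSE); p2 <- geo(sp$phase2, FALSE)
  if (!identity_photo) { p1 <- photo(p1, 1, mode); p2 <- photo(p2, 2, mode) }
  out <- sp
  out$phase1 <- p1
  out$phase2 <- p2
  out$mask <- geo(sp$mask, TRUE)
  out$draw <- draw
  out
}

#' Build an augmented training dataset
#'
#' Produces `length(pairs) * multiplicity` augmented pairs (plus the
#' originals when `include_originals` is set), with all draws deterministic
#' from the seed. Each augmented pair records its source pair and draw.
#'
#' @param pairs nonempty list of slice pairs.
#' @param params an [augment_params()] with `multiplicity >= 1`.
#' @return list of slice pairs.
#' @export
build_augmented_dataset <- function(pairs, params) {
  if (length(pairs) == 0) stopf("cannot augment an empty dataset")
  if (params$multiplicity < 1) stopf("multiplicity must be >= 1")
  out <- with_seed(params$seed, {
    res <- list()
    for (i in seq_along(pairs)) {
      for (m in seq_len(params$multiplicity)) {
        d <- draw_augment(params)
        ap <- augment_pair(pairs[[i]], d, params)
        ap$source <- i
        res[[length(res) + 1]] <- ap
      }
    }
    res
  })
  if (params$include_originals) out <- c(pairs, out)
  out
}
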