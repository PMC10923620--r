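# Preprocessing: B-spline nonrigid registration of phase 2 onto the phase-1
# grid, tumor-slice selection, resampling to the network grid, normalization.

# Cubic B-spline kernel.
bspline3 <- function(t) {
  a <- abs(t)
  ifelse(a < 1, (4 - 6 * a^2 + 3 * a^3) / 6,
         ifelse(a < 2, (2 - a)^3 / 6, 0))
}

# Basis matrix (n voxels x nc control points) for control spacing s; control
# points sit at positions (j - 1) * s, j = 0..nc-1, so every voxel has full
# cubic support.
bspline_basis <- function(n, s) {
  nc <- as.integer(ceiling((n - 1) / s)) + 3L
  pos <- (seq_len(nc) - 2) * s
  outer(seq_len(n) - 1, pos, function(p, q) bspline3((p - q) / s))
}

# theta: (ncx, ncy, ncz) array of coefficients -> dense (nx, ny, nz) field.
tensor3_apply <- function(theta, Bx, By, Bz) {
  d <- dim(theta)
  nx <- nrow(Bx); ny <- nrow(By); nz <- nrow(Bz)
  a <- array(Bx %*% matrix(theta, d[1]), c(nx, d[2], d[3]))
  a <- aperm(a, c(2, 1, 3))
  a <- array(By %*% matrix(a, d[2]), c(ny, nx, d[3]))
  a <- aperm(a, c(2, 1, 3))
  a <- aperm(a, c(3, 1, 2))
  a <- array(Bz %*% matrix(a, d[3]), c(nz, nx, ny))
  aperm(a, c(2, 3, 1))
}

# Squared-second-difference penalty on a coefficient array, with gradient.
d2_penalty <- function(theta) {
  d <- dim(theta)
  val <- 0
  grad <- array(0, d)
  for (ax in 1:3) {
    if (d[ax] < 3) next
    p <- aperm(theta, c(ax, setdiff(1:3, ax)))
    m <- matrix(p, d[ax])
    d2 <- m[-c(1, 2), , drop = FALSE] - 2 * m[-c(1, nrow(m)), , drop = FALSE] +
      m[-c(nrow(m) - 1, nrow(m)), , drop = FALSE]
    val <- val + sum(d2^2)
    g <- matrix(0, nrow(m), ncol(m))
    n2 <- nrow(d2)
    g[1:n2, ] <- g[1:n2, ] + d2
    g[2:(n2 + 1), ] <- g[2:(n2 + 1), ] - 2 * d2
    g[3:(n2 + 2), ] <- g[3:(n2 + 2), ] + d2
    g <- array(g, dim(p))
    inv <- order(c(ax, setdiff(1:3, ax)))
    grad <- grad + aperm(g, inv)
  }
  list(value = val, grad = 2 * grad)
}

#' Registration parameters
#'
#' Coarse-to-fine free-form-deformation settings: one optimization level per
#' control-point spacing, mean-squared-intensity metric, L-BFGS-B optimizer,
#' and a light second-difference penalty on the control coefficients that
#' regularizes the field where the images carry no gradient information.
#'
#' @param spacings list of per-level control spacings (x, y, z voxels),
#'   coarse to fine.
#' @param iterations L-BFGS-B iterations per level.
#' @param lambda weight of the coefficient-smoothness penalty (applied to the
#'   mean squared second difference, so it is spacing-independent).
#' @param smooth_sigma per-level Gaussian smoothing of the images before the
#'   metric is evaluated (0 = none).
#' @return A list of class `registration_params`.
#' @export
registration_params <- function(spacings = list(c(16, 16, 8), c(8, 8, 4)),
                                iterations = 60, lambda = 3e-3,
                                smooth_sigma = c(1.5, 1)) {
  structure(list(spacings = spacings, iterations = iterations,
                 lambda = lambda, smooth_sigma = smooth_sigma),
            class = "registration_params")
}

#' Register phase 2 onto the phase-1 grid (B-spline FFD)
#'
#' Deformable registration with a cubic B-spline displacement model, run
#' coarse-to-fine over the control spacings in `params`. Both volumes must
#' already live on a common grid (the phantom generator and the 2D slice
#' pairing both assume this). The procedure is fully deterministic.
#'
#' @param moving volume to deform (phase 2), 3D array or `mri_volume`.
#' @param fixed reference volume (phase 1), same grid.
#' @param params a [registration_params()].
#' @return list with `registered` (moving resampled onto the fixed grid),
#'   `field` (displacement field, `dim = c(dims, 3)`, mapping fixed-grid
#'   coordinates to moving-grid coordinates), and `trace` (per-level MSE).
#' @export
register_phase2_to_phase1 <- function(moving, fixed,
                                      params = registration_params()) {
  if (inherits(moving, "mri_volume")) moving <- moving$voxels
  if (inherits(fixed, "mri_volume")) fixed <- fixed$voxels
  if (!all(is.finite(moving)) || !all(is.finite(fixed)))
    stopf("registration inputs must be finite")
  dims <- dim(fixed)
  if (!identical(dims, dim(moving)))
    stopf("moving and fixed volumes must share one grid")
  X <- array(rep(seq_len(dims[1]) - 1, times = dims[2] * dims[3]), dims)
  Y <- array(rep(rep(seq_len(dims[2]) - 1, each = dims[1]), times = dims[3]),
             dims)
  Z <- array(rep(seq_len(dims[3]) - 1, each = dims[1] * dims[2]), dims)
  nvox <- prod(dims)
  u <- array(0, c(dims, 3))

  # z-score both images for the metric so a global intensity offset between
  # the two phases (hepatobiliary vs portal-venous base signal) does not
  # bias the deformation estimate. The MSE trace and the divergence check
  # live on this metric scale.
  zsc <- function(v) (v - mean(v)) / max(sd(v), 1e-12)
  fixed_z <- zsc(fixed); moving_z <- zsc(moving)
  # trace metric: z-scored images smoothed with the finest-level sigma, so
  # every trace row (and the divergence check) measures the same quantity
  sig_t <- params$smooth_sigma[min(length(params$spacings),
                                   length(params$smooth_sigma))]
  Ft <- if (sig_t > 0) gauss_smooth_3d(fixed_z, c(sig_t, sig_t, sig_t / 2))
        else fixed_z
  Mt <- if (sig_t > 0) gauss_smooth_3d(moving_z, c(sig_t, sig_t, sig_t / 2))
        else moving_z
  mse0 <- mean((Mt - Ft)^2)
  trace <- data.frame(level = 0, spacing = NA, mse = mse0)

  for (lev in seq_along(params$spacings)) {
    sp <- params$spacings[[lev]]
    sig <- params$smooth_sigma[min(lev, length(params$smooth_sigma))]
    Fs <- if (sig > 0) gauss_smooth_3d(fixed_z, c(sig, sig, sig / 2))
          else fixed_z
    Ms <- if (sig > 0) gauss_smooth_3d(moving_z, c(sig, sig, sig / 2))
          else moving_z
    gx <- Ms; gx[] <- 0; gy <- gx; gz <- gx
    gx[2:(dims[1] - 1), , ] <- (Ms[3:dims[1], , ] - Ms[1:(dims[1] - 2), , ]) / 2
    gy[, 2:(dims[2] - 1), ] <- (Ms[, 3:dims[2], ] - Ms[, 1:(dims[2] - 2), ]) / 2
    gz[, , 2:(dims[3] - 1)] <- (Ms[, , 3:dims[3]] - Ms[, , 1:(dims[3] - 2)]) / 2
    Bx <- bspline_basis(dims[1], sp[1])
    By <- bspline_basis(dims[2], sp[2])
    Bz <- bspline_basis(dims[3], sp[3])
    nc <- c(ncol(Bx), ncol(By), ncol(Bz))
    npar <- prod(nc)

    level_field <- function(th) {
      th <- array(th, c(nc, 3))
      list(x = tensor3_apply(th[, , , 1], Bx, By, Bz),
           y = tensor3_apply(th[, , , 2], Bx, By, Bz),
           z = tensor3_apply(th[, , , 3], Bx, By, Bz))
    }
    fn <- function(th) {
      fl <- level_field(th)
      xs <- X + u[, , , 1] + fl$x; ys <- Y + u[, , , 2] + fl$y
      zs <- Z + u[, , , 3] + fl$z
      r <- interp3(Ms, xs, ys, zs) - Fs
      pen <- 0
      tha <- array(th, c(nc, 3))
      for (a in 1:3) pen <- pen + d2_penalty(tha[, , , a])$value
      mean(r^2) + params$lambda * pen / npar
    }
    gr <- function(th) {
      fl <- level_field(th)
      xs <- X + u[, , , 1] + fl$x; ys <- Y + u[, , , 2] + fl$y
      zs <- Z + u[, , , 3] + fl$z
      r <- array(interp3(Ms, xs, ys, zs) - Fs, dims)
      out <- array(0, c(nc, 3))
      tha <- array(th, c(nc, 3))
      tBx <- t(Bx); tBy <- t(By); tBz <- t(Bz)
      for (a in 1:3) {
        ga <- switch(a, gx, gy, gz)
        dU <- array(2 / nvox * r * interp3(ga, xs, ys, zs), dims)
        out[, , , a] <- tensor3_apply(dU, tBx, tBy, tBz) +
          params$lambda / npar * d2_penalty(tha[, , , a])$grad
      }
      as.numeric(out)
    }
    opt <- optim(rep(0, npar * 3), fn, gr, method = "L-BFGS-B",
                 control = list(maxit = params$iterations))
    fl <- level_field(opt$par)
    u[, , , 1] <- u[, , , 1] + fl$x
    u[, , , 2] <- u[, , , 2] + fl$y
    u[, , , 3] <- u[, , , 3] + fl$z
    mse_l <- mean((array(interp3(Mt, X + u[, , , 1], Y + u[, , , 2],
                                 Z + u[, , , 3]), dims) - Ft)^2)
    trace <- rbind(trace, data.frame(level = lev,
                                     spacing = paste(sp, collapse = "x"),
                                     mse = mse_l))
  }
  registered <- array(interp3(moving, X + u[, , , 1], Y + u[, , , 2],
                              Z + u[, , , 3]), dims)
  mse_final <- tail(trace$mse, 1)
  if (mse_final > mse0 * 1.05 + 1e-12) {
    cond <- simpleError(sprintf(
      "registration diverged: final MSE %.3g exceeds initial %.3g",
      mse_final, mse0))
    cond$trace <- trace
    stop(cond)
  }
  list(registered = registered, field = u, trace = trace)
}

#' Mean residual displacement between two fields
#'
#' Mean Euclidean norm of the difference between an estimated and a reference
#' displacement field, evaluated over a mask (displacement is only
#' identifiable where the image has intensity structure, so the liver region
#' is the natural evaluation domain for phantoms).
#'
#' @param field,true_field arrays with `dim = c(dims, 3)`.
#' @param mask optional binary 3D array; default: everywhere.
#' @return Mean residual in voxels.
#' @export
registration_residual <- function(field, true_field, mask = NULL) {
  d <- sqrt((field[, , , 1] - true_field[, , , 1])^2 +
              (field[, , , 2] - true_field[, , , 2])^2 +
              (field[, , , 3] - true_field[, , , 3])^2)
  if (is.null(mask)) mean(d) else mean(d[mask > 0])
}

#' Select tumor-bearing slice pairs
#'
#' Returns exactly the z-slices where the mask has at least one foreground
#' voxel, in ascending z, pairing the phase-1 slice with the co-registered
#' phase-2 slice at the same z. An empty mask yields an empty list.
#'
#' @param case list with `phase1`, `phase2` (registered onto the phase-1
#'   grid), and `gt_mask` or `mask`; a `phantom_case` works directly (its
#'   `phase2_registered` field is preferred over `phase2` when present).
#' @return list of slice pairs: `phase1`, `phase2`, `mask` (matrices),
#'   `case_id`, `slice`.
#' @export
select_tumor_slices <- function(case) {
  mask <- case$gt_mask %||% case$mask
  p2 <- case$phase2_registered %||% case$phase2
  if (is.null(mask)) stopf("case has no mask")
  zs <- which(apply(mask, 3, sum) > 0)
  lapply(zs, function(z) list(phase1 = case$phase1[, , z],
                              phase2 = p2[, , z],
                              mask = mask[, , z],
                              case_id = case$id %||% "case",
                              slice = z))
}

#' Resample a 2D slice to the network input grid
#'
#' Bilinear interpolation for images, nearest-neighbour for masks. The target
#' must be divisible by 8 on both axes because the network performs three
#' pooling stages.
#'
#' @param img 2D matrix.
#' @param target `c(h, w)`.
#' @param mask logical; use nearest-neighbour (keeps values in \{0, 1\}).
#' @return Resampled matrix of shape `target`.
#' @export
resample_slice <- function(img, target, mask = FALSE) {
  if (length(target) == 1) target <- c(target, target)
  if (any(target < 8) || any(target %% 8 != 0))
    stopf("target size must be >= 8 and divisible by 8 (three pooling stages)")
  resize2d(img, target[1], target[2],
           method = if (mask) "nearest" else "bilinear")
}

#' Min-max intensity normalization of a slice
#'
#' Per-slice scaling to \[0, 1\]; a constant slice maps to all zeros.
#'
#' @param img 2D matrix with finite values.
#' @return Normalized matrix.
#' @export
normalize_intensity <- function(img) {
  if (!all(is.finite(img))) stopf("normalize_intensity: non-finite input")
  lo <- min(img); hi <- max(img)
  if (hi - lo < .Machine$double.eps) return(img * 0)
  (img - lo) / (hi - lo)
}

# Network-ready slice pairs for one case: tumor slices, resampled to
# `input_size` and min-max normalized; masks resampled nearest.
make_network_pairs <- function(case, input_size) {
  sp <- select_tumor_slices(case)
  lapply(sp, function(s) {
    s$phase1 <- normalize_intensity(resample_slice(s$phase1, input_size))
    s$phase2 <- normalize_intensity(resample_slice(s$phase2, input_size))
    s$mask <- resample_slice(s$mask, input_size, mask = TRUE)
    s
  })
}
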