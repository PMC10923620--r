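#' Specification of a synthetic dual-phase phantom
#'
#' Describes one synthetic "patient": a liver-like ellipsoid with smooth
#' internal texture on a dark background, zero or more lobulated lesions that
#' are hypointense in phase 1 (hepatobiliary-like) and carry an independent
#' contrast in phase 2 (portal-venous-like), an optional confounder structure,
#' a smooth inter-phase deformation, and additive Gaussian noise. All
#' intensities are generated in \[0, 1\]; a given (spec, seed) pair yields
#' bit-identical output.
#'
#' @param volume_shape integer triple, volume size in voxels (x, y, z).
#' @param liver_axes ellipsoid semi-axes of the liver region, in voxels.
#' @param n_lesions number of lesions (>= 0).
#' @param lesion_radius_range (min, max) in-plane lesion radius, voxels.
#' @param contrast_phase1 signed lesion-minus-liver intensity offset in
#'   phase 1; negative means hypointense.
#' @param contrast_phase2 signed offset in phase 2.
#' @param confounder_mode `"none"`, `"organ_mimic"` (a structure whose phase-1
#'   intensity matches the lesion but whose phase-2 intensity matches normal
#'   liver), or `"unclear_boundary"` (lesion border smoothed so the boundary
#'   gradient is strongly reduced).
#' @param deformation_amplitude maximum displacement (voxels) of the observed
#'   phase 2 relative to its aligned render; 0 disables deformation.
#' @param noise_sigma additive Gaussian noise s.d. as a fraction of the \[0,1\]
#'   dynamic range.
#' @param texture_amplitude s.d. of the smooth intra-liver texture field.
#' @param seed integer RNG seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(volume_shape = c(64, 64, 16),
                         liver_axes = c(26, 24, 6.5),
                         n_lesions = 1,
                         lesion_radius_range = c(4, 7),
                         contrast_phase1 = -0.35,
                         contrast_phase2 = -0.18,
                         confounder_mode = c("none", "organ_mimic",
                                             "unclear_boundary"),
                         deformation_amplitude = 0,
                         noise_sigma = 0.01,
                         texture_amplitude = 0.04,
                         seed = 1L) {
  confounder_mode <- match.arg(confounder_mode)
  volume_shape <- as.integer(volume_shape)
  if (length(volume_shape) != 3 || any(volume_shape < 8))
    stopf("volume_shape must be three integers >= 8")
  if (length(liver_axes) != 3 || any(liver_axes <= 0))
    stopf("liver_axes must be three positive semi-axes")
  if (n_lesions < 0) stopf("n_lesions must be >= 0")
  if (length(lesion_radius_range) != 2 ||
      lesion_radius_range[1] > lesion_radius_range[2])
    stopf("lesion_radius_range must be (min, max)")
  if (lesion_radius_range[2] >= min(liver_axes[1:2]))
    stopf("lesion radius must fit inside liver_axes")
  if (noise_sigma < 0) stopf("noise_sigma must be >= 0")
  structure(list(volume_shape = volume_shape, liver_axes = liver_axes,
                 n_lesions = as.integer(n_lesions),
                 lesion_radius_range = lesion_radius_range,
                 contrast_phase1 = contrast_phase1,
                 contrast_phase2 = contrast_phase2,
                 confounder_mode = confounder_mode,
                 deformation_amplitude = deformation_amplitude,
                 noise_sigma = noise_sigma,
                 texture_amplitude = texture_amplitude,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Lobulated blob mask: ellipsoid (in-plane radius r, axial semi-axis zr)
# whose local radius is modulated by a smooth random field.
blob_mask <- function(dims, center, r, zr, lobulation = 0.18,
                      field_sigma = 3) {
  X <- array(rep(seq_len(dims[1]) - 1, times = dims[2] * dims[3]), dims)
  Y <- array(rep(rep(seq_len(dims[2]) - 1, each = dims[1]), times = dims[3]),
             dims)
  Z <- array(rep(seq_len(dims[3]) - 1, each = dims[1] * dims[2]), dims)
  d <- sqrt((X - center[1])^2 + (Y - center[2])^2 +
              ((Z - center[3]) * r / zr)^2)
  s <- gauss_smooth_3d(array(rnorm(prod(dims)), dims),
                       c(field_sigma, field_sigma, max(1, field_sigma / 2)))
  s <- s / max(stats::sd(s), 1e-12)
  d <= r * pmin(pmax(1 + lobulation * s, 0.7), 1.3)
}

ellipsoid_mask <- function(dims, center, axes) {
  X <- array(rep(seq_len(dims[1]) - 1, times = dims[2] * dims[3]), dims)
  Y <- array(rep(rep(seq_len(dims[2]) - 1, each = dims[1]), times = dims[3]),
             dims)
  Z <- array(rep(seq_len(dims[3]) - 1, each = dims[1] * dims[2]), dims)
  ((X - center[1]) / axes[1])^2 + ((Y - center[2]) / axes[2])^2 +
    ((Z - center[3]) / axes[3])^2 <= 1
}

# Sample a lesion centre such that an (r, r, zr) ellipsoid fits inside the
# liver ellipsoid.
sample_center <- function(dims, liver_axes, r, zr, max_try = 200,
                          reject = NULL) {
  ctr <- (dims - 1) / 2
  eff <- pmax(liver_axes - c(r, r, zr), 0.5)
  for (i in seq_len(max_try)) {
    u <- runif(3, -1, 1)
    cand <- ctr + u * eff
    inside <- sum(((cand - ctr) / eff)^2) <= 1
    if (inside && (is.null(reject) || !reject(cand))) return(cand)
  }
  NULL
}

#' Generate one synthetic dual-phase phantom case
#'
#' Renders the two phases on a common grid, applies the configured confounder,
#' deforms the observed phase 2 by a smooth displacement field with known
#' inverse, and adds noise. The returned `true_deformation` is the field that
#' an ideal registration of phase 2 onto the phase-1 grid should recover
#' (fixed-grid coordinates to moving-grid coordinates).
#'
#' @param spec a [phantom_spec()].
#' @return A list of class `phantom_case` with elements `phase1`, `phase2`
#'   (observed, deformed), `phase2_aligned`, `gt_mask`, `mimic_mask` (or
#'   NULL), `liver_mask`, `true_roi`, `true_deformation`, `spec`, `seed`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    dims <- spec$volume_shape
    ctr <- (dims - 1) / 2
    liver <- ellipsoid_mask(dims, ctr, spec$liver_axes)
    tex1 <- gauss_smooth_3d(array(rnorm(prod(dims)), dims), c(3, 3, 1.5))
    tex2 <- gauss_smooth_3d(array(rnorm(prod(dims)), dims), c(3, 3, 1.5))
    tex1 <- tex1 / max(stats::sd(tex1), 1e-12) * spec$texture_amplitude
    tex2 <- tex2 / max(stats::sd(tex2), 1e-12) * spec$texture_amplitude

    p1 <- array(0.12, dims); p2 <- array(0.12, dims)
    p1[liver] <- 0.62 + tex1[liver]
    p2[liver] <- 0.55 + tex2[liver]

    gt <- array(FALSE, dims)
    lesion_centers <- list()
    if (spec$n_lesions > 0) {
      for (k in seq_len(spec$n_lesions)) {
        placed <- FALSE
        for (attempt in 1:20) {
          r <- runif(1, spec$lesion_radius_range[1],
                     spec$lesion_radius_range[2])
          zr <- max(2, 0.5 * r)
          reject <- NULL
          if (length(lesion_centers)) {
            reject <- function(c0) any(vapply(lesion_centers, function(lc)
              sqrt(sum((c0[1:2] - lc[1:2])^2)) <
                2.2 * spec$lesion_radius_range[2], logical(1)))
          }
          cen <- sample_center(dims, spec$liver_axes, r, zr, reject = reject)
          if (is.null(cen)) next
          b <- blob_mask(dims, cen, r, zr) & liver
          if (sum(b) >= 8) {
            gt <- gt | b
            lesion_centers[[length(lesion_centers) + 1]] <- cen
            placed <- TRUE
            break
          }
        }
        if (!placed)
          stopf("could not place lesion %d inside liver (seed %d)",
                k, spec$seed)
      }
    }
    p1[gt] <- 0.62 + spec$contrast_phase1 + 0.5 * tex1[gt]
    p2[gt] <- 0.55 + spec$contrast_phase2 + 0.5 * tex2[gt]

    true_roi <- mask_bbox(gt)

    mimic <- NULL
    if (spec$confounder_mode == "organ_mimic") {
      # The mimic is drawn from exactly the lesion distribution (same radius
      # range, same lobulated shape process, same placement rule as a second
      # lesion, same intensity offset and texture damping in phase 1), so a
      # phase-1 observer has no intensity, shape or positional cue separating
      # it from tumor; only phase 2, where it keeps normal liver intensity,
      # disambiguates.
      placed <- FALSE
      for (attempt in 1:40) {
        r <- runif(1, spec$lesion_radius_range[1],
                   spec$lesion_radius_range[2])
        zr <- max(2, 0.5 * r)
        reject <- function(c0) {
          if (!length(lesion_centers)) return(FALSE)
          any(vapply(lesion_centers, function(lc)
            sqrt(sum((c0[1:2] - lc[1:2])^2)) <
              2.2 * spec$lesion_radius_range[2], logical(1)))
        }
        cen <- sample_center(dims, spec$liver_axes, r, zr, reject = reject)
        if (is.null(cen)) next
        b <- blob_mask(dims, cen, r, zr) & liver & !gt
        if (sum(b) >= 8) { mimic <- b; placed <- TRUE; break }
      }
      if (!placed)
        stopf("could not place organ-mimic confounder (seed %d)", spec$seed)
      p1[mimic] <- 0.62 + spec$contrast_phase1 + 0.5 * tex1[mimic]
    }

    if (spec$confounder_mode == "unclear_boundary" && any(gt)) {
      # blend each phase with a smoothed copy near the lesion border; this
      # reduces the boundary |gradient| by roughly a factor of 3 (sigma 1.8).
      g <- gauss_smooth_3d(gt * 1.0, 1.8)
      w <- pmin(4 * g * (1 - g), 1)
      p1 <- (1 - w) * p1 + w * gauss_smooth_3d(p1, 1.8)
      p2 <- (1 - w) * p2 + w * gauss_smooth_3d(p2, 1.8)
    }

    p2_aligned <- p2
    if (spec$deformation_amplitude > 0) {
      u <- bump_field(dims, spec$deformation_amplitude, center = ctr,
                      axes = spec$liver_axes)
      X <- array(rep(seq_len(dims[1]) - 1, times = dims[2] * dims[3]), dims)
      Y <- array(rep(rep(seq_len(dims[2]) - 1, each = dims[1]),
                     times = dims[3]), dims)
      Z <- array(rep(seq_len(dims[3]) - 1, each = dims[1] * dims[2]), dims)
      p2_obs <- array(interp3(p2_aligned, X + u[, , , 1], Y + u[, , , 2],
                              Z + u[, , , 3]), dims)
      true_def <- invert_field(u)
    } else {
      p2_obs <- p2_aligned
      true_def <- array(0, c(dims, 3))
    }

    if (spec$noise_sigma > 0) {
      p1 <- p1 + rnorm(prod(dims), sd = spec$noise_sigma)
      p2_obs <- p2_obs + rnorm(prod(dims), sd = spec$noise_sigma)
    }
    p1 <- pmin(pmax(p1, 0), 1); dim(p1) <- dims
    p2_obs <- pmin(pmax(p2_obs, 0), 1); dim(p2_obs) <- dims

    structure(list(phase1 = p1, phase2 = p2_obs, phase2_aligned = p2_aligned,
                   gt_mask = array(as.integer(gt), dims),
                   mimic_mask = if (!is.null(mimic))
                     array(as.integer(mimic), dims) else NULL,
                   liver_mask = array(as.integer(liver), dims),
                   true_roi = true_roi, true_deformation = true_def,
                   spec = spec, seed = spec$seed),
              class = "phantom_case")
  })
}

# Smooth random displacement field: a few Gaussian-smoothed random spikes per
# component, rescaled so the maximum displacement magnitude equals `amp`.
# The smoothing sigma (6, 6, 3) keeps amp below half the smoothing scale for
# the amplitudes used here, so the warp stays invertible in practice. Bump
# centres are drawn inside the liver ellipsoid when given, concentrating the
# breathing-like misalignment in the organ of interest.
bump_field <- function(dims, amp, n_bumps = 6, sigma = c(6, 6, 3),
                       center = NULL, axes = NULL) {
  u <- array(0, c(dims, 3))
  for (a in 1:3) {
    f <- array(0, dims)
    for (b in seq_len(n_bumps)) {
      if (!is.null(center)) {
        repeat {
          v <- runif(3, -1, 1)
          if (sum(v^2) <= 1) break
        }
        cp <- pmin(pmax(round(center + v * axes), 1), dims)
        cx <- cp[1]; cy <- cp[2]; cz <- cp[3]
      } else {
        cx <- sample.int(dims[1], 1); cy <- sample.int(dims[2], 1)
        cz <- sample.int(dims[3], 1)
      }
      f[cx, cy, cz] <- f[cx, cy, cz] + rnorm(1)
    }
    u[, , , a] <- gauss_smooth_3d(f, sigma)
  }
  mag <- sqrt(u[, , , 1]^2 + u[, , , 2]^2 + u[, , , 3]^2)
  u * (amp / max(mag, 1e-12))
}

# Exact (fixed-point) inverse of a displacement field: v with
# v(x) + u(x + v(x)) = 0.
invert_field <- function(u, n_iter = 15) {
  dims <- dim(u)[1:3]
  X <- array(rep(seq_len(dims[1]) - 1, times = dims[2] * dims[3]), dims)
  Y <- array(rep(rep(seq_len(dims[2]) - 1, each = dims[1]), times = dims[3]),
             dims)
  Z <- array(rep(seq_len(dims[3]) - 1, each = dims[1] * dims[2]), dims)
  v <- array(0, dim(u))
  for (i in seq_len(n_iter)) {
    xs <- X + v[, , , 1]; ys <- Y + v[, , , 2]; zs <- Z + v[, , , 3]
    v[, , , 1] <- -interp3(u[, , , 1], xs, ys, zs)
    v[, , , 2] <- -interp3(u[, , , 2], xs, ys, zs)
    v[, , , 3] <- -interp3(u[, , , 3], xs, ys, zs)
  }
  v
}

#' Generate a deterministic collection of phantom cases
#'
#' Per-case seeds are derived deterministically from the master seed, so the
#' same (spec, n_cases, seed) always yields the same dataset. The returned
#' manifest records every derived seed.
#'
#' @param spec a [phantom_spec()]; its own seed field is replaced per case.
#' @param n_cases number of cases (>= 1).
#' @param seed master seed.
#' @return list with `cases` (list of `phantom_case`) and `manifest`
#'   (data.frame of id and seed).
#' @export
generate_dataset <- function(spec, n_cases, seed) {
  if (n_cases < 1) stopf("n_cases must be >= 1")
  seeds <- vapply(seq_len(n_cases), function(i) derive_seed(seed, i),
                  numeric(1))
  cases <- lapply(seq_len(n_cases), function(i) {
    s <- spec; s$seed <- as.integer(seeds[i])
    cs <- generate_phantom(s)
    cs$id <- sprintf("case%03d", i)
    cs
  })
  list(cases = cases,
       manifest = data.frame(id = vapply(cases, `[[`, "", "id"),
                             seed = seeds))
}
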