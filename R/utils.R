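# Shared internal helpers: seeded evaluation, smoothing, resampling.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards so library code never perturbs user RNG.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic child-seed derivation; exact in double arithmetic and < 2^31.
derive_seed <- function(master, i) {
  ((as.numeric(master) %% 65011) * 100003 + as.numeric(i) * 7919 + 12345) %%
    2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# 1D Gaussian smoothing matrix with renormalized (reflecting-mass) edges.
smooth_matrix_1d <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- dnorm(seq(-r, r), sd = sigma)
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - r):(i + r)
    ok <- j >= 1 & j <= n
    M[i, j[ok]] <- k[ok]
    M[i, ] <- M[i, ] / sum(M[i, ])
  }
  M
}

# Separable Gaussian smoothing of a 3D array.
gauss_smooth_3d <- function(a, sigma) {
  d <- dim(a)
  if (length(sigma) == 1) sigma <- rep(sigma, 3)
  if (sigma[1] > 0)
    a <- array(smooth_matrix_1d(d[1], sigma[1]) %*% matrix(a, d[1]), d)
  if (sigma[2] > 0) {
    a <- aperm(a, c(2, 1, 3))
    a <- array(smooth_matrix_1d(d[2], sigma[2]) %*% matrix(a, d[2]),
               c(d[2], d[1], d[3]))
    a <- aperm(a, c(2, 1, 3))
  }
  if (sigma[3] > 0) {
    a <- aperm(a, c(3, 1, 2))
    a <- array(smooth_matrix_1d(d[3], sigma[3]) %*% matrix(a, d[3]),
               c(d[3], d[1], d[2]))
    a <- aperm(a, c(2, 3, 1))
  }
  a
}

gauss_smooth_2d <- function(m, sigma) {
  d <- dim(m)
  m <- smooth_matrix_1d(d[1], sigma) %*% m
  m %*% t(smooth_matrix_1d(d[2], sigma))
}

# Binary dilation by n steps of the 6-connected neighbourhood (3D).
dilate6 <- function(mask, n = 1L) {
  d <- dim(mask)
  m <- mask > 0
  for (i in seq_len(n)) {
    s <- m
    s[-1, , ] <- s[-1, , ] | m[-d[1], , ]
    s[-d[1], , ] <- s[-d[1], , ] | m[-1, , ]
    s[, -1, ] <- s[, -1, ] | m[, -d[2], ]
    s[, -d[2], ] <- s[, -d[2], ] | m[, -1, ]
    s[, , -1] <- s[, , -1] | m[, , -d[3]]
    s[, , -d[3]] <- s[, , -d[3]] | m[, , -1]
    m <- s
  }
  m
}

# Bilinear / nearest 2D resampling with pixel-centre alignment; exact
# identity when the target equals the source size.
resize2d <- function(img, h2, w2, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  h1 <- nrow(img); w1 <- ncol(img)
  if (h2 == h1 && w2 == w1) return(img)
  x <- (seq_len(h2) - 0.5) * h1 / h2 - 0.5
  y <- (seq_len(w2) - 0.5) * w1 / w2 - 0.5
  if (method == "nearest") {
    xi <- pmin(pmax(round(x) + 1, 1), h1)
    yi <- pmin(pmax(round(y) + 1, 1), w1)
    return(img[xi, yi, drop = FALSE])
  }
  x0 <- pmin(pmax(floor(x), 0), h1 - 1); fx <- pmin(pmax(x - x0, 0), 1)
  y0 <- pmin(pmax(floor(y), 0), w1 - 1); fy <- pmin(pmax(y - y0, 0), 1)
  x1 <- pmin(x0 + 1, h1 - 1); y1 <- pmin(y0 + 1, w1 - 1)
  A <- img[x0 + 1, y0 + 1, drop = FALSE]; B <- img[x1 + 1, y0 + 1, drop = FALSE]
  C <- img[x0 + 1, y1 + 1, drop = FALSE]; D <- img[x1 + 1, y1 + 1, drop = FALSE]
  wx <- matrix(fx, h2, w2); wy <- matrix(fy, h2, w2, byrow = TRUE)
  A * (1 - wx) * (1 - wy) + B * wx * (1 - wy) + C * (1 - wx) * wy + D * wx * wy
}

# Trilinear sampling of a 3D volume at 0-based voxel coordinates.
interp3 <- function(vol, xq, yq, zq) {
  .interp3_cpp(vol, as.numeric(xq), as.numeric(yq), as.numeric(zq))
}

is_binary <- function(x) all(x %in% c(0, 1))

stopf <- function(...) stop(sprintf(...), call. = FALSE)
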