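# Layer primitives for the segmentation networks. Feature maps are R arrays
# (H, W, C, N); all forwards return caches sufficient for the backward pass.
# Padding is c(top, bottom, left, right); 3x3 convs use (1,1,1,1), the 2x2
# "deconv" of the expansive path uses (1,0,1,0) so spatial size is preserved.

pad_for <- function(k) {
  if (k == 3) c(1L, 1L, 1L, 1L)
  else if (k == 2) c(1L, 0L, 1L, 0L)
  else c(0L, 0L, 0L, 0L)
}

conv_fwd <- function(x, p) .conv2d_fwd_cpp(x, p$W, p$b, pad_for(dim(p$W)[1]))

conv_bwd <- function(x, p, dy) .conv2d_bwd_cpp(x, p$W, dy, pad_for(dim(p$W)[1]))

conv_param <- function(kh, kw, cin, cout, init = c("he", "zero")) {
  init <- match.arg(init)
  W <- if (init == "he")
    array(rnorm(kh * kw * cin * cout, sd = sqrt(2 / (kh * kw * cin))),
          c(kh, kw, cin, cout))
  else array(0, c(kh, kw, cin, cout))
  list(W = W, b = numeric(cout))
}

bn_param <- function(c) list(gamma = rep(1, c), beta = rep(0, c),
                             rm = rep(0, c), rv = rep(1, c))

# Per-channel batch normalization over the (H, W, N) axes. Uses batch
# statistics in training mode (and updates running moments in `p`), running
# moments at inference.
bn_fwd <- function(x, p, train, momentum = 0.1, eps = 1e-5) {
  d <- dim(x); hw <- d[1] * d[2]; C <- d[3]; N <- d[4]
  xm <- matrix(x, hw, C * N)
  if (train) {
    cs <- colSums(xm); cs2 <- colSums(xm^2)
    m <- rowSums(matrix(cs, C, N)) / (hw * N)
    v <- rowSums(matrix(cs2, C, N)) / (hw * N) - m^2
    v <- pmax(v, 0)
    p$rm <- (1 - momentum) * p$rm + momentum * m
    p$rv <- (1 - momentum) * p$rv + momentum * v
  } else {
    m <- p$rm; v <- p$rv
  }
  istd <- 1 / sqrt(v + eps)
  mv <- rep(rep(m, each = hw), times = N)
  iv <- rep(rep(istd, each = hw), times = N)
  xhat <- (as.numeric(xm) - mv) * iv
  gv <- rep(rep(p$gamma, each = hw), times = N)
  bv <- rep(rep(p$beta, each = hw), times = N)
  y <- array(xhat * gv + bv, d)
  list(y = y, cache = list(xhat = xhat, istd = istd, d = d), p = p)
}

bn_bwd <- function(dy, p, cache) {
  d <- cache$d; hw <- d[1] * d[2]; C <- d[3]; N <- d[4]
  m_count <- hw * N
  dyv <- as.numeric(dy)
  xhat <- cache$xhat
  sum_by_channel <- function(v)
    rowSums(matrix(colSums(matrix(v, hw, C * N)), C, N))
  dgamma <- sum_by_channel(dyv * xhat)
  dbeta <- sum_by_channel(dyv)
  gv <- rep(rep(p$gamma, each = hw), times = N)
  iv <- rep(rep(cache$istd, each = hw), times = N)
  s1 <- rep(rep(dbeta, each = hw), times = N)
  s2 <- rep(rep(dgamma, each = hw), times = N)
  dx <- gv * iv / m_count * (m_count * dyv - s1 - xhat * s2)
  list(dx = array(dx, d), dgamma = dgamma, dbeta = dbeta)
}

relu_fwd <- function(x) {
  y <- x; y[y < 0] <- 0
  y
}

relu_bwd <- function(dy, y) {
  dy[y <= 0] <- 0
  dy
}

sigmoid <- function(x) 1 / (1 + exp(-x))

concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

split_ch <- function(d, c1) {
  list(a = d[, , seq_len(c1), , drop = FALSE],
       b = d[, , -seq_len(c1), , drop = FALSE])
}

# Stack a list of 2D matrices into an (H, W, 1, N) batch tensor.
stack_slices <- function(mats) {
  h <- nrow(mats[[1]]); w <- ncol(mats[[1]])
  array(unlist(mats, use.names = FALSE), c(h, w, 1, length(mats)))
}
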