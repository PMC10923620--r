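# The per-phase encoder-decoder segmentation network.
#
# Contracting path: six 3x3 conv blocks (conv + BN + ReLU), a 2x2 stride-2
# max pool after every two blocks (three pooling stages), then two 1x1 conv
# blocks at the bottleneck. Expansive path: three deconv blocks, each an
# upsampling, a 2x2 conv, a skip concatenation with the matching contracting
# feature map, and two 3x3 conv blocks. A 1x1 conv + sigmoid head produces a
# per-pixel tumor score map the same size as the input.

#' DCNN configuration
#'
#' @param input_size `(h, w)`, both divisible by 8 (three pooling stages).
#' @param base_channels width of the first conv block; doubled after each
#'   pooling stage (bottleneck runs at 8x).
#' @param bn_momentum running-moment update rate of batch normalization.
#' @param smooth Dice-loss smoothing constant used in training.
#' @return list of class `dcnn_config`.
#' @export
dcnn_config <- function(input_size = c(256, 256), base_channels = 32L,
                        bn_momentum = 0.1, smooth = 1) {
  if (length(input_size) == 1) input_size <- c(input_size, input_size)
  if (any(input_size < 8) || any(input_size %% 8 != 0))
    stopf("input_size must be >= 8 and divisible by 8 (three pooling stages)")
  structure(list(input_size = as.integer(input_size),
                 base_channels = as.integer(base_channels),
                 bn_momentum = bn_momentum, smooth = smooth),
            class = "dcnn_config")
}

dcnn_init_params <- function(C) {
  list(
    c1a = conv_param(3, 3, 1, C),       n1a = bn_param(C),
    c1b = conv_param(3, 3, C, C),       n1b = bn_param(C),
    c2a = conv_param(3, 3, C, 2 * C),   n2a = bn_param(2 * C),
    c2b = conv_param(3, 3, 2 * C, 2 * C), n2b = bn_param(2 * C),
    c3a = conv_param(3, 3, 2 * C, 4 * C), n3a = bn_param(4 * C),
    c3b = conv_param(3, 3, 4 * C, 4 * C), n3b = bn_param(4 * C),
    c4a = conv_param(1, 1, 4 * C, 8 * C), n4a = bn_param(8 * C),
    c4b = conv_param(1, 1, 8 * C, 8 * C), n4b = bn_param(8 * C),
    d1c = conv_param(2, 2, 8 * C, 4 * C),
    c5a = conv_param(3, 3, 8 * C, 4 * C), n5a = bn_param(4 * C),
    c5b = conv_param(3, 3, 4 * C, 4 * C), n5b = bn_param(4 * C),
    d2c = conv_param(2, 2, 4 * C, 2 * C),
    c6a = conv_param(3, 3, 4 * C, 2 * C), n6a = bn_param(2 * C),
    c6b = conv_param(3, 3, 2 * C, 2 * C), n6b = bn_param(2 * C),
    d3c = conv_param(2, 2, 2 * C, C),
    c7a = conv_param(3, 3, 2 * C, C),   n7a = bn_param(C),
    c7b = conv_param(3, 3, C, C),       n7b = bn_param(C),
    head = conv_param(1, 1, C, 1)
  ) -> p
  # negative head bias: start from a sparse-foreground prior (tumor occupies
  # a small image fraction), which accelerates Dice-loss convergence
  p$head$b <- -2
  p
}

#' Build a DCNN with seed-reproducible initialization
#'
#' @param cfg a [dcnn_config()].
#' @param seed integer seed for the He-normal weight draws.
#' @return list of class `dcnn` with `cfg` and `params`.
#' @export
build_dcnn <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "dcnn_config"))
  params <- with_seed(seed, dcnn_init_params(cfg$base_channels))
  structure(list(cfg = cfg, params = params, seed = as.integer(seed)),
            class = "dcnn")
}

# --- forward ---------------------------------------------------------------

# Shared conv+BN+ReLU step operating on an environment P (so BN running
# moments persist) and a cache environment.
cbr_fwd_step <- function(P, cache, x, cn, nn, train, momentum) {
  z <- conv_fwd(x, P[[cn]])
  bf <- bn_fwd(z, P[[nn]], train, momentum)
  P[[nn]] <- bf$p
  y <- relu_fwd(bf$y)
  cache[[cn]] <- list(x = x, bn = bf$cache, y = y)
  y
}

dcnn_encoder_fwd <- function(P, cache, x, train, momentum) {
  r1a <- cbr_fwd_step(P, cache, x, "c1a", "n1a", train, momentum)
  s1 <- cbr_fwd_step(P, cache, r1a, "c1b", "n1b", train, momentum)
  mp1 <- .maxpool_fwd_cpp(s1); cache$mp1 <- list(idx = mp1$idx, d = dim(s1))
  r2a <- cbr_fwd_step(P, cache, mp1$y, "c2a", "n2a", train, momentum)
  s2 <- cbr_fwd_step(P, cache, r2a, "c2b", "n2b", train, momentum)
  mp2 <- .maxpool_fwd_cpp(s2); cache$mp2 <- list(idx = mp2$idx, d = dim(s2))
  r3a <- cbr_fwd_step(P, cache, mp2$y, "c3a", "n3a", train, momentum)
  s3 <- cbr_fwd_step(P, cache, r3a, "c3b", "n3b", train, momentum)
  mp3 <- .maxpool_fwd_cpp(s3); cache$mp3 <- list(idx = mp3$idx, d = dim(s3))
  r4a <- cbr_fwd_step(P, cache, mp3$y, "c4a", "n4a", train, momentum)
  r4b <- cbr_fwd_step(P, cache, r4a, "c4b", "n4b", train, momentum)
  list(bottleneck = r4b, s1 = s1, s2 = s2, s3 = s3)
}

dcnn_decoder_fwd <- function(P, cache, enc, train, momentum) {
  u1 <- .upsample2_fwd_cpp(enc$bottleneck)
  d1 <- conv_fwd(u1, P$d1c); cache$d1c <- list(x = u1)
  k1 <- concat_ch(d1, enc$s3); cache$k1c <- dim(d1)[3]
  r5a <- cbr_fwd_step(P, cache, k1, "c5a", "n5a", train, momentum)
  r5b <- cbr_fwd_step(P, cache, r5a, "c5b", "n5b", train, momentum)
  u2 <- .upsample2_fwd_cpp(r5b)
  d2 <- conv_fwd(u2, P$d2c); cache$d2c <- list(x = u2)
  k2 <- concat_ch(d2, enc$s2); cache$k2c <- dim(d2)[3]
  r6a <- cbr_fwd_step(P, cache, k2, "c6a", "n6a", train, momentum)
  r6b <- cbr_fwd_step(P, cache, r6a, "c6b", "n6b", train, momentum)
  u3 <- .upsample2_fwd_cpp(r6b)
  d3 <- conv_fwd(u3, P$d3c); cache$d3c <- list(x = u3)
  k3 <- concat_ch(d3, enc$s1); cache$k3c <- dim(d3)[3]
  r7a <- cbr_fwd_step(P, cache, k3, "c7a", "n7a", train, momentum)
  r7b <- cbr_fwd_step(P, cache, r7a, "c7b", "n7b", train, momentum)
  zh <- conv_fwd(r7b, P$head); cache$head <- list(x = r7b)
  out <- sigmoid(zh)
  cache$out <- out
  out
}

#' Forward pass of the DCNN
#'
#' @param net a [build_dcnn()] network.
#' @param x input batch, array `(h, w, 1, n)` or a single matrix.
#' @param train logical; use batch statistics and keep caches for backprop.
#' @return For `train = FALSE`: the score map array (values in \[0, 1\]).
#'   For `train = TRUE`: list with `out`, `cache`, and the updated `net`
#'   (batch-norm running moments advance during training).
#' @export
dcnn_forward <- function(net, x, train = FALSE) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1, 1))
  d <- dim(x)
  if (any(d[1:2] %% 8 != 0))
    stopf("input size must be divisible by 8")
  P <- list2env(net$params)
  cache <- new.env(parent = emptyenv())
  enc <- dcnn_encoder_fwd(P, cache, x, train, net$cfg$bn_momentum)
  out <- dcnn_decoder_fwd(P, cache, enc, train, net$cfg$bn_momentum)
  if (!train) return(out)
  net$params <- as.list(P)[names(net$params)]
  list(out = out, cache = cache, net = net)
}

# --- backward --------------------------------------------------------------

cbr_bwd_step <- function(P, cache, grads, dy, cn, nn) {
  cc <- cache[[cn]]
  dz <- relu_bwd(dy, cc$y)
  bb <- bn_bwd(dz, P[[nn]], cc$bn)
  grads[[nn]] <- list(gamma = bb$dgamma, beta = bb$dbeta)
  cb <- conv_bwd(cc$x, P[[cn]], bb$dx)
  grads[[cn]] <- list(W = cb$dW, b = cb$db)
  cb$dx
}

# Full backward pass; `dout` is the gradient of the loss w.r.t. the sigmoid
# output. Returns a named list of per-parameter gradients.
dcnn_backward <- function(net, cache, dout) {
  P <- list2env(net$params)
  grads <- new.env(parent = emptyenv())
  dzh <- dout * cache$out * (1 - cache$out)
  cb <- conv_bwd(cache$head$x, P$head, dzh)
  grads$head <- list(W = cb$dW, b = cb$db)
  dy <- cb$dx
  dy <- cbr_bwd_step(P, cache, grads, dy, "c7b", "n7b")
  dk3 <- cbr_bwd_step(P, cache, grads, dy, "c7a", "n7a")
  sp3 <- split_ch(dk3, cache$k3c)
  cb <- conv_bwd(cache$d3c$x, P$d3c, sp3$a)
  grads$d3c <- list(W = cb$dW, b = cb$db)
  dr6b <- .upsample2_bwd_cpp(cb$dx)
  ds1 <- sp3$b
  dy <- cbr_bwd_step(P, cache, grads, dr6b, "c6b", "n6b")
  dk2 <- cbr_bwd_step(P, cache, grads, dy, "c6a", "n6a")
  sp2 <- split_ch(dk2, cache$k2c)
  cb <- conv_bwd(cache$d2c$x, P$d2c, sp2$a)
  grads$d2c <- list(W = cb$dW, b = cb$db)
  dr5b <- .upsample2_bwd_cpp(cb$dx)
  ds2 <- sp2$b
  dy <- cbr_bwd_step(P, cache, grads, dr5b, "c5b", "n5b")
  dk1 <- cbr_bwd_step(P, cache, grads, dy, "c5a", "n5a")
  sp1 <- split_ch(dk1, cache$k1c)
  cb <- conv_bwd(cache$d1c$x, P$d1c, sp1$a)
  grads$d1c <- list(W = cb$dW, b = cb$db)
  dr4b <- .upsample2_bwd_cpp(cb$dx)
  ds3 <- sp1$b
  dcnn_encoder_bwd(P, cache, grads, dr4b, ds1, ds2, ds3)
  as.list(grads)
}

# Encoder backward; skip gradients (ds1..ds3) default to zero for the
# stage-1 encoder-only training path.
dcnn_encoder_bwd <- function(P, cache, grads, dbottleneck,
                             ds1 = 0, ds2 = 0, ds3 = 0) {
  dy <- cbr_bwd_step(P, cache, grads, dbottleneck, "c4b", "n4b")
  dp3 <- cbr_bwd_step(P, cache, grads, dy, "c4a", "n4a")
  dS3 <- .maxpool_bwd_cpp(dp3, cache$mp3$idx, cache$mp3$d) + ds3
  dy <- cbr_bwd_step(P, cache, grads, dS3, "c3b", "n3b")
  dp2 <- cbr_bwd_step(P, cache, grads, dy, "c3a", "n3a")
  dS2 <- .maxpool_bwd_cpp(dp2, cache$mp2$idx, cache$mp2$d) + ds2
  dy <- cbr_bwd_step(P, cache, grads, dS2, "c2b", "n2b")
  dp1 <- cbr_bwd_step(P, cache, grads, dy, "c2a", "n2a")
  dS1 <- .maxpool_bwd_cpp(dp1, cache$mp1$idx, cache$mp1$d) + ds1
  dy <- cbr_bwd_step(P, cache, grads, dS1, "c1b", "n1b")
  cbr_bwd_step(P, cache, grads, dy, "c1a", "n1a")
  invisible(NULL)
}

# --- losses ----------------------------------------------------------------

#' Soft Dice loss
#'
#' `1 - (2 * sum(pred * target) + smooth) / (sum(pred) + sum(target) +
#' smooth)`, treating the whole input as one sample. With `smooth = 0` the
#' loss is 0 for perfect binary overlap and 1 for disjoint nonempty masks.
#'
#' @param pred score map with values in \[0, 1\].
#' @param target binary mask of the same shape.
#' @param smooth smoothing constant (>= 0); the default 1 avoids 0/0 on
#'   empty slices.
#' @return scalar loss in \[0, 1\].
#' @export
dice_loss <- function(pred, target, smooth = 1) {
  if (!identical(dim(pred) %||% length(pred), dim(target) %||% length(target)))
    stopf("dice_loss: pred and target shapes differ")
  if (any(pred < 0 | pred > 1)) stopf("dice_loss: pred must lie in [0, 1]")
  if (!is_binary(target)) stopf("dice_loss: target must be binary")
  1 - (2 * sum(pred * target) + smooth) / (sum(pred) + sum(target) + smooth)
}

# Batch Dice loss (mean of per-sample soft Dice) with analytic gradient.
dice_batch <- function(pred, target, smooth = 1) {
  N <- dim(pred)[4]
  pm <- matrix(pred, ncol = N); tm <- matrix(target, ncol = N)
  inter <- colSums(pm * tm); sp <- colSums(pm); st <- colSums(tm)
  den <- sp + st + smooth
  loss <- mean(1 - (2 * inter + smooth) / den)
  dd <- -(2 * tm * rep(den, each = nrow(tm)) -
            rep(2 * inter + smooth, each = nrow(tm))) /
    rep(den^2, each = nrow(tm)) / N
  list(loss = loss, grad = array(dd, dim(pred)))
}

#' Threshold a score map into a binary mask
#'
#' @param s score map (any array/matrix of probabilities).
#' @param threshold probability in (0, 1); voxels with `s >= threshold`
#'   become foreground.
#' @return binary array of the same shape.
#' @export
binarize <- function(s, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) stopf("threshold must be in (0, 1)")
  out <- (s >= threshold) * 1
  if (!is.null(dim(s))) dim(out) <- dim(s)
  out
}

#' Save / load network weights
#'
#' Serialization keeps forward outputs bit-identical: `load_weights(
#' save_weights(net, path))` reproduces exactly the same score maps.
#'
#' @param net a `dcnn` or `dfn` object.
#' @param path file path (RDS serialization with a format tag).
#' @name weights_io
#' @export
save_weights <- function(net, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  saveRDS(list(format = "dfnseg-weights-1", net = net), path)
  invisible(path)
}

#' @rdname weights_io
#' @export
load_weights <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "dfnseg-weights-1"))
    stopf("%s is not a dfnseg weights file", path)
  obj$net
}
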