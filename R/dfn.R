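# Deep fusion network: two phase-specific sub-networks whose score maps are
# summed and passed through a small fusion block (two 3x3 conv+BN+ReLU
# layers, a 1x1 conv, and a sigmoid) to produce the final map.

#' Fusion network configuration
#'
#' @param alpha loss weights of the two sub-networks in the composite loss
#'   (both default 0.5).
#' @param fusion_channels width of the fusion block's conv layers.
#' @param freeze_subnets if TRUE, only fusion-block parameters update during
#'   the fusion training stage.
#' @param fusion_input `"sum"` (elementwise sum of the sub score maps, the
#'   printed formula) or `"concat"` (ablation variant).
#' @return list of class `fusion_config` (the number of sub-networks is
#'   fixed at 2, one per MRI phase).
#' @export
fusion_config <- function(alpha = c(0.5, 0.5), fusion_channels = 8L,
                          freeze_subnets = FALSE,
                          fusion_input = c("sum", "concat")) {
  fusion_input <- match.arg(fusion_input)
  if (length(alpha) != 2 || any(alpha < 0))
    stopf("alpha must be two non-negative loss weights")
  structure(list(n_subnets = 2L, alpha = alpha,
                 fusion_channels = as.integer(fusion_channels),
                 freeze_subnets = freeze_subnets,
                 fusion_input = fusion_input),
            class = "fusion_config")
}

# Fusion-block parameters, initialized as an approximate identity on the
# summed score map (center-tap pass-through plus small symmetry-breaking
# noise), so an untrained fusion block already acts like an average vote of
# the two sub-networks.
fusion_init_params <- function(cf, cin) {
  f1 <- conv_param(3, 3, cin, cf)
  f1$W <- f1$W * 0.05
  f1$W[2, 2, 1, 1] <- f1$W[2, 2, 1, 1] + 1
  f2 <- conv_param(3, 3, cf, cf)
  f2$W <- f2$W * 0.05
  f2$W[2, 2, 1, 1] <- f2$W[2, 2, 1, 1] + 1
  # mean-vote readout: the decision boundary sits at a summed score of ~1
  # (both sub-networks at 0.5), so a single confident sub-network does not
  # by itself cross the threshold
  f3 <- conv_param(1, 1, cf, 1)
  f3$W <- f3$W * 0.05
  f3$W[1, 1, 1, 1] <- f3$W[1, 1, 1, 1] + 4
  f3$b <- -4
  list(f1 = f1, g1 = bn_param(cf), f2 = f2, g2 = bn_param(cf), f3 = f3)
}

#' Build a deep fusion network
#'
#' Two sub-networks (one per phase) with identical configuration plus the
#' fusion block. Sub-network weights are drawn from seeds derived from
#' `seed`, so the whole construction is reproducible.
#'
#' @param cfg a [fusion_config()].
#' @param sub_cfg the shared [dcnn_config()] of the two sub-networks.
#' @param seed integer seed.
#' @return list of class `dfn` with `sub1`, `sub2`, `fusion`, `cfg`,
#'   `sub_cfg`.
#' @export
build_dfn <- function(cfg, sub_cfg, seed = 1L) {
  stopifnot(inherits(cfg, "fusion_config"), inherits(sub_cfg, "dcnn_config"))
  sub1 <- build_dcnn(sub_cfg, derive_seed(seed, 1))
  sub2 <- build_dcnn(sub_cfg, derive_seed(seed, 2))
  cin <- if (cfg$fusion_input == "sum") 1L else 2L
  fusion <- with_seed(derive_seed(seed, 3),
                      fusion_init_params(cfg$fusion_channels, cin))
  structure(list(sub1 = sub1, sub2 = sub2, fusion = fusion, cfg = cfg,
                 sub_cfg = sub_cfg, seed = as.integer(seed)),
            class = "dfn")
}

fusion_fwd <- function(P, cache, x, train, momentum) {
  r1 <- cbr_fwd_step(P, cache, x, "f1", "g1", train, momentum)
  r2 <- cbr_fwd_step(P, cache, r1, "f2", "g2", train, momentum)
  z <- conv_fwd(r2, P$f3); cache$f3 <- list(x = r2)
  out <- sigmoid(z)
  cache$fout <- out
  out
}

fusion_bwd <- function(P, cache, dout) {
  grads <- new.env(parent = emptyenv())
  dz <- dout * cache$fout * (1 - cache$fout)
  cb <- conv_bwd(cache$f3$x, P$f3, dz)
  grads$f3 <- list(W = cb$dW, b = cb$db)
  dy <- cbr_bwd_step(P, cache, grads, cb$dx, "f2", "g2")
  dx <- cbr_bwd_step(P, cache, grads, dy, "f1", "g1")
  list(grads = as.list(grads), dx = dx)
}

#' Forward pass of the deep fusion network
#'
#' Each phase feeds its own sub-network; the two score maps are combined
#' (elementwise sum by default) and mapped through the fusion block to the
#' final score map. The intermediate sub-network score maps are exposed, and
#' equal what each sub-network produces standalone on its phase.
#'
#' @param net a [build_dfn()] network.
#' @param x1,x2 phase-1 / phase-2 input batches `(h, w, 1, n)` or matrices.
#' @param train logical; keep caches for backprop.
#' @return For `train = FALSE`: list with `out`, `sub1`, `sub2` score maps.
#'   For `train = TRUE`: additionally `cache` and the updated `net`.
#' @export
dfn_forward <- function(net, x1, x2, train = FALSE) {
  if (is.matrix(x1)) x1 <- array(x1, c(dim(x1), 1, 1))
  if (is.matrix(x2)) x2 <- array(x2, c(dim(x2), 1, 1))
  if (!identical(dim(x1), dim(x2)))
    stopf("phase-1 and phase-2 inputs must share one shape")
  if (train) {
    fw1 <- dcnn_forward(net$sub1, x1, train = TRUE)
    fw2 <- dcnn_forward(net$sub2, x2, train = TRUE)
    net$sub1 <- fw1$net; net$sub2 <- fw2$net
    o1 <- fw1$out; o2 <- fw2$out
  } else {
    o1 <- dcnn_forward(net$sub1, x1)
    o2 <- dcnn_forward(net$sub2, x2)
  }
  fin <- if (net$cfg$fusion_input == "sum") o1 + o2 else concat_ch(o1, o2)
  P <- list2env(net$fusion)
  fcache <- new.env(parent = emptyenv())
  out <- fusion_fwd(P, fcache, fin, train, net$sub_cfg$bn_momentum)
  if (!train) return(list(out = out, sub1 = o1, sub2 = o2))
  net$fusion <- as.list(P)[names(net$fusion)]
  list(out = out, sub1 = o1, sub2 = o2, net = net,
       cache = list(sub1 = fw1$cache, sub2 = fw2$cache, fusion = fcache,
                    fP = P))
}

# Backward pass of the DFN under the composite loss. `d_fused` is the loss
# gradient w.r.t. the fused output; `d_sub1`/`d_sub2` are the (alpha-
# weighted) sub-loss gradients w.r.t. the sub score maps. Returns gradients
# for both sub-networks and the fusion block.
dfn_backward <- function(net, fw, d_fused, d_sub1 = NULL, d_sub2 = NULL) {
  fb <- fusion_bwd(fw$cache$fP, fw$cache$fusion, d_fused)
  if (net$cfg$fusion_input == "sum") {
    do1 <- fb$dx; do2 <- fb$dx
  } else {
    sp <- split_ch(fb$dx, 1L)
    do1 <- sp$a; do2 <- sp$b
  }
  if (!is.null(d_sub1)) do1 <- do1 + d_sub1
  if (!is.null(d_sub2)) do2 <- do2 + d_sub2
  g1 <- dcnn_backward(net$sub1, fw$cache$sub1, do1)
  g2 <- dcnn_backward(net$sub2, fw$cache$sub2, do2)
  list(sub1 = g1, sub2 = g2, fusion = fb$grads)
}

#' Composite loss of the deep fusion network
#'
#' `total = alpha1 * L_subnet1 + alpha2 * L_subnet2 + L_fusion`, where every
#' term is a soft Dice loss against the same ground truth. The breakdown
#' fields always satisfy the stated weighted sum exactly.
#'
#' @param G binary ground-truth mask.
#' @param sub_maps list of the two sub-network score maps.
#' @param fused the fused score map.
#' @param cfg a [fusion_config()] providing the alpha weights.
#' @param smooth Dice smoothing constant.
#' @return list with `subnet_losses` (length 2), `fusion_loss`, and `total`.
#' @export
composite_loss <- function(G, sub_maps, fused, cfg = fusion_config(),
                           smooth = 1) {
  if (any(cfg$alpha < 0)) stopf("alpha weights must be non-negative")
  ls <- vapply(sub_maps, function(p) dice_loss(p, G, smooth), numeric(1))
  lf <- dice_loss(fused, G, smooth)
  list(subnet_losses = ls, fusion_loss = lf,
       total = sum(ls * cfg$alpha) + lf)
}
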