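# Minibatch optimizers over nested parameter lists. Parameters and gradients
# are named lists of layers; each layer is a list of numeric arrays (conv:
# W, b; batch norm: gamma, beta — running moments are not optimized).

#' Training configuration
#'
#' Defaults follow the reference training protocol: Adam for the per-phase network and
#' plain SGD for the fusion network, base learning rates 1e-4 and 1e-7
#' respectively, batch size 8. Epoch budgets are configurable; the staged
#' protocol uses `epochs = c(e1, e2, e3)` (encoder pre-training, full-network
#' training, augmented fine-tuning) and `epochs_fusion` for the fusion stage.
#'
#' @param optimizer `"adam"` or `"sgd"`.
#' @param base_lr learning rate (> 0).
#' @param batch_size minibatch size (>= 1).
#' @param epochs integer triple for the three DCNN stages.
#' @param epochs_fusion epochs of the fusion training stage.
#' @param momentum SGD momentum (0 = plain SGD).
#' @param seed integer seed driving batch shuffling.
#' @return list of class `train_config`.
#' @export
train_config <- function(optimizer = c("adam", "sgd"), base_lr = 1e-4,
                         batch_size = 8L, epochs = c(20L, 40L, 40L),
                         epochs_fusion = 40L, momentum = 0, seed = 1L) {
  optimizer <- match.arg(optimizer)
  if (base_lr <= 0) stopf("base_lr must be > 0")
  if (batch_size < 1) stopf("batch_size must be >= 1")
  structure(list(optimizer = optimizer, base_lr = base_lr,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 epochs_fusion = as.integer(epochs_fusion),
                 momentum = momentum, seed = as.integer(seed)),
            class = "train_config")
}

opt_init <- function(cfg) {
  list(type = cfg$optimizer, lr = cfg$base_lr, momentum = cfg$momentum,
       beta1 = 0.9, beta2 = 0.999, eps = 1e-8, t = 0,
       state = new.env(parent = emptyenv()))
}

# Apply one update step. Only layers present in `grads` (and only fields
# present per layer) are updated, which is how freezing and stage-wise
# training are expressed.
opt_step <- function(opt, params, grads) {
  opt$t <- opt$t + 1
  st <- opt$state
  for (ln in names(grads)) {
    for (fn in names(grads[[ln]])) {
      g <- grads[[ln]][[fn]]
      key <- paste0(ln, ".", fn)
      p <- params[[ln]][[fn]]
      if (opt$type == "adam") {
        s <- st[[key]] %||% list(m = 0 * g, v = 0 * g)
        s$m <- opt$beta1 * s$m + (1 - opt$beta1) * g
        s$v <- opt$beta2 * s$v + (1 - opt$beta2) * g^2
        st[[key]] <- s
        mhat <- s$m / (1 - opt$beta1^opt$t)
        vhat <- s$v / (1 - opt$beta2^opt$t)
        p <- p - opt$lr * mhat / (sqrt(vhat) + opt$eps)
      } else {
        if (opt$momentum > 0) {
          v <- st[[key]] %||% 0 * g
          v <- opt$momentum * v - opt$lr * g
          st[[key]] <- v
          p <- p + v
        } else {
          p <- p - opt$lr * g
        }
      }
      params[[ln]][[fn]] <- p
    }
  }
  list(opt = opt, params = params)
}
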