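# Training protocols: staged training of the per-phase network, two-subset
# training of the fusion network, and the leave-one-out cross-validation
# harness. All stochasticity (shuffling, augmentation draws) is derived from
# the configured seeds, so identical configurations reproduce identical
# histories.

ENC_LAYERS <- c("c1a", "n1a", "c1b", "n1b", "c2a", "n2a", "c2b", "n2b",
                "c3a", "n3a", "c3b", "n3b", "c4a", "n4a", "c4b", "n4b")

hard_dice_counts <- function(pred, target) {
  b <- pred >= 0.5
  t <- target > 0
  c(tp = sum(b & t), fp = sum(b & !t), fn = sum(!b & t))
}

# Shared epoch loop. `step_fn(idx)` consumes a batch index vector, performs
# one optimization step (mutating state in its enclosure), and returns
# c(loss, tp, fp, fn). Appends one history row per epoch.
epoch_loop <- function(n_items, n_epochs, batch_size, seed, stage, step_fn,
                       history) {
  for (ep in seq_len(n_epochs)) {
    perm <- with_seed(derive_seed(seed, ep), sample.int(n_items))
    batches <- split(perm, ceiling(seq_along(perm) / batch_size))
    tot <- c(0, 0, 0, 0)
    for (b in batches) {
      r <- step_fn(b)
      if (!is.finite(r[1])) {
        cond <- simpleError(sprintf("non-finite loss in stage '%s'", stage))
        cond$history <- history
        stop(cond)
      }
      tot <- tot + c(r[1] * length(b), r[2:4])
    }
    dsc <- if (tot[2] + tot[3] + tot[4] == 0) 1
           else 2 * tot[2] / (tot[3] + 2 * tot[2] + tot[4])
    history <- rbind(history,
                     data.frame(stage = stage, epoch = ep,
                                loss = tot[1] / n_items, dice = dsc))
  }
  history
}

pairs_to_tensors <- function(pairs, phase) {
  key <- paste0("phase", phase)
  list(x = stack_slices(lapply(pairs, `[[`, key)),
       y = stack_slices(lapply(pairs, `[[`, "mask")))
}

#' Staged training of the per-phase network
#'
#' Three stages: (1) the contracting path is trained on non-augmented data
#' through a temporary head (1x1 conv + sigmoid + x8 upsampling on the
#' bottleneck) that is discarded afterwards; (2) the entire network is
#' trained on the same non-augmented data; (3) the network is fine-tuned on
#' an augmented dataset built from the training pairs. Deterministic given
#' the seeds in `cfg` and `aug`.
#'
#' @param net a [build_dcnn()] network.
#' @param pairs nonempty list of network-ready slice pairs.
#' @param cfg a [train_config()] (`epochs` gives the three stage budgets).
#' @param aug an [augment_params()] for stage 3.
#' @param phase which phase feeds the network (1 or 2).
#' @return list with the trained `net` and a `history` data.frame (stage,
#'   epoch, mean loss, aggregate training Dice).
#' @export
train_dcnn_staged <- function(net, pairs, cfg, aug = augment_params(),
                              phase = 1) {
  if (length(pairs) == 0) stopf("training dataset is empty")
  smooth <- net$cfg$smooth
  history <- data.frame()
  dat <- pairs_to_tensors(pairs, phase)
  n <- dim(dat$x)[4]

  # stage 1: contracting path via temporary upsampling head
  C <- net$cfg$base_channels
  tmp_head <- with_seed(derive_seed(cfg$seed, 9001),
                        conv_param(1, 1, 8 * C, 1))
  tmp_head$b <- -2  # same sparse-foreground prior as the main head
  opt <- opt_init(cfg)
  step1 <- function(idx) {
    xb <- dat$x[, , , idx, drop = FALSE]
    yb <- dat$y[, , , idx, drop = FALSE]
    P <- list2env(net$params)
    cache <- new.env(parent = emptyenv())
    enc <- dcnn_encoder_fwd(P, cache, xb, TRUE, net$cfg$bn_momentum)
    net$params <<- as.list(P)[names(net$params)]
    z <- conv_fwd(enc$bottleneck, tmp_head)
    s <- sigmoid(z)
    u <- .upsample2_fwd_cpp(.upsample2_fwd_cpp(.upsample2_fwd_cpp(s)))
    db <- dice_batch(u, yb, smooth)
    du <- .upsample2_bwd_cpp(.upsample2_bwd_cpp(.upsample2_bwd_cpp(db$grad)))
    dz <- du * s * (1 - s)
    cb <- conv_bwd(enc$bottleneck, tmp_head, dz)
    grads <- new.env(parent = emptyenv())
    grads$tmp_head <- list(W = cb$dW, b = cb$db)
    dcnn_encoder_bwd(P, cache, grads, cb$dx)
    g <- as.list(grads)
    all_p <- c(net$params, list(tmp_head = tmp_head))
    upd <- opt_step(opt, all_p, g)
    opt <<- upd$opt
    tmp_head <<- upd$params$tmp_head
    net$params <<- upd$params[names(net$params)]
    c(db$loss, hard_dice_counts(u, yb))
  }
  history <- epoch_loop(n, cfg$epochs[1], cfg$batch_size,
                        derive_seed(cfg$seed, 1), "encoder", step1, history)

  # stages 2 and 3: full network (stage 3 on augmented data)
  full_stage <- function(data, n_epochs, tag, seed) {
    step <- function(idx) {
      xb <- data$x[, , , idx, drop = FALSE]
      yb <- data$y[, , , idx, drop = FALSE]
      fw <- dcnn_forward(net, xb, train = TRUE)
      net <<- fw$net
      db <- dice_batch(fw$out, yb, smooth)
      grads <- dcnn_backward(net, fw$cache, db$grad)
      upd <- opt_step(opt, net$params, grads)
      opt <<- upd$opt
      net$params <<- upd$params
      c(db$loss, hard_dice_counts(fw$out, yb))
    }
    history <<- epoch_loop(dim(data$x)[4], n_epochs, cfg$batch_size, seed,
                           tag, step, history)
  }
  opt <- opt_init(cfg)  # fresh optimizer state once the temporary head is gone
  full_stage(dat, cfg$epochs[2], "full", derive_seed(cfg$seed, 2))
  if (cfg$epochs[3] > 0) {
    aug_pairs <- build_augmented_dataset(pairs, aug)
    aug_dat <- pairs_to_tensors(aug_pairs, phase)
    full_stage(aug_dat, cfg$epochs[3], "augmented", derive_seed(cfg$seed, 3))
  }
  list(net = net, history = history)
}

#' Split a training dataset into two case-level subsets
#'
#' The split is by case id, never by slice, so slices of one patient never
#' straddle the two subsets. Sizes differ by at most one (the extra case
#' goes to subset A); the split is deterministic per seed.
#'
#' @param dataset list of slice pairs carrying `case_id`, or a character
#'   vector of case ids.
#' @param seed integer seed.
#' @return list with `a`, `b` (same type as the input) and `ids_a`, `ids_b`.
#' @export
split_training_subsets <- function(dataset, seed = 1L) {
  ids <- if (is.character(dataset)) dataset
         else unique(vapply(dataset, `[[`, "", "case_id"))
  if (length(ids) < 2) stopf("need at least 2 cases to split")
  perm <- with_seed(seed, sample(ids))
  na <- ceiling(length(ids) / 2)
  ids_a <- sort(perm[seq_len(na)])
  ids_b <- sort(perm[-seq_len(na)])
  if (is.character(dataset))
    return(list(a = ids_a, b = ids_b, ids_a = ids_a, ids_b = ids_b))
  keep <- function(ids) Filter(function(p) p$case_id %in% ids, dataset)
  list(a = keep(ids_a), b = keep(ids_b), ids_a = ids_a, ids_b = ids_b)
}

#' Two-subset training of the deep fusion network
#'
#' The training cases are split into two equal case-level subsets. Subset A
#' trains the two sub-networks (phase 1 and phase 2) with the full staged
#' protocol; subset B then trains the assembled fusion network under the
#' composite loss. With `freeze_subnets` in the fusion config, only
#' fusion-block parameters update in the second phase.
#'
#' @param dfn a [build_dfn()] network.
#' @param pairs slice pairs containing both phases and `case_id`.
#' @param cfg_sub [train_config()] for the staged sub-network training.
#' @param cfg_fusion [train_config()] for the fusion stage (SGD by default).
#' @param aug [augment_params()] for stage 3 of the sub-network protocol.
#' @return list with the trained `net` and combined `history` (with a `net`
#'   column: sub1 / sub2 / dfn).
#' @export
train_dfn <- function(dfn, pairs, cfg_sub, cfg_fusion,
                      aug = augment_params()) {
  if (length(pairs) == 0) stopf("training dataset is empty")
  sp <- split_training_subsets(pairs, derive_seed(cfg_fusion$seed, 77))
  t1 <- train_dcnn_staged(dfn$sub1, sp$a, cfg_sub, aug, phase = 1)
  t2 <- train_dcnn_staged(dfn$sub2, sp$a, cfg_sub, aug, phase = 2)
  dfn$sub1 <- t1$net
  dfn$sub2 <- t2$net
  history <- rbind(cbind(net = "sub1", t1$history),
                   cbind(net = "sub2", t2$history))

  x1 <- stack_slices(lapply(sp$b, `[[`, "phase1"))
  x2 <- stack_slices(lapply(sp$b, `[[`, "phase2"))
  y <- stack_slices(lapply(sp$b, `[[`, "mask"))
  smooth <- dfn$sub_cfg$smooth
  alpha <- dfn$cfg$alpha
  opt <- opt_init(cfg_fusion)
  step <- function(idx) {
    b1 <- x1[, , , idx, drop = FALSE]; b2 <- x2[, , , idx, drop = FALSE]
    yb <- y[, , , idx, drop = FALSE]
    if (dfn$cfg$freeze_subnets) {
      # frozen sub-nets run in inference mode: weights and batch-norm
      # moments stay bit-identical through the fusion stage
      o1 <- dcnn_forward(dfn$sub1, b1)
      o2 <- dcnn_forward(dfn$sub2, b2)
      fin <- if (dfn$cfg$fusion_input == "sum") o1 + o2 else concat_ch(o1, o2)
      P <- list2env(dfn$fusion)
      fc <- new.env(parent = emptyenv())
      out <- fusion_fwd(P, fc, fin, TRUE, dfn$sub_cfg$bn_momentum)
      dfn$fusion <<- as.list(P)[names(dfn$fusion)]
      df <- dice_batch(out, yb, smooth)
      d1 <- dice_batch(o1, yb, smooth)
      d2 <- dice_batch(o2, yb, smooth)
      fb <- fusion_bwd(P, fc, df$grad)
      upd <- opt_step(opt, dfn$fusion, fb$grads)
      opt <<- upd$opt
      dfn$fusion <<- upd$params
      loss_total <- sum(alpha * c(d1$loss, d2$loss)) + df$loss
      return(c(loss_total, hard_dice_counts(out, yb)))
    }
    fw <- dfn_forward(dfn, b1, b2, train = TRUE)
    dfn <<- fw$net
    df <- dice_batch(fw$out, yb, smooth)
    d1 <- dice_batch(fw$sub1, yb, smooth)
    d2 <- dice_batch(fw$sub2, yb, smooth)
    g <- dfn_backward(dfn, fw, df$grad, alpha[1] * d1$grad, alpha[2] * d2$grad)
    {
      all_p <- c(stats::setNames(dfn$sub1$params,
                                 paste0("s1.", names(dfn$sub1$params))),
                 stats::setNames(dfn$sub2$params,
                                 paste0("s2.", names(dfn$sub2$params))),
                 dfn$fusion)
      all_g <- c(stats::setNames(g$sub1, paste0("s1.", names(g$sub1))),
                 stats::setNames(g$sub2, paste0("s2.", names(g$sub2))),
                 g$fusion)
      upd <- opt_step(opt, all_p, all_g)
      opt <<- upd$opt
      dfn$sub1$params <<- stats::setNames(
        upd$params[paste0("s1.", names(dfn$sub1$params))],
        names(dfn$sub1$params))
      dfn$sub2$params <<- stats::setNames(
        upd$params[paste0("s2.", names(dfn$sub2$params))],
        names(dfn$sub2$params))
      dfn$fusion <<- upd$params[names(dfn$fusion)]
    }
    loss_total <- sum(alpha * c(d1$loss, d2$loss)) + df$loss
    c(loss_total, hard_dice_counts(fw$out, yb))
  }
  history <- rbind(history,
                   cbind(net = "dfn",
                         epoch_loop(dim(y)[4], cfg_fusion$epochs_fusion,
                                    cfg_fusion$batch_size,
                                    derive_seed(cfg_fusion$seed, 4),
                                    "fusion", step, data.frame())))
  list(net = dfn, history = history)
}

#' Leave-one-out cross-validation harness
#'
#' One fold per case: the model is trained on all other cases and evaluated
#' volume-level on the held-out case. Each fold's record carries the training
#' manifest (the case ids actually used), so the no-leakage property is
#' assertable.
#'
#' @param cases list of cases, each with at least `id` and `gt_mask`.
#' @param train_fn `function(train_cases, fold_seed)` returning a model.
#' @param predict_fn `function(model, case)` returning a full-grid binary
#'   mask.
#' @param seed master seed; per-fold seeds are derived from it.
#' @return list with `results` (data.frame: case_id, dsc, precision, recall)
#'   and `manifests` (per-fold training case ids).
#' @export
run_loocv <- function(cases, train_fn, predict_fn, seed = 1L) {
  if (length(cases) < 2) stopf("LOOCV needs at least 2 cases")
  rows <- list(); manifests <- list()
  for (i in seq_along(cases)) {
    train_cases <- cases[-i]
    model <- train_fn(train_cases, derive_seed(seed, i))
    pred <- predict_fn(model, cases[[i]])
    sm <- seg_metrics(confusion_counts(pred, cases[[i]]$gt_mask))
    id <- cases[[i]]$id %||% as.character(i)
    rows[[i]] <- data.frame(case_id = id, dsc = sm$dsc,
                            precision = sm$precision, recall = sm$recall)
    manifests[[id]] <- vapply(train_cases, function(cs)
      cs$id %||% "", character(1))
  }
  list(results = do.call(rbind, rows), manifests = manifests)
}
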