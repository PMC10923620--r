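make_tiny_pairs <- function(n_cases = 2, slices = 3, size = 16) {
  pairs <- list()
  for (cid in seq_len(n_cases))
    for (s in seq_len(slices))
      pairs[[length(pairs) + 1]] <-
        random_slice_pair(cid * 10 + s, n = size,
                          case_id = paste0("case", cid), slice = s)
  pairs
}

test_that("staged training rejects an empty dataset", {
  net <- tiny_dcnn(input = 16)
  expect_error(train_dcnn_staged(net, list(), train_config()), "empty")
})

test_that("history has one row per epoch with ordered stage tags", {
  net <- tiny_dcnn(seed = 2, input = 16)
  tc <- train_config(optimizer = "adam", base_lr = 1e-3,
                     epochs = c(2, 3, 2), batch_size = 4, seed = 1)
  tr <- train_dcnn_staged(net, make_tiny_pairs(), tc,
                          augment_params(multiplicity = 1, seed = 2))
  h <- tr$history
  expect_equal(nrow(h), 2 + 3 + 2)
  expect_equal(rle(h$stage)$values, c("encoder", "full", "augmented"))
  expect_equal(rle(h$stage)$lengths, c(2, 3, 2))
  expect_true(all(is.finite(h$loss)))
})

test_that("training is deterministic given the seeds", {
  tc <- train_config(optimizer = "adam", base_lr = 1e-3,
                     epochs = c(1, 2, 1), batch_size = 4, seed = 5)
  pairs <- make_tiny_pairs()
  t1 <- train_dcnn_staged(tiny_dcnn(seed = 3, input = 16), pairs, tc,
                          augment_params(multiplicity = 1, seed = 6))
  t2 <- train_dcnn_staged(tiny_dcnn(seed = 3, input = 16), pairs, tc,
                          augment_params(multiplicity = 1, seed = 6))
  expect_identical(t1$history, t2$history)
  expect_identical(t1$net$params, t2$net$params)
})

test_that("case-level subset splitting is balanced, disjoint and seeded", {
  ids10 <- paste0("p", 1:10)
  s <- split_training_subsets(ids10, seed = 3)
  expect_length(s$ids_a, 5); expect_length(s$ids_b, 5)
  expect_length(intersect(s$ids_a, s$ids_b), 0)
  expect_setequal(c(s$ids_a, s$ids_b), ids10)
  # odd count: the extra case goes to subset A
  s11 <- split_training_subsets(paste0("p", 1:11), seed = 3)
  expect_length(s11$ids_a, 6); expect_length(s11$ids_b, 5)
  expect_identical(split_training_subsets(ids10, 7),
                   split_training_subsets(ids10, 7))
  expect_error(split_training_subsets("one"), "at least 2")
  # slice-pair input: every pair of one case lands in one subset
  pairs <- make_tiny_pairs(n_cases = 4)
  sp <- split_training_subsets(pairs, seed = 1)
  expect_length(intersect(unique(vapply(sp$a, `[[`, "", "case_id")),
                          unique(vapply(sp$b, `[[`, "", "case_id"))), 0)
})

test_that("freezing sub-networks leaves their weights bit-identical", {
  cfg <- dcnn_config(16, base_channels = 2)
  dfn <- build_dfn(fusion_config(freeze_subnets = TRUE), cfg, seed = 1)
  tc_sub <- train_config(optimizer = "adam", base_lr = 1e-3,
                         epochs = c(1, 1, 0), batch_size = 4, seed = 2)
  tc_fus <- train_config(optimizer = "sgd", base_lr = 0.01,
                         epochs_fusion = 2, batch_size = 4, seed = 3)
  tr <- train_dfn(dfn, make_tiny_pairs(n_cases = 4), tc_sub, tc_fus,
                  augment_params(multiplicity = 1, seed = 4))
  # sub-net weights after the fusion stage equal their post-stage-A values:
  # retrain the sub-nets alone on subset A and compare
  sp <- split_training_subsets(make_tiny_pairs(n_cases = 4),
                               dfnseg:::derive_seed(tc_fus$seed, 77))
  ref1 <- train_dcnn_staged(build_dcnn(cfg, dfnseg:::derive_seed(1, 1)),
                            sp$a, tc_sub,
                            augment_params(multiplicity = 1, seed = 4),
                            phase = 1)
  expect_identical(tr$net$sub1$params, ref1$net$params)
  expect_true(any(tr$history$stage == "fusion"))
  expect_true(all(is.finite(tr$history$loss)))
})

test_that("LOOCV trains each fold without its test case", {
  spec <- tiny_phantom_spec()
  ds <- generate_dataset(spec, 3, seed = 9)
  cases <- lapply(ds$cases, function(cs) {
    cs$pairs <- dfnseg:::make_network_pairs(cs, 16L)
    cs
  })
  seen <- list()
  train_fn <- function(train_cases, fold_seed) {
    ids <- vapply(train_cases, `[[`, "", "id")
    seen[[length(seen) + 1]] <<- ids
    pairs <- do.call(c, lapply(train_cases, `[[`, "pairs"))
    tc <- train_config(optimizer = "adam", base_lr = 1e-3,
                       epochs = c(1, 1, 0), batch_size = 4,
                       seed = fold_seed %% 1000)
    train_dcnn_staged(build_dcnn(dcnn_config(16, base_channels = 2), 1),
                      pairs, tc)$net
  }
  predict_fn <- function(model, case)
    segment_case(model, case, infer_config(16, phase = 1))
  out <- run_loocv(cases, train_fn, predict_fn, seed = 4)
  expect_equal(nrow(out$results), 3)
  expect_true(all(out$results$dsc >= 0 & out$results$dsc <= 1))
  for (i in 1:3) {
    id <- cases[[i]]$id
    expect_false(id %in% out$manifests[[id]])
    expect_length(out$manifests[[id]], 2)
  }
  expect_error(run_loocv(cases[1], train_fn, predict_fn), "at least 2")
})
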