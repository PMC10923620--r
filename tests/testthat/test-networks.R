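test_that("score maps keep the input shape and stay in [0, 1]", {
  net <- tiny_dcnn(seed = 1, input = 16, base = 2)
  x <- dfnseg:::with_seed(1, matrix(runif(16 * 16), 16))
  out <- dcnn_forward(net, x)
  expect_equal(dim(out), c(16, 16, 1, 1))
  expect_true(all(out >= 0 & out <= 1))
})

test_that("sizes not divisible by 8 are rejected", {
  expect_error(dcnn_config(c(100, 100)), "divisible by 8")
  expect_error(dcnn_config(4), "divisible by 8")
  net <- tiny_dcnn(input = 16)
  expect_error(dcnn_forward(net, matrix(0, 20, 20)), "divisible by 8")
})

test_that("dice loss matches its closed form on canonical cases", {
  m <- matrix(0, 4, 4); m[1:2, 1:2] <- 1
  expect_equal(dice_loss(m, m, smooth = 0), 0)
  disj <- matrix(0, 4, 4); disj[3:4, 3:4] <- 1
  expect_equal(dice_loss(disj, m, smooth = 0), 1)
  # uniform 0.5 prediction against half-foreground 2x2 grid: loss is 0.5
  half <- matrix(c(1, 1, 0, 0), 2)
  expect_equal(dice_loss(matrix(0.5, 2, 2), half, smooth = 0), 0.5)
  expect_error(dice_loss(matrix(0.5, 2, 2), matrix(0, 3, 3)), "shapes")
  expect_error(dice_loss(matrix(2, 2, 2), half), "\\[0, 1\\]")
})

test_that("dice loss is symmetric for binary arguments", {
  for (seed in 1:5) {
    a <- dfnseg:::with_seed(seed, matrix(rbinom(64, 1, 0.4), 8))
    b <- dfnseg:::with_seed(seed + 50, matrix(rbinom(64, 1, 0.4), 8))
    expect_equal(dice_loss(a, b, smooth = 0.5), dice_loss(b, a, smooth = 0.5))
  }
})

test_that("composite loss is the stated weighted sum, linear in alpha", {
  G <- matrix(c(1, 0, 0, 1), 2)
  s1 <- matrix(0.6, 2, 2); s2 <- matrix(0.3, 2, 2); f <- matrix(0.8, 2, 2)
  cfg <- fusion_config(alpha = c(0.5, 0.5))
  cl <- composite_loss(G, list(s1, s2), f, cfg)
  expect_equal(cl$total,
               0.5 * cl$subnet_losses[1] + 0.5 * cl$subnet_losses[2] +
                 cl$fusion_loss)
  # alpha = 0 leaves the fusion term alone
  cl0 <- composite_loss(G, list(s1, s2), f, fusion_config(alpha = c(0, 0)))
  expect_equal(cl0$total, cl0$fusion_loss)
  # perfect predictions with smooth = 0 give zero total
  clp <- composite_loss(G, list(G, G), G, cfg, smooth = 0)
  expect_equal(clp$total, 0)
  expect_error(fusion_config(alpha = c(-1, 1)), "non-negative")
})

test_that("binarize uses the >= tie rule and matches a brute-force count", {
  expect_true(all(binarize(matrix(0.4, 3, 3), 0.5) == 0))
  expect_true(all(binarize(matrix(0.5, 3, 3), 0.5) == 1))
  s <- dfnseg:::with_seed(9, matrix(runif(256), 16))
  expect_equal(sum(binarize(s, 0.3)), sum(s >= 0.3))
  expect_error(binarize(s, 1.5), "threshold")
})

test_that("fusion network exposes sub-maps equal to standalone sub-networks", {
  cfg <- dcnn_config(16, base_channels = 2)
  dfn <- build_dfn(fusion_config(), cfg, seed = 4)
  x1 <- dfnseg:::with_seed(1, matrix(runif(256), 16))
  x2 <- dfnseg:::with_seed(2, matrix(runif(256), 16))
  fw <- dfn_forward(dfn, x1, x2)
  expect_equal(dim(fw$out), c(16, 16, 1, 1))
  expect_true(all(fw$out >= 0 & fw$out <= 1))
  expect_identical(fw$sub1, dcnn_forward(dfn$sub1, x1))
  expect_identical(fw$sub2, dcnn_forward(dfn$sub2, x2))
  expect_error(dfn_forward(dfn, x1, matrix(0, 8, 8)), "share one shape")
})

test_that("all-zero sub-maps propagate to a spatially constant fused map", {
  dfn <- build_dfn(fusion_config(), dcnn_config(16, base_channels = 2), 5)
  zero <- array(0, c(16, 16, 1, 1))
  P <- list2env(dfn$fusion)
  cache <- new.env(parent = emptyenv())
  out <- dfnseg:::fusion_fwd(P, cache, zero + zero, train = FALSE, 0.1)
  inner <- out[2:15, 2:15, 1, 1]  # border pixels see zero padding
  expect_lt(diff(range(inner)), 1e-12)
})

test_that("weight serialization leaves forward outputs bit-identical", {
  td <- withr::local_tempdir()
  net <- tiny_dcnn(seed = 6, input = 16)
  x <- dfnseg:::with_seed(3, matrix(runif(256), 16))
  p <- file.path(td, "w.rds")
  save_weights(net, p)
  expect_identical(dcnn_forward(load_weights(p), x), dcnn_forward(net, x))
  dfn <- build_dfn(fusion_config(), dcnn_config(16, base_channels = 2), 7)
  save_weights(dfn, p)
  expect_identical(dfn_forward(load_weights(p), x, x)$out,
                   dfn_forward(dfn, x, x)$out)
})

test_that("analytic gradients match finite differences", {
  net <- tiny_dcnn(seed = 3, input = 8, base = 2)
  x <- dfnseg:::with_seed(1, array(runif(8 * 8 * 2), c(8, 8, 1, 2)))
  y <- dfnseg:::with_seed(2, array(rbinom(8 * 8 * 2, 1, 0.3), c(8, 8, 1, 2)))
  fw <- dcnn_forward(net, x, train = TRUE)
  db <- dfnseg:::dice_batch(fw$out, y, 1)
  grads <- dfnseg:::dcnn_backward(fw$net, fw$cache, db$grad)
  loss_at <- function(n2) {
    dfnseg:::dice_batch(dcnn_forward(n2, x, train = TRUE)$out, y, 1)$loss
  }
  eps <- 1e-5
  for (probe in list(c("c1a", "W", 3), c("c3b", "W", 10), c("d2c", "W", 5),
                     c("head", "b", 1), c("n2a", "gamma", 1),
                     c("n5b", "beta", 2))) {
    layer <- probe[1]; field <- probe[2]; idx <- as.integer(probe[3])
    n2 <- net
    n2$params[[layer]][[field]][idx] <- n2$params[[layer]][[field]][idx] + eps
    lp <- loss_at(n2)
    n2$params[[layer]][[field]][idx] <-
      n2$params[[layer]][[field]][idx] - 2 * eps
    lm <- loss_at(n2)
    expect_equal(grads[[layer]][[field]][idx], (lp - lm) / (2 * eps),
                 tolerance = 1e-4)
  }
})
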