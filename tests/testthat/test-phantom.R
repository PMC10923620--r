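test_that("identical (spec, seed) yields bit-identical phantoms", {
  sp <- tiny_phantom_spec(seed = 7, deformation_amplitude = 1)
  a <- generate_phantom(sp)
  b <- generate_phantom(sp)
  expect_identical(a$phase1, b$phase1)
  expect_identical(a$phase2, b$phase2)
  expect_identical(a$gt_mask, b$gt_mask)
  expect_identical(a$true_deformation, b$true_deformation)
})

test_that("no-lesion spec gives empty mask and degenerate ROI", {
  cs <- generate_phantom(tiny_phantom_spec(n_lesions = 0))
  expect_true(all(cs$gt_mask == 0))
  expect_true(cs$true_roi$empty)
})

test_that("zero deformation amplitude leaves phase 2 aligned", {
  cs <- generate_phantom(tiny_phantom_spec(seed = 3, noise_sigma = 0))
  expect_identical(cs$phase2, cs$phase2_aligned)
  expect_true(all(cs$true_deformation == 0))
})

test_that("phantom invariants hold across seeds", {
  for (seed in 1:5) {
    cs <- generate_phantom(tiny_phantom_spec(seed = seed))
    expect_true(all(cs$phase1 >= 0 & cs$phase1 <= 1))
    expect_true(all(cs$phase2 >= 0 & cs$phase2 <= 1))
    expect_gt(sum(cs$gt_mask), 0)
    expect_true(all(cs$liver_mask[cs$gt_mask > 0] == 1))
    bb <- dfnseg:::mask_bbox(cs$gt_mask)
    r <- cs$true_roi
    expect_true(r$x[1] <= bb$x[1] && r$x[2] >= bb$x[2] &&
                  r$y[1] <= bb$y[1] && r$y[2] >= bb$y[2] &&
                  r$z[1] <= bb$z[1] && r$z[2] >= bb$z[2])
  }
})

test_that("lesion-to-liver contrast matches the configured offset", {
  for (seed in c(2, 9)) {
    sp <- tiny_phantom_spec(seed = seed, contrast_phase1 = -0.35,
                            contrast_phase2 = -0.18)
    cs <- generate_phantom(sp)
    gt <- cs$gt_mask > 0
    ring <- dfnseg:::dilate6(gt, 3) & !dfnseg:::dilate6(gt, 1) &
      cs$liver_mask > 0
    expect_lt(abs(mean(cs$phase1[gt]) - mean(cs$phase1[ring]) + 0.35), 0.05)
    expect_lt(abs(mean(cs$phase2_aligned[gt]) - mean(cs$phase2_aligned[ring]) +
                    0.18), 0.05)
  }
})

test_that("organ mimic is phase-1 indistinguishable but phase-2 separable", {
  cs <- generate_phantom(tiny_phantom_spec(seed = 4,
                                           confounder_mode = "organ_mimic"))
  gt <- cs$gt_mask > 0; mm <- cs$mimic_mask > 0
  expect_gt(sum(mm), 0)
  expect_false(any(gt & mm))
  # phase 1: overlapping intensity distributions by construction
  expect_lt(abs(mean(cs$phase1[gt]) - mean(cs$phase1[mm])), 0.05)
  # phase 2: mimic looks like normal liver, lesion does not
  liver_only <- cs$liver_mask > 0 & !gt & !mm
  expect_lt(abs(mean(cs$phase2_aligned[mm]) -
                  mean(cs$phase2_aligned[liver_only])), 0.05)
  expect_gt(abs(mean(cs$phase2_aligned[gt]) -
                  mean(cs$phase2_aligned[mm])), 0.10)
})

test_that("unclear-boundary mode reduces the lesion border gradient", {
  grad_at_border <- function(cs) {
    g <- cs$phase1
    d <- dim(g)
    gx <- abs(g[-1, , ] - g[-d[1], , ])
    border <- (dfnseg:::dilate6(cs$gt_mask > 0, 1) &
                 !(cs$gt_mask > 0))[-1, , ]
    mean(gx[border])
  }
  sharp <- generate_phantom(phantom_spec(seed = 5, noise_sigma = 0))
  blurred <- generate_phantom(phantom_spec(
    seed = 5, noise_sigma = 0, confounder_mode = "unclear_boundary"))
  expect_lt(grad_at_border(blurred), 0.5 * grad_at_border(sharp))
})

test_that("generate_dataset derives distinct per-case seeds deterministically", {
  sp <- tiny_phantom_spec()
  expect_error(generate_dataset(sp, 0, seed = 1), "n_cases")
  d1 <- generate_dataset(sp, 3, seed = 0)
  d2 <- generate_dataset(sp, 3, seed = 0)
  expect_equal(nrow(d1$manifest), 3)
  expect_equal(length(unique(d1$manifest$seed)), 3)
  expect_identical(d1$manifest, d2$manifest)
  expect_identical(d1$cases[[2]]$phase1, d2$cases[[2]]$phase1)
})

test_that("invalid phantom specs are rejected", {
  expect_error(phantom_spec(lesion_radius_range = c(30, 40)), "fit inside")
  expect_error(phantom_spec(lesion_radius_range = c(5, 3)), "min, max")
  expect_error(phantom_spec(n_lesions = -1), "n_lesions")
})
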