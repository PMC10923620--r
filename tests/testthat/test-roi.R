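test_that("box construction takes per-axis interval unions", {
  # consistent rectangles reproduce their common ranges exactly
  b <- box_from_rectangles(planar_rectangle("xy", c(10, 20), c(5, 15)),
                           planar_rectangle("xz", c(10, 20), c(2, 6)),
                           planar_rectangle("yz", c(5, 15), c(2, 6)),
                           margin = 0, bounds = c(64, 64, 16))
  expect_equal(b$x, c(10, 20)); expect_equal(b$y, c(5, 15))
  expect_equal(b$z, c(2, 6))
  # disagreeing x constraints: the union [10, 24)
  b2 <- box_from_rectangles(planar_rectangle("xy", c(10, 20), c(5, 15)),
                            planar_rectangle("xz", c(12, 24), c(2, 6)),
                            planar_rectangle("yz", c(5, 15), c(2, 6)),
                            margin = 0, bounds = c(64, 64, 16))
  expect_equal(b2$x, c(10, 24))
  # brute-force oracle on a small grid: every voxel satisfying all three
  # rectangles' constraints lies inside the box
  inside_rects <- function(v) {
    v[1] >= 10 && v[1] < 24 && v[2] >= 5 && v[2] < 15 && v[3] >= 2 && v[3] < 6
  }
  grid <- expand.grid(x = 0:30, y = 0:30, z = 0:10)
  sel <- apply(grid, 1, inside_rects)
  inbox <- grid$x >= b2$x[1] & grid$x < b2$x[2] &
    grid$y >= b2$y[1] & grid$y < b2$y[2] &
    grid$z >= b2$z[1] & grid$z < b2$z[2]
  expect_true(all(inbox[sel]))
  expect_error(box_from_rectangles(planar_rectangle("xy", c(1, 2), c(1, 2)),
                                   planar_rectangle("xy", c(1, 2), c(1, 2)),
                                   planar_rectangle("yz", c(1, 2), c(1, 2)),
                                   0, c(8, 8, 8)),
               "planes")
})

test_that("enlarging a rectangle never shrinks the box", {
  base <- list(planar_rectangle("xy", c(10, 20), c(5, 15)),
               planar_rectangle("xz", c(10, 20), c(2, 6)),
               planar_rectangle("yz", c(5, 15), c(2, 6)))
  b0 <- box_from_rectangles(base[[1]], base[[2]], base[[3]], 0, c(64, 64, 16))
  bigger <- planar_rectangle("xy", c(8, 22), c(3, 17))
  b1 <- box_from_rectangles(bigger, base[[2]], base[[3]], 0, c(64, 64, 16))
  expect_lte(b1$x[1], b0$x[1]); expect_gte(b1$x[2], b0$x[2])
  expect_lte(b1$y[1], b0$y[1]); expect_gte(b1$y[2], b0$y[2])
})

test_that("jittered ground-truth rectangles still contain every lesion voxel", {
  for (seed in 1:10) {
    cs <- generate_phantom(tiny_phantom_spec(seed = seed))
    bb <- cs$true_roi
    jit <- function(r, lo, hi, s) {
      j <- dfnseg:::with_seed(s, sample(-2:2, 2, replace = TRUE))
      # rough manual rectangles never cut into the lesion: clamp to the box
      c(min(r[1] + j[1], r[1]), max(r[2] + j[2], r[2]))
    }
    rxy <- planar_rectangle("xy", jit(bb$x, s = seed), jit(bb$y, s = seed + 1))
    rxz <- planar_rectangle("xz", jit(bb$x, s = seed + 2), jit(bb$z, s = seed + 3))
    ryz <- planar_rectangle("yz", jit(bb$y, s = seed + 4), jit(bb$z, s = seed + 5))
    box <- box_from_rectangles(rxy, rxz, ryz, margin = 2, bounds = dim(cs$gt_mask))
    idx <- which(cs$gt_mask > 0, arr.ind = TRUE) - 1
    expect_true(all(idx[, 1] >= box$x[1] & idx[, 1] < box$x[2] &
                      idx[, 2] >= box$y[1] & idx[, 2] < box$y[2] &
                      idx[, 3] >= box$z[1] & idx[, 3] < box$z[2]))
  }
})

test_that("crop and paste are exact inverses over the box", {
  cs <- generate_phantom(tiny_phantom_spec(seed = 3))
  d <- dim(cs$phase1)
  full <- dfnseg:::full_box(d)
  expect_identical(crop_to_roi(cs$phase1, full), cs$phase1)
  box <- roi_box(c(4, 20), c(6, 22), c(1, 6))
  blk <- crop_to_roi(cs$phase1, box)
  expect_equal(dim(blk), c(16, 16, 5))
  back <- paste_from_roi(blk, box, d)
  expect_identical(back[5:20, 7:22, 2:6], blk)
  expect_true(all(back[1:4, , ] == 0))
  # cropping the mask by its own bounding box preserves foreground count
  bb <- dfnseg:::mask_bbox(cs$gt_mask)
  expect_equal(sum(crop_to_roi(cs$gt_mask, bb)), sum(cs$gt_mask))
  expect_error(crop_to_roi(cs$phase1, roi_box(c(0, 100), c(0, 4), c(0, 4))),
               "bounds")
})

test_that("roi_from_mask degenerates to the tight bounding box", {
  cs <- generate_phantom(tiny_phantom_spec(seed = 5))
  b <- roi_from_mask(cs$gt_mask, jitter = 0, margin = 0)
  expect_identical(unclass(b), unclass(dfnseg:::mask_bbox(cs$gt_mask)))
  bj <- roi_from_mask(cs$gt_mask, jitter = 2, margin = 2, seed = 9)
  expect_identical(bj, roi_from_mask(cs$gt_mask, jitter = 2, margin = 2,
                                     seed = 9))
  expect_true(roi_from_mask(array(0L, c(4, 4, 4)))$empty)
})

test_that("ROI-constrained predictions stay inside the box", {
  cs <- generate_phantom(tiny_phantom_spec(seed = 6))
  dfn <- build_dfn(fusion_config(), dcnn_config(16, base_channels = 2), 2)
  box <- roi_from_mask(cs$gt_mask, jitter = 1, margin = 2, seed = 3)
  icfg <- infer_config(16)
  pred <- segment_roi(dfn, cs, box, icfg)
  idx <- which(pred > 0, arr.ind = TRUE) - 1
  if (nrow(idx) > 0)
    expect_true(all(idx[, 1] >= box$x[1] & idx[, 1] < box$x[2] &
                      idx[, 2] >= box$y[1] & idx[, 2] < box$y[2] &
                      idx[, 3] >= box$z[1] & idx[, 3] < box$z[2]))
  expect_error(segment_roi(dfn, cs, roi_box(NULL, NULL, NULL, empty = TRUE),
                           icfg), "degenerate")
})

test_that("a full-volume box reduces ROI inference to full-size inference", {
  cs <- generate_phantom(tiny_phantom_spec(seed = 7))
  dfn <- build_dfn(fusion_config(), dcnn_config(16, base_channels = 2), 4)
  icfg <- infer_config(16)
  expect_identical(segment_roi(dfn, cs, dfnseg:::full_box(dim(cs$phase1)),
                               icfg),
                   segment_case(dfn, cs, icfg))
})

test_that("ROI JSON round trips with its coordinate convention", {
  td <- withr::local_tempdir()
  b <- roi_box(c(3, 10), c(4, 12), c(0, 5))
  p <- file.path(td, "roi.json")
  save_roi(b, p)
  expect_identical(load_roi(p)$x, b$x)
  expect_identical(load_roi(p)$z, b$z)
  bad <- file.path(td, "bad.json")
  jsonlite::write_json(list(convention = "1-based"), bad, auto_unbox = TRUE)
  expect_error(load_roi(bad), "convention")
})
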