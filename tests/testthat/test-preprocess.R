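make_volume <- function(values, contrast = "T1w", dims = NULL, ...) {
  if (is.null(dims)) dims <- c(length(values), 1, 1)
  contrast_volume(array(values, dims), contrast = contrast, ...)
}

test_that("cohort normalization maps pooled percentiles to the endpoints", {
  v <- make_volume(0:100)
  out <- normalize_cohort(list(v))[[1]]$voxels
  # p1 of 0..100 is 1 -> 0; p99 is 99 -> 255; extremes clip
  expect_equal(out[2, 1, 1], 0)
  expect_equal(out[100, 1, 1], 255)
  expect_equal(out[1, 1, 1], 0)    # value 0 < p1, clipped
  expect_equal(out[101, 1, 1], 255) # value 100 > p99, clipped
})

test_that("volumes of one contrast share a single map; pooled p99 lands on 255", {
  set.seed(5)
  a <- make_volume(stats::runif(500, 0, 80))
  b <- make_volume(stats::runif(500, 20, 300))
  out <- normalize_cohort(list(a, b))
  # identical coefficients: transform of a's voxels using b's fitted map
  pooled_in <- c(a$voxels, b$voxels)
  q <- unname(stats::quantile(pooled_in, c(0.01, 0.99)))
  expected_a <- pmin(pmax((a$voxels - q[1]) / (q[2] - q[1]) * 255, 0), 255)
  expect_equal(out[[1]]$voxels, expected_a)
  # independent percentile routine on the transformed pooled voxels
  pooled_out <- c(out[[1]]$voxels, out[[2]]$voxels)
  # hand-rolled linear-interpolation order statistic (matches the mapping's
  # percentile definition without calling quantile())
  srt <- sort(pooled_out)
  h <- (length(srt) - 1) * 0.99
  p99 <- srt[floor(h) + 1] + (h - floor(h)) * (srt[floor(h) + 2] - srt[floor(h) + 1])
  # clipping pulls the interpolated statistic below 255 by at most the gap
  # between adjacent order statistics at the clip point
  expect_equal(p99, 255, tolerance = 1e-4)
})

test_that("normalization is monotone within contrast and rejects constants", {
  set.seed(6)
  v <- make_volume(stats::runif(300, 0, 10))
  out <- normalize_cohort(list(v))[[1]]$voxels
  expect_true(all(diff(out[order(v$voxels)]) >= 0))
  expect_error(normalize_cohort(list(make_volume(rep(7, 50), "UTE"))),
               "UTE")
})

test_that("fusion stacks channels in T1w/T2w/UTE order without resampling", {
  d <- c(4, 5, 3)
  red <- contrast_volume(array(255, d), contrast = "T1w")
  zero_g <- contrast_volume(array(0, d), contrast = "T2w")
  zero_b <- contrast_volume(array(0, d), contrast = "UTE")
  fused <- fuse_contrasts(red, zero_g, zero_b)
  expect_true(all(fused[, , , 1] == 255) && all(fused[, , , 2:3] == 0))
  blue <- fuse_contrasts(zero_g2 <- contrast_volume(array(0, d), contrast = "T1w"),
                         contrast_volume(array(0, d), contrast = "T2w"),
                         contrast_volume(array(255, d), contrast = "UTE"))
  expect_true(all(blue[, , , 3] == 255) && all(blue[, , , 1:2] == 0))
  expect_error(fuse_contrasts(red, zero_g,
                              contrast_volume(array(0, c(4, 5, 2)),
                                              contrast = "UTE")),
               "4 x 5 x 2")
})

test_that("splitting a phantom into contrasts and fusing round-trips exactly", {
  st <- generate_phantom(phantom_spec(5, class_sequence = c(1, 2, 3, 4, 2),
                                      seed = 31))
  vol <- stack_to_volume(st)
  chans <- lapply(1:3, function(ch)
    contrast_volume(array(vol[, , , ch], dim(vol)[1:3]),
                    contrast = c("T1w", "T2w", "UTE")[ch]))
  refused <- fuse_contrasts(chans[[1]], chans[[2]], chans[[3]])
  expect_equal(unclass(refused), unclass(vol), ignore_attr = TRUE)
})

test_that("axial reslicing follows the ROI bounding range", {
  vol <- new_pv_test_volume <- local({
    v <- array(100, c(6, 6, 30, 3))
    plaquevae:::new_pseudo_color_volume(v)
  })
  m <- array(FALSE, c(6, 6, 30))
  m[3, 3, 11:20] <- TRUE
  stack <- extract_axial_mpr(vol, roi_mask(m, "l1"))
  expect_length(stack$slices, 10L)
  expect_identical(stack$meta$axial_indices, 11:20)
  # single-voxel ROI: one slice with exactly one non-black pixel
  m1 <- array(FALSE, c(6, 6, 30)); m1[2, 5, 7] <- TRUE
  one <- extract_axial_mpr(vol, roi_mask(m1, "l2"))
  expect_length(one$slices, 1L)
  nonblack <- apply(one$slices[[1]], c(1, 2), function(px) any(px != 0))
  expect_identical(sum(nonblack), 1L)
  expect_error(extract_axial_mpr(vol, roi_mask(array(c(TRUE, rep(FALSE, 7)),
                                                     c(2, 2, 2)))),
               "shape")
})

test_that("reslicing a stacked phantom volume recovers the original slices", {
  st <- generate_phantom(phantom_spec(4, class_sequence = c(1, 2, 3, 4),
                                      seed = 17))
  vol <- stack_to_volume(st)
  roi <- roi_mask(array(TRUE, dim(vol)[1:3]), "phantom")
  back <- extract_axial_mpr(vol, roi)
  expect_length(back$slices, 4L)
  for (i in 1:4) expect_equal(back$slices[[i]], st$slices[[i]])
})

test_that("autocrop returns the minimal bounding box and is idempotent", {
  img <- array(0, c(10, 10, 3))
  img[3, 7, 1] <- 200
  expect_identical(dim(autocrop(img)), c(1L, 1L, 3L))
  img2 <- array(0, c(10, 10, 3))
  img2[2:5, 1:8, 2] <- 50
  cropped <- autocrop(img2)
  expect_identical(dim(cropped), c(4L, 8L, 3L))
  expect_identical(autocrop(cropped), cropped)
  expect_error(autocrop(array(0, c(5, 5, 3))), "background")
})

test_that("resizing is identity at target size and preserves uniform colors", {
  img <- random_image(64)
  expect_identical(resize_to_standard(img, 64), img)
  uni <- array(rep(c(10, 200, 30), each = 128 * 128), c(128, 128, 3))
  down <- resize_to_standard(uni, 64)
  expect_identical(dim(down), c(64L, 64L, 3L))
  expect_equal(unique(as.vector(down[, , 2])), 200)
  # mean preservation on a checkerboard, within 1 intensity unit
  board <- array(0, c(128, 128, 3))
  board[, , 1] <- 255 * ((row(board[, , 1]) + col(board[, , 1])) %% 2)
  down2 <- resize_to_standard(board, 64)
  for (ch in 1:3) {
    m_in <- sum(board[, , ch]) / (128 * 128)
    m_out <- sum(down2[, , ch]) / (64 * 64)
    expect_lt(abs(m_in - m_out), 1)
  }
})

test_that("hex-range removal hits exactly the packed-value interval", {
  img <- array(0, c(2, 2, 3))
  img[1, 1, ] <- c(0x80, 0x00, 0x00)  # v = 0x800000, lower endpoint
  img[1, 2, ] <- c(0x7f, 0xff, 0xff)  # v = 0x7fffff, just below
  img[2, 1, ] <- c(0xff, 0x00, 0x00)  # v = 0xff0000, upper endpoint
  img[2, 2, ] <- c(0xff, 0x00, 0x01)  # v = 0xff0001, just above
  out <- remove_hex_range(img)
  expect_equal(out[1, 1, ], c(0, 0, 0))
  expect_equal(out[2, 1, ], c(0, 0, 0))
  expect_equal(out[1, 2, ], img[1, 2, ])
  expect_equal(out[2, 2, ], img[2, 2, ])
  expect_error(remove_hex_range(img, lo = 10, hi = 2), "lo")
})

test_that("hex-range removal agrees with a brute-force scan and is idempotent", {
  withr::local_seed(8)
  for (rep in 1:5) {
    img <- random_image(32)
    filtered <- remove_hex_range(img)
    expect_equal(filtered, brute_force_hex_filter(img, 0x800000, 0xff0000))
    expect_identical(remove_hex_range(filtered), filtered)
    # removal never introduces non-black colors: changed pixels are black
    changed <- which(apply(img != filtered, c(1, 2), any), arr.ind = TRUE)
    if (nrow(changed) > 0)
      expect_true(all(filtered[cbind(changed[, 1], changed[, 2], 1)] == 0 &
                      filtered[cbind(changed[, 1], changed[, 2], 2)] == 0 &
                      filtered[cbind(changed[, 1], changed[, 2], 3)] == 0))
  }
})

test_that("the full chain preserves slice count and dominant lumen color", {
  classes <- c(1, 2, 3, 4, 3, 2)
  st <- generate_phantom(phantom_spec(length(classes),
                                      class_sequence = classes, seed = 77))
  vol <- stack_to_volume(st)
  roi <- roi_mask(array(TRUE, dim(vol)[1:3]), "chain")
  processed <- preprocess_lesion(vol, roi)
  expect_length(processed$slices, length(classes))
  # pixel-majority oracle: dominant occluding color class is unchanged
  dominant <- function(img) {
    px <- matrix(img, ncol = 3)
    px <- px[rowSums(px) > 0, , drop = FALSE]  # ignore background
    counts <- c(green = sum(px[, 2] > px[, 1] & px[, 2] > px[, 3]),
                bright_blue = sum(px[, 3] > 180 & px[, 3] > px[, 2]),
                dark_blue = sum(px[, 3] <= 180 & px[, 3] > px[, 1] &
                                px[, 3] > px[, 2]))
    names(which.max(counts))
  }
  expected <- c(`1` = "green", `2` = "green", `3` = "bright_blue",
                `4` = "dark_blue")
  for (i in seq_along(classes)) {
    if (classes[i] == 2) next  # partial infill: green vs blue is a toss-up
    expect_identical(dominant(processed$slices[[i]]),
                     unname(expected[as.character(classes[i])]),
                     label = sprintf("slice %d (class %d)", i, classes[i]))
  }
})
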