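test_that("preprocess_channel identity and degenerate cases", {
  vx <- voxel_size(0.144, 0.144, 0.988)
  const <- array(40, c(6, 8, 8))
  expect_identical(preprocess_channel(const, vx), const)
  withr::with_seed(2, {
    img <- array(sample(0:255, 6 * 8 * 8, replace = TRUE), c(6, 8, 8))
    expect_identical(
      preprocess_channel(img, vx, contact_params(gaussian_sigma = 0,
                                                 saturation = 0)),
      img)
  })
})

test_that("contrast stretch saturates about the requested voxel fraction", {
  vx <- voxel_size(1, 1, 1)
  withr::with_seed(8, {
    img <- array(round(rnorm(40 * 40 * 40, 128, 10)), c(40, 40, 40))
    img[sample(length(img), 640)] <- sample(c(0, 255), 640, TRUE)  # 1% outliers
    out <- preprocess_channel(img, vx, contact_params(gaussian_sigma = 0,
                                                      saturation = 0.7))
    n_sat <- sum(out == 0) + sum(out == 255)
    # <= 0.7% plus one quantile step of voxels pinned at the range limits
    expect_lte(n_sat, 0.007 * length(img) + 2 * 640)
    expect_gt(n_sat, 0)
  })
})

test_that("crosstalk subtraction is a clamped voxelwise difference", {
  a <- array(runif(64, 0, 100), c(4, 4, 4))
  expect_equal(subtract_crosstalk(a, a), array(0, c(4, 4, 4)))
  z <- array(0, c(4, 4, 4))
  expect_equal(subtract_crosstalk(a, z), a)
  expect_true(all(subtract_crosstalk(z, a) == 0))
  expect_error(subtract_crosstalk(a, array(0, c(4, 4, 5))))
})

test_that("contact_ratio matches voxel enumeration", {
  d <- c(12, 12, 12)
  vessel <- array(FALSE, d)
  vessel[2:11, 2:11, 2:11] <- TRUE              # 1000-voxel cube
  glia <- array(FALSE, d)
  glia[2:4, 2:11, 2:11] <- TRUE                 # 3 x 10 x 10 slab of it
  res <- contact_ratio(glia, vessel)
  expect_equal(res$contact_ratio_percent, 30)
  expect_equal(res$overlap_voxels, 300L)
  expect_equal(res$vessel_voxels, 1000L)

  expect_equal(contact_ratio(vessel, vessel)$contact_ratio_percent, 100)
  far <- array(FALSE, d)
  far[1, 1, 1] <- TRUE
  expect_equal(contact_ratio(far, vessel)$contact_ratio_percent, 0)
  expect_error(contact_ratio(glia, array(FALSE, d)),
               class = "gliavasc_undefined_ratio")
})

test_that("contact_ratio is bounded and monotone under glia dilation", {
  for (seed in 1:3) {
    glia <- random_blob_mask(c(12, 16, 16), frac = 0.2, sigma = 1.5,
                             seed = seed)
    vessel <- random_blob_mask(c(12, 16, 16), frac = 0.3, sigma = 1.5,
                               seed = seed + 50)
    if (!any(vessel)) next
    r <- contact_ratio(glia, vessel)
    expect_gte(r$contact_ratio_percent, 0)
    expect_lte(r$contact_ratio_percent, 100)
    expect_lte(r$overlap_voxels, min(r$glia_voxels, r$vessel_voxels))
    dil <- array(gliavasc:::dilate_box_cpp(glia, dim(glia), c(1L, 1L, 1L)),
                 dim(glia))
    expect_gte(contact_ratio(dil, vessel)$contact_ratio_percent,
               r$contact_ratio_percent)
  }
})

test_that("the contact pipeline handles an empty glial channel", {
  p <- synth_params(shape = c(32, 64, 64), n_cells = 0, coverage_fraction = 0,
                    crosstalk = 0, noise_sd = 0, seed = 1)
  s <- suppressMessages(generate_stack(p))
  # glia channel is pure background here
  q <- suppressMessages(suppressWarnings(quantify_contact(s$stack)))
  expect_equal(tidy(q)$contact_ratio_percent, 0)
})

test_that("crosstalk subtraction suppresses bleed-induced false contact", {
  p <- synth_params(shape = c(48, 128, 128), n_cells = 0,
                    coverage_fraction = 0, crosstalk = 0.3, seed = 6)
  s <- suppressMessages(generate_stack(p))
  with_sub <- suppressMessages(tidy(quantify_contact(s$stack)))
  without <- suppressMessages(tidy(quantify_contact(
    s$stack, contact_params(crosstalk = "none"))))
  expect_lt(with_sub$contact_ratio_percent, 5)
  expect_gt(without$contact_ratio_percent, 50)
})

test_that("subtraction timing is configurable and masks are exportable", {
  p <- synth_params(shape = c(32, 64, 64), n_cells = 0,
                    coverage_fraction = 0.1, seed = 4)
  s <- suppressMessages(generate_stack(p))
  q <- suppressMessages(quantify_contact(
    s$stack, contact_params(crosstalk = "after"), keep_masks = TRUE))
  expect_named(q$masks, c("glia", "vessel"))
  expect_identical(dim(q$masks$vessel), dim(s$truth$vessel_mask))
})
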