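test_that("extract_surface matches enumeration", {
  d <- c(14, 14, 14)
  cube <- array(FALSE, d)
  cube[3:12, 3:12, 3:12] <- TRUE
  surf <- extract_surface(cube)
  expect_equal(sum(surf), 1000 - 8^3)           # 488 boundary voxels
  expect_true(all(cube[surf]))

  single <- array(FALSE, c(3, 3, 3))
  single[2, 2, 2] <- TRUE
  expect_identical(extract_surface(single), single)

  empty <- array(FALSE, c(3, 3, 3))
  expect_identical(extract_surface(empty), empty)

  # voxels on the image border are surface
  full <- array(TRUE, c(4, 4, 4))
  sf <- extract_surface(full)
  expect_equal(sum(sf), 64 - 8)
})

test_that("surface contact percentage matches the slab fixture", {
  d <- c(16, 16, 16)
  vx <- voxel_size(1, 1, 1)
  cube <- array(FALSE, d)
  cube[4:13, 4:13, 4:13] <- TRUE
  # 10 x 10 x 1 slab flush against one cube face
  slab <- array(FALSE, d)
  slab[4:13, 4:13, 3] <- TRUE
  res <- surface_contact_percent(cube, slab, vx, contact_distance = 1)
  expect_equal(res$vessel_surface_voxels, 488L)
  expect_equal(res$contact_surface_voxels, 100L)
  expect_equal(res$contact_percent, 100 * 100 / 488, tolerance = 1e-12)
  expect_equal(res$aqp4_volume_um3, 100)

  # empty AQP4 -> 0%; AQP4 covering the dilated cube -> 100%
  expect_equal(surface_contact_percent(cube, array(FALSE, d),
                                       vx)$contact_percent, 0)
  dil <- array(gliavasc:::dilate_box_cpp(cube, d, c(1L, 1L, 1L)), d)
  expect_equal(surface_contact_percent(cube, dil & !cube, vx)$contact_percent,
               100)
  expect_error(surface_contact_percent(array(FALSE, d), slab, vx),
               class = "gliavasc_undefined_ratio")
})

test_that("surface contact is monotone in contact distance and shift-invariant", {
  withr::with_seed(17, {
    vessel <- random_blob_mask(c(14, 18, 18), frac = 0.25, sigma = 2, seed = 3)
    aqp4 <- random_blob_mask(c(14, 18, 18), frac = 0.08, sigma = 1.5, seed = 9)
    vx <- voxel_size(0.3, 0.3, 1)
    pcts <- vapply(0:3, function(r) {
      surface_contact_percent(vessel, aqp4, vx, r)$contact_percent
    }, numeric(1))
    expect_true(all(diff(pcts) >= 0))

    # joint translation leaves the percentage unchanged (away from borders)
    shift1 <- gliavasc:::shift_mask
    v2 <- shift1(shift1(vessel, 2, 1), 3, 1)
    a2 <- shift1(shift1(aqp4, 2, 1), 3, 1)
    inner <- function(m) m[, 2:18, 2:18]
    if (sum(vessel) == sum(v2)) {               # nothing clipped
      expect_equal(surface_contact_percent(v2, a2, vx, 1)$contact_percent,
                   surface_contact_percent(vessel, aqp4, vx, 1)$contact_percent)
    }
  })
})

test_that("aqp4 volume is linear in the voxel volume", {
  d <- c(6, 6, 6)
  vessel <- array(FALSE, d)
  vessel[3, 3, 3] <- TRUE
  aqp4 <- array(FALSE, d)
  aqp4[2, 2, 2] <- TRUE
  aqp4[4, 4, 4] <- TRUE
  r1 <- surface_contact_percent(vessel, aqp4, voxel_size(1, 1, 1))
  r2 <- surface_contact_percent(vessel, aqp4, voxel_size(2, 1, 1))
  expect_equal(r1$aqp4_volume_um3, 2)
  expect_equal(r2$aqp4_volume_um3, 4)
})

test_that("the AQP4 pipeline recovers shell coverage and rejects no-signal", {
  p <- synth_params(shape = c(48, 128, 128), n_cells = 0, coverage_fraction = 0,
                    aqp4_surface_fraction = 0.3, crosstalk = 0,
                    noise_sd = 127, seed = 2)
  s <- suppressMessages(generate_stack(p))
  q <- suppressMessages(quantify_aqp4(s$stack))
  truth <- s$truth$true_surface_contact_percent
  expect_lt(abs(tidy(q)$contact_percent - truth) / truth, 0.25)

  # AQP4 channel with no signal above threshold: zero contact via the
  # degenerate-segmentation path
  p0 <- synth_params(shape = c(32, 64, 64), n_cells = 0, coverage_fraction = 0,
                     aqp4_surface_fraction = 0, crosstalk = 0,
                     noise_sd = 127, seed = 3)
  s0 <- suppressMessages(generate_stack(p0))
  stack0 <- calibrated_stack(
    list(vessel = get_channel(s0$stack, "vessel"),
         aqp4 = array(1200, p0$shape)),
    voxel = s0$stack$voxel, roles = c("vessel", "aqp4"), bit_depth = 16)
  q0 <- suppressMessages(suppressWarnings(quantify_aqp4(stack0)))
  expect_equal(tidy(q0)$contact_percent, 0)
})
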