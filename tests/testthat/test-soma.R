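test_that("segment_soma_mask recovers noise-free objects exactly", {
  d <- c(16, 24, 24)
  truth <- make_ball(d, c(8, 8, 8), 5) | make_ball(d, c(8, 17, 17), 4)
  img <- array(10, d)
  img[truth] <- 200
  expect_identical(segment_soma_mask(img, "renyi"), truth)
  # on a two-level image every method agrees
  expect_identical(segment_soma_mask(img, "otsu"), truth)
  expect_error(segment_soma_mask(array(5, d)),
               class = "gliavasc_degenerate_histogram")
})

test_that("a pure-noise stack does not segment most of the volume", {
  withr::with_seed(13, {
    img <- array(pmax(0, round(rnorm(16 * 24 * 24, 20, 5))), c(16, 24, 24))
    mask <- segment_soma_mask(img, "renyi")
    expect_lt(mean(mask), 0.5)
  })
})

test_that("measure_objects reports volume, intensity, flatness, centroid", {
  vx <- voxel_size(0.144, 0.144, 0.988)
  lab <- array(0L, c(3, 3, 3))
  lab[2, 2, 2] <- 1L
  inten <- array(7, c(3, 3, 3))
  tab <- measure_objects(lab, inten, vx)
  expect_tibble(tab)
  expect_equal(tab$volume_um3, voxel_volume(vx), tolerance = 1e-12)
  expect_equal(tab$mean_intensity, 7)
  expect_equal(tab$flatness, 1, tolerance = 1e-6)

  # digital ball: flatness ~1, volume within 10% of (4/3) pi r^3
  d <- c(16, 16, 16)
  ball <- make_ball(d, c(8, 8, 8), 6)
  labb <- array(0L, d)
  labb[ball] <- 1L
  tb <- measure_objects(labb, array(100, d), voxel_size(1, 1, 1))
  expect_gte(tb$flatness, 1)
  expect_lte(tb$flatness, 1.1)
  expect_lt(abs(tb$volume_um3 - 4 / 3 * pi * 216) / (4 / 3 * pi * 216), 0.1)

  # prolate ellipsoid with semi-axes (12, 4, 1) um rendered at 0.25 um
  # isotropic voxels: flatness R2/R3 ~ 4
  vx25 <- voxel_size(0.25, 0.25, 0.25)
  semi_px <- c(1, 4, 12) / 0.25                 # (z, y, x) semi-axes in px
  d2 <- c(11, 35, 99)
  ctr <- (d2 + 1) / 2
  zz <- ((seq_len(d2[1]) - ctr[1]) / semi_px[1])^2
  yy <- ((seq_len(d2[2]) - ctr[2]) / semi_px[2])^2
  xx <- ((seq_len(d2[3]) - ctr[3]) / semi_px[3])^2
  ell <- outer(outer(zz, yy, "+"), xx, "+") <= 1
  labe <- array(0L, d2)
  labe[ell] <- 1L
  te <- measure_objects(labe, array(50, d2), vx25)
  expect_lt(abs(te$flatness - 4) / 4, 0.1)
  expect_gt(te$flatness, 3.5)  # above the spurious-object cut
  tr13 <- measure_objects(labe, array(50, d2), vx25,
                          flatness_mode = "R1R3")
  expect_lt(abs(tr13$flatness - 12) / 12, 0.15)

  expect_error(measure_objects(labe, array(0, c(2, 2, 2)), vx25))
  empty <- measure_objects(array(0L, c(2, 2, 2)), array(0, c(2, 2, 2)),
                           voxel_size(1, 1, 1))
  expect_equal(nrow(empty), 0)
})

test_that("filter_objects keeps inclusive boundaries and matches a scan", {
  tab <- tibble::tibble(
    label = 1:4,
    voxel_count = 1L,
    volume_um3 = c(199.9, 200, 500, 500),
    mean_intensity = c(200, 60, 59.9, 100),
    flatness = c(1.2, 3.5, 1.0, 3.51),
    cz = 0, cy = 0, cx = 0
  )
  kept <- filter_objects(tab)
  expect_identical(kept$label, 2L)  # only the all-inclusive-boundary row

  withr::with_seed(31, {
    rnd <- tibble::tibble(
      label = 1:100,
      voxel_count = 1L,
      volume_um3 = runif(100, 0, 1200),
      mean_intensity = runif(100, 0, 255),
      flatness = runif(100, 1, 6),
      cz = 0, cy = 0, cx = 0
    )
    kept2 <- filter_objects(rnd)
    manual <- rnd[rnd$volume_um3 >= 200 & rnd$mean_intensity >= 60 &
                    rnd$flatness <= 3.5, ]
    expect_identical(kept2, manual)
    expect_identical(filter_objects(kept2), kept2)  # idempotent

    # raising min_volume never increases the retained count
    counts <- vapply(c(0, 100, 200, 400, 800), function(v) {
      nrow(filter_objects(rnd, min_volume = v))
    }, numeric(1))
    expect_true(all(diff(counts) <= 0))
  })
})

test_that("mean_soma_volume averages volumes", {
  tab <- tibble::tibble(volume_um3 = c(100, 300))
  expect_equal(mean_soma_volume(tab), 200)
  expect_equal(mean_soma_volume(tab[1, ]), 100)
  expect_error(mean_soma_volume(tab[0, ]), class = "gliavasc_no_objects")
})

test_that("the full soma pipeline recovers mean volumes on small stacks", {
  errs <- c()
  for (seed in 1:3) {
    p <- synth_params(shape = c(48, 160, 160), n_vessels = 0, n_cells = 3,
                      soma_volume_range = c(300, 600), coverage_fraction = 0,
                      noise_sd = 237, seed = seed)
    s <- suppressMessages(suppressWarnings(generate_stack(p)))
    q <- suppressMessages(quantify_soma(s$stack))
    expect_equal(glance(q)$n_objects, length(s$truth$true_soma_volumes))
    errs <- c(errs, glance(q)$mean_volume_um3 /
                mean(s$truth$true_soma_volumes) - 1)
  }
  expect_lt(mean(abs(errs)), 0.1)
})
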