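test_that("histogram_256 bins 8-bit data by identity and conserves counts", {
  withr::with_seed(1, {
    img <- array(sample(0:255, 4000, replace = TRUE), c(10, 20, 20))
    h <- histogram_256(img)
    expect_equal(h$counts, tabulate(img + 1, 256))
    expect_equal(sum(h$counts), length(img))
    expect_equal(c(h$lo, h$hi), c(0, 255))

    img16 <- array(sample(0:65535, 5000, replace = TRUE), c(5, 10, 100))
    h16 <- histogram_256(img16)
    expect_equal(sum(h16$counts), length(img16))

    hc <- histogram_256(array(42, c(2, 2, 2)))
    expect_true(hc$degenerate)
    expect_error(threshold_otsu(hc),
                 class = "gliavasc_degenerate_histogram")
  })
})

test_that("each threshold method equals its exhaustive-search oracle", {
  withr::with_seed(42, {
    for (i in 1:200) {
      h <- random_histogram()
      expect_identical(threshold_otsu(h)$bin, oracle_otsu(h$counts))
      expect_identical(threshold_max_entropy(h)$bin,
                       oracle_renyi_order(h$counts, 1))
      expect_identical(threshold_default_isodata(h)$bin,
                       oracle_isodata(h$counts))
      # Renyi: per-order argmax plus the published combination rule
      per_order <- vapply(c(0.5, 1, 2), function(rho) {
        oracle_renyi_order(h$counts, rho)
      }, integer(1))
      expect_identical(threshold_renyi(h)$bin,
                       gliavasc:::combine_renyi(per_order, h$counts))
    }
  })
})

test_that("Renyi with orders (1,1,1) reduces to the Kapur maximum entropy", {
  withr::with_seed(7, {
    for (i in 1:50) {
      h <- random_histogram()
      expect_identical(threshold_renyi(h, orders = c(1, 1, 1))$bin,
                       threshold_max_entropy(h)$bin)
    }
  })
})

test_that("thresholds are invariant under scaling all counts", {
  withr::with_seed(3, {
    for (i in 1:25) {
      h <- random_histogram()
      h7 <- h
      h7$counts <- h$counts * 7L
      for (f in list(threshold_otsu, threshold_max_entropy,
                     threshold_renyi, threshold_default_isodata)) {
        expect_identical(f(h)$bin, f(h7)$bin)
      }
    }
  })
})

test_that("every method lands in the gap of a two-delta histogram", {
  withr::with_seed(9, {
    for (i in 1:25) {
      a <- sample(0:120, 1)
      b <- sample(135:255, 1)
      counts <- integer(256)
      counts[a + 1] <- sample(50:500, 1)
      counts[b + 1] <- sample(50:500, 1)
      h <- structure(list(counts = counts, lo = 0, hi = 255,
                          degenerate = FALSE), class = "histogram256")
      for (f in list(threshold_otsu, threshold_max_entropy,
                     threshold_renyi, threshold_default_isodata)) {
        t <- f(h)$bin
        expect_gte(t, a)
        expect_lt(t, b)
      }
      # Otsu's criterion is flat across the gap; ties break to smallest
      if (counts[a + 1] == counts[b + 1]) {
        expect_identical(threshold_otsu(h)$bin, a)
      }
    }
  })
})

test_that("intermeans fixed points match hand-iterated values", {
  two_delta <- function(a, b, na = 100L, nb = 100L) {
    counts <- integer(256)
    counts[a + 1] <- na
    counts[b + 1] <- nb
    structure(list(counts = counts, lo = 0, hi = 255, degenerate = FALSE),
              class = "histogram256")
  }
  # equal masses at 0 and 255: floor((0 + 255) / 2) = 127 is stable
  expect_identical(threshold_default_isodata(two_delta(0, 255))$bin, 127L)
  # masses at 10 and 200: fixed point floor((10 + 200) / 2) = 105
  expect_identical(threshold_default_isodata(two_delta(10, 200))$bin, 105L)
})

test_that("Otsu separates two well-separated Gaussian modes", {
  withr::with_seed(5, {
    v <- c(round(rnorm(5000, 50, 5)), round(rnorm(5000, 180, 10)))
    v <- pmin(pmax(v, 0), 255)
    h <- histogram_256(v)
    t <- threshold_otsu(h)$bin
    expect_identical(t, oracle_otsu(h$counts))
    expect_gt(t, 65)
    expect_lt(t, 165)
  })
})

test_that("binarize uses the strictly-greater foreground convention", {
  img <- array(c(9, 10, 11, 200), c(1, 2, 2))
  h <- histogram_256(img)
  thr <- threshold_otsu(h)
  mask <- binarize(img, thr, h)
  expect_identical(mask, img > thr$level_native)
})
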