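# Independent brute-force oracles and small geometry builders shared by the
# tests. Everything here is deliberately written as plain loops over the
# criterion definitions, independent of the package's implementations.

# exhaustive-search threshold oracles ---------------------------------------

# Ties (which genuinely occur, e.g. symmetric class entropies) break to the
# smallest threshold; a relative tolerance keeps that well-defined under
# floating-point noise.
oracle_argmax <- function(crit) {
  m <- max(crit, na.rm = TRUE)
  tol <- 1e-9 * max(1, abs(m))
  min(which(crit >= m - tol)) - 1L
}

oracle_otsu <- function(counts) {
  p <- counts / sum(counts)
  crit <- rep(-Inf, 255)
  for (t in 0:254) {
    if (!any(counts[1:(t + 1)] > 0) || !any(counts[(t + 2):256] > 0)) next
    w0 <- sum(p[1:(t + 1)])
    w1 <- 1 - w0
    mu0 <- sum((0:t) * p[1:(t + 1)]) / w0
    mu1 <- sum(((t + 1):255) * p[(t + 2):256]) / w1
    crit[t + 1] <- w0 * w1 * (mu0 - mu1)^2
  }
  oracle_argmax(crit)
}

oracle_renyi_order <- function(counts, rho) {
  p <- counts / sum(counts)
  crit <- rep(-Inf, 255)
  for (t in 0:254) {
    if (!any(counts[1:(t + 1)] > 0) || !any(counts[(t + 2):256] > 0)) next
    P0 <- sum(p[1:(t + 1)])
    q0 <- p[1:(t + 1)] / P0
    q1 <- p[(t + 2):256] / (1 - P0)
    q0 <- q0[q0 > 0]
    q1 <- q1[q1 > 0]
    crit[t + 1] <- if (abs(rho - 1) < 1e-12) {
      -sum(q0 * log(q0)) - sum(q1 * log(q1))
    } else {
      (log(sum(q0^rho)) + log(sum(q1^rho))) / (1 - rho)
    }
  }
  oracle_argmax(crit)
}

oracle_isodata <- function(counts) {
  bins <- 0:255
  occupied <- which(counts > 0) - 1L
  t <- min(max(127L, min(occupied)), max(occupied) - 1L)
  repeat {
    sel <- bins <= t
    mu0 <- sum(bins[sel] * counts[sel]) / sum(counts[sel])
    mu1 <- sum(bins[!sel] * counts[!sel]) / sum(counts[!sel])
    t_new <- as.integer(floor((mu0 + mu1) / 2))
    t_new <- min(max(t_new, min(occupied)), max(occupied) - 1L)
    if (t_new == t) return(t)
    t <- t_new
  }
}

random_histogram <- function() {
  counts <- integer(256)
  k <- sample(3:40, 1)
  bins <- sample(0:255, k)
  counts[bins + 1] <- rpois(k, lambda = sample(5:500, 1)) + 1L
  structure(list(counts = counts, lo = 0, hi = 255, degenerate = FALSE),
            class = "histogram256")
}

# direct set-definition morphology oracle ------------------------------------

se_offsets <- function(radii) {
  r <- ceiling(radii)
  off <- expand.grid(oz = -r[3]:r[3], oy = -r[2]:r[2], ox = -r[1]:r[1])
  keep <- (off$ox / radii[1])^2 + (off$oy / radii[2])^2 +
    (off$oz / radii[3])^2 <= 1
  as.matrix(off[keep, c("oz", "oy", "ox")])
}

# Erosion/dilation by explicit structuring-element sweep; out-of-bounds
# treated as inside for erosion (the element may overhang the border).
oracle_opening <- function(mask, radii) {
  d <- dim(mask)
  off <- se_offsets(radii)
  ero <- array(FALSE, d)
  for (i0 in 1:d[1]) for (i1 in 1:d[2]) for (i2 in 1:d[3]) {
    if (!mask[i0, i1, i2]) next
    ok <- TRUE
    for (k in seq_len(nrow(off))) {
      q0 <- i0 + off[k, 1]; q1 <- i1 + off[k, 2]; q2 <- i2 + off[k, 3]
      if (q0 < 1 || q0 > d[1] || q1 < 1 || q1 > d[2] || q2 < 1 || q2 > d[3])
        next
      if (!mask[q0, q1, q2]) { ok <- FALSE; break }
    }
    ero[i0, i1, i2] <- ok
  }
  dil <- array(FALSE, d)
  idx <- which(ero, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    for (k in seq_len(nrow(off))) {
      q0 <- idx[r, 1] + off[k, 1]; q1 <- idx[r, 2] + off[k, 2]
      q2 <- idx[r, 3] + off[k, 3]
      if (q0 >= 1 && q0 <= d[1] && q1 >= 1 && q1 <= d[2] &&
          q2 >= 1 && q2 <= d[3]) {
        dil[q0, q1, q2] <- TRUE
      }
    }
  }
  dil
}

# geometry builders ----------------------------------------------------------

make_ball <- function(dims, center, radius) {
  out <- array(FALSE, dims)
  for (z in 1:dims[1]) for (y in 1:dims[2]) for (x in 1:dims[3]) {
    if ((z - center[1])^2 + (y - center[2])^2 + (x - center[3])^2 <= radius^2)
      out[z, y, x] <- TRUE
  }
  out
}

random_blob_mask <- function(dims, frac = 0.4, sigma = 2, seed = 1) {
  withr::with_seed(seed, {
    noise <- array(rnorm(prod(dims)), dims)
    sm <- array(gliavasc:::gauss3d_cpp(as.numeric(noise), dims,
                                       rep(sigma, 3)), dims)
    sm > quantile(sm, 1 - frac)
  })
}

expect_tibble <- function(x) testthat::expect_s3_class(x, "tbl_df")
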