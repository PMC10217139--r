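#' 256-bin intensity histogram
#'
#' All automatic thresholds in the package operate on a 256-bin histogram,
#' also for 16-bit data (min-max mapped onto the bins), mirroring the
#' behaviour of the macro environment the pipelines replicate. For 8-bit
#' data bin `k` counts pixels of value `k` exactly.
#'
#' @param x A numeric array or vector of integer-valued intensities.
#' @return A `histogram256` object: `counts` (256 integers), `lo`, `hi`
#'   (native range mapped onto the bins) and `degenerate` (constant image).
#' @export
histogram_256 <- function(x) {
  v <- as.numeric(x)
  if (length(v) == 0 || all(is.na(v))) abort("empty image")
  v <- v[!is.na(v)]
  lo <- min(v)
  hi <- max(v)
  if (lo == hi) {
    counts <- integer(256)
    counts[bin_of(lo, lo, hi) + 1L] <- length(v)
    return(structure(list(counts = counts, lo = lo, hi = hi, degenerate = TRUE),
                     class = "histogram256"))
  }
  if (lo >= 0 && hi <= 255 && all(v == floor(v))) {
    lo <- 0; hi <- 255
    counts <- tabulate(v + 1L, nbins = 256L)
  } else {
    counts <- tabulate(bin_of(v, lo, hi) + 1L, nbins = 256L)
  }
  structure(list(counts = counts, lo = lo, hi = hi, degenerate = FALSE),
            class = "histogram256")
}

# Map native intensities onto bins 0..255 for a given range.
bin_of <- function(v, lo, hi) {
  if (lo == hi) return(rep(0L, length(v)))
  if (lo == 0 && hi == 255) {
    return(as.integer(pmin(pmax(floor(v), 0), 255)))
  }
  b <- floor((v - lo) * 256 / (hi - lo + 1))
  as.integer(pmin(pmax(b, 0), 255))
}

# Largest native intensity that maps to bin <= t (the threshold cut point).
native_level <- function(t, lo, hi) {
  if (lo == 0 && hi == 255) return(t)
  ceiling((t + 1) * (hi - lo + 1) / 256) - 1 + lo
}

new_threshold <- function(bin, method, h) {
  structure(list(bin = as.integer(bin), method = method,
                 level_native = native_level(as.integer(bin), h$lo, h$hi)),
            class = "threshold_level")
}

#' @export
print.threshold_level <- function(x, ...) {
  cat(sprintf("<threshold_level> method = %s, bin = %d, native level = %g (foreground > level)\n",
              x$method, x$bin, x$level_native))
  invisible(x)
}

check_histogram <- function(h) {
  if (!inherits(h, "histogram256")) h <- histogram_256(h)
  if (sum(h$counts) == 0) abort("empty histogram")
  if (h$degenerate || sum(h$counts > 0) < 2) {
    abort("degenerate histogram: fewer than two occupied bins",
          class = "gliavasc_degenerate_histogram")
  }
  h
}

#' Otsu threshold
#'
#' Returns the bin `t` maximising the between-class variance
#' `w0(t) * w1(t) * (mu0(t) - mu1(t))^2`, where the background class is
#' `bins <= t` and the foreground class `bins > t`. Ties are broken by the
#' smallest `t`; the foreground convention everywhere in the package is
#' *strictly greater than* the threshold.
#'
#' @param h A [histogram_256()] (or raw intensities, converted internally).
#' @return A `threshold_level`.
#' @export
threshold_otsu <- function(h) {
  h <- check_histogram(h)
  crit <- otsu_criterion(h$counts)
  new_threshold(argmax_bin(crit), "otsu", h)
}

# Smallest bin whose criterion is within a relative tolerance of the
# maximum: mathematically tied splits (which do occur, e.g. for symmetric
# class entropies) must deterministically break to the smaller threshold
# regardless of float rounding.
argmax_bin <- function(crit) {
  m <- max(crit)
  tol <- 1e-9 * max(1, abs(m))
  min(which(crit >= m - tol)) - 1L
}

otsu_criterion <- function(counts) {
  p <- counts / sum(counts)
  bins <- 0:255
  w0 <- cumsum(p)
  m <- cumsum(p * bins)
  mt <- m[256]
  occ <- cumsum(counts > 0)
  crit <- rep(-Inf, 255)
  t <- 1:255
  valid <- occ[t] >= 1 & occ[t] < occ[256]
  mu0 <- m[t] / w0[t]
  mu1 <- (mt - m[t]) / (1 - w0[t])
  v <- w0[t] * (1 - w0[t]) * (mu0 - mu1)^2
  crit[valid] <- v[valid]
  crit  # crit[k] is the criterion for threshold bin t = k - 1
}

#' Kapur maximum-entropy threshold
#'
#' Returns the bin `t` maximising the sum of the Shannon entropies of the
#' normalised background (`bins <= t`) and foreground (`bins > t`) class
#' histograms. Ties are broken by the smallest `t`.
#'
#' @inheritParams threshold_otsu
#' @return A `threshold_level`.
#' @export
threshold_max_entropy <- function(h) {
  h <- check_histogram(h)
  crit <- renyi_criterion(h$counts, 1)
  new_threshold(argmax_bin(crit), "max_entropy", h)
}

# Two-class Renyi entropy criterion for every candidate threshold t = 0..254;
# rho = 1 is the Shannon/Kapur limit. Returns a length-255 vector.
renyi_criterion <- function(counts, rho) {
  p <- counts / sum(counts)
  P <- cumsum(p)
  occ <- cumsum(counts > 0)
  n_occ <- occ[256]
  crit <- rep(-Inf, 255)
  for (t in 1:255) {
    # both classes must actually contain occupied bins; the cumulative
    # probability alone can round to (0, 1) even for an empty class
    if (occ[t] < 1 || occ[t] >= n_occ) next
    P0 <- P[t]
    q0 <- p[1:t] / P0
    q1 <- p[(t + 1):256] / (1 - P0)
    q0 <- q0[q0 > 0]
    q1 <- q1[q1 > 0]
    if (abs(rho - 1) < 1e-12) {
      crit[t] <- -sum(q0 * log(q0)) - sum(q1 * log(q1))
    } else {
      crit[t] <- (log(sum(q0^rho)) + log(sum(q1^rho))) / (1 - rho)
    }
  }
  crit  # crit[k] is the criterion for threshold bin t = k - 1
}

#' Renyi-entropy threshold
#'
#' For each entropic order `rho` the bin maximising the sum of the two-class
#' Renyi entropies is found (with `rho = 1` the Kapur/Shannon limit); the
#' three per-order thresholds are then sorted and combined by the published
#' three-threshold weighting rule: thresholds within 5 bins of each other
#' pool their weight on the middle value, and the final threshold is the
#' cumulative-probability-weighted blend
#' `t1*(P(t1) + w*b1/4) + t2*w*b2/4 + t3*(1 - P(t3) + w*b3/4)` with
#' `w = P(t3) - P(t1)` and `(b1,b2,b3)` the proximity weights.
#' `orders = c(1, 1, 1)` reduces exactly to [threshold_max_entropy()].
#'
#' @inheritParams threshold_otsu
#' @param orders Three positive entropic orders; default `c(0.5, 1, 2)`.
#' @return A `threshold_level`.
#' @export
threshold_renyi <- function(h, orders = c(0.5, 1, 2)) {
  h <- check_histogram(h)
  if (length(orders) != 3 || any(orders <= 0)) {
    abort("`orders` must be three positive entropic orders")
  }
  ts <- vapply(orders, function(rho) {
    argmax_bin(renyi_criterion(h$counts, rho))
  }, integer(1))
  new_threshold(combine_renyi(ts, h$counts), "renyi", h)
}

# Three-threshold combination rule (orders sorted ascending before use).
combine_renyi <- function(ts, counts) {
  ts <- sort(as.integer(ts))
  t1 <- ts[1]; t2 <- ts[2]; t3 <- ts[3]
  p <- counts / sum(counts)
  P <- cumsum(p)
  cp <- function(t) if (t < 0) 0 else P[t + 1]
  if (abs(t1 - t2) <= 5) {
    if (abs(t2 - t3) <= 5) {
      b <- c(1, 2, 1)
    } else {
      b <- c(0, 1, 3)
    }
  } else {
    if (abs(t2 - t3) <= 5) {
      b <- c(3, 1, 0)
    } else {
      b <- c(1, 2, 1)
    }
  }
  w <- cp(t3) - cp(t1)
  t_star <- t1 * (cp(t1) + 0.25 * w * b[1]) +
    0.25 * t2 * w * b[2] +
    t3 * (1 - cp(t3) + 0.25 * w * b[3])
  as.integer(round(t_star))
}

#' IsoData intermeans threshold ("Default")
#'
#' The iterative intermeans rule: starting from the histogram midpoint,
#' repeat `t <- floor((mean of bins <= t + mean of bins > t) / 2)` until the
#' value is stable, and return the fixed point. This is the "Default"
#' automatic threshold of the macro environment the pipelines replicate.
#'
#' @inheritParams threshold_otsu
#' @return A `threshold_level`.
#' @export
threshold_default_isodata <- function(h) {
  h <- check_histogram(h)
  counts <- h$counts
  bins <- 0:255
  occupied <- which(counts > 0) - 1L
  t <- 127L
  t <- min(max(t, min(occupied)), max(occupied) - 1L)
  for (iter in 1:256) {
    below <- counts[bins <= t]
    above <- counts[bins > t]
    mu0 <- sum(bins[bins <= t] * below) / sum(below)
    mu1 <- sum(bins[bins > t] * above) / sum(above)
    if (!is.finite(mu0)) mu0 <- min(occupied)
    if (!is.finite(mu1)) mu1 <- max(occupied)
    t_new <- as.integer(floor((mu0 + mu1) / 2))
    t_new <- min(max(t_new, min(occupied)), max(occupied) - 1L)
    if (t_new == t) {
      return(new_threshold(t, "default", h))
    }
    t <- t_new
  }
  abort("intermeans iteration did not converge within 256 steps")
}

#' Automatic threshold by method name
#'
#' @param x Intensity array (a whole-stack histogram is used).
#' @param method One of `"otsu"`, `"renyi"`, `"max_entropy"`, `"default"`.
#' @param orders Entropic orders forwarded to [threshold_renyi()].
#' @return A `threshold_level` carrying the histogram used as attribute
#'   `"histogram"`.
#' @export
auto_threshold <- function(x, method = c("otsu", "renyi", "max_entropy", "default"),
                           orders = c(0.5, 1, 2)) {
  method <- match.arg(method)
  h <- histogram_256(x)
  thr <- switch(method,
    otsu = threshold_otsu(h),
    renyi = threshold_renyi(h, orders),
    max_entropy = threshold_max_entropy(h),
    default = threshold_default_isodata(h)
  )
  attr(thr, "histogram") <- h
  thr
}

#' Binarise an image at a threshold
#'
#' Foreground is *strictly above* the threshold bin, evaluated in the same
#' 256-bin mapping used to select it.
#'
#' @param x Intensity array.
#' @param thr A `threshold_level` from one of the threshold functions.
#' @param h The [histogram_256()] the threshold was computed on; defaults to
#'   the one attached to `thr`, else recomputed from `x`.
#' @return A logical array of the same shape.
#' @export
binarize <- function(x, thr, h = NULL) {
  stopifnot(inherits(thr, "threshold_level"))
  h <- h %||% attr(thr, "histogram") %||% histogram_256(x)
  m <- array(bin_of(as.numeric(x), h$lo, h$hi) > thr$bin, dim = dim(x))
  m
}
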