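#' Maximum-intensity projection over z
#'
#' @param channel 3-D intensity array `[z, y, x]` with at least one slice.
#' @return 2-D matrix `[y, x]`; each pixel is the maximum over its z column.
#' @export
max_projection <- function(channel) {
  stopifnot(is.array(channel), length(dim(channel)) == 3)
  d <- dim(channel)
  if (d[1] == 0) abort("empty stack")
  out <- channel[1, , ]
  if (d[1] > 1) {
    for (z in 2:d[1]) out <- pmax(out, channel[z, , ])
  }
  matrix(out, nrow = d[2], ncol = d[3])
}

#' Immunopositive area on a 2-D projection
#'
#' Thresholds the projection with the named automatic method and reports
#' the area of pixels strictly above the threshold, in um^2. The published
#' pairing is `"default"` (IsoData intermeans) for Iba1/microglia and
#' `"max_entropy"` for GFAP/astrocytes.
#'
#' @param projection 2-D matrix (e.g. from [max_projection()]).
#' @param method Threshold method name.
#' @param voxel A [voxel_size()]; only `dx` and `dy` are used.
#' @param depth Optional number of z slices that went into the projection,
#'   recorded in the output.
#' @return One-row tibble: `area_um2`, `positive_pixels`, `threshold_bin`,
#'   `method`, `depth`.
#' @export
immunopositive_area <- function(projection,
                                method = c("default", "max_entropy", "otsu",
                                           "renyi"),
                                voxel, depth = NA_integer_) {
  method <- match.arg(method)
  stopifnot(is.matrix(projection))
  voxel <- as_voxel_size(voxel)
  thr <- auto_threshold(projection, method)
  h <- attr(thr, "histogram")
  pos <- sum(bin_of(as.numeric(projection), h$lo, h$hi) > thr$bin)
  tibble(area_um2 = pos * voxel$dx * voxel$dy,
         positive_pixels = as.integer(pos),
         threshold_bin = thr$bin,
         method = method,
         depth = as.integer(depth))
}

#' Quantify immunopositive area in a calibrated stack
#'
#' Convenience wrapper: maximum-intensity projection of one channel
#' followed by [immunopositive_area()].
#'
#' @param stack A [calibrated_stack()].
#' @param channel Channel selector forwarded to [get_channel()].
#' @param method Threshold method (see [immunopositive_area()]).
#' @return One-row tibble as for [immunopositive_area()], with `depth` set
#'   to the stack's slice count.
#' @export
quantify_area <- function(stack, channel = "glia", method = "default") {
  stopifnot(inherits(stack, "calibrated_stack"))
  ch <- get_channel(stack, channel)
  res <- immunopositive_area(max_projection(ch), method, stack$voxel,
                             depth = dim(ch)[1])
  log_stage("area2d", sprintf("method=%s area=%.1fum2", method, res$area_um2))
  res
}
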