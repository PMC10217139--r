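#' Soma-volumetry parameters
#'
#' Defaults reproduce the published cell-body pipeline: Renyi-entropy
#' thresholding of the glial channel, morphological opening with pixel radii
#' (5.5, 5.5, 2) in (x, y, z) to strip processes, watershed splitting of
#' touching cell bodies, then feature filters keeping objects with a volume
#' of at least 200 um^3, mean native intensity of at least 60 and flatness
#' of at most 3.5.
#'
#' @param threshold_method Histogram threshold for the glial channel.
#' @param opening_radii Structuring-element radii `(rx, ry, rz)` in pixels.
#' @param min_volume Minimum object volume in um^3 (kept side inclusive).
#' @param min_mean_intensity Minimum mean native intensity over the object's
#'   voxels in the original (pre-opening) channel.
#' @param max_flatness Maximum equivalent-ellipsoid flatness.
#' @param watershed_h Watershed dynamic in scaled pixel units.
#' @param flatness_mode `"R2R3"` (intermediate/smallest semi-axis, default)
#'   or `"R1R3"` (largest/smallest).
#' @return A `soma_params` list.
#' @export
soma_params <- function(threshold_method = "renyi",
                        opening_radii = c(5.5, 5.5, 2),
                        min_volume = 200,
                        min_mean_intensity = 60,
                        max_flatness = 3.5,
                        watershed_h = 1,
                        flatness_mode = c("R2R3", "R1R3")) {
  flatness_mode <- match.arg(flatness_mode)
  if (any(opening_radii <= 0)) abort("opening radii must be positive")
  if (min_volume < 0) abort("min_volume must be >= 0")
  if (min_mean_intensity < 0) abort("min_mean_intensity must be >= 0")
  if (max_flatness < 1) abort("max_flatness must be >= 1")
  if (watershed_h < 0) abort("watershed_h must be >= 0")
  structure(list(threshold_method = threshold_method,
                 opening_radii = as.numeric(opening_radii),
                 min_volume = min_volume,
                 min_mean_intensity = min_mean_intensity,
                 max_flatness = max_flatness,
                 watershed_h = watershed_h,
                 flatness_mode = flatness_mode),
            class = "soma_params")
}

#' Segment the glial soma mask by whole-stack auto-thresholding
#'
#' The threshold is computed on the histogram of the whole stack (not per
#' slice) so a single object cannot change label across slices.
#'
#' @param glia_channel 3-D intensity array.
#' @param method Threshold method name (default `"renyi"`).
#' @return Logical mask of voxels strictly above the threshold.
#' @export
segment_soma_mask <- function(glia_channel, method = "renyi") {
  thr <- auto_threshold(glia_channel, method)
  binarize(glia_channel, thr)
}

#' Measure labelled 3-D objects
#'
#' One row per label: voxel count, physical volume, mean native intensity
#' over the original channel, equivalent-ellipsoid flatness and centroid in
#' um. Flatness derives from the eigenvalues of the um-scaled second-moment
#' matrix (with the voxel self-moment `d^2/12` added per axis): semi-axes
#' `Rk = sqrt(5 * lambda_k)` with `R1 >= R2 >= R3`, flatness `R2/R3` (or
#' `R1/R3`). The `sqrt(5)` factor is exact for a uniform solid ellipsoid and
#' cancels in the ratio.
#'
#' @param labels Integer 3-D label array (0 = background).
#' @param intensity Original intensity channel, same shape.
#' @param voxel A [voxel_size()].
#' @param flatness_mode `"R2R3"` (default) or `"R1R3"`.
#' @return A tibble with columns `label`, `voxel_count`, `volume_um3`,
#'   `mean_intensity`, `flatness`, `cz`, `cy`, `cx`.
#' @export
measure_objects <- function(labels, intensity, voxel,
                            flatness_mode = c("R2R3", "R1R3")) {
  flatness_mode <- match.arg(flatness_mode)
  if (!identical(dim(labels), dim(intensity))) {
    abort("label and intensity arrays must share one shape")
  }
  voxel <- as_voxel_size(voxel)
  d <- dim(labels)
  idx <- which(labels > 0)
  if (length(idx) == 0) {
    return(tibble(label = integer(), voxel_count = integer(),
                  volume_um3 = numeric(), mean_intensity = numeric(),
                  flatness = numeric(), cz = numeric(), cy = numeric(),
                  cx = numeric()))
  }
  lab <- labels[idx]
  i0 <- (idx - 1) %% d[1]
  i1 <- ((idx - 1) %/% d[1]) %% d[2]
  i2 <- (idx - 1) %/% (d[1] * d[2])
  z <- i0 * voxel$dz
  y <- i1 * voxel$dy
  x <- i2 * voxel$dx
  inten <- intensity[idx]
  sums <- rowsum(cbind(1, inten, z, y, x,
                       z * z, y * y, x * x, z * y, z * x, y * x), lab)
  u <- as.integer(rownames(sums))
  nvox <- sums[, 1]
  cz <- sums[, 3] / nvox
  cy <- sums[, 4] / nvox
  cx <- sums[, 5] / nvox
  corr <- c(voxel$dz^2, voxel$dy^2, voxel$dx^2) / 12
  flat <- vapply(seq_along(u), function(k) {
    nk <- nvox[k]
    M <- matrix(0, 3, 3)
    M[1, 1] <- sums[k, 6] / nk - cz[k]^2 + corr[1]
    M[2, 2] <- sums[k, 7] / nk - cy[k]^2 + corr[2]
    M[3, 3] <- sums[k, 8] / nk - cx[k]^2 + corr[3]
    M[1, 2] <- M[2, 1] <- sums[k, 9] / nk - cz[k] * cy[k]
    M[1, 3] <- M[3, 1] <- sums[k, 10] / nk - cz[k] * cx[k]
    M[2, 3] <- M[3, 2] <- sums[k, 11] / nk - cy[k] * cx[k]
    ev <- sort(eigen(M, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    ev <- pmax(ev, .Machine$double.eps)
    R <- sqrt(5 * ev)
    if (flatness_mode == "R2R3") R[2] / R[3] else R[1] / R[3]
  }, numeric(1))
  tibble(label = u,
         voxel_count = as.integer(nvox),
         volume_um3 = nvox * voxel_volume(voxel),
         mean_intensity = sums[, 2] / nvox,
         flatness = flat,
         cz = cz, cy = cy, cx = cx)
}

#' Filter measured objects by volume, intensity and flatness
#'
#' Keeps rows with `volume_um3 >= min_volume`, `mean_intensity >=
#' min_mean_intensity` and `flatness <= max_flatness` (all boundaries
#' inclusive on the kept side); row order is preserved.
#'
#' @param objects Tibble from [measure_objects()].
#' @param params A [soma_params()] (or individual limits via `...`).
#' @param min_volume,min_mean_intensity,max_flatness Individual overrides.
#' @return The filtered tibble (a subset of the input).
#' @export
filter_objects <- function(objects, params = soma_params(),
                           min_volume = params$min_volume,
                           min_mean_intensity = params$min_mean_intensity,
                           max_flatness = params$max_flatness) {
  dplyr::filter(objects,
                .data$volume_um3 >= min_volume,
                .data$mean_intensity >= min_mean_intensity,
                .data$flatness <= max_flatness)
}

#' Mean soma volume
#'
#' @param objects Non-empty tibble from [measure_objects()] /
#'   [filter_objects()].
#' @return Arithmetic mean of `volume_um3`.
#' @export
mean_soma_volume <- function(objects) {
  if (nrow(objects) == 0) {
    abort("no objects to average", class = "gliavasc_no_objects")
  }
  mean(objects$volume_um3)
}

#' Quantify glial soma volumes in a calibrated stack
#'
#' Full cell-body pipeline: whole-stack auto-threshold of the glial channel,
#' anisotropic morphological opening, distance-transform watershed split,
#' per-object measurement on the original channel, then feature filtering.
#'
#' @param stack A [calibrated_stack()] with a channel of role `"glia"` (or
#'   pass `channel` explicitly).
#' @param params A [soma_params()].
#' @param channel Optional channel selector forwarded to [get_channel()].
#' @return A `soma_quant` object; `tidy()` returns the retained object
#'   table, `glance()` the one-row summary with the mean soma volume.
#' @export
quantify_soma <- function(stack, params = soma_params(), channel = "glia") {
  stopifnot(inherits(stack, "calibrated_stack"))
  glia <- get_channel(stack, channel)
  mask <- segment_soma_mask(glia, params$threshold_method)
  opened <- open_ellipsoid(mask, params$opening_radii)
  labels <- split_touching(opened, h = params$watershed_h, voxel = stack$voxel)
  objects <- measure_objects(labels, glia, stack$voxel, params$flatness_mode)
  kept <- filter_objects(objects, params)
  log_stage("soma_volumetry",
            sprintf("method=%s objects=%d kept=%d",
                    params$threshold_method, nrow(objects), nrow(kept)))
  structure(list(objects = kept, all_objects = objects, labels = labels,
                 params = params, voxel = stack$voxel),
            class = "soma_quant")
}

#' @export
print.soma_quant <- function(x, ...) {
  cat(sprintf("<soma_quant> %d object(s) retained of %d segmented\n",
              nrow(x$objects), nrow(x$all_objects)))
  if (nrow(x$objects) > 0) {
    cat(sprintf("  mean soma volume: %.1f um^3\n", mean_soma_volume(x$objects)))
  }
  invisible(x)
}

#' @export
tidy.soma_quant <- function(x, ...) x$objects

#' @export
glance.soma_quant <- function(x, ...) {
  tibble(n_objects = nrow(x$objects),
         n_segmented = nrow(x$all_objects),
         mean_volume_um3 = if (nrow(x$objects) > 0) mean_soma_volume(x$objects) else NA_real_,
         sd_volume_um3 = if (nrow(x$objects) > 1) sd(x$objects$volume_um3) else NA_real_)
}

#' @export
autoplot.soma_quant <- function(object, ...) {
  ggplot2::ggplot(object$objects,
                  ggplot2::aes(x = .data$volume_um3)) +
    ggplot2::geom_histogram(bins = 20, fill = "grey35") +
    ggplot2::geom_vline(xintercept = object$params$min_volume,
                        linetype = "dashed") +
    ggplot2::labs(x = expression(volume ~ (mu * m^3)), y = "objects",
                  title = "Soma volume distribution") +
    ggplot2::theme_minimal()
}

log_stage <- function(stage, summary) {
  message(sprintf("[%s] %s", stage, summary))
}
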