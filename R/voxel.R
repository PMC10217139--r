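#' Voxel calibration in micrometres
#'
#' Holds the physical size of one voxel. Two-photon stacks in the intravital
#' regime are strongly anisotropic (e.g. 0.144 x 0.144 x 0.988 um); all
#' physical measurements (volumes, distances, moments) in the package are
#' expressed through this calibration.
#'
#' @param dx,dy,dz Physical size of a voxel along x, y and z, in um. All
#'   strictly positive.
#' @return A `voxel_size` object (named list with `dx`, `dy`, `dz`).
#' @examples
#' vx <- voxel_size(0.144, 0.144, 0.988)
#' voxel_volume(vx)
#' @export
voxel_size <- function(dx, dy, dz) {
  vals <- c(dx = dx, dy = dy, dz = dz)
  if (length(vals) != 3 || !all(is.finite(vals)) || any(vals <= 0)) {
    abort("voxel dimensions must be three strictly positive finite numbers",
          class = "gliavasc_calibration_error")
  }
  structure(list(dx = as.numeric(dx), dy = as.numeric(dy), dz = as.numeric(dz)),
            class = "voxel_size")
}

#' @rdname voxel_size
#' @param voxel A `voxel_size` object.
#' @export
voxel_volume <- function(voxel) {
  voxel <- as_voxel_size(voxel)
  voxel$dx * voxel$dy * voxel$dz
}

#' Convert a voxel count to physical volume
#'
#' @param voxel_count Non-negative number of voxels.
#' @param voxel A [voxel_size()].
#' @return Volume in um^3, exactly `voxel_count * dx * dy * dz`.
#' @examples
#' volume_um3(9763, voxel_size(0.144, 0.144, 0.988)) # ~200 um^3
#' @export
volume_um3 <- function(voxel_count, voxel) {
  if (any(voxel_count < 0)) {
    abort("voxel_count must be non-negative")
  }
  voxel_count * voxel_volume(voxel)
}

as_voxel_size <- function(x) {
  if (inherits(x, "voxel_size")) return(x)
  if (is.numeric(x) && length(x) == 3) {
    nm <- names(x)
    if (!is.null(nm) && all(c("dx", "dy", "dz") %in% nm)) {
      return(voxel_size(x[["dx"]], x[["dy"]], x[["dz"]]))
    }
    return(voxel_size(x[[1]], x[[2]], x[[3]]))
  }
  if (is.list(x) && all(c("dx", "dy", "dz") %in% names(x))) {
    return(voxel_size(x$dx, x$dy, x$dz))
  }
  abort("cannot interpret `voxel` as a voxel size",
        class = "gliavasc_calibration_error")
}

#' @export
print.voxel_size <- function(x, ...) {
  cat(sprintf("<voxel_size> dx = %g, dy = %g, dz = %g um (voxel volume %.6g um^3)\n",
              x$dx, x$dy, x$dz, voxel_volume(x)))
  invisible(x)
}
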