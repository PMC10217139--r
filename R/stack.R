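#' Calibrated multi-channel image stack
#'
#' The universal input container: one 3-D intensity array per channel,
#' indexed `[z, y, x]`, plus the voxel calibration in um and a role for each
#' channel (`"glia"`, `"vessel"`, `"aqp4"` or `"nuclei"`). Intensities are
#' kept in native integer units; no normalisation is applied, because
#' absolute intensity filters (e.g. a minimum mean soma intensity of 60)
#' operate on native levels.
#'
#' @param channels A 3-D numeric array or a (optionally named) list of 3-D
#'   arrays sharing one shape, each indexed `[z, y, x]`.
#' @param voxel A [voxel_size()].
#' @param roles Character vector, one role per channel, values in
#'   `c("glia", "vessel", "aqp4", "nuclei")` or `NA`.
#' @param bit_depth 8 or 16; intensities must lie in `[0, 2^bit_depth - 1]`.
#' @return A `calibrated_stack` object.
#' @export
calibrated_stack <- function(channels, voxel, roles = NULL, bit_depth = 8) {
  if (is.array(channels) && length(dim(channels)) == 3) {
    channels <- list(channels)
  }
  if (!is.list(channels) || length(channels) == 0) {
    abort("`channels` must be a non-empty list of 3-D arrays")
  }
  dims <- lapply(channels, dim)
  if (any(vapply(dims, length, 1L) != 3)) {
    abort("every channel must be a 3-D array indexed [z, y, x]")
  }
  if (length(unique(lapply(dims, as.integer))) != 1) {
    abort("all channels must share an identical shape")
  }
  if (!bit_depth %in% c(8, 16)) {
    abort("`bit_depth` must be 8 or 16")
  }
  maxval <- 2^bit_depth - 1
  for (ch in channels) {
    rng <- range(ch)
    if (rng[1] < 0 || rng[2] > maxval) {
      abort(sprintf("intensities must lie within [0, %d]", maxval))
    }
  }
  if (is.null(names(channels)) || any(!nzchar(names(channels)))) {
    names(channels) <- paste0("ch", seq_along(channels))
  }
  if (is.null(roles)) {
    roles <- rep(NA_character_, length(channels))
  }
  roles <- as.character(roles)
  if (length(roles) != length(channels)) {
    abort("`roles` must name one role per channel")
  }
  known <- c("glia", "vessel", "aqp4", "nuclei")
  if (any(!is.na(roles) & !roles %in% known)) {
    abort(sprintf("channel roles must be one of %s",
                  paste(known, collapse = ", ")))
  }
  structure(
    list(channels = channels, roles = roles,
         voxel = as_voxel_size(voxel), bit_depth = as.integer(bit_depth)),
    class = "calibrated_stack"
  )
}

#' @export
print.calibrated_stack <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf("<calibrated_stack> %d x %d x %d (z,y,x), %d channel(s), %d-bit\n",
              d[1], d[2], d[3], length(x$channels), x$bit_depth))
  cat(sprintf("  voxel: %g x %g x %g um\n", x$voxel$dx, x$voxel$dy, x$voxel$dz))
  cat(sprintf("  roles: %s\n",
              paste(sprintf("%s=%s", names(x$channels), x$roles), collapse = ", ")))
  invisible(x)
}

#' Extract a channel from a stack by role or index
#'
#' @param stack A [calibrated_stack()].
#' @param which A role name (`"glia"`, `"vessel"`, `"aqp4"`, `"nuclei"`),
#'   a channel name, or an integer index.
#' @return The channel's 3-D array.
#' @export
get_channel <- function(stack, which) {
  stopifnot(inherits(stack, "calibrated_stack"))
  if (is.numeric(which)) {
    if (which < 1 || which > length(stack$channels)) {
      abort("channel index out of range")
    }
    return(stack$channels[[which]])
  }
  if (which %in% stack$roles) {
    return(stack$channels[[match(which, stack$roles)]])
  }
  if (which %in% names(stack$channels)) {
    return(stack$channels[[which]])
  }
  abort(sprintf("no channel with role or name '%s'", which))
}

sidecar_path <- function(path) paste0(path, ".yaml")

#' Read a calibrated stack from TIFF
#'
#' Reads a multi-page TIFF (or OME-TIFF) as a `[z, y, x]` stack. Calibration
#' precedence is: explicit `voxel` argument, then OME-XML `PhysicalSize*`
#' metadata embedded in the image description, then a YAML sidecar
#' (`<path>.yaml`) as written by [write_stack()]; if none is available the
#' read fails rather than silently assuming a voxel size. Plane-major pages
#' map to z; multi-channel stacks are stored channel-interleaved
#' (z1c1, z1c2, z2c1, ...).
#'
#' @param path Path to the TIFF file.
#' @param voxel Optional [voxel_size()] overriding any file metadata.
#' @param roles Optional channel-role vector overriding file metadata.
#' @param n_channels Optional channel count when neither OME metadata nor a
#'   sidecar declares it (defaults to 1).
#' @return A [calibrated_stack()].
#' @export
read_stack <- function(path, voxel = NULL, roles = NULL, n_channels = NULL) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path))
  }
  pages <- tryCatch(
    tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE),
    error = function(e) abort(sprintf("unreadable TIFF: %s", conditionMessage(e)))
  )
  if (length(pages) == 0) abort("file contains no image pages")

  desc <- attr(pages[[1]], "description")
  ome <- parse_ome_description(desc)

  side <- NULL
  if (file.exists(sidecar_path(path))) {
    side <- yaml::read_yaml(sidecar_path(path))
  }

  if (is.null(voxel)) {
    if (!is.null(ome$voxel)) {
      voxel <- ome$voxel
    } else if (!is.null(side$voxel)) {
      voxel <- as_voxel_size(unlist(side$voxel))
    } else {
      abort("no calibration metadata found; supply `voxel`",
            class = "gliavasc_calibration_error")
    }
  }
  voxel <- as_voxel_size(voxel)

  nc <- n_channels %||% ome$size_c %||% side$n_channels %||% 1L
  nc <- as.integer(nc)

  bits <- attr(pages[[1]], "bits.per.sample") %||% side$bit_depth
  if (is.null(bits)) {
    bits <- if (max(vapply(pages, max, 0)) > 255) 16L else 8L
  }

  # pages carrying multiple samples: samples are channels
  if (length(dim(pages[[1]])) == 3) {
    nc <- dim(pages[[1]])[3]
    nz <- length(pages)
    planes <- vector("list", nz * nc)
    for (z in seq_len(nz)) {
      for (ch in seq_len(nc)) planes[[(z - 1) * nc + ch]] <- pages[[z]][, , ch]
    }
    pages <- planes
  }
  if (length(pages) %% nc != 0) {
    abort("page count is not a multiple of the channel count; cannot interpret as a stack")
  }
  nz <- length(pages) %/% nc
  ny <- nrow(pages[[1]])
  nx <- ncol(pages[[1]])

  channels <- vector("list", nc)
  for (ch in seq_len(nc)) {
    arr <- array(0, dim = c(nz, ny, nx))
    for (z in seq_len(nz)) arr[z, , ] <- pages[[(z - 1) * nc + ch]]
    channels[[ch]] <- arr
  }
  if (!is.null(side$channel_names) && length(side$channel_names) == nc) {
    names(channels) <- unlist(side$channel_names)
  }
  if (is.null(roles)) {
    roles <- if (!is.null(side$roles)) as.character(unlist(side$roles)) else NULL
    if (!is.null(roles)) roles[roles == "NA"] <- NA_character_
  }
  calibrated_stack(channels, voxel = voxel, roles = roles, bit_depth = bits)
}

#' Write a calibrated stack to TIFF with a YAML calibration sidecar
#'
#' Writes a plane-major multi-page TIFF (channel-interleaved within each z)
#' plus `<path>.yaml` carrying the voxel calibration, channel names, roles
#' and bit depth, so that `read_stack(write_stack(s))` reproduces `s`
#' bit-exactly.
#'
#' @param stack A [calibrated_stack()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "calibrated_stack"))
  if (length(stack$channels) == 0) abort("stack has no channels")
  maxval <- 2^stack$bit_depth - 1
  d <- dim(stack$channels[[1]])
  nz <- d[1]
  nc <- length(stack$channels)
  pages <- vector("list", nz * nc)
  for (z in seq_len(nz)) {
    for (ch in seq_len(nc)) {
      pages[[(z - 1) * nc + ch]] <-
        matrix(stack$channels[[ch]][z, , ], d[2], d[3]) / maxval
    }
  }
  ok <- tryCatch(
    tiff::writeTIFF(pages, path, bits.per.sample = stack$bit_depth,
                    compression = "LZW", reduce = FALSE),
    error = function(e) abort(sprintf("cannot write TIFF: %s", conditionMessage(e)))
  )
  yaml::write_yaml(
    list(voxel = list(dx = stack$voxel$dx, dy = stack$voxel$dy, dz = stack$voxel$dz),
         n_channels = nc,
         channel_names = as.list(names(stack$channels)),
         roles = as.list(ifelse(is.na(stack$roles), "NA", stack$roles)),
         bit_depth = stack$bit_depth),
    sidecar_path(path)
  )
  invisible(path)
}

# Extract PhysicalSizeX/Y/Z and SizeC from an OME-XML image description.
parse_ome_description <- function(desc) {
  out <- list(voxel = NULL, size_c = NULL)
  if (is.null(desc) || !nzchar(desc) || !grepl("<OME", desc, fixed = TRUE)) {
    return(out)
  }
  doc <- tryCatch(xml2::read_xml(desc), error = function(e) NULL)
  if (is.null(doc)) return(out)
  px <- xml2::xml_find_first(doc, ".//*[local-name()='Pixels']")
  if (inherits(px, "xml_missing")) return(out)
  sx <- as.numeric(xml2::xml_attr(px, "PhysicalSizeX"))
  sy <- as.numeric(xml2::xml_attr(px, "PhysicalSizeY"))
  sz <- as.numeric(xml2::xml_attr(px, "PhysicalSizeZ"))
  if (!any(is.na(c(sx, sy, sz)))) {
    out$voxel <- voxel_size(sx, sy, sz)
  }
  sc <- as.integer(xml2::xml_attr(px, "SizeC"))
  if (!is.na(sc)) out$size_c <- sc
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
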