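#' Synthetic-stack generator parameters
#'
#' The generator emulates the structure the quantification pipelines
#' assume: calibrated anisotropic voxels (two-photon default 0.144 x 0.144
#' x 0.988 um), tubular vessels rendered as correlated random-walk
#' centrelines with a fixed radius, ellipsoidal glial somata in the 200-1100
#' um^3 volume regime with thin processes, astrocytic endfeet co-covering a
#' stated fraction of the vessel volume, an optional 1-voxel perivascular
#' AQP4 shell over a stated fraction of the vessel surface, spectral
#' crosstalk of the vessel channel into the glial channel, and additive
#' Gaussian noise on a two-level (background/foreground) rendering. SNR is
#' defined as `(foreground - background) / noise_sd`.
#'
#' @param shape Stack shape `(nz, ny, nx)` in voxels.
#' @param voxel A [voxel_size()]; default the two-photon calibration.
#' @param n_vessels Number of vessels.
#' @param vessel_radius_um Vessel tube radius in um (default 2, a cortical
#'   capillary).
#' @param n_cells Number of glial somata.
#' @param soma_volume_range Range of true soma volumes in um^3 (sampled
#'   uniformly per cell).
#' @param coverage_fraction Fraction of vessel voxels co-covered by glial
#'   endfeet, in `[0, 1]`. Endfeet are rendered as perivascular sleeves
#'   straddling the lumen boundary (penetrating inward by about the lateral
#'   optical resolution, `endfoot_inner_um`), as in real data where the
#'   dextran-filled lumen and the abluminal endfoot sheet overlap within
#'   the point-spread function; the band length along the vessel is chosen
#'   to realise the requested vessel-voxel coverage.
#' @param endfoot_inner_um,endfoot_outer_um Inward penetration and outward
#'   extent of the endfoot sleeve relative to the vessel radius, in um.
#' @param aqp4_surface_fraction Fraction of the vessel surface covered by
#'   the AQP4 shell, in `[0, 1]` (0 = no AQP4 channel).
#' @param crosstalk Bleed coefficient of the vessel channel into the glial
#'   channel, in `[0, 1)`.
#' @param background,foreground Two rendering levels in native units
#'   (glial and AQP4 structures render at `foreground`).
#' @param vessel_foreground Rendering level of the vessel lumen in the
#'   vessel channel. Channel gains are set independently at acquisition;
#'   the vascular channel is kept conservatively below the glial one so
#'   the brightest structure (lumen plus crosstalk in the glial channel)
#'   stays within the detector range.
#' @param noise_sd Gaussian noise standard deviation in native units.
#' @param n_processes Thin processes per soma.
#' @param bit_depth 8 or 16.
#' @param seed Integer seed fixing all randomness.
#' @return A `synth_params` list.
#' @export
synth_params <- function(shape = c(128, 256, 256),
                         voxel = voxel_size(0.144, 0.144, 0.988),
                         n_vessels = 1,
                         vessel_radius_um = 2,
                         n_cells = 8,
                         soma_volume_range = c(200, 1100),
                         coverage_fraction = 0.15,
                         endfoot_inner_um = 0.4,
                         endfoot_outer_um = 0.8,
                         aqp4_surface_fraction = 0,
                         crosstalk = 0.3,
                         background = 1200,
                         foreground = 3100,
                         vessel_foreground = 2100,
                         noise_sd = 380,
                         n_processes = 3,
                         bit_depth = 16,
                         seed = 1) {
  if (coverage_fraction < 0 || coverage_fraction > 1) {
    abort("coverage_fraction must lie in [0, 1]")
  }
  if (aqp4_surface_fraction < 0 || aqp4_surface_fraction > 1) {
    abort("aqp4_surface_fraction must lie in [0, 1]")
  }
  if (crosstalk < 0 || crosstalk >= 1) abort("crosstalk must lie in [0, 1)")
  maxval <- 2^bit_depth - 1
  if (background < 0 || foreground > maxval || background >= foreground) {
    abort("need 0 <= background < foreground <= native maximum")
  }
  if (vessel_foreground <= background || vessel_foreground > maxval) {
    abort("vessel_foreground must lie in (background, native maximum]")
  }
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  if (endfoot_inner_um <= 0 || endfoot_inner_um >= vessel_radius_um) {
    abort("endfoot_inner_um must lie in (0, vessel_radius_um)")
  }
  if (endfoot_outer_um <= 0) abort("endfoot_outer_um must be > 0")
  structure(list(shape = as.integer(shape), voxel = as_voxel_size(voxel),
                 n_vessels = n_vessels, vessel_radius_um = vessel_radius_um,
                 n_cells = n_cells, soma_volume_range = soma_volume_range,
                 coverage_fraction = coverage_fraction,
                 endfoot_inner_um = endfoot_inner_um,
                 endfoot_outer_um = endfoot_outer_um,
                 aqp4_surface_fraction = aqp4_surface_fraction,
                 crosstalk = crosstalk, background = background,
                 foreground = foreground,
                 vessel_foreground = vessel_foreground, noise_sd = noise_sd,
                 n_processes = n_processes, bit_depth = as.integer(bit_depth),
                 seed = as.integer(seed)),
            class = "synth_params")
}

#' Generate a synthetic calibrated stack with exact ground truth
#'
#' @param params A [synth_params()].
#' @return A list of class `synth_stack` with elements `stack` (a
#'   [calibrated_stack()]) and `truth` (vessel/glia/AQP4 masks, per-soma
#'   label array and volumes, and the true contact values recomputed from
#'   the masks by the same definitions the pipelines use).
#' @export
generate_stack <- function(params = synth_params()) {
  stopifnot(inherits(params, "synth_params"))
  withr::with_seed(params$seed, generate_stack_impl(params))
}

generate_stack_impl <- function(p) {
  d <- p$shape
  vx <- p$voxel
  sp_um <- c(vx$dz, vx$dy, vx$dx)  # physical step along (z, y, x)
  extent <- d * sp_um
  min_extent <- min(extent)
  if (p$n_vessels > 0 && 2 * p$vessel_radius_um >= min_extent) {
    abort("stack too small for the requested vessel radius")
  }

  vessel_mask <- array(FALSE, d)
  vessel_dir <- c(1, 0, 0)  # dominant direction, (z, y, x) physical
  dist2 <- NULL             # squared distance to the vessel centreline, um^2
  if (p$n_vessels > 0) {
    centerline <- array(FALSE, d)
    # bias vessels along the longest axis so they traverse the volume
    main_axis <- which.max(extent)
    for (v in seq_len(p$n_vessels)) {
      path <- vessel_path(extent, main_axis, p$vessel_radius_um)
      if (v == 1) vessel_dir <- attr(path, "direction")
      ijk <- um_to_index(path, sp_um, d)
      centerline[ijk] <- TRUE
    }
    dist2 <- edt_sq_cpp(centerline, d, sp_um)
    vessel_mask <- array(dist2 <= p$vessel_radius_um^2, d)
  }

  glia_mask <- array(FALSE, d)
  soma_labels <- array(0L, d)
  soma_volumes <- numeric(0)
  if (p$n_cells > 0) {
    keep_out <- if (any(vessel_mask)) {
      sqrt(edt_sq_cpp(vessel_mask, d, sp_um))
    } else {
      array(Inf, d)
    }
    placed <- 0
    centers <- matrix(numeric(0), ncol = 3)
    attempts <- 0
    rmax_um <- (3 * max(p$soma_volume_range) / (4 * pi))^(1 / 3) * 1.3
    while (placed < p$n_cells && attempts < 400 * p$n_cells) {
      attempts <- attempts + 1
      ctr <- runif(3, min = rmax_um + sp_um, max = extent - rmax_um - sp_um)
      if (any(extent < 2 * (rmax_um + sp_um))) {
        abort("stack too small for the requested soma sizes")
      }
      idx <- um_to_index(matrix(ctr, 1), sp_um, d)
      if (keep_out[idx] < rmax_um + 1) next
      if (placed > 0 &&
          min(sqrt(colSums((t(centers) - ctr)^2))) < 2.2 * rmax_um) next
      placed <- placed + 1
      centers <- rbind(centers, ctr)
      vol <- runif(1, p$soma_volume_range[1], p$soma_volume_range[2])
      r0 <- (3 * vol / (4 * pi))^(1 / 3)
      f <- runif(3, 0.85, 1.2)
      f <- f / prod(f)^(1 / 3)
      semi <- r0 * f  # (z, y, x) semi-axes, volume-preserving anisotropy
      blob <- render_ellipsoid(d, sp_um, ctr, semi)
      soma_labels[blob & soma_labels == 0L] <- placed
      glia_mask <- glia_mask | blob
      # thin processes radiating from the soma
      for (pr in seq_len(p$n_processes)) {
        u <- rnorm(3)
        u <- u / sqrt(sum(u^2))
        len <- runif(1, 6, 14)
        steps <- seq(max(semi) * 0.9, max(semi) * 0.9 + len,
                     by = min(sp_um) / 2)
        pts <- t(vapply(steps, function(s) ctr + s * u, numeric(3)))
        inside <- pts[, 1] >= 0 & pts[, 2] >= 0 & pts[, 3] >= 0 &
          pts[, 1] < extent[1] & pts[, 2] < extent[2] & pts[, 3] < extent[3]
        if (any(inside)) {
          glia_mask[um_to_index(pts[inside, , drop = FALSE], sp_um, d)] <- TRUE
        }
      }
    }
    if (placed < p$n_cells) {
      warn(sprintf("placed %d of %d requested somata (volume too crowded)",
                   placed, p$n_cells))
    }
    soma_volumes <- vapply(seq_len(placed), function(k) {
      volume_um3(sum(soma_labels == k), vx)
    }, numeric(1))
  }

  # Endfeet: a perivascular sleeve straddling the lumen boundary over a
  # contiguous band along the vessel. The sleeve reaches endfoot_inner_um
  # inward of the nominal radius (the overlap the optical resolution
  # produces between the lumen mask and the abluminal endfoot sheet) and
  # endfoot_outer_um outward; the band length is set so that the sleeve
  # covers the requested fraction of vessel voxels.
  if (p$coverage_fraction > 0 && any(vessel_mask)) {
    r_in2 <- (p$vessel_radius_um - p$endfoot_inner_um)^2
    r_out2 <- (p$vessel_radius_um + p$endfoot_outer_um)^2
    sleeve <- array(dist2 > r_in2 & dist2 <= r_out2, d)
    inner_idx <- which(sleeve & vessel_mask)
    n_target <- round(p$coverage_fraction * sum(vessel_mask))
    if (p$coverage_fraction == 1) {
      # full enwrapment: glia covers the whole vessel and its sleeve
      glia_mask <- glia_mask | vessel_mask | sleeve
      n_target <- 0
    } else if (n_target > length(inner_idx)) {
      warn(sprintf(
        "coverage_fraction %.2f exceeds the sleeve capacity (max %.2f); covering the full vessel length",
        p$coverage_fraction, length(inner_idx) / sum(vessel_mask)))
      n_target <- length(inner_idx)
    }
    if (n_target > 0) {
      # band kept clear of the stack faces so it is a true sleeve of tube
      # surface, not the cut face at the volume border
      proj_in <- sort(index_projection(inner_idx, d, sp_um, vessel_dir))
      start <- min(round(0.08 * length(proj_in)) + 1,
                   max(length(proj_in) - n_target + 1, 1))
      cut_lo <- proj_in[start]
      cut_hi <- proj_in[min(start + n_target - 1, length(proj_in))]
      sleeve_idx <- which(sleeve)
      proj_all <- index_projection(sleeve_idx, d, sp_um, vessel_dir)
      glia_mask[sleeve_idx[proj_all >= cut_lo & proj_all <= cut_hi]] <- TRUE
    }
  }

  # AQP4: 1-voxel shell just outside a contiguous band of the vessel surface
  aqp4_mask <- NULL
  if (p$aqp4_surface_fraction > 0 && any(vessel_mask)) {
    surf <- extract_surface(vessel_mask)
    sidx <- which(surf)
    proj <- index_projection(sidx, d, sp_um, vessel_dir)
    k <- round(p$aqp4_surface_fraction * length(sidx))
    aqp4_mask <- array(FALSE, d)
    if (k > 0) {
      ord <- sidx[order(proj)]
      start <- min(round(0.08 * length(ord)) + 1,
                   max(length(ord) - k + 1, 1))
      chosen <- array(FALSE, d)
      chosen[ord[seq(start, min(start + k - 1, length(ord)))]] <- TRUE
      shell <- array(FALSE, d)
      for (axis in 1:3) {
        for (by in c(-1L, 1L)) {
          shell <- shell | shift_mask(chosen, axis, by)
        }
      }
      aqp4_mask <- shell & !vessel_mask
    }
  }

  amp <- p$foreground - p$background
  amp_v <- p$vessel_foreground - p$background
  maxval <- 2^p$bit_depth - 1
  render <- function(signal) {
    x <- p$background + signal
    if (p$noise_sd > 0) x <- x + rnorm(length(x), 0, p$noise_sd)
    array(pmin(pmax(round(x), 0), maxval), d)
  }

  channels <- list()
  roles <- character(0)
  channels$glia <- render(amp * glia_mask + p$crosstalk * amp_v * vessel_mask)
  roles <- c(roles, "glia")
  if (p$n_vessels > 0) {
    channels$vessel <- render(amp_v * vessel_mask)
    roles <- c(roles, "vessel")
  }
  if (!is.null(aqp4_mask)) {
    channels$aqp4 <- render(amp * aqp4_mask)
    roles <- c(roles, "aqp4")
  }

  stack <- calibrated_stack(channels, voxel = vx, roles = roles,
                            bit_depth = p$bit_depth)

  true_contact <- if (any(vessel_mask)) {
    100 * sum(glia_mask & vessel_mask) / sum(vessel_mask)
  } else {
    NA_real_
  }
  true_surface <- if (!is.null(aqp4_mask) && any(vessel_mask)) {
    surface_contact_percent(vessel_mask, aqp4_mask, vx, 1)$contact_percent
  } else {
    NA_real_
  }

  truth <- structure(
    list(vessel_mask = vessel_mask, glia_mask = glia_mask,
         soma_labels = soma_labels, aqp4_mask = aqp4_mask,
         true_soma_volumes = soma_volumes,
         true_contact_ratio_percent = true_contact,
         true_surface_contact_percent = true_surface,
         voxel = vx),
    class = "synth_truth"
  )
  structure(list(stack = stack, truth = truth, params = p),
            class = "synth_stack")
}

# Correlated random walk in physical um coordinates, biased along one axis.
# The path traverses the whole field of view along the main axis; lateral
# excursions reflect at the volume walls (a vessel does not simply end
# inside the imaged field).
vessel_path <- function(extent, main_axis, radius) {
  start <- runif(3, 0.25, 0.75) * extent
  start[main_axis] <- 0
  dir <- rnorm(3, 0, 0.1)
  dir[main_axis] <- 1
  dir <- dir / sqrt(sum(dir^2))
  step <- min(extent) / 200
  n_max <- ceiling(3 * sum(extent) / step)
  pts <- matrix(NA_real_, n_max, 3)
  pos <- start
  main_dir <- dir
  lateral <- setdiff(1:3, main_axis)
  for (i in seq_len(n_max)) {
    pts[i, ] <- pos
    pos <- pos + dir * step
    for (ax in lateral) {
      if (pos[ax] < 0) {
        pos[ax] <- -pos[ax]
        dir[ax] <- -dir[ax]
        main_dir[ax] <- -main_dir[ax]
      } else if (pos[ax] >= extent[ax]) {
        pos[ax] <- 2 * extent[ax] - pos[ax] - 1e-9
        dir[ax] <- -dir[ax]
        main_dir[ax] <- -main_dir[ax]
      }
    }
    if (pos[main_axis] < 0 || pos[main_axis] >= extent[main_axis]) {
      pts <- pts[seq_len(i), , drop = FALSE]
      break
    }
    wiggle <- rnorm(3, 0, 0.03)
    dir <- dir + wiggle
    dir <- dir / sqrt(sum(dir^2))
    # curvature bound: stay within ~30 degrees of the main direction
    if (sum(dir * main_dir) < cos(pi / 6)) {
      dir <- 0.8 * main_dir + 0.2 * dir
      dir <- dir / sqrt(sum(dir^2))
    }
  }
  pts <- pts[!is.na(pts[, 1]), , drop = FALSE]
  attr(pts, "direction") <- main_dir
  pts
}

# Convert physical (z, y, x) um coordinates to linear array indices.
um_to_index <- function(pts, sp_um, d) {
  i0 <- pmin(pmax(floor(pts[, 1] / sp_um[1]), 0), d[1] - 1)
  i1 <- pmin(pmax(floor(pts[, 2] / sp_um[2]), 0), d[2] - 1)
  i2 <- pmin(pmax(floor(pts[, 3] / sp_um[3]), 0), d[3] - 1)
  as.integer(i0 + d[1] * (i1 + d[2] * i2) + 1)
}

# Projection of voxel centres onto a direction, for ordering voxels along a
# vessel.
index_projection <- function(idx, d, sp_um, dir) {
  i0 <- (idx - 1) %% d[1]
  i1 <- ((idx - 1) %/% d[1]) %% d[2]
  i2 <- (idx - 1) %/% (d[1] * d[2])
  i0 * sp_um[1] * dir[1] + i1 * sp_um[2] * dir[2] + i2 * sp_um[3] * dir[3]
}

# Render an axis-aligned ellipsoid with semi-axes in (z, y, x) um.
render_ellipsoid <- function(d, sp_um, center, semi) {
  lo <- pmax(floor((center - semi) / sp_um), 0)
  hi <- pmin(ceiling((center + semi) / sp_um), d - 1)
  z <- (lo[1]:hi[1]) * sp_um[1]
  y <- (lo[2]:hi[2]) * sp_um[2]
  x <- (lo[3]:hi[3]) * sp_um[3]
  zz <- ((z - center[1]) / semi[1])^2
  yy <- ((y - center[2]) / semi[2])^2
  xx <- ((x - center[3]) / semi[3])^2
  block <- outer(outer(zz, yy, "+"), xx, "+") <= 1
  out <- array(FALSE, d)
  out[(lo[1]:hi[1]) + 1, (lo[2]:hi[2]) + 1, (lo[3]:hi[3]) + 1] <- block
  out
}

#' Recompute true contact values from stored ground-truth masks
#'
#' Self-consistency accessor: re-applies the contact-ratio and
#' surface-contact definitions to the stored masks; the results must equal
#' the stored truth values exactly.
#'
#' @param truth A `synth_truth` (from [generate_stack()]).
#' @param voxel Optional [voxel_size()]; defaults to the truth's own.
#' @return One-row tibble: `n_vessel_voxels`, `n_glia_voxels`,
#'   `true_contact_ratio_percent`, `true_surface_contact_percent`,
#'   `mean_true_soma_volume_um3`.
#' @export
truth_from_masks <- function(truth, voxel = NULL) {
  stopifnot(inherits(truth, "synth_truth"))
  voxel <- as_voxel_size(voxel %||% truth$voxel)
  contact <- if (any(truth$vessel_mask)) {
    100 * sum(truth$glia_mask & truth$vessel_mask) / sum(truth$vessel_mask)
  } else {
    NA_real_
  }
  surface <- if (!is.null(truth$aqp4_mask) && any(truth$vessel_mask)) {
    surface_contact_percent(truth$vessel_mask, truth$aqp4_mask, voxel,
                            1)$contact_percent
  } else {
    NA_real_
  }
  tibble(n_vessel_voxels = sum(truth$vessel_mask),
         n_glia_voxels = sum(truth$glia_mask),
         true_contact_ratio_percent = contact,
         true_surface_contact_percent = surface,
         mean_true_soma_volume_um3 = if (length(truth$true_soma_volumes)) {
           mean(truth$true_soma_volumes)
         } else {
           NA_real_
         })
}

#' @export
print.synth_stack <- function(x, ...) {
  cat("<synth_stack>\n")
  print(x$stack)
  t <- x$truth
  cat(sprintf("  truth: %d somata, contact %.2f%%, surface contact %s\n",
              length(t$true_soma_volumes),
              t$true_contact_ratio_percent,
              ifelse(is.na(t$true_surface_contact_percent), "-",
                     sprintf("%.2f%%", t$true_surface_contact_percent))))
  invisible(x)
}
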