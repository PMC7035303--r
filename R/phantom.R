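#' Voxelized vessel phantom geometry
#'
#' A tube of constant circular cross-section around an ordered 3D
#' centerline, on an isotropic voxel grid. Used as ground truth for the
#' centerline flow-extraction pipeline: the velocity field built on it is a
#' fully developed (parabolic) Poiseuille profile at every cardiac phase, so
#' the through-plane flow is known exactly by construction.
#'
#' @param centerline_points n x 3 matrix of ordered centerline coordinates,
#'   mm. Consecutive points must be at most one voxel apart.
#' @param radius Lumen radius, mm; at least 2 voxels so the lumen is
#'   resolvable.
#' @param voxel_size Isotropic voxel edge, mm.
#' @param grid_shape Integer vector of length 3, grid dimensions in voxels.
#' @return A `vessel_phantom` object.
#' @seealso [straight_phantom()], [curved_phantom()], [build_phantom()]
#' @export
vessel_phantom <- function(centerline_points, radius, voxel_size, grid_shape) {
  centerline_points <- as.matrix(centerline_points)
  if (ncol(centerline_points) != 3 || nrow(centerline_points) < 2) {
    stopf("centerline_points must be an n x 3 matrix with n >= 2")
  }
  if (!is_scalar_num(radius) || !is_scalar_num(voxel_size) ||
      radius <= 0 || voxel_size <= 0) {
    stopf("radius and voxel_size must be positive scalars")
  }
  if (radius < 2 * voxel_size) {
    stopf("radius (%.2f mm) must be >= 2 voxels (%.2f mm) to resolve the lumen",
          radius, 2 * voxel_size)
  }
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3 || any(grid_shape < 3)) {
    stopf("grid_shape must be 3 positive integers")
  }
  step <- sqrt(rowSums(diff(centerline_points)^2))
  if (any(step > voxel_size * (1 + 1e-9))) {
    stopf("consecutive centerline points must be <= 1 voxel apart")
  }
  extent <- grid_shape * voxel_size
  lo <- apply(centerline_points, 2, min)
  hi <- apply(centerline_points, 2, max)
  if (any(lo < radius) || any(hi > extent - radius)) {
    stopf("centerline must stay >= radius from the grid boundary")
  }
  structure(list(centerline_points = centerline_points, radius = radius,
                 voxel_size = voxel_size, grid_shape = grid_shape),
            class = "vessel_phantom")
}

#' Straight tube phantom along the x axis
#'
#' @param length_mm Tube length, mm.
#' @param radius Lumen radius, mm.
#' @param voxel_size Isotropic voxel edge, mm.
#' @return A [vessel_phantom].
#' @export
straight_phantom <- function(length_mm = 10, radius = 2, voxel_size = 0.5) {
  cross <- 2 * (radius + 3 * voxel_size)
  pad <- 2 * voxel_size
  nx <- ceiling((length_mm + 2 * radius + 2 * pad) / voxel_size)
  nyz <- ceiling(cross / voxel_size)
  ctr <- nyz * voxel_size / 2
  x <- seq(radius + pad, radius + pad + length_mm, by = voxel_size)
  vessel_phantom(cbind(x, ctr, ctr), radius, voxel_size,
                 c(nx, nyz, nyz))
}

#' Curved (circular-arc) tube phantom in the xy plane
#'
#' @param bend_radius Radius of curvature of the centerline, mm.
#' @param arc_deg Arc swept by the centerline, degrees.
#' @inheritParams straight_phantom
#' @return A [vessel_phantom].
#' @export
curved_phantom <- function(bend_radius = 20, arc_deg = 45, radius = 2,
                           voxel_size = 0.5) {
  arc_len <- bend_radius * arc_deg * pi / 180
  n <- ceiling(arc_len / (0.9 * voxel_size)) + 1
  th <- seq(0, arc_deg * pi / 180, length.out = n)
  x <- bend_radius * sin(th)
  y <- bend_radius * (1 - cos(th))
  margin <- radius + 3 * voxel_size
  pts <- cbind(x - min(x) + margin, y - min(y) + margin, margin)
  hi <- apply(pts, 2, max)
  grid <- ceiling((hi + margin) / voxel_size)
  grid[3] <- ceiling(2 * margin / voxel_size)
  vessel_phantom(pts, radius, voxel_size, grid)
}

## Unit tangents along the centerline (central differences).
centerline_tangents <- function(pts) {
  n <- nrow(pts)
  d <- matrix(0, n, 3)
  d[1, ] <- pts[2, ] - pts[1, ]
  d[n, ] <- pts[n, ] - pts[n - 1, ]
  if (n > 2) {
    d[2:(n - 1), ] <- pts[3:n, , drop = FALSE] - pts[1:(n - 2), , drop = FALSE]
  }
  d / sqrt(rowSums(d^2))
}

## Voxel-centre coordinates (mm) of a grid, as an nvox x 3 matrix.
voxel_centres <- function(grid_shape, voxel_size) {
  ax <- lapply(grid_shape, function(n) (seq_len(n) - 0.5) * voxel_size)
  g <- expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]])
  as.matrix(g)
}

#' Build a pulsatile 4D velocity field on a vessel phantom
#'
#' At each cardiac phase the axial velocity is a fully developed Poiseuille
#' profile carrying the waveform's instantaneous flow rate:
#' `v(r, t) = 2 Q(t) / (pi R^2) * (1 - r^2 / R^2)` for `r <= R`, zero
#' outside the lumen, directed along the local centerline tangent. Voxels
#' are assigned to the nearest centerline point; `r` is the perpendicular
#' distance to its tangent line.
#'
#' @param phantom A [vessel_phantom].
#' @param waveform A [flow_waveform] giving `Q(t)` at each phase (one phase
#'   per sample; 20 by default upstream).
#' @param venc Velocity-encoding limit, cm/s (default 110).
#' @param aliasing If `FALSE` (default) a peak velocity above `venc` is a
#'   configuration error; if `TRUE` velocities wrap into `[-venc, venc)`.
#' @return A `velocity_field_4d` object: components `vx`, `vy`, `vz` as
#'   4D arrays (grid x phase, cm/s), plus `phase_times` (s), `rr_interval`,
#'   `venc`, `voxel_size`, `n_phases`.
#' @export
build_phantom <- function(phantom, waveform, venc = 110, aliasing = FALSE) {
  stopifnot(inherits(phantom, "vessel_phantom"))
  assert_waveform(waveform)
  q <- waveform$flow_rates
  r_cm <- phantom$radius / 10
  vmax <- 2 * max(abs(q)) / (pi * r_cm^2)
  if (!aliasing && vmax > venc) {
    stopf("peak velocity %.1f cm/s exceeds VENC %.1f cm/s; enable aliasing or raise VENC",
          vmax, venc)
  }
  pts <- phantom$centerline_points
  tg <- centerline_tangents(pts)
  vox <- voxel_centres(phantom$grid_shape, phantom$voxel_size)
  ## nearest centerline point per voxel (chunked distance computation)
  nvox <- nrow(vox)
  nearest <- integer(nvox)
  chunk <- 50000L
  p2 <- rowSums(pts^2)
  for (i0 in seq(1, nvox, by = chunk)) {
    i1 <- min(i0 + chunk - 1L, nvox)
    v <- vox[i0:i1, , drop = FALSE]
    d2 <- outer(rowSums(v^2), p2, "+") - 2 * v %*% t(pts)
    nearest[i0:i1] <- max.col(-d2, ties.method = "first")
  }
  d <- vox - pts[nearest, , drop = FALSE]
  tgv <- tg[nearest, , drop = FALSE]
  axial <- rowSums(d * tgv)
  r2 <- pmax(rowSums(d^2) - axial^2, 0)
  spacing <- max(sqrt(rowSums(diff(pts)^2)))
  in_lumen <- r2 <= phantom$radius^2 & abs(axial) <= spacing
  profile <- numeric(nvox)
  profile[in_lumen] <- (1 - r2[in_lumen] / phantom$radius^2) / (pi * r_cm^2)
  np <- length(q)
  dims <- c(phantom$grid_shape, np)
  comp <- lapply(1:3, function(k) {
    arr <- outer(profile * tgv[, k], 2 * q)  # nvox x np
    if (aliasing) arr <- ((arr + venc) %% (2 * venc)) - venc
    array(arr, dim = dims)
  })
  structure(list(vx = comp[[1]], vy = comp[[2]], vz = comp[[3]],
                 n_phases = np, venc = venc,
                 voxel_size = phantom$voxel_size,
                 grid_shape = phantom$grid_shape,
                 phase_times = waveform$times,
                 rr_interval = waveform$rr_interval),
            class = "velocity_field_4d")
}

#' @export
print.velocity_field_4d <- function(x, ...) {
  cat(sprintf("<velocity_field_4d> %s voxels x %d phases, voxel %.2f mm, VENC %g cm/s\n",
              paste(x$grid_shape, collapse = "x"), x$n_phases, x$voxel_size,
              x$venc))
  invisible(x)
}

#' Through-plane flow at a cross-section of the velocity field
#'
#' Sums the tangent-projected velocity over voxels whose centres lie within
#' half a voxel of the plane through `point` normal to `tangent`, times the
#' voxel cross-sectional area, giving volumetric flow in ml/s.
#'
#' @param field A `velocity_field_4d`.
#' @param point Plane centre, mm (length-3).
#' @param tangent Unit normal of the plane (flow direction).
#' @param phase Cardiac phase index (1-based).
#' @param max_radius Only voxels within this lateral distance of `point`
#'   contribute (guards against a curved vessel re-entering the slab);
#'   default `Inf`.
#' @return Flow rate, ml/s.
#' @export
cross_section_flow <- function(field, point, tangent, phase,
                               max_radius = Inf) {
  stopifnot(inherits(field, "velocity_field_4d"))
  point <- as.numeric(point); tangent <- as.numeric(tangent)
  if (length(point) != 3 || length(tangent) != 3) {
    stopf("point and tangent must be length-3")
  }
  tangent <- tangent / sqrt(sum(tangent^2))
  if (phase < 1 || phase > field$n_phases) stopf("phase index out of range")
  extent <- field$grid_shape * field$voxel_size
  if (any(point < 0) || any(point > extent)) {
    stopf("cross-section point lies outside the grid")
  }
  vox <- voxel_centres(field$grid_shape, field$voxel_size)
  d <- sweep(vox, 2, point)
  axial <- d %*% tangent
  ## half-open slab: a plane exactly between two voxel layers counts one
  sel <- axial >= -field$voxel_size / 2 & axial < field$voxel_size / 2
  if (is.finite(max_radius)) {
    lat2 <- rowSums(d^2) - axial^2
    sel <- sel & lat2 <= max_radius^2
  }
  if (!any(sel)) stopf("cross-section plane contains no voxels")
  idx <- which(sel)
  np <- prod(field$grid_shape)
  off <- (phase - 1) * np
  vdot <- field$vx[off + idx] * tangent[1] +
    field$vy[off + idx] * tangent[2] +
    field$vz[off + idx] * tangent[3]
  sum(vdot) * field$voxel_size^2 * MM2_TO_CM2
}

#' Extract a segment flow waveform from six consecutive centerline voxels
#'
#' Per cardiac phase, measures the cross-sectional flow at six consecutive
#' centerline voxels (one voxel apart) and averages them, mirroring the
#' segment-length convention of centerline-based 4D flow processing. The
#' six-voxel span frequently corresponds to the M1 length proximal to its
#' first bifurcation and is used for all segments for consistency.
#'
#' @param field A `velocity_field_4d` built on `phantom`.
#' @param phantom The [vessel_phantom] the field was built on.
#' @param start_voxel Index (1-based) of the first centerline point of the
#'   window.
#' @param n_window Number of consecutive centerline voxels to average
#'   (default 6).
#' @param artery,side Labels for the output waveform.
#' @return A [flow_waveform] with one sample per cardiac phase.
#' @export
extract_centerline_flow <- function(field, phantom, start_voxel = 1,
                                    n_window = 6, artery = "ICA",
                                    side = "unknown") {
  stopifnot(inherits(field, "velocity_field_4d"),
            inherits(phantom, "vessel_phantom"))
  pts <- phantom$centerline_points
  n <- nrow(pts)
  if (start_voxel < 1 || start_voxel + n_window - 1 > n) {
    stopf("need %d consecutive centerline voxels from index %d; only %d available",
          n_window, start_voxel, n - start_voxel + 1)
  }
  tg <- centerline_tangents(pts)
  idx <- start_voxel:(start_voxel + n_window - 1)
  flows <- sapply(seq_len(field$n_phases), function(ph) {
    mean(sapply(idx, function(i) {
      cross_section_flow(field, pts[i, ], tg[i, ], ph,
                         max_radius = 1.5 * phantom$radius)
    }))
  })
  flow_waveform(field$phase_times, flows, field$rr_interval,
                artery = artery, side = side)
}
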