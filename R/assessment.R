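#' Long-axis specification for LV delineation
#'
#' Plays the role of the operator's manual definition of the LV long axis
#' and base plane: delineation casts rays perpendicular to the apex-to-base
#' axis and integrates the cavity up to the base plane (the plane through
#' `base_point_mm` normal to the axis).
#'
#' @param apex_point_mm,base_point_mm Numeric length-3 points in mm, in the
#'   image coordinate system centred on the grid centre.
#' @return An object of class `long_axis_spec` with a unit `normal`.
#' @export
long_axis_spec <- function(apex_point_mm, base_point_mm) {
  apex <- as.numeric(apex_point_mm)
  base <- as.numeric(base_point_mm)
  if (length(apex) != 3L || length(base) != 3L ||
      any(!is.finite(c(apex, base))))
    pg_stop("petgate_invalid_parameter", "apex and base must be finite 3-vectors")
  d <- base - apex
  len <- sqrt(sum(d^2))
  if (len <= 0)
    pg_stop("petgate_invalid_parameter", "apex and base must differ")
  structure(list(apex_point_mm = apex, base_point_mm = base,
                 base_plane_normal = d / len),
            class = "long_axis_spec")
}

#' Long axis of a phantom
#'
#' The "manual" axis definition is exact in simulation: the axis runs along
#' the phantom's z axis from the epicardial apex to the epicardial base.
#'
#' @param phantom A [phantom_spec()].
#' @return A [long_axis_spec()].
#' @export
phantom_long_axis <- function(phantom) {
  c_epi <- phantom$epicardial_semi_axes_mm[3]
  long_axis_spec(c(0, 0, -c_epi), c(0, 0, c_epi))
}

#' Convert gated count images to exposure-normalised rate images
#'
#' Under beat rejection or fixed-width gating, gates accumulate unequal
#' acquisition time; dividing each gate's counts by its exposure makes the
#' gates comparable.  Gates with zero exposure are marked missing rather
#' than set to zero.
#'
#' @param gis A `gated_image_set`.
#' @return A `gated_rate_set`: list with `rates` (per-gate arrays, `NULL`
#'   where missing), `usable` (logical), plus grid metadata.
#' @export
normalize_by_exposure <- function(gis) {
  stopifnot(inherits(gis, "gated_image_set"))
  usable <- gis$exposure_ms > 0
  if (!any(usable))
    pg_stop("petgate_empty_data", "every gate has zero exposure")
  rates <- vector("list", gis$n_gates)
  for (g in which(usable))
    rates[[g]] <- gis$images[[g]] / gis$exposure_ms[g]
  structure(list(rates = rates, usable = usable,
                 voxel_size_mm = gis$voxel_size_mm,
                 grid_shape = gis$grid_shape, n_gates = gis$n_gates),
            class = "gated_rate_set")
}

# Vectorised trilinear interpolation of a 3-D array at continuous voxel
# coordinates (1-based, voxel centres at integers); outside -> 0.
trilinear <- function(img, fx, fy, fz) {
  d <- dim(img)
  out <- numeric(length(fx))
  ok <- fx >= 1 & fx <= d[1] & fy >= 1 & fy <= d[2] & fz >= 1 & fz <= d[3]
  if (!any(ok)) return(out)
  fx <- fx[ok]; fy <- fy[ok]; fz <- fz[ok]
  x0 <- pmin(floor(fx), d[1] - 1L); y0 <- pmin(floor(fy), d[2] - 1L)
  z0 <- pmin(floor(fz), d[3] - 1L)
  tx <- fx - x0; ty <- fy - y0; tz <- fz - z0
  at <- function(ix, iy, iz) img[cbind(ix, iy, iz)]
  v000 <- at(x0, y0, z0);         v100 <- at(x0 + 1, y0, z0)
  v010 <- at(x0, y0 + 1, z0);     v110 <- at(x0 + 1, y0 + 1, z0)
  v001 <- at(x0, y0, z0 + 1);     v101 <- at(x0 + 1, y0, z0 + 1)
  v011 <- at(x0, y0 + 1, z0 + 1); v111 <- at(x0 + 1, y0 + 1, z0 + 1)
  c00 <- v000 * (1 - tx) + v100 * tx
  c10 <- v010 * (1 - tx) + v110 * tx
  c01 <- v001 * (1 - tx) + v101 * tx
  c11 <- v011 * (1 - tx) + v111 * tx
  c0 <- c00 * (1 - ty) + c10 * ty
  c1 <- c01 * (1 - ty) + c11 * ty
  out[ok] <- c0 * (1 - tz) + c1 * tz
  out
}

#' Delineate the LV cavity with an uptake-threshold geometric model
#'
#' Surrogate for threshold-based gated-image analysis: radial rays are cast
#' perpendicular to the LV long axis at equispaced stations between apex
#' and base plane.  On each ray, the endocardial edge is placed at the
#' innermost crossing of `threshold_fraction` times that ray's maximum
#' uptake (sub-sample position by linear interpolation).  The cavity
#' volume is integrated over stations as circular sectors and clipped at
#' the base plane.
#'
#' @param rate_image 3-D array of exposure-normalised activity.
#' @param axis_spec A [long_axis_spec()].
#' @param threshold_fraction Fraction of the per-ray maximum defining the
#'   endocardial edge, in (0, 1); default 0.5.
#' @param voxel_size_mm Voxel edge lengths (mm).
#' @param n_stations Axial stations between apex and base (default 20).
#' @param n_angles Angular sectors per station (default 36).
#' @param r_step_mm Radial sampling step (mm; default 0.5).
#' @param r_max_mm Maximum ray length; defaults to the largest radius that
#'   stays inside the grid.
#' @return Cavity volume in mL.
#' @export
delineate_lv <- function(rate_image, axis_spec, threshold_fraction = 0.5,
                         voxel_size_mm, n_stations = 20, n_angles = 36,
                         r_step_mm = 0.5, r_max_mm = NULL) {
  stopifnot(inherits(axis_spec, "long_axis_spec"))
  check_scalar_number(threshold_fraction, "threshold_fraction",
                      lower = 0, upper = 1,
                      strict_lower = TRUE, strict_upper = TRUE)
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3L)
  d <- dim(rate_image)
  if (is.null(d) || length(d) != 3L)
    pg_stop("petgate_invalid_parameter", "rate_image must be a 3-D array")
  mx <- max(rate_image)
  mn <- min(rate_image)
  if (!is.finite(mx) || mx <= 0 || mx - mn <= 1e-12 * max(mx, 1))
    pg_stop("petgate_delineation_failure",
            "no supra-threshold myocardium found in image")

  if (is.null(r_max_mm))
    r_max_mm <- min(d * voxel_size_mm) / 2 - max(voxel_size_mm)
  u <- axis_spec$base_plane_normal
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- c(u[2] * ref[3] - u[3] * ref[2],
          u[3] * ref[1] - u[1] * ref[3],
          u[1] * ref[2] - u[2] * ref[1])
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(u[2] * e1[3] - u[3] * e1[2],
          u[3] * e1[1] - u[1] * e1[3],
          u[1] * e1[2] - u[2] * e1[1])

  L <- sqrt(sum((axis_spec$base_point_mm - axis_spec$apex_point_mm)^2))
  dz <- L / n_stations
  st <- (seq_len(n_stations) - 0.5) * dz
  theta <- (seq_len(n_angles) - 1) * 2 * pi / n_angles
  radii <- seq(0, r_max_mm, by = r_step_mm)
  nr <- length(radii)

  # sample points: radius fastest, then angle, then station
  grid <- expand.grid(r = radii, th = theta, s = st)
  dir1 <- cos(grid$th)
  dir2 <- sin(grid$th)
  px <- axis_spec$apex_point_mm[1] + grid$s * u[1] +
    grid$r * (dir1 * e1[1] + dir2 * e2[1])
  py <- axis_spec$apex_point_mm[2] + grid$s * u[2] +
    grid$r * (dir1 * e1[2] + dir2 * e2[2])
  pz <- axis_spec$apex_point_mm[3] + grid$s * u[3] +
    grid$r * (dir1 * e1[3] + dir2 * e2[3])
  fx <- px / voxel_size_mm[1] + (d[1] + 1) / 2
  fy <- py / voxel_size_mm[2] + (d[2] + 1) / 2
  fz <- pz / voxel_size_mm[3] + (d[3] + 1) / 2
  vals <- matrix(trilinear(rate_image, fx, fy, fz), nrow = nr)

  n_rays <- ncol(vals)
  edge_r <- numeric(n_rays)
  for (j in seq_len(n_rays)) {
    prof <- vals[, j]
    vmax <- max(prof)
    if (vmax <= 0) { edge_r[j] <- 0; next }
    level <- threshold_fraction * vmax
    if (prof[1] >= level) { edge_r[j] <- 0; next }
    i <- which(prof >= level)[1]
    # linear interpolation of the crossing between samples i-1 and i
    denom <- prof[i] - prof[i - 1]
    frac <- if (denom > 0) (level - prof[i - 1]) / denom else 0
    edge_r[j] <- radii[i - 1] + frac * r_step_mm
  }

  area <- colSums(matrix(edge_r^2, nrow = n_angles)) * pi / n_angles
  sum(area) * dz / 1000
}

#' Per-gate LV volume curve from a gated image set
#'
#' Applies [delineate_lv()] to each exposure-normalised gate image.  Gates
#' with zero exposure, or where delineation fails, are recorded as missing
#' (`NA`), not zero.
#'
#' @param gis A `gated_image_set`.
#' @param axis_spec A [long_axis_spec()].
#' @param threshold_fraction Passed to [delineate_lv()].
#' @param ... Further arguments to [delineate_lv()].
#' @return A `volume_curve`: list with `volume_ml` (length `n_gates`, `NA`
#'   where missing), `exposure_ms` and `n_gates`.
#' @export
volume_curve <- function(gis, axis_spec, threshold_fraction = 0.5, ...) {
  rs <- normalize_by_exposure(gis)
  vol <- rep(NA_real_, rs$n_gates)
  for (g in which(rs$usable)) {
    vol[g] <- tryCatch(
      delineate_lv(rs$rates[[g]], axis_spec, threshold_fraction,
                   rs$voxel_size_mm, ...),
      petgate_delineation_failure = function(e) NA_real_)
  }
  structure(list(volume_ml = vol, exposure_ms = gis$exposure_ms,
                 n_gates = rs$n_gates),
            class = "volume_curve")
}

#' @export
print.volume_curve <- function(x, ...) {
  cat(sprintf("LV volume curve over %d gates (mL): %s\n", x$n_gates,
              paste(ifelse(is.na(x$volume_ml), "NA",
                           sprintf("%.1f", x$volume_ml)), collapse = ", ")))
  invisible(x)
}

#' Automatic end-diastolic / end-systolic phase detection
#'
#' The end-diastolic gate is the one with maximal cavity volume and the
#' end-systolic gate the one with minimal volume; ties are broken toward
#' the lower gate index and missing gates are skipped.
#'
#' @param vcurve A `volume_curve`.
#' @return Named integer vector `c(ed_gate, es_gate)` with 0-based indices.
#' @export
detect_ed_es <- function(vcurve) {
  stopifnot(inherits(vcurve, "volume_curve"))
  v <- vcurve$volume_ml
  if (sum(!is.na(v)) < 2L)
    pg_stop("petgate_insufficient_data",
            "need at least two usable gates for ED/ES detection")
  vmax <- replace(v, is.na(v), -Inf)
  vmin <- replace(v, is.na(v), Inf)
  c(ed_gate = which.max(vmax) - 1L, es_gate = which.min(vmin) - 1L)
}

#' Global function parameters from a volume curve
#'
#' EDV and ESV are the volumes at the automatically detected end-diastolic
#' and end-systolic gates; EF = 100 (EDV - ESV) / EDV.
#'
#' @param x A `volume_curve`, or a single EDV value in mL.
#' @param esv_ml ESV in mL, when `x` is a numeric EDV.
#' @return A `function_params` object (`edv_ml`, `esv_ml`, `ef_pct`).
#' @export
function_params <- function(x, esv_ml = NULL) {
  if (inherits(x, "volume_curve")) {
    phase <- detect_ed_es(x)
    return(new_function_params(x$volume_ml[phase["ed_gate"] + 1L],
                               x$volume_ml[phase["es_gate"] + 1L]))
  }
  if (is.numeric(x) && length(x) == 1L && !is.null(esv_ml))
    return(new_function_params(x, esv_ml))
  pg_stop("petgate_invalid_parameter",
          "supply a volume_curve, or edv_ml and esv_ml")
}
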