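#' Dynamic ellipsoidal-shell left-ventricle phantom
#'
#' Defines the geometry and activity of a synthetic beating LV: a
#' myocardial shell between a fixed outer (epicardial) ellipsoid and an
#' inner (endocardial) cavity ellipsoid whose volume follows the cyclic
#' volume curve of [volume_model()].  The cavity keeps a fixed axis ratio
#' and is rescaled isotropically so that its volume matches any requested
#' value between `esv_ml` and `edv_ml`.  The long axis lies along the
#' third (z) grid axis and the phantom is centred in the voxel grid.
#'
#' @param grid_shape Integer vector of length 3 (or a scalar, recycled):
#'   voxels per axis.
#' @param voxel_size_mm Voxel edge lengths in mm (scalar or length 3).
#' @param edv_ml End-diastolic cavity volume (mL).
#' @param esv_ml End-systolic cavity volume (mL); must satisfy
#'   `0 < esv_ml < edv_ml`.
#' @param wall_thickness_mm Myocardial wall thickness added to the
#'   end-diastolic cavity semi-axes to obtain the epicardial ellipsoid when
#'   `epicardial_semi_axes_mm` is not given.
#' @param epicardial_semi_axes_mm Optional explicit outer semi-axes (mm).
#' @param long_axis_ratio Ratio of the cavity's long (z) to short semi-axis.
#' @param myocardium_activity Relative emission rate per myocardial voxel.
#' @param background_activity Relative emission rate elsewhere (cavity and
#'   surroundings).
#' @param t_sys_ms Duration of the systolic contraction phase (ms); held
#'   constant across beats, reflecting the physiological finding that
#'   systole duration varies little with cycle length.
#'
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(64, 64, 64),
                         voxel_size_mm = c(2, 2, 2),
                         edv_ml = 160, esv_ml = 82,
                         wall_thickness_mm = 9,
                         epicardial_semi_axes_mm = NULL,
                         long_axis_ratio = 1.55,
                         myocardium_activity = 1,
                         background_activity = 0.05,
                         t_sys_ms = 300) {
  if (length(grid_shape) == 1L) grid_shape <- rep(grid_shape, 3L)
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3L)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 4L))
    pg_stop("petgate_invalid_parameter", "grid_shape must be 3 values >= 4")
  if (length(voxel_size_mm) != 3L || any(!is.finite(voxel_size_mm)) ||
      any(voxel_size_mm <= 0))
    pg_stop("petgate_invalid_parameter", "voxel_size_mm must be positive")
  check_scalar_number(edv_ml, "edv_ml", lower = 0, strict_lower = TRUE)
  check_scalar_number(esv_ml, "esv_ml", lower = 0, strict_lower = TRUE)
  if (esv_ml >= edv_ml)
    pg_stop("petgate_invalid_parameter", "esv_ml must be smaller than edv_ml")
  check_scalar_number(long_axis_ratio, "long_axis_ratio",
                      lower = 0, strict_lower = TRUE)
  check_scalar_number(myocardium_activity, "myocardium_activity", lower = 0)
  check_scalar_number(background_activity, "background_activity", lower = 0)
  check_scalar_number(t_sys_ms, "t_sys_ms", lower = 0, strict_lower = TRUE)

  # end-diastolic cavity semi-axes: a = b, c = ratio * a, volume = edv
  a <- (edv_ml * 1000 * 3 / (4 * pi * long_axis_ratio))^(1 / 3)
  cavity_semi_axes_mm <- c(a, a, long_axis_ratio * a)
  if (is.null(epicardial_semi_axes_mm)) {
    check_scalar_number(wall_thickness_mm, "wall_thickness_mm",
                        lower = 0, strict_lower = TRUE)
    epicardial_semi_axes_mm <- cavity_semi_axes_mm + wall_thickness_mm
  }
  if (length(epicardial_semi_axes_mm) != 3L ||
      any(epicardial_semi_axes_mm <= cavity_semi_axes_mm))
    pg_stop("petgate_invalid_parameter",
            "end-diastolic cavity must lie strictly inside the epicardial ellipsoid")
  half_extent <- grid_shape * voxel_size_mm / 2
  if (any(epicardial_semi_axes_mm >= half_extent))
    pg_stop("petgate_invalid_parameter",
            "epicardial ellipsoid does not fit inside the voxel grid")

  structure(list(grid_shape = grid_shape,
                 voxel_size_mm = as.numeric(voxel_size_mm),
                 edv_ml = edv_ml, esv_ml = esv_ml,
                 cavity_semi_axes_mm = cavity_semi_axes_mm,
                 epicardial_semi_axes_mm = as.numeric(epicardial_semi_axes_mm),
                 myocardium_activity = myocardium_activity,
                 background_activity = background_activity,
                 t_sys_ms = t_sys_ms),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf(
    "LV phantom: grid %s @ %s mm, EDV %.0f mL, ESV %.0f mL (EF %.1f%%), t_sys %.0f ms\n",
    paste(x$grid_shape, collapse = "x"),
    paste(signif(x$voxel_size_mm, 3), collapse = "x"),
    x$edv_ml, x$esv_ml, 100 * (x$edv_ml - x$esv_ml) / x$edv_ml, x$t_sys_ms))
  invisible(x)
}

#' Cyclic left-ventricular volume curve
#'
#' Cavity volume within one beat: a cosine interpolation from EDV down to
#' ESV over the fixed systolic phase `[0, t_sys_ms]`, followed by a linear
#' diastolic refill from ESV back to EDV over the remainder of the R-R
#' interval.  Because systole has fixed duration, the early-cycle volumes
#' are identical across beats of different length.
#'
#' @param shape Curve family; only `"cosine_linear"` is implemented.
#' @param t_sys_ms Systole duration in ms.
#' @return An object of class `volume_model`.
#' @export
volume_model <- function(shape = "cosine_linear", t_sys_ms = 300) {
  shape <- match.arg(shape, "cosine_linear")
  check_scalar_number(t_sys_ms, "t_sys_ms", lower = 0, strict_lower = TRUE)
  structure(list(shape = shape, t_sys_ms = t_sys_ms), class = "volume_model")
}

#' Cavity volume at a time point within a beat
#'
#' @param t_since_r_ms Time since the R peak opening the beat (ms); may be
#'   a vector.  Must satisfy `0 <= t < rr_ms`.
#' @param rr_ms Duration of the beat's R-R interval (ms); scalar or vector
#'   matching `t_since_r_ms`.
#' @param phantom A [phantom_spec()].
#' @param model A [volume_model()].
#' @return Cavity volume(s) in mL.  If `rr_ms <= t_sys_ms` the systolic
#'   phase is compressed to fit the beat.
#' @export
lv_volume_at <- function(t_since_r_ms, rr_ms, phantom, model) {
  if (any(!is.finite(t_since_r_ms)) || any(t_since_r_ms < 0))
    pg_stop("petgate_invalid_parameter", "t_since_r_ms must be >= 0")
  if (any(!is.finite(rr_ms)) || any(rr_ms <= 0))
    pg_stop("petgate_invalid_parameter", "rr_ms must be positive")
  if (any(t_since_r_ms >= rr_ms))
    pg_stop("petgate_invalid_parameter", "t_since_r_ms must be < rr_ms")
  edv <- phantom$edv_ml
  esv <- phantom$esv_ml
  tsys <- pmin(model$t_sys_ms, rr_ms)
  n <- max(length(t_since_r_ms), length(rr_ms))
  t <- rep_len(t_since_r_ms, n)
  rr <- rep_len(rr_ms, n)
  tsys <- rep_len(tsys, n)
  v <- numeric(n)
  sys <- t <= tsys
  v[sys] <- esv + (edv - esv) / 2 * (1 + cos(pi * t[sys] / tsys[sys]))
  dia <- !sys
  v[dia] <- esv + (edv - esv) * (t[dia] - tsys[dia]) / (rr[dia] - tsys[dia])
  v
}

# Per-voxel normalised squared radii for the phantom grid: r2_epi relative
# to the epicardial ellipsoid, r_cav relative to the end-diastolic cavity
# ellipsoid (so a cavity scaled by s contains a voxel iff r_cav <= s).
phantom_geometry <- function(phantom) {
  n <- phantom$grid_shape
  h <- phantom$voxel_size_mm
  coords <- lapply(1:3, function(k) (seq_len(n[k]) - (n[k] + 1) / 2) * h[k])
  sq <- function(axes, k) (coords[[k]] / axes[k])^2
  tile3 <- function(x2, y2, z2) {
    rep(x2, times = n[2] * n[3]) +
      rep(rep(y2, each = n[1]), times = n[3]) +
      rep(z2, each = n[1] * n[2])
  }
  ae <- phantom$epicardial_semi_axes_mm
  ac <- phantom$cavity_semi_axes_mm
  list(r2_epi = tile3(sq(ae, 1), sq(ae, 2), sq(ae, 3)),
       r_cav = sqrt(tile3(sq(ac, 1), sq(ac, 2), sq(ac, 3))),
       n_vox = prod(n))
}

cavity_scale <- function(phantom, cavity_volume_ml) {
  (cavity_volume_ml / phantom$edv_ml)^(1 / 3)
}

#' Render a single activity frame of the phantom
#'
#' Voxels whose centres lie inside the epicardial ellipsoid but outside the
#' cavity ellipsoid (rescaled isotropically to the requested volume) carry
#' `myocardium_activity`; all other voxels carry `background_activity`.
#'
#' @param phantom A [phantom_spec()].
#' @param cavity_volume_ml Cavity volume; must lie in `[esv_ml, edv_ml]`.
#' @return A 3-D numeric array of relative activity with dim `grid_shape`.
#' @export
render_frame <- function(phantom, cavity_volume_ml) {
  check_scalar_number(cavity_volume_ml, "cavity_volume_ml",
                      lower = phantom$esv_ml, upper = phantom$edv_ml)
  geo <- phantom_geometry(phantom)
  s <- cavity_scale(phantom, cavity_volume_ml)
  myo <- geo$r2_epi <= 1 & geo$r_cav > s
  img <- rep(phantom$background_activity, geo$n_vox)
  img[myo] <- phantom$myocardium_activity
  array(img, dim = phantom$grid_shape)
}

#' Noise-free multi-phase reference function parameters
#'
#' Emulates the volumetric reference modality (CINE MR sampling the cardiac
#' cycle at a fixed number of phases): the analytic volume curve is sampled
#' at `n_phases` equispaced phases anchored at the R peak, and EDV/ESV are
#' its maximum and minimum.
#'
#' @param phantom A [phantom_spec()].
#' @param model A [volume_model()].
#' @param rr_ms R-R interval of the sampled beat (ms).
#' @param n_phases Number of cardiac phases (default 25).
#' @return A `function_params` object with fields `edv_ml`, `esv_ml`,
#'   `ef_pct`.
#' @export
reference_function_params <- function(phantom, model, rr_ms, n_phases = 25) {
  check_scalar_number(rr_ms, "rr_ms", lower = 0, strict_lower = TRUE)
  check_scalar_number(n_phases, "n_phases", lower = 2)
  t <- (seq_len(n_phases) - 1) * rr_ms / n_phases
  v <- lv_volume_at(t, rr_ms, phantom, model)
  new_function_params(max(v), min(v))
}

new_function_params <- function(edv_ml, esv_ml) {
  if (!is.finite(edv_ml) || edv_ml <= 0)
    pg_stop("petgate_invalid_result", "EDV must be positive")
  structure(list(edv_ml = edv_ml, esv_ml = esv_ml,
                 ef_pct = 100 * (edv_ml - esv_ml) / edv_ml),
            class = "function_params")
}

#' @export
print.function_params <- function(x, ...) {
  cat(sprintf("EDV %.1f mL, ESV %.1f mL, EF %.1f%%\n",
              x$edv_ml, x$esv_ml, x$ef_pct))
  invisible(x)
}
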