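# Shared fixtures: a small, fast phantom for unit tests and a regular
# zero-variance R-peak train builder.

small_phantom <- function(edv_ml = 120, esv_ml = 60, ...) {
  phantom_spec(grid_shape = 32, voxel_size_mm = 3.5,
               edv_ml = edv_ml, esv_ml = esv_ml, ...)
}

regular_train <- function(n_beats, rr_ms = 1000) {
  ts <- (0:n_beats) * rr_ms
  structure(list(timestamps_ms = ts,
                 labels = rep("normal", n_beats),
                 duration_ms = ts[length(ts)]),
            class = "rpeak_train")
}

# brute-force voxelisation oracle: myocardial voxel count by explicit
# voxel-centre membership in the analytic ellipsoids
oracle_myo_count <- function(phantom, cavity_volume_ml) {
  n <- phantom$grid_shape
  h <- phantom$voxel_size_mm
  g <- expand.grid(x = (seq_len(n[1]) - (n[1] + 1) / 2) * h[1],
                   y = (seq_len(n[2]) - (n[2] + 1) / 2) * h[2],
                   z = (seq_len(n[3]) - (n[3] + 1) / 2) * h[3])
  ae <- phantom$epicardial_semi_axes_mm
  ac <- phantom$cavity_semi_axes_mm * (cavity_volume_ml / phantom$edv_ml)^(1 / 3)
  in_epi <- (g$x / ae[1])^2 + (g$y / ae[2])^2 + (g$z / ae[3])^2 <= 1
  in_cav <- (g$x / ac[1])^2 + (g$y / ac[2])^2 + (g$z / ac[3])^2 <= 1
  sum(in_epi & !in_cav)
}
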