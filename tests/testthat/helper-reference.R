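# Shared fixtures: the packaged reference two-phase curves and small
# builders used across test files.

ref_growth <- function() reference_params("growth")
ref_regression <- function() reference_params("regression")

# Build a minimal single-lesion observation table from a logistic curve.
obs_from_curve <- function(params, days, animal = "pig01", lesion = "site1",
                           conv = cell_volume_conversion()) {
  data.frame(animal_id = animal, lesion_id = lesion, day = days,
             volume_mm3 = volume_at(params, days, conv),
             surface_mm2 = NA_real_, detected = TRUE)
}

# Exact lattice-point count inside a sphere of radius r (voxel units),
# voxel centres at half-integer offsets from the array centre.
lattice_sphere_count <- function(r, n) {
  g <- seq_len(n) - 0.5 - n / 2
  sum(outer(outer(g^2, g^2, `+`), g^2, `+`) <= r^2)
}

# Digital sphere label array of radius r voxels in an n^3 grid.
digital_sphere <- function(r, n = 2 * ceiling(r) + 5) {
  g <- seq_len(n) - 0.5 - n / 2
  arr <- array(0L, c(n, n, n))
  arr[outer(outer(g^2, g^2, `+`), g^2, `+`) <= r^2] <- 1L
  arr
}
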