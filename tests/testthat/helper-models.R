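# Small fixtures built in code: a short filament and compact maps keep
# the unit tests fast; full-size recovery runs live in the acceptance
# tests.

small_params <- function() helical_params()

# Blocked thin filament, 18 genetic subunits (functional unit + flanks).
blocked_model <- function(n = 18, params = small_params()) {
  m <- build_actin_filament(n, params)
  m <- add_tropomyosin(m)
  add_troponin(m)
}

# Mixed-state (Ca2+-treated-like) model: a-c at 28 deg, d-g at 18 deg.
mixed_model <- function(n = 18, params = small_params()) {
  m <- build_actin_filament(n, params)
  m <- add_tropomyosin(m, repeat_azimuths(a = 28, b = 28, c = 28,
                                          d = 18, e = 18, f = 18, g = 18))
  add_troponin(m)
}

# A stubby actin-only filament and map for docking unit tests.
stub_actin <- function(n = 8, params = small_params()) {
  build_actin_filament(n, params)
}

stub_map <- function(model, box = c(48, 48, 64), voxel = 4, resolution = 28) {
  render_map(model, voxel = voxel, resolution = resolution, box = box)
}

# A single free-standing Gaussian blob model at a given position.
blob_model <- function(xyz = c(0, 0, 0), weight = 10) {
  df <- data.frame(x = xyz[1], y = xyz[2], z = xyz[3], weight = weight,
                   component = "actin", strand = 1L, subunit_index = 0L,
                   subunit_label = NA_character_, residue_tag = NA_character_,
                   in_unit = FALSE, stringsAsFactors = FALSE)
  thinfilament:::new_filament_model(df, small_params())
}

expect_angle_equal <- function(a, b, tol) {
  expect_lt(abs(wrap_angle(a - b)), tol)
}
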