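#' Construct a density map object
#'
#' A 3D scalar grid with MRC semantics: isotropic voxel size, a physical
#' origin (position of voxel `[1,1,1]`), x the fastest-varying axis.
#'
#' @param grid 3D numeric array.
#' @param voxel Voxel edge length (Angstrom).
#' @param origin Length-3 numeric, position of the first voxel (Angstrom).
#' @param resolution Nominal resolution of the content (Angstrom) or `NA`.
#' @return An object of class `density_map`.
#' @export
density_map <- function(grid, voxel, origin = c(0, 0, 0), resolution = NA) {
  if (!is.array(grid) || length(dim(grid)) != 3)
    stopf("invalid-argument: grid must be a 3D array")
  if (any(dim(grid) < 2)) stopf("invalid-argument: grid dimensions must be >= 2")
  if (!is.numeric(voxel) || voxel <= 0)
    stopf("invalid-argument: voxel_size must be positive")
  if (!all(is.finite(grid))) stopf("invalid-argument: grid values must be finite")
  structure(list(grid = grid, voxel = voxel, origin = as.numeric(origin),
                 resolution = resolution),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  d <- dim(x$grid)
  cat(sprintf("Density map %dx%dx%d, voxel %.2f A, origin (%.1f, %.1f, %.1f)\n",
              d[1], d[2], d[3], x$voxel, x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Gaussian width for a nominal resolution
#'
#' The package renders each particle as an isotropic Gaussian whose
#' Fourier amplitude falls to 1/e at spatial frequency `1/resolution`:
#' `sigma = resolution / (sqrt(2) * pi)` (6.30 Angstrom at 28 Angstrom
#' resolution).  This is the operational definition of "resolution" for
#' all model-derived maps in the package.
#'
#' @param resolution Nominal resolution (Angstrom).
#' @return Real-space standard deviation sigma (Angstrom).
#' @export
resolution_sigma <- function(resolution) resolution / (sqrt(2) * pi)

# Physical coordinates of the voxel centres of a map along each axis.
map_axes <- function(map) {
  d <- dim(map$grid)
  lapply(1:3, function(i) map$origin[i] + map$voxel * (seq_len(d[i]) - 1))
}

# Coordinates (m x 3) of the voxels at the given 1-based flat indices.
voxel_coords <- function(map, idx) {
  d <- dim(map$grid)
  idx0 <- idx - 1L
  i <- idx0 %% d[1]
  j <- (idx0 %/% d[1]) %% d[2]
  k <- idx0 %/% (d[1] * d[2])
  cbind(map$origin[1] + map$voxel * i,
        map$origin[2] + map$voxel * j,
        map$origin[3] + map$voxel * k)
}

#' Render an EM-like density map from a filament model
#'
#' Each particle contributes a weight-scaled normalised isotropic
#' Gaussian of width [resolution_sigma()]; the integral of the map over
#' space equals the total particle weight (up to the finite Gaussian
#' cutoff, within 1 percent).  The grid is centred on the filament axis
#' (x = y = 0) and on the model's axial midpoint unless an origin is
#' given.
#'
#' @param model A `filament_model` (or any object with `x,y,z,weight`).
#' @param voxel Voxel size (Angstrom); default 4 (7-fold oversampled at
#'   the default 28 Angstrom resolution).
#' @param resolution Nominal resolution (Angstrom); must be at least
#'   `2 * voxel` (Nyquist).
#' @param box Grid dimensions, length-3 integer (nx, ny, nz).
#' @param origin Optional explicit origin (Angstrom).
#' @param cutoff_sd Gaussian truncation radius in standard deviations.
#' @return A `density_map` carrying the rendering resolution.
#' @export
render_map <- function(model, voxel = 4, resolution = 28,
                       box = c(96, 96, 96), origin = NULL,
                       cutoff_sd = 4.5) {
  if (resolution < 2 * voxel)
    stopf("invalid-argument: resolution %.3g A violates Nyquist for voxel %.3g A",
          resolution, voxel)
  box <- as.integer(box)
  coords <- model_coords(model)
  if (is.null(origin)) {
    zmid <- mean(range(coords[, 3]))
    origin <- c(-(box[1] - 1) / 2 * voxel,
                -(box[2] - 1) / 2 * voxel,
                zmid - (box[3] - 1) / 2 * voxel)
  }
  hi <- origin + (box - 1) * voxel
  inside <- coords[, 1] >= origin[1] & coords[, 1] <= hi[1] &
            coords[, 2] >= origin[2] & coords[, 2] <= hi[2] &
            coords[, 3] >= origin[3] & coords[, 3] <= hi[3]
  if (!all(inside))
    stopf("invalid-argument: %d particles lie outside the box", sum(!inside))
  sigma <- resolution_sigma(resolution)
  v <- cpp_render_gaussians(box, voxel, origin, coords, model$weight,
                            sigma, cutoff_sd)
  density_map(array(v, dim = box), voxel, origin, resolution = resolution)
}

#' Noise specification for simulated maps
#'
#' @param snr Ratio of signal variance to noise variance, measured within
#'   the filament envelope (must be positive; `Inf` means no noise).
#' @param seed Integer seed controlling the noise realisation.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(snr, seed = 1L) {
  if (!is.numeric(snr) || snr <= 0)
    stopf("invalid-argument: snr must be positive")
  structure(list(snr = snr, seed = as.integer(seed)), class = "noise_spec")
}

#' Binary mask of the filament envelope
#'
#' Voxels whose (noise-free) density exceeds a fraction of the maximum;
#' used to calibrate noise against signal variance.
#'
#' @param map A clean `density_map`.
#' @param frac Threshold fraction of the map maximum.
#' @return Logical array of the grid's dimensions.
#' @export
filament_envelope <- function(map, frac = 0.02) {
  map$grid > frac * max(map$grid)
}

#' Add white Gaussian noise at a target envelope signal-to-noise ratio
#'
#' Independent zero-mean Gaussian noise is added to every voxel.  Its
#' variance is the variance of the input map within the filament
#' envelope divided by `spec$snr`, so the realised variance ratio inside
#' the envelope matches the requested SNR.  Negative-stain contrast is
#' taken as already normalised: protein density is positive.
#'
#' @param map A clean `density_map`.
#' @param spec A [noise_spec()].
#' @return A `density_map` with noise added (input returned unchanged for
#'   infinite SNR).
#' @export
add_noise <- function(map, spec) {
  if (!inherits(spec, "noise_spec")) spec <- do.call(noise_spec, as.list(spec))
  if (!is.finite(spec$snr)) return(map)
  env <- filament_envelope(map)
  sig_var <- var(map$grid[env])
  if (!is.finite(sig_var) || sig_var == 0)
    stopf("degenerate-input: map has no signal variance in its envelope")
  sd_noise <- sqrt(sig_var / spec$snr)
  noisy <- with_seed(spec$seed, {
    map$grid + array(rnorm(length(map$grid), 0, sd_noise), dim(map$grid))
  })
  out <- map
  out$grid <- noisy
  out
}

#' Render a pair of half maps with independent noise
#'
#' Both maps share the identical rendered signal; each receives an
#' independent noise realisation (sub-seeds derived from `spec$seed`), as
#' in half-map resolution estimation by Fourier shell correlation.
#'
#' @inheritParams render_map
#' @param spec A [noise_spec()].
#' @return A list of two `density_map`s.
#' @export
half_map_pair <- function(model, voxel = 4, resolution = 28, spec,
                          box = c(96, 96, 96), origin = NULL) {
  clean <- render_map(model, voxel, resolution, box, origin)
  if (!is.finite(spec$snr)) return(list(clean, clean))
  seeds <- derive_seeds(spec$seed, 2)
  list(add_noise(clean, noise_spec(spec$snr, seeds[1])),
       add_noise(clean, noise_spec(spec$snr, seeds[2])))
}
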