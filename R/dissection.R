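#' Least-squares amplitude scale between a map and a model map
#'
#' The scalar `s` minimising `sum((map - s * model_map)^2)` over the
#' model mask: `s = <map, model> / <model, model>`.  By default the mask
#' is the support of the model density (rendered Gaussians are
#' compactly truncated), so voxels far from the model never influence
#' the estimate.
#'
#' @param map,model_map `density_map`s on identical grids.
#' @param mask Optional logical array selecting the voxels to use.
#' @return The scale factor (positive for any overlapping signal).
#' @export
amplitude_scale <- function(map, model_map, mask = NULL) {
  if (!all(dim(map$grid) == dim(model_map$grid)) ||
      abs(map$voxel - model_map$voxel) > 1e-9)
    stopf("invalid-argument: map and model map grids differ")
  if (is.null(mask)) mask <- model_map$grid != 0
  mm <- sum(model_map$grid[mask]^2)
  if (!is.finite(mm) || mm == 0)
    stopf("degenerate-input: model density is zero within the mask")
  sum(map$grid[mask] * model_map$grid[mask]) / mm
}

#' Subtract a docked component's model density from a map
#'
#' The two-stage dissection: stage 1 subtracts the docked F-actin model
#' density, leaving the rod-like tropomyosin strands plus the globular
#' troponin densities; stage 2 subtracts actin plus tropomyosin, leaving
#' troponin alone.  The model density is rendered on the map's grid at
#' the map's nominal resolution, scaled by a single least-squares factor
#' per subtraction event, and subtracted voxel-wise, so that
#' `difference + s * model_density` reconstructs the input exactly.
#'
#' @param map A `density_map`.
#' @param model A docked `filament_model` (pose already applied; see
#'   [apply_transform()] / [mark_docked()]).
#' @param component `"actin"`, `"actin_tropomyosin"`, or a character
#'   vector of component names (e.g. `c("actin","tropomyosin","troponin")`).
#' @param scale `TRUE` (fit the least-squares amplitude scale, default),
#'   `FALSE` (subtract unscaled model density), or a number to use as
#'   the scale directly (e.g. to share one joint scale across staged
#'   subtractions).
#' @param resolution Rendering resolution; defaults to the map's.
#' @return A `difference_map` (a `density_map` with attributes
#'   `subtracted_components`, `scale_factor`, `model_map`).
#' @export
subtract_component <- function(map, model,
                               component = c("actin", "actin_tropomyosin"),
                               scale = TRUE, resolution = NULL) {
  if (!isTRUE(attr(model, "docked")))
    stopf("invalid-state: model must be docked before subtraction (see mark_docked)")
  if (identical(component, c("actin", "actin_tropomyosin")))
    component <- "actin"  # default stage
  comps <- if (identical(component, "actin_tropomyosin"))
    c("actin", "tropomyosin") else component
  sel <- select_particles(model, component = comps)
  if (!any(sel)) stopf("invalid-argument: no particles of component %s",
                       paste(comps, collapse = "+"))
  resolution <- resolution %||% map$resolution
  sub <- model[sel, , drop = FALSE]
  mm <- render_map(sub, voxel = map$voxel, resolution = resolution,
                   box = dim(map$grid), origin = map$origin)
  s <- if (is.numeric(scale)) scale
       else if (isTRUE(scale)) amplitude_scale(map, mm) else 1
  out <- map
  out$grid <- map$grid - s * mm$grid
  attr(out, "subtracted_components") <- comps
  attr(out, "scale_factor") <- s
  attr(out, "model_map") <- mm
  class(out) <- c("difference_map", class(map))
  out
}

#' Zero a difference map outside the neighbourhood of one component
#'
#' Retains voxels within `radius` of the named component's particles and
#' zeroes everything else; used to isolate e.g. the troponin blob or the
#' TnT1 tail before span and stagger measurements.
#'
#' @param diff A `density_map` or `difference_map`.
#' @param model The docked `filament_model` providing the particle
#'   positions.
#' @param component Component name(s).
#' @param radius Retention radius (Angstrom); `Inf` returns the map
#'   unchanged.
#' @param strand,tag Optional extra selectors (see [select_particles()]).
#' @param exclusive Additionally require retained voxels to lie closer to
#'   the selected particles than to any other particle of the model
#'   (nearest-component zoning, useful to keep e.g. the TnT1 tail free of
#'   troponin-core density).
#' @return A `density_map` of the same geometry.
#' @export
segment_component <- function(diff, model, component, radius,
                              strand = NULL, tag = NULL, exclusive = FALSE) {
  sel <- select_particles(model, component = component, strand = strand,
                          tag = tag)
  if (!any(sel)) stopf("degenerate-input: empty component selection")
  if (!is.finite(radius)) return(diff)
  idx <- cpp_mask_near_points(dim(diff$grid), diff$voxel, diff$origin,
                              model_coords(model, sel), radius, 1L)
  if (exclusive && any(!sel)) {
    pts <- voxel_coords(diff, idx)
    dsel <- min_dist2(pts, model_coords(model, sel))
    doth <- min_dist2(pts, model_coords(model, !sel))
    idx <- idx[dsel <= doth]
  }
  g <- array(0, dim(diff$grid))
  g[idx] <- diff$grid[idx]
  out <- diff
  out$grid <- g
  class(out) <- "density_map"
  attr(out, "subtracted_components") <- attr(diff, "subtracted_components")
  out
}

# Squared distance from each point to its nearest row of `coords`.
min_dist2 <- function(pts, coords) {
  dmin <- rep(Inf, nrow(pts))
  for (p in seq_len(nrow(coords))) {
    dd <- (pts[, 1] - coords[p, 1])^2 + (pts[, 2] - coords[p, 2])^2 +
          (pts[, 3] - coords[p, 3])^2
    dmin <- pmin(dmin, dd)
  }
  dmin
}

#' Joint least-squares amplitude scales for overlapping model maps
#'
#' When two rendered components overlap in space (e.g. the troponin core
#' and the TnT1 tail), per-component scales fitted one at a time absorb
#' each other's density; the joint linear least-squares solution
#' `map ~ sum_i s_i * model_i` over the union of the model supports
#' separates them correctly.
#'
#' @param map A `density_map`.
#' @param model_maps Named list of `density_map`s on the same grid.
#' @param mask Optional logical array; default is the union of supports.
#' @return Named numeric vector of scale factors.
#' @export
amplitude_scales <- function(map, model_maps, mask = NULL) {
  if (is.null(mask)) {
    mask <- Reduce(`|`, lapply(model_maps, function(m) m$grid != 0))
  }
  A <- vapply(model_maps, function(m) m$grid[mask], numeric(sum(mask)))
  M <- crossprod(A)
  if (rcond(M) < 1e-12)
    stopf("degenerate-input: model maps are collinear within the mask")
  s <- solve(M, crossprod(A, map$grid[mask]))
  stats::setNames(as.numeric(s), names(model_maps))
}
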