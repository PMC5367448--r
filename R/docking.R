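#' Rigid-body transforms
#'
#' A proper rotation plus translation, applied as `x' = R x + t`.
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation Length-3 numeric (Angstrom).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3, 3)) ||
      abs(det(rotation) - 1) > 1e-9 ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stopf("invalid-argument: rotation must be a proper orthonormal 3x3 matrix")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Cylindrical pose: rotation about the filament (z) axis plus axial shift
#'
#' @param azimuth Rotation about +z (degrees).
#' @param axial Translation along z (Angstrom).
#' @return A `rigid_transform`.
#' @export
cylindrical_transform <- function(azimuth = 0, axial = 0) {
  th <- azimuth * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  rigid_transform(R, c(0, 0, axial))
}

#' Compose two rigid transforms (apply `b` first, then `a`)
#' @param a,b `rigid_transform` objects.
#' @return A `rigid_transform`.
#' @export
compose_transform <- function(a, b) {
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' Apply a rigid transform to coordinates or to a filament model
#'
#' @param x An n x 3 matrix or a `filament_model`.
#' @param tf A `rigid_transform`.
#' @param docked For models: mark the result as docked (pose applied),
#'   enabling downstream subtraction.
#' @return Transformed coordinates or model.
#' @export
apply_transform <- function(x, tf, docked = TRUE) {
  if (inherits(x, "filament_model")) {
    xyz <- model_coords(x) %*% t(tf$rotation)
    xyz <- sweep(xyz, 2, tf$translation, "+")
    x$x <- xyz[, 1]; x$y <- xyz[, 2]; x$z <- xyz[, 3]
    attr(x, "docked") <- docked
    return(x)
  }
  sweep(x %*% t(tf$rotation), 2, tf$translation, "+")
}

#' Mark a model as docked without moving it
#'
#' Used when a map was simulated in the model's own frame, so the
#' identity pose is the docked pose.
#'
#' @param model A `filament_model`.
#' @return The model with its docked flag set.
#' @export
mark_docked <- function(model) {
  attr(model, "docked") <- TRUE
  model
}

#' Masked real-space correlation between a map and a posed model
#'
#' Renders the posed model's Gaussian density at the voxels lying within
#' `mask_radius` of any of its particles and returns the Pearson
#' correlation with the map over those voxels.  The score is invariant
#' under affine intensity rescaling of the map.
#'
#' @param map A `density_map`.
#' @param model A `filament_model`.
#' @param pose A `rigid_transform` (default identity).
#' @param mask_radius Mask radius around model particles (Angstrom);
#'   the default 12 isolates the scored component at ~28 Angstrom
#'   resolution without bleeding into neighbouring components.
#' @param resolution Rendering resolution; defaults to the map's.
#' @param stride Score every `stride`-th voxel along each axis (>1 speeds
#'   up global searches; the grid oversamples the resolution).
#' @return Correlation in `[-1, 1]`.
#' @export
score_fit <- function(map, model, pose = rigid_transform(),
                      mask_radius = 12, resolution = NULL, stride = 1L) {
  resolution <- resolution %||% map$resolution
  if (is.null(resolution) || is.na(resolution))
    stopf("invalid-argument: resolution unknown; pass `resolution`")
  coords <- apply_transform(model_coords(model), pose)
  idx <- cpp_mask_near_points(dim(map$grid), map$voxel, map$origin,
                              coords, mask_radius, as.integer(stride))
  if (length(idx) < 2) stopf("degenerate-input: empty scoring mask")
  pts <- voxel_coords(map, idx)
  sigma <- resolution_sigma(resolution)
  dens <- cpp_density_at_points(pts, coords, model$weight, sigma, 4.5)
  if (sd(dens) == 0 || sd(map$grid[idx]) == 0) return(0)
  cor(map$grid[idx], dens)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Shared grid-scan driver: scores a cylindrical pose grid for `coords`
# against map values sampled at a fixed mask, then locates the optimum
# with one-dimensional parabolic refinement along each axis.
scan_poses <- function(map, coords, weights, mask_idx, sigma,
                       az_grid, dz_grid, dr_grid = 0) {
  pts <- voxel_coords(map, mask_idx)
  vals <- map$grid[mask_idx]
  sc <- cpp_score_pose_grid(pts, vals, coords, weights, sigma, 4.5,
                            az_grid, dz_grid, dr_grid)
  sc <- array(sc, dim = c(length(az_grid), length(dz_grid), length(dr_grid)))
  best <- which(sc == max(sc), arr.ind = TRUE)[1, ]
  ia <- best[1]; iz <- best[2]; ir <- best[3]
  az <- az_grid[ia]; dz <- dz_grid[iz]; dr <- dr_grid[ir]
  if (ia > 1 && ia < length(az_grid))
    az <- az + parabolic_peak(sc[ia - 1, iz, ir], sc[ia, iz, ir],
                              sc[ia + 1, iz, ir], az_grid[2] - az_grid[1])
  if (iz > 1 && iz < length(dz_grid))
    dz <- dz + parabolic_peak(sc[ia, iz - 1, ir], sc[ia, iz, ir],
                              sc[ia, iz + 1, ir], dz_grid[2] - dz_grid[1])
  if (length(dr_grid) > 2 && ir > 1 && ir < length(dr_grid))
    dr <- dr + parabolic_peak(sc[ia, iz, ir - 1], sc[ia, iz, ir],
                              sc[ia, iz, ir + 1], dr_grid[2] - dr_grid[1])
  list(azimuth = az, axial = dz, radial = dr, score = max(sc), grid = sc)
}

#' Global rigid-body fit of a model into a map
#'
#' Exhaustive search over a cylindrical pose grid (azimuth about the
#' filament axis, axial shift), followed by parabolic sub-grid
#' refinement of the score surface around the grid optimum -- the only
#' sub-grid step.  Deterministic given the grid.
#'
#' @param map A `density_map`.
#' @param model The model to dock (e.g. the actin filament).
#' @param az_range,az_step Azimuth search range and step (degrees).
#' @param dz_range,dz_step Axial search range (Angstrom); the default
#'   covers plus/minus one genetic rise.
#' @param mask_radius,resolution,stride Passed to the scoring mask; see
#'   [score_fit()].
#' @param refine Apply parabolic sub-grid refinement (default `TRUE`;
#'   disable to compare against grid-exhaustive enumeration).
#' @return A list with `transform` (`rigid_transform`), `azimuth`,
#'   `axial`, `score`, and the full score `grid`.
#' @export
global_fit <- function(map, model, az_range = c(-6, 6), az_step = 1,
                       dz_range = NULL, dz_step = 1,
                       mask_radius = 12, resolution = NULL, stride = 3L,
                       refine = TRUE) {
  resolution <- resolution %||% map$resolution
  params <- attr(model, "params")
  if (is.null(dz_range)) {
    r <- if (!is.null(params)) params$rise else 27.5
    dz_range <- c(-r, r)
  }
  az_grid <- seq(az_range[1], az_range[2], by = az_step)
  dz_grid <- seq(dz_range[1], dz_range[2], by = dz_step)
  coords <- model_coords(model)
  # one fixed mask, modestly dilated; a filament is dense enough that the
  # scored neighbourhood covers every pose of the search
  idx <- cpp_mask_near_points(dim(map$grid), map$voxel, map$origin, coords,
                              mask_radius + 8, as.integer(stride))
  if (length(idx) < 2) stopf("degenerate-input: empty scoring mask")
  res <- scan_poses(map, coords, model$weight, idx,
                    resolution_sigma(resolution), az_grid, dz_grid)
  if (!refine) {
    best <- which(res$grid == max(res$grid), arr.ind = TRUE)[1, ]
    res$azimuth <- az_grid[best[1]]
    res$axial <- dz_grid[best[2]]
  }
  if (res$score <= 0)
    warning("fit-failure: no pose scored above 0", call. = FALSE)
  res$transform <- cylindrical_transform(res$azimuth, res$axial)
  res
}

#' Localised three-subunit tropomyosin segment fit
#'
#' Implements the per-subunit refinement stage: for the pseudo-repeat
#' centred on a named actin subunit of one strand, the tropomyosin
#' segment spanning that subunit plus the subunits on either side along
#' the strand (`window = 3` long-pitch subunits) is posed rigidly over a
#' cylindrical grid (azimuth about the filament axis, axial shift,
#' radial shift), all other components fixed.  Because the reference
#' model is the blocked-state strand, the fitted azimuth is directly the
#' rotation from the blocked reference.
#'
#' By default the correlation is scored over voxels near the *central*
#' pseudo-repeat's beads (`score_span = "centre"`): the flanking repeats
#' supply the boundary density context that makes the terminal fits
#' well-posed, while the score reports the position of the chosen
#' repeat.  `score_span = "window"` scores the whole segment instead, in
#' which case a window covering the entire strand reproduces the global
#' fit.
#'
#' @param map A `density_map` (typically a stage-1 difference map with
#'   actin subtracted).
#' @param tm_model A `filament_model` containing the blocked-reference
#'   tropomyosin (posed by the global fit).
#' @param subunit_label Label `a`-`g` of the chosen actin subunit.
#' @param strand Strand 1 or 2.
#' @param window Odd number of long-pitch subunits spanned (default 3).
#' @param az_range,az_step Azimuth search grid (degrees).
#' @param dz_range,dz_step Axial-shift grid (Angstrom).
#' @param dr_grid Radial-shift grid (Angstrom).
#' @param mask_radius,resolution Scoring parameters, see [score_fit()].
#' @param radial_band Half-width (Angstrom) of the annulus around the
#'   segment's mean radius to which scoring is confined (`NULL` or `Inf`
#'   disables); keeps troponin (outside) and actin (inside) density from
#'   steering the rod fit.
#' @param exclude Optional n x 3 matrix of points (e.g. docked troponin
#'   core positions, fanned over the plausible azimuth range) whose
#'   `exclude_radius` neighbourhood is removed from the scoring corridor.
#' @param exclude_radius Exclusion radius (Angstrom) around `exclude`.
#' @param score_span `"centre"` or `"window"`.
#' @param anchor Labelling anchor (defaults to the model's).
#' @return A `segment_fit`: list with `subunit_label`, `strand`,
#'   `azimuth` (deg, relative to blocked), `axial_shift`, `radial_shift`
#'   (Angstrom) and `score`.
#' @export
local_segment_fit <- function(map, tm_model, subunit_label, strand,
                              window = 3,
                              az_range = c(-20, 50), az_step = 2,
                              dz_range = c(-3, 3), dz_step = 1.5,
                              dr_grid = c(-2, 0, 2),
                              mask_radius = 12, radial_band = 8,
                              exclude = NULL, exclude_radius = 14,
                              resolution = NULL,
                              score_span = c("centre", "window"),
                              anchor = default_anchor(tm_model)) {
  score_span <- match.arg(score_span)
  resolution <- resolution %||% map$resolution
  if (window %% 2 != 1) stopf("invalid-argument: window must be odd")
  params <- attr(tm_model, "params")
  labs <- label_subunits(tm_model, anchor)
  ls <- labs[labs$strand == strand & labs$label == subunit_label &
               labs$in_unit, ]
  if (nrow(ls) != 1)
    stopf("invalid-argument: subunit %s strand %d not found in unit",
          subunit_label, strand)
  z_c <- ls$z
  tm <- tm_model$component == "tropomyosin" & tm_model$strand == strand
  ztm <- tm_model$z[tm]
  half <- window * params$rise   # window/2 long-pitch steps of 2*rise
  seg <- tm & tm_model$z >= z_c - half & tm_model$z <= z_c + half
  # flanking context: the strand must actually extend past the window
  # core (unless the window already swallows the whole strand, the
  # limiting case in which the fit reduces to a global one)
  need <- (window - 1) / 2 * 2 * params$rise + params$rise
  whole_strand <- all(ztm >= z_c - half & ztm <= z_c + half)
  if (!whole_strand &&
      (min(ztm) > z_c - need + 1e-6 || max(ztm) < z_c + need - 1e-6))
    stopf("requires flanking context: subunit %s strand %d sits at the strand end",
          subunit_label, strand)
  seg_coords <- model_coords(tm_model, seg)
  seg_w <- tm_model$weight[seg]
  ctr <- seg & abs(tm_model$z - z_c) <= params$rise
  mask_src <- if (score_span == "centre") model_coords(tm_model, ctr)
              else seg_coords
  # the scored corridor must cover the whole azimuthal search arc, or
  # large rotations would be scored against empty space: fan the mask
  # source through the search range before dilating by mask_radius
  fan <- do.call(rbind, lapply(seq(az_range[1], az_range[2], by = 5),
    function(a) apply_transform(mask_src, cylindrical_transform(a, 0))))
  idx <- cpp_mask_near_points(dim(map$grid), map$voxel, map$origin,
                              fan, mask_radius, 1L)
  # confine scoring to the thin annulus the rod occupies: the troponin
  # core (outside) and actin (inside) are different components and must
  # not steer the tropomyosin fit
  if (!is.null(radial_band) && is.finite(radial_band)) {
    pv <- voxel_coords(map, idx)
    rv <- sqrt(pv[, 1]^2 + pv[, 2]^2)
    r0 <- mean(sqrt(mask_src[, 1]^2 + mask_src[, 2]^2))
    keep <- abs(rv - r0) <= radial_band
    # likewise confine the corridor axially to the repeat's own
    # half-spans, so neighbouring repeats are context, not signal
    if (score_span == "centre")
      keep <- keep & abs(pv[, 3] - z_c) <= params$rise
    idx <- idx[keep]
  }
  # carve out regions occupied by other docked components (e.g. the
  # troponin core next to subunits c and d)
  if (!is.null(exclude) && length(idx)) {
    pv <- voxel_coords(map, idx)
    idx <- idx[min_dist2(pv, exclude) > exclude_radius^2]
  }
  if (length(idx) < 2) stopf("degenerate-input: empty scoring mask")
  az_grid <- seq(az_range[1], az_range[2], by = az_step)
  dz_grid <- seq(dz_range[1], dz_range[2], by = dz_step)
  res <- scan_poses(map, seg_coords, seg_w, idx,
                    resolution_sigma(resolution), az_grid, dz_grid, dr_grid)
  structure(list(subunit_label = subunit_label, strand = strand,
                 azimuth = wrap_angle(res$azimuth),
                 axial_shift = res$axial, radial_shift = res$radial,
                 score = min(max(res$score, -1), 1)),
            class = "segment_fit")
}

#' @export
print.segment_fit <- function(x, ...) {
  cat(sprintf("Segment fit %s/strand %d: azimuth %.2f deg, dz %.2f A, dr %.2f A, score %.3f\n",
              x$subunit_label, x$strand, x$azimuth, x$axial_shift,
              x$radial_shift, x$score))
  invisible(x)
}

#' Fit all pseudo-repeats of the functional unit
#'
#' Runs [local_segment_fit()] for every labelled subunit (`a`-`g`) on
#' both strands and collects the results.
#'
#' @inheritParams local_segment_fit
#' @param ... Passed to [local_segment_fit()].
#' @return Data frame: `subunit_label`, `strand`, `azimuth`,
#'   `axial_shift`, `radial_shift`, `score`.
#' @export
fit_all_segments <- function(map, tm_model, ...) {
  grid <- expand.grid(label = letters[1:7], strand = 1:2,
                      stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    f <- local_segment_fit(map, tm_model, grid$label[i], grid$strand[i], ...)
    data.frame(subunit_label = f$subunit_label, strand = f$strand,
               azimuth = f$azimuth, axial_shift = f$axial_shift,
               radial_shift = f$radial_shift, score = f$score,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Rank candidate models by global fit quality
#'
#' Each candidate is globally fitted into the map and candidates are
#' returned sorted by descending best score; ties are broken by
#' lexicographic model id.
#'
#' @param map A `density_map`.
#' @param candidates Named list of `filament_model`s (>= 2).
#' @param ... Passed to [global_fit()] (e.g. a wide `az_range` to allow
#'   polarity flips).
#' @return Data frame `id`, `score`, ordered best-first.
#' @export
rank_candidate_models <- function(map, candidates, ...) {
  if (length(candidates) < 2)
    stopf("invalid-argument: need at least two candidate models")
  ids <- names(candidates) %||% as.character(seq_along(candidates))
  if (is.null(names(candidates))) names(candidates) <- ids
  scores <- vapply(candidates, function(m) global_fit(map, m, ...)$score, 0)
  ord <- order(-scores, ids)
  data.frame(id = ids[ord], score = as.numeric(scores[ord]),
             stringsAsFactors = FALSE)
}
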