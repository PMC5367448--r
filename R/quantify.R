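#' Rotation of a pseudo-repeat relative to the blocked state
#'
#' Signed azimuth difference between the Ca2+-treated and the
#' Ca2+-free (blocked) fit of the same pseudo-repeat, wrapped to
#' `(-180, 180]` degrees.
#'
#' @param fit_treated,fit_free `segment_fit`s for the same subunit and
#'   strand.
#' @return Rotation from blocked (degrees).
#' @export
rotation_from_blocked <- function(fit_treated, fit_free) {
  if (!identical(fit_treated$subunit_label, fit_free$subunit_label) ||
      !identical(fit_treated$strand, fit_free$strand))
    stopf("invalid-argument: fits refer to different subunits")
  wrap_angle(fit_treated$azimuth - fit_free$azimuth)
}

#' Classify a tropomyosin rotation into B, C or M state
#'
#' Deterministic banding of the rotation-from-blocked angle:
#' `B` below `t_BC`, `C` in `[t_BC, t_CM)`, `M` at or above `t_CM`.
#' The default thresholds (9 and 23 degrees) are the midpoints between
#' the canonical state rotations 0, 18 and 28 degrees; a rotation
#' exactly on a boundary is assigned to the more activated state.
#'
#' @param rotation Rotation(s) from blocked (degrees).
#' @param thresholds Length-2 increasing positive vector `c(t_BC, t_CM)`.
#' @return Character vector of states (`"B"`, `"C"`, `"M"`).
#' @export
classify_state <- function(rotation, thresholds = c(9, 23)) {
  if (length(thresholds) != 2 || thresholds[1] <= 0 ||
      thresholds[2] <= thresholds[1])
    stopf("invalid-argument: thresholds must satisfy 0 < t_BC < t_CM")
  ifelse(rotation >= thresholds[2], "M",
         ifelse(rotation >= thresholds[1], "C", "B"))
}

#' Build a per-pseudo-repeat state call
#'
#' @param subunit_label Label `a`-`g`.
#' @param rotation Rotation from blocked (degrees).
#' @param score Fit correlation.
#' @param thresholds Passed to [classify_state()].
#' @return An object of class `state_call`.
#' @export
state_call <- function(subunit_label, rotation, score = NA_real_,
                       thresholds = c(9, 23)) {
  structure(list(subunit_label = subunit_label,
                 rotation_from_B = rotation,
                 state = classify_state(rotation, thresholds),
                 score = score),
            class = "state_call")
}

#' Group-mean rotations of the barbed- and pointed-side repeats
#'
#' Pools both strands and averages the rotation-from-blocked over the
#' two label groups observed to behave differently in Ca2+-treated
#' filaments: subunits a-c on the barbed side of troponin and d-g on
#' the pointed side.  Means are unweighted arithmetic means.
#'
#' @param rotations Data frame with columns `subunit_label`, `strand`,
#'   `rotation` (one row per repeat per strand; all seven labels must be
#'   present on each strand).
#' @param grouping List of two character vectors of labels.
#' @return A list with two `group_rotation` entries (`group`, `mean`,
#'   `rotations`) and `difference` (first minus second mean, degrees).
#' @export
group_means <- function(rotations,
                        grouping = list(barbed = c("a", "b", "c"),
                                        pointed = c("d", "e", "f", "g"))) {
  for (s in unique(rotations$strand)) {
    have <- rotations$subunit_label[rotations$strand == s]
    if (!all(letters[1:7] %in% have))
      stopf("invalid-argument: strand %s is missing labels %s", s,
            paste(setdiff(letters[1:7], have), collapse = ","))
  }
  gr <- lapply(grouping, function(g) {
    if (!length(g)) stopf("invalid-argument: empty group")
    r <- rotations$rotation[rotations$subunit_label %in% g]
    structure(list(group = g, mean = mean(r), rotations = r),
              class = "group_rotation")
  })
  gr$difference <- gr[[1]]$mean - gr[[2]]$mean
  gr
}

#' Axial stagger between the troponin densities of the two strands
#'
#' Separates the troponin density of a stage-2 (troponin-only)
#' difference map by nearest-strand assignment of the voxels around the
#' troponin particles, collapses each strand's density onto the filament
#' axis to give 1D axial profiles, and returns the axial lag maximising
#' their cross-correlation, with parabolic sub-voxel interpolation.
#' Positive lags mean strand 2 sits toward the pointed (high-z) end.
#'
#' By default only the globular troponin cores are used for the strand
#' profiles: they are the compact features that define the stagger,
#' whereas the elongated TnT1 tails flatten the correlation peak and
#' admit more noise.
#'
#' @param diff A troponin-only `density_map` (stage-2 difference).
#' @param model The docked `filament_model` carrying troponin particles
#'   on both strands.
#' @param radius Voxel-assignment radius around troponin particles
#'   (Angstrom).
#' @param max_lag Largest |lag| searched (Angstrom).
#' @param tag Residue tag of the troponin particles used (default
#'   `"core"`; `NULL` uses the whole complex, and models without tags
#'   fall back to that automatically).
#' @return Stagger (Angstrom).
#' @export
troponin_stagger <- function(diff, model, radius = 16, max_lag = 60,
                             tag = "core") {
  strands <- sort(unique(model$strand[model$component == "troponin"]))
  if (length(strands) < 2)
    stopf("degenerate-input: troponin present on fewer than two strands")
  if (!is.null(tag) &&
      !any(select_particles(model, "troponin", tag = tag)))
    tag <- NULL
  prof <- list()
  sel_list <- lapply(1:2, function(s)
    select_particles(model, component = "troponin", strand = s, tag = tag))
  # voxels near troponin, assigned to the nearest strand's particles
  idx <- lapply(1:2, function(s)
    cpp_mask_near_points(dim(diff$grid), diff$voxel, diff$origin,
                         model_coords(model, sel_list[[s]]), radius, 1L))
  both <- sort(unique(c(idx[[1]], idx[[2]])))
  pts <- voxel_coords(diff, both)
  d2 <- vapply(1:2, function(s) {
    co <- model_coords(model, sel_list[[s]])
    dmin <- rep(Inf, nrow(pts))
    for (p in seq_len(nrow(co))) {
      dd <- (pts[, 1] - co[p, 1])^2 + (pts[, 2] - co[p, 2])^2 +
            (pts[, 3] - co[p, 3])^2
      dmin <- pmin(dmin, dd)
    }
    dmin
  }, numeric(nrow(pts)))
  assign_s <- max.col(-d2)
  nz <- dim(diff$grid)[3]
  zlev <- diff$origin[3] + diff$voxel * (seq_len(nz) - 1)
  kz <- round((pts[, 3] - diff$origin[3]) / diff$voxel) + 1
  prof <- lapply(1:2, function(s) {
    keep <- assign_s == s & idx_in(both, idx[[s]])
    p <- numeric(nz)
    tt <- tapply(diff$grid[both[keep]], kz[keep], sum)
    p[as.integer(names(tt))] <- tt
    p
  })
  # upsample the axial profiles (cubic spline to ~1 A) so the lag search
  # and its parabolic refinement are not limited by the voxel pitch
  up <- max(1L, ceiling(diff$voxel))
  nfine <- (nz - 1) * up + 1
  s1 <- stats::spline(seq_len(nz), prof[[1]], n = nfine)$y
  s2 <- stats::spline(seq_len(nz), prof[[2]], n = nfine)$y
  step <- diff$voxel / up
  lag_max <- floor(max_lag / step)
  lags <- (-lag_max):lag_max
  cc <- vapply(lags, function(l) {
    # correlate s1[k] with s2[k + l]: positive l = strand2 shifted up
    k <- seq_len(nfine)
    k2 <- k + l
    ok <- k2 >= 1 & k2 <= nfine
    sum(s1[k[ok]] * s2[k2[ok]])
  }, 0)
  ib <- which.max(cc)
  lag <- lags[ib]
  if (ib > 1 && ib < length(lags))
    lag <- lag + parabolic_peak(cc[ib - 1], cc[ib], cc[ib + 1], 1)
  lag * step
}

idx_in <- function(x, table) x %in% table

#' Axial span of a segmented density feature
#'
#' Measures the axial (z) extent of the region whose density exceeds
#' `threshold_fraction` of the map maximum.  Because rendering at finite
#' resolution widens a feature, the raw extent of a rod-like feature
#' exceeds its underlying length by `2 * sigma * qnorm(1 - f)` (the
#' half-maximum-style overshoot of an erf-shaped edge); when the map
#' carries a resolution, this edge correction is subtracted so the
#' returned span estimates the underlying feature length.
#'
#' The extent is measured on the axial density profile (total density per
#' z-slab), which integrates out transverse noise.
#'
#' @param segmented A single-component `density_map` (e.g. from
#'   [segment_component()]).
#' @param threshold_fraction Fraction of the maximum density.
#' @param correct_edges Apply the resolution edge correction (default
#'   `TRUE` when the resolution is known).
#' @return Axial span (Angstrom).
#' @export
axial_span <- function(segmented, threshold_fraction = 0.2,
                       correct_edges = TRUE) {
  g <- segmented$grid
  prof <- apply(g, 3, sum)
  mx <- max(prof)
  if (mx <= 0) stopf("degenerate-input: no density above zero")
  kz <- which(prof >= threshold_fraction * mx) - 1
  if (!length(kz)) stopf("degenerate-input: nothing above threshold")
  span <- (max(kz) - min(kz)) * segmented$voxel
  res <- segmented$resolution
  if (correct_edges && !is.null(res) && !is.na(res)) {
    span <- span - 2 * resolution_sigma(res) * qnorm(1 - threshold_fraction)
    span <- max(span, 0)
  }
  span
}

#' Fourier shell correlation between two maps
#'
#' Per-shell normalised complex correlation of the two maps' Fourier
#' transforms, with shells one Fourier voxel wide and no masking.  The
#' resolution is the reciprocal of the first frequency at which the
#' curve crosses the threshold (linear interpolation between shells);
#' if the curve never crosses, the band limit (2 * voxel) is reported.
#'
#' @param map1,map2 `density_map`s on identical grids.
#' @param threshold FSC threshold (default 0.5, typical for
#'   negative-stain reconstructions; 0.143 is the common half-map
#'   alternative).
#' @return An `fsc_curve`: list with `freq` (1/Angstrom shell centres),
#'   `fsc`, `threshold`, `resolution` (Angstrom).
#' @export
fsc <- function(map1, map2, threshold = 0.5) {
  if (!all(dim(map1$grid) == dim(map2$grid)) ||
      abs(map1$voxel - map2$voxel) > 1e-9)
    stopf("invalid-argument: maps must share one grid")
  d <- dim(map1$grid)
  F1 <- fft(map1$grid)
  F2 <- fft(map2$grid)
  fr <- lapply(1:3, function(i) {
    k <- c(0:(d[i] %/% 2), -((d[i] - d[i] %/% 2 - 1):1)) / (d[i] * map1$voxel)
    k[seq_len(d[i])]
  })
  fmag <- sqrt(outer(outer(fr[[1]]^2, fr[[2]]^2, "+"), fr[[3]]^2, "+"))
  df <- 1 / (max(d) * map1$voxel)          # one Fourier voxel
  shell <- as.integer(round(fmag / df))
  nshell <- as.integer(1 / (2 * map1$voxel) / df)  # up to Nyquist
  num <- rep(0, nshell); den1 <- rep(0, nshell); den2 <- rep(0, nshell)
  cross <- Re(F1 * Conj(F2))
  a1 <- Mod(F1)^2; a2 <- Mod(F2)^2
  sh <- shell + 1L
  ok <- shell >= 1L & shell <= nshell
  num <- as.numeric(tapply(cross[ok], sh[ok], sum))
  den1 <- as.numeric(tapply(a1[ok], sh[ok], sum))
  den2 <- as.numeric(tapply(a2[ok], sh[ok], sum))
  shells_present <- sort(unique(sh[ok])) - 1L
  freq <- shells_present * df
  curve <- num / sqrt(den1 * den2)
  curve[!is.finite(curve)] <- 0
  cross_i <- which(curve < threshold)
  if (!length(cross_i)) {
    res <- 2 * map1$voxel
  } else {
    i <- cross_i[1]
    if (i == 1) {
      res <- 1 / freq[1]
    } else {
      f0 <- freq[i - 1]; f1 <- freq[i]
      c0 <- curve[i - 1]; c1 <- curve[i]
      fx <- f0 + (threshold - c0) / (c1 - c0) * (f1 - f0)
      res <- 1 / fx
    }
  }
  structure(list(freq = freq, fsc = curve, threshold = threshold,
                 resolution = res, n_voxels = as.numeric(table(sh[ok]))),
            class = "fsc_curve")
}

#' @export
print.fsc_curve <- function(x, ...) {
  cat(sprintf("FSC curve, %d shells; resolution %.2f A at threshold %.3f\n",
              length(x$freq), x$resolution, x$threshold))
  invisible(x)
}

#' Displacement of a residue selection between two docked states
#'
#' Superposes the second model onto the first by least squares over a
#' reference frame selection (default: all actin particles -- the
#' filament scaffold, which does not move between states) and returns
#' the displacement of the centroid of the residue selection.  The
#' choice of frame matters and is therefore explicit.
#'
#' @param model_state1,model_state2 `filament_model`s (or any data frames
#'   with coordinates) with identical particle layout.
#' @param selection Logical/integer row selection of the residue(s) of
#'   interest, or a list of arguments to [select_particles()].
#' @param frame Row selection for the superposition frame, same forms as
#'   `selection`; default selects actin.
#' @return Displacement (Angstrom).
#' @export
residue_displacement <- function(model_state1, model_state2, selection,
                                 frame = list(component = "actin")) {
  resolve <- function(model, sel) {
    if (is.list(sel)) do.call(select_particles, c(list(model), sel)) else sel
  }
  f1 <- resolve(model_state1, frame); f2 <- resolve(model_state2, frame)
  s1 <- resolve(model_state1, selection); s2 <- resolve(model_state2, selection)
  if (!any(s1) || !any(s2))
    stopf("invalid-argument: selection absent from one of the models")
  if (sum(f1) != sum(f2))
    stopf("invalid-argument: frame selections differ in size")
  A <- model_coords(model_state1, f1)
  B <- model_coords(model_state2, f2)
  # Kabsch least-squares superposition of frame B onto frame A
  ca <- colMeans(A); cb <- colMeans(B)
  H <- crossprod(sweep(B, 2, cb), sweep(A, 2, ca))
  sv <- svd(H)
  dsign <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, dsign)) %*% t(sv$u)
  move <- function(X) sweep(sweep(X, 2, cb) %*% t(R), 2, ca, "+")
  p1 <- colMeans(model_coords(model_state1, s1))
  p2 <- colMeans(move(model_coords(model_state2, s2)))
  sqrt(sum((p1 - p2)^2))
}
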