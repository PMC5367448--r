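#' Helical lattice constants of the thin filament
#'
#' The geometry of every model built by this package derives from four
#' numbers: the axial rise and azimuthal twist per subunit of the actin
#' *genetic* helix (the single-start helix relating every consecutive
#' subunit), and the radii at which actin subunit centres and the
#' tropomyosin strand axes sit.  The two visually apparent "long-pitch
#' strands" are the two-start description of the same lattice: long-pitch
#' neighbours along one strand are separated axially by exactly `2 * rise`.
#'
#' The default rise of 27.5 Angstrom is the canonical value for F-actin;
#' the default twist of -166.67 degrees describes the left-handed genetic
#' helix (close to 13/6 symmetry).  The radii are literature-typical values
#' for the actin subunit centre of mass and the tropomyosin coiled-coil
#' axis and are freely configurable.
#'
#' @param rise Axial rise per genetic-helix subunit (Angstrom).
#' @param twist Azimuthal twist per genetic-helix subunit (degrees,
#'   signed; negative = left-handed).
#' @param actin_radius Radius of the actin subunit centre from the
#'   filament axis (Angstrom).
#' @param tm_radius Radius of the tropomyosin strand axis from the
#'   filament axis (Angstrom).
#' @return An object of class `helical_params`.
#' @examples
#' p <- helical_params()
#' p$rise  # 27.5
#' @export
helical_params <- function(rise = 27.5, twist = -166.67,
                           actin_radius = 25, tm_radius = 39) {
  if (!is.numeric(rise) || length(rise) != 1 || rise <= 0)
    stopf("invalid-argument: rise must be a positive scalar")
  if (!is.numeric(twist) || length(twist) != 1 ||
      abs(twist) <= 90 || abs(twist) >= 180)
    stopf("invalid-argument: |twist| must lie in (90, 180) degrees")
  if (actin_radius <= 0 || tm_radius <= 0)
    stopf("invalid-argument: radii must be positive")
  structure(list(rise = rise, twist = twist,
                 actin_radius = actin_radius, tm_radius = tm_radius),
            class = "helical_params")
}

#' @export
print.helical_params <- function(x, ...) {
  cat(sprintf(
    "Helical lattice: rise %.2f A, twist %.2f deg, r(actin) %.1f A, r(Tm) %.1f A\n",
    x$rise, x$twist, x$actin_radius, x$tm_radius))
  invisible(x)
}

# Azimuthal phase of the blocked-state tropomyosin strand relative to its
# actin subunits (degrees).  A convention: the absolute azimuth of the
# blocked strand never enters any reported quantity (all state calls are
# rotations relative to this reference).
TM_PHASE <- 20

# Local bead cloud of one actin subunit, expressed in the subunit frame
# (u = radial, t = tangential, w = axial), Angstrom.  Eleven beads give a
# compact ~50 x 35 A blob centred on the subunit origin; at ~28 A
# resolution this is indistinguishable from an atomic subunit.
ACTIN_BEADS <- matrix(c(
   0,  0,   0,
   7,  0,   0,
  -7,  0,   0,
   0,  7,   0,
   0, -7,   0,
   0,  0,  10,
   0,  0, -10,
   5,  5,   6,
  -5, -5,  -6,
   4, -4,   4,
  -4,  4,  -4
), ncol = 3, byrow = TRUE)
ACTIN_BEAD_WEIGHT <- 42 / 11  # ~42 kDa subunit spread over the beads

new_filament_model <- function(df, params, anchor = NA_integer_,
                               tm_offsets = NULL) {
  rownames(df) <- NULL
  structure(df, params = params, anchor = anchor, tm_offsets = tm_offsets,
            class = c("filament_model", "data.frame"))
}

#' @export
print.filament_model <- function(x, ...) {
  comp <- table(x$component)
  cat(sprintf("Filament model: %d particles (%s)\n", nrow(x),
              paste(sprintf("%s %d", names(comp), comp), collapse = ", ")))
  na <- sum(x$component == "actin" & x$subunit_index >= 0)
  cat(sprintf("  actin subunits: %d; anchor index: %s\n",
              length(unique(x$subunit_index[x$component == "actin"])),
              attr(x, "anchor")))
  invisible(x)
}

#' Extract the particle coordinate matrix of a model
#'
#' @param model A `filament_model`.
#' @param sel Optional row selection (logical or integer indices).
#' @return An n x 3 numeric matrix of positions (Angstrom).
#' @export
model_coords <- function(model, sel = NULL) {
  m <- cbind(model$x, model$y, model$z)
  if (!is.null(sel)) m <- m[sel, , drop = FALSE]
  m
}

#' Select particles of a model by component, strand, label or tag
#'
#' @param model A `filament_model`.
#' @param component Component name(s): `"actin"`, `"tropomyosin"`,
#'   `"troponin"`, or `NULL` for all.
#' @param strand Strand number(s) (1, 2) or `NULL`.
#' @param label Subunit label(s) (`"a"`..`"g"`) or `NULL`.
#' @param tag Residue tag(s) (e.g. `"TnT1"`, `"core"`) or `NULL`.
#' @return A logical vector over the model's rows.
#' @export
select_particles <- function(model, component = NULL, strand = NULL,
                             label = NULL, tag = NULL) {
  keep <- rep(TRUE, nrow(model))
  if (!is.null(component)) keep <- keep & model$component %in% component
  if (!is.null(strand)) keep <- keep & model$strand %in% strand
  if (!is.null(label)) keep <- keep & !is.na(model$subunit_label) &
      model$subunit_label %in% label
  if (!is.null(tag)) keep <- keep & !is.na(model$residue_tag) &
      model$residue_tag %in% tag
  keep
}

#' Build the actin two-start filament
#'
#' Places `n_subunits` actin subunits on the genetic helix: subunit `k`
#' (0-based) is centred at axial position `k * rise`, azimuth `k * twist`,
#' radius `actin_radius`.  Subunits with even `k` belong to long-pitch
#' strand 1 and odd `k` to strand 2.  Each subunit is represented by a
#' compact bead cloud rigidly attached to the subunit frame, so that the
#' lattice's helical symmetry operator maps subunit `k` onto `k + 1`
#' exactly.  The barbed (Z-band) end is at low axial coordinate.
#'
#' @param n_subunits Number of genetic-helix subunits (>= 1).
#' @param params A [helical_params()] object.
#' @return A `filament_model` data frame with columns `x`, `y`, `z`,
#'   `weight`, `component`, `strand`, `subunit_index`, `subunit_label`,
#'   `residue_tag`, `in_unit`.
#' @examples
#' m <- build_actin_filament(14, helical_params())
#' diff(range(m$z[m$weight > 0]))  # axial extent
#' @export
build_actin_filament <- function(n_subunits, params = helical_params()) {
  if (!is.numeric(n_subunits) || length(n_subunits) != 1 ||
      n_subunits < 1 || n_subunits != round(n_subunits))
    stopf("invalid-argument: n_subunits must be a positive integer")
  n <- as.integer(n_subunits)
  ks <- seq_len(n) - 1L
  per <- nrow(ACTIN_BEADS)
  rows <- vector("list", n)
  for (k in ks) {
    phi <- k * params$twist * pi / 180
    u <- c(cos(phi), sin(phi), 0)
    tg <- c(-sin(phi), cos(phi), 0)
    ctr <- params$actin_radius * u + c(0, 0, k * params$rise)
    xyz <- t(ctr + t(ACTIN_BEADS %*% rbind(u, tg, c(0, 0, 1))))
    rows[[k + 1L]] <- data.frame(
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      weight = rep(ACTIN_BEAD_WEIGHT, per),
      component = "actin",
      strand = as.integer(k %% 2L) + 1L,
      subunit_index = k,
      subunit_label = NA_character_,
      residue_tag = NA_character_,
      in_unit = FALSE,
      stringsAsFactors = FALSE)
  }
  new_filament_model(do.call(rbind, rows), params)
}

#' Per-pseudo-repeat tropomyosin azimuthal offsets
#'
#' A named mapping from subunit labels `a`..`g` to the azimuthal offset
#' (degrees) of the corresponding tropomyosin pseudo-repeat relative to
#' the blocked-state reference azimuth.  An all-zero mapping reproduces
#' the blocked (Ca2+-free) state.  Positive offsets rotate tropomyosin
#' from the outer-domain (blocked) position toward the inner-domain
#' (myosin-state) position, viewed from the pointed end.
#'
#' @param ... Either a single named numeric vector or named arguments
#'   `a = , b = , ...`.  Missing labels default to 0.
#' @return A named numeric vector of class `repeat_azimuths` with entries
#'   for all seven labels.
#' @examples
#' repeat_azimuths(a = 28, b = 28, c = 28, d = 18, e = 18, f = 18, g = 18)
#' @export
repeat_azimuths <- function(...) {
  args <- list(...)
  if (length(args) == 1 && is.null(names(args)) && is.numeric(args[[1]]))
    args <- as.list(args[[1]])
  off <- stats::setNames(rep(0, 7), letters[1:7])
  if (length(args)) {
    if (is.null(names(args)) || any(!names(args) %in% letters[1:7]))
      stopf("invalid-argument: offsets must be named with labels a-g")
    off[names(args)] <- unlist(args)
  }
  if (any(off < 0 | off > 45))
    stopf("invalid-argument: azimuth offsets must lie in [0, 45] degrees")
  structure(off, class = c("repeat_azimuths", "numeric"))
}

#' Azimuth presets for the three regulatory states
#'
#' Offsets (degrees from the blocked reference) used to build canonical
#' state models: blocked (B) 0, closed (C) 18, myosin/open (M) 28.  The C
#' and M values are the mean rotations measured for pseudo-repeats on the
#' pointed (d-g) and barbed (a-c) sides of troponin in Ca2+-treated
#' filaments.
#'
#' @return Named numeric vector `c(B = 0, C = 18, M = 28)`.
#' @export
state_offsets <- function() c(B = 0, C = 18, M = 28)

# Default anchor: the strand-1 subunit to be labelled "c", chosen so the
# 14-subunit functional unit sits centrally with at least one long-pitch
# flanking subunit per strand below label "a".
default_anchor <- function(model) {
  a <- attr(model, "anchor")
  if (!is.null(a) && !is.na(a)) return(a)
  k1 <- sort(unique(model$subunit_index[model$component == "actin" &
                                        model$strand == 1]))
  n1 <- length(k1)
  if (n1 < 7) stopf("invalid-argument: model too short for labelling")
  lead <- (n1 - 7L) %/% 2L  # long-pitch flanks below label "a"
  k1[lead + 2L + 1L]        # a at position lead+1, c two later
}

# Label the long-pitch subunits of each strand a-g (periodically extended
# to flanks) relative to the anchor.  Returns a data.frame:
# subunit_index, strand, z, label (a-g), in_unit.
label_subunits <- function(model, anchor = default_anchor(model),
                           stagger_subunits = 1L) {
  act <- model[model$component == "actin", ]
  out <- NULL
  for (s in 1:2) {
    ks <- sort(unique(act$subunit_index[act$strand == s]))
    anc <- if (s == 1) anchor else anchor + stagger_subunits
    # long-pitch position relative to the anchor ("c"); label a is -2
    rel <- (ks - anc) %/% 2L
    li <- ((rel + 2L) %% 7L) + 1L
    zc <- vapply(ks, function(k)
      mean(act$z[act$strand == s & act$subunit_index == k]), 0)
    out <- rbind(out, data.frame(
      subunit_index = ks, strand = s, z = zc,
      label = letters[li],
      in_unit = rel >= -2L & rel <= 4L,
      stringsAsFactors = FALSE))
  }
  out
}

# Piecewise-linear interpolation of per-repeat azimuth offsets along one
# strand.  `centres` are repeat-centre axial positions, `offsets` the
# offsets there; values beyond the ends are held constant.
interp_offsets <- function(z, centres, offsets) {
  if (length(centres) == 1) return(rep(offsets, length(z)))
  o <- order(centres)
  stats::approx(centres[o], offsets[o], xout = z, rule = 2)$y
}

# Blocked-reference azimuth (degrees) of the tropomyosin strand `s` at
# axial position z.  The strand follows the long-pitch helix through its
# actin subunits: slope = (2*twist mod 360)/(2*rise) deg/A.
tm_base_azimuth <- function(params, strand, z) {
  slope <- ((2 * params$twist) %% 360) / (2 * params$rise)
  anchor_z <- if (strand == 1) 0 else params$rise
  anchor_phi <- if (strand == 1) 0 else params$twist
  anchor_phi + slope * (z - anchor_z) + TM_PHASE
}

#' Add tropomyosin strands to a filament model
#'
#' Lays two continuous strands of rod-like pseudo-atoms along the
#' long-pitch helices at radius `tm_radius`, one bead every ~5.5 Angstrom.
#' Each pseudo-repeat is centred on one actin subunit of its strand; at
#' the repeat centre the strand's local azimuth equals the blocked
#' reference plus the repeat's offset, and offsets are interpolated
#' linearly in the axial coordinate between adjacent repeat centres so the
#' strand stays continuous.  Offsets are keyed by subunit label (a-g,
#' assigned relative to `anchor`) and extended periodically to flanking
#' repeats, emulating the repeating regulatory lattice of a long filament.
#'
#' @param model A `filament_model` containing actin.
#' @param azimuths A [repeat_azimuths()] mapping (default: all zero, the
#'   blocked state).
#' @param anchor Genetic index of the strand-1 subunit labelled `c`
#'   (default: central placement).
#' @param bead_spacing Axial spacing of strand beads (Angstrom).
#' @return The model with tropomyosin particles appended.
#' @export
add_tropomyosin <- function(model, azimuths = repeat_azimuths(),
                            anchor = default_anchor(model),
                            bead_spacing = 5.5) {
  if (!any(model$component == "actin"))
    stopf("invalid-argument: model contains no actin")
  azimuths <- repeat_azimuths(unclass(azimuths))
  params <- attr(model, "params")
  labs <- label_subunits(model, anchor)
  tm_offsets <- list()
  rows <- list()
  for (s in 1:2) {
    ls <- labs[labs$strand == s, ]
    offs <- as.numeric(azimuths[ls$label])
    zr <- range(ls$z)
    # strand extends half a long-pitch step past the outermost repeats
    zs <- seq(zr[1] - params$rise, zr[2] + params$rise, by = bead_spacing)
    off_z <- interp_offsets(zs, ls$z, offs)
    phi <- (tm_base_azimuth(params, s, zs) + off_z) * pi / 180
    # nearest repeat centre owns each bead
    own <- ls$subunit_index[vapply(zs, function(z)
      which.min(abs(ls$z - z)), 1L)]
    rows[[s]] <- data.frame(
      x = params$tm_radius * cos(phi), y = params$tm_radius * sin(phi),
      z = zs, weight = 1.0, component = "tropomyosin",
      strand = s, subunit_index = own,
      subunit_label = NA_character_, residue_tag = NA_character_,
      in_unit = FALSE, stringsAsFactors = FALSE)
    tm_offsets[[s]] <- list(centres = ls$z, offsets = offs)
  }
  df <- rbind(as.data.frame(model), rows[[1]], rows[[2]])
  new_filament_model(df, params, anchor = anchor, tm_offsets = tm_offsets)
}

# Troponin core bead cloud in a local frame (u = radial, t = tangential,
# w = axial), Angstrom: an ellipsoid ~45 A tall, ~25 A wide.
TROPONIN_CORE_BEADS <- matrix(c(
   0,  0,   0,
   0,  0,  12,
   0,  0, -12,
   6,  0,   5,
  -6,  0,  -5,
   0,  6,  -5,
   0, -6,   5,
   4,  4,  18
), ncol = 3, byrow = TRUE)
TROPONIN_CORE_WEIGHT <- 6.5  # ~52 kDa core over 8 beads

#' Add troponin complexes to a filament model
#'
#' Places one troponin complex per regulatory unit per strand: a globular
#' core (TnC + TnI + TnT2) centred axially between the `c` and `d`
#' subunits of its strand just outside the tropomyosin radius, and an
#' elongated TnT1 tail of beads running along the tropomyosin strand
#' toward the pointed (high-z) end over an axial span of two long-pitch
#' subunits (110 Angstrom at the default rise).  The strand-2 complex is
#' axially offset from strand 1 by `stagger` (default: one genetic-helix
#' rise, the arrangement seen in the reconstructions).  Troponin rides at
#' the local tropomyosin azimuth of its strand, as it is
#' tropomyosin-bound.
#'
#' @param model A `filament_model` with actin (tropomyosin optional; the
#'   blocked reference azimuth is used if absent).
#' @param every_n Actin subunits per regulatory unit along a strand
#'   (default 7).  Currently one complex per strand is placed at the
#'   anchor; `every_n` validates the unit length.
#' @param stagger Axial offset of the strand-2 complex (Angstrom).
#' @param anchor Strand-1 subunit index labelled `c`.
#' @return The model with troponin particles appended.
#' @export
add_troponin <- function(model, every_n = 7, stagger = NULL,
                         anchor = default_anchor(model)) {
  if (every_n < 1) stopf("invalid-argument: every_n must be >= 1")
  params <- attr(model, "params")
  if (is.null(stagger)) stagger <- params$rise
  if (stagger < 0) stopf("invalid-argument: stagger must be >= 0")
  tm_off <- attr(model, "tm_offsets")
  local_phi <- function(s, z) {
    off <- 0
    if (!is.null(tm_off) && length(tm_off) >= s)
      off <- interp_offsets(z, tm_off[[s]]$centres, tm_off[[s]]$offsets)
    tm_base_azimuth(params, s, z) + off
  }
  act <- model[model$component == "actin", ]
  z_anchor <- mean(act$z[act$subunit_index == anchor])
  if (!is.finite(z_anchor))
    stopf("invalid-argument: anchor subunit %d absent from model", anchor)
  core_r <- params$tm_radius + 9
  tail_r <- params$tm_radius + 3
  tail_span <- 2 * (2 * params$rise)          # two long-pitch subunits
  rows <- list()
  for (s in 1:2) {
    z_core <- z_anchor + params$rise + (if (s == 2) stagger else 0)
    phi0 <- local_phi(s, z_core) * pi / 180
    u <- c(cos(phi0), sin(phi0), 0); tg <- c(-sin(phi0), cos(phi0), 0)
    ctr <- core_r * u + c(0, 0, z_core)
    xyz <- t(ctr + t(TROPONIN_CORE_BEADS %*% rbind(u, tg, c(0, 0, 1))))
    core <- data.frame(
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      weight = TROPONIN_CORE_WEIGHT, component = "troponin",
      strand = s, subunit_index = anchor + (s == 2),
      subunit_label = NA_character_, residue_tag = "core",
      in_unit = FALSE, stringsAsFactors = FALSE)
    zt <- seq(z_core, z_core + tail_span, by = 5.5)
    phit <- local_phi(s, zt) * pi / 180
    tail <- data.frame(
      x = tail_r * cos(phit), y = tail_r * sin(phit), z = zt,
      weight = 1.2, component = "troponin",
      strand = s, subunit_index = anchor + (s == 2),
      subunit_label = NA_character_, residue_tag = "TnT1",
      in_unit = FALSE, stringsAsFactors = FALSE)
    rows[[s]] <- rbind(core, tail)
  }
  df <- rbind(as.data.frame(model), rows[[1]], rows[[2]])
  new_filament_model(df, params, anchor = anchor,
                     tm_offsets = attr(model, "tm_offsets"))
}

#' Extract the 14-subunit functional unit
#'
#' The functional (regulatory) unit comprises fourteen actin subunits
#' (seven per strand, labelled `a`-`g`), two tropomyosin strands and two
#' troponin complexes.  Labels are assigned relative to the troponin
#' anchor: `c` and `d` flank the troponin core, `a`-`b` lie on the barbed
#' (low-z) side and `e`-`g` on the pointed side.  One long-pitch flanking
#' subunit per strand is retained on each side of the unit (unlabelled,
#' `in_unit = FALSE`) because localised fitting of the terminal repeats
#' needs their density context.  Applying the extraction to its own output
#' returns it unchanged.
#'
#' @param model A `filament_model` with at least 18 genetic subunits
#'   (14 in the unit plus 2 flanking per end).
#' @param anchor Strand-1 subunit index labelled `c`.
#' @return A `filament_model` restricted to the unit plus flanks, with
#'   labels filled in.
#' @export
functional_unit <- function(model, anchor = default_anchor(model)) {
  act_k <- unique(model$subunit_index[model$component == "actin"])
  if (length(act_k) < 18 && !any(model$in_unit))
    stopf("invalid-argument: model too short (need >= 18 genetic subunits, have %d)",
          length(act_k))
  labs <- label_subunits(model, anchor)
  # unit + one long-pitch flank per strand per side
  keep_tab <- NULL
  for (s in 1:2) {
    ls <- labs[labs$strand == s, ]
    ls <- ls[order(ls$z), ]
    iu <- which(ls$in_unit)
    sel <- seq(max(1, min(iu) - 1), min(nrow(ls), max(iu) + 1))
    keep_tab <- rbind(keep_tab, ls[sel, ])
  }
  df <- as.data.frame(model)
  is_act <- df$component == "actin"
  key <- paste(df$strand, df$subunit_index)
  kkey <- paste(keep_tab$strand, keep_tab$subunit_index)
  keep <- !is_act | key %in% kkey
  df <- df[keep, ]
  # assign labels to unit actin subunits only
  is_act <- df$component == "actin"
  m <- match(paste(df$strand, df$subunit_index), kkey)
  midx <- ifelse(is.na(m), 1L, m)
  unit_row <- is_act & !is.na(m) & keep_tab$in_unit[midx]
  df$subunit_label[is_act] <- NA_character_
  df$subunit_label[unit_row] <- keep_tab$label[m[unit_row]]
  df$in_unit <- FALSE
  df$in_unit[unit_row] <- TRUE
  new_filament_model(df, attr(model, "params"), anchor = anchor,
                     tm_offsets = attr(model, "tm_offsets"))
}

#' Named residue selections of the troponin subunits
#'
#' Residue ranges used when working with atomic models: the elongated
#' N-terminal tail of TnT (TnT1, residues 1-158), its major
#' tropomyosin-binding domain (114-138), the C-terminal actin-binding
#' region of TnI (176-184) and the two TnI residues commonly carrying
#' FRET probes (96 and 117).
#'
#' @return A named list of integer vectors.
#' @export
residue_selections <- function() {
  list(TnT1 = 1:158,
       TnT_tm_binding = 114:138,
       TnI_cterm = 176:184,
       TnI_fret = c(96L, 117L))
}

#' Apply the lattice's helical symmetry operator to coordinates
#'
#' Rotates by `n * twist` about the filament (z) axis and translates by
#' `n * rise` along it.
#'
#' @param coords n x 3 coordinate matrix.
#' @param params A [helical_params()].
#' @param n Number of subunit steps (may be negative).
#' @return Transformed coordinate matrix.
#' @export
helical_operator <- function(coords, params, n = 1) {
  th <- n * params$twist * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  out <- coords %*% t(R)
  out[, 3] <- out[, 3] + n * params$rise
  out
}

#' Read back the tropomyosin azimuth offset at each repeat centre
#'
#' Measures, from particle coordinates alone, the azimuthal offset of the
#' tropomyosin strand from the blocked reference at each labelled repeat
#' centre.  Used to verify that construction honours the requested
#' offsets.
#'
#' @param model A `filament_model` with tropomyosin.
#' @return Data frame: strand, subunit_index, label, offset (deg).
#' @export
tm_offset_readback <- function(model) {
  params <- attr(model, "params")
  labs <- label_subunits(model, default_anchor(model))
  out <- NULL
  for (s in 1:2) {
    tm <- model[model$component == "tropomyosin" & model$strand == s, ]
    if (!nrow(tm)) next
    ls <- labs[labs$strand == s, ]
    for (i in seq_len(nrow(ls))) {
      j <- which.min(abs(tm$z - ls$z[i]))
      phi <- atan2(tm$y[j], tm$x[j]) * 180 / pi
      base <- tm_base_azimuth(params, s, tm$z[j])
      out <- rbind(out, data.frame(
        strand = s, subunit_index = ls$subunit_index[i], label = ls$label[i],
        offset = wrap_angle(phi - base), stringsAsFactors = FALSE))
    }
  }
  out
}
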