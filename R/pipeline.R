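#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with the defaults
#' used throughout: the canonical lattice (27.5 Angstrom rise), the
#' mixed-state Ca2+-treated azimuth pattern (a-c at the myosin-state
#' offset 28 degrees, d-g at the closed-state offset 18 degrees), 28
#' Angstrom rendering at 4 Angstrom voxels, envelope SNR 2, and the B/C/M
#' state thresholds (9 and 23 degrees).  Serialises round-trip stably to
#' YAML.
#'
#' @param ... Overrides of the default entries (see the function body /
#'   vignette for the full list).
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    schema_version = 1L,
    seed = 1L,
    n_subunits = 18L,
    rise = 27.5, twist = -166.67, actin_radius = 25, tm_radius = 39,
    stagger = 27.5,
    azimuths_treated = list(a = 28, b = 28, c = 28,
                            d = 18, e = 18, f = 18, g = 18),
    azimuths_free = list(a = 0, b = 0, c = 0, d = 0, e = 0, f = 0, g = 0),
    voxel = 4, resolution = 28, box = c(96L, 96L, 144L),
    snr = 2,
    thresholds = c(9, 23),
    global_az_range = c(-6, 6), global_az_step = 1, global_dz_step = 1,
    local_az_range = c(-20, 50), local_az_step = 2,
    local_dz_range = c(-3, 3), local_dz_step = 1.5,
    local_dr_grid = c(-2, 0, 2),
    mask_radius = 12,
    tn_radius = 18,
    tnt1_threshold = 0.2,
    fsc_threshold = 0.5,
    half_maps = FALSE,
    out_dir = NULL)
  over <- list(...)
  bad <- setdiff(names(over), names(defaults))
  if (length(bad)) stopf("invalid-argument: unknown config entries %s",
                         paste(bad, collapse = ", "))
  structure(modifyList(defaults, over, keep.null = TRUE),
            class = c("pipeline_config", "list"))
}

#' Write / read a pipeline configuration as YAML
#' @param config A `pipeline_config`.
#' @param path File path.
#' @return `path` (write) or a `pipeline_config` (read).
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

# Build the ground-truth model pair (Ca2+-free / Ca2+-treated) described
# by a config.  Returns list(free, treated, params, anchor).
build_state_models <- function(config) {
  params <- helical_params(config$rise, config$twist,
                           config$actin_radius, config$tm_radius)
  base <- build_actin_filament(config$n_subunits, params)
  anchor <- default_anchor(base)
  mk <- function(az) {
    m <- add_tropomyosin(base, repeat_azimuths(unlist(az)), anchor = anchor)
    add_troponin(m, stagger = config$stagger, anchor = anchor)
  }
  list(free = mk(config$azimuths_free),
       treated = mk(config$azimuths_treated),
       params = params, anchor = anchor)
}

#' Run the end-to-end dissection pipeline on synthetic maps
#'
#' Executes build, render, noise, global docking, stage-1 difference
#' (actin subtracted), localised per-subunit tropomyosin fitting on both
#' states, rotation/state quantification, stage-2 difference (actin plus
#' fitted tropomyosin subtracted), troponin stagger and TnT1 span
#' measurement, and (optionally) half-map FSC.  All randomness derives
#' from `config$seed`; the same config yields a byte-identical report.
#'
#' @param config A [pipeline_config()].
#' @return A report list; if `config$out_dir` is set, maps (MRC), models
#'   (PDB), fits (TSV) and the report (JSON) are also written there.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stage <- "build"
  report <- list(schema_version = config$schema_version,
                 config = unclass(config))
  tryCatch({
    models <- build_state_models(config)
    seeds <- derive_seeds(config$seed, 4)

    stage <- "render"
    maps <- list()
    for (st in c("free", "treated")) {
      clean <- render_map(models[[st]], config$voxel, config$resolution,
                          config$box)
      maps[[st]] <- list(clean = clean,
                         noisy = add_noise(clean, noise_spec(config$snr,
                           seeds[match(st, c("free", "treated"))])))
    }

    stage <- "global_fit"
    actin_only <- function(m) {
      am <- m[select_particles(m, "actin"), , drop = FALSE]
      new_filament_model(as.data.frame(am), attr(m, "params"),
                         anchor = attr(m, "anchor"))
    }
    # one centroid bead per subunit is indistinguishable from the full
    # bead cloud for whole-filament docking at ~28 A and much cheaper
    coarse_actin <- function(m) {
      am <- as.data.frame(m[select_particles(m, "actin"), , drop = FALSE])
      agg <- do.call(rbind, lapply(split(am, am$subunit_index), function(s)
        data.frame(x = mean(s$x), y = mean(s$y), z = mean(s$z),
                   weight = sum(s$weight), component = "actin",
                   strand = s$strand[1], subunit_index = s$subunit_index[1],
                   subunit_label = NA_character_,
                   residue_tag = NA_character_, in_unit = FALSE,
                   stringsAsFactors = FALSE)))
      new_filament_model(agg, attr(m, "params"), anchor = attr(m, "anchor"))
    }
    gf <- lapply(maps, function(mp)
      global_fit(mp$noisy, coarse_actin(models$free),
                 az_range = config$global_az_range,
                 az_step = config$global_az_step,
                 dz_step = config$global_dz_step,
                 mask_radius = config$mask_radius))
    report$global_fit <- lapply(gf, function(g)
      list(azimuth = g$azimuth, axial = g$axial, score = g$score))

    stage <- "stage1_difference"
    docked_actin <- lapply(gf, function(g)
      apply_transform(actin_only(models$free), g$transform))
    diff1 <- list(
      free = subtract_component(maps$free$noisy, docked_actin$free, "actin"),
      treated = subtract_component(maps$treated$noisy, docked_actin$treated,
                                   "actin"))
    report$stage1_scale <- lapply(diff1, attr, "scale_factor")

    stage <- "local_fits"
    ref <- lapply(gf, function(g) apply_transform(models$free, g$transform))
    # the troponin core sits against the tropomyosin annulus next to
    # subunits c/d; its density must not steer the rod fits, so its
    # neighbourhood (fanned over the plausible rotation range) is
    # excluded from the scoring corridors
    core_exclusion <- function(m) {
      pts <- model_coords(m, select_particles(m, "troponin", tag = "core"))
      do.call(rbind, lapply(seq(0, 30, by = 6), function(a)
        apply_transform(pts, cylindrical_transform(a, 0))))
    }
    fits <- lapply(names(diff1), function(st)
      fit_all_segments(diff1[[st]], ref[[st]],
                       exclude = core_exclusion(ref[[st]]),
                       az_range = config$local_az_range,
                       az_step = config$local_az_step,
                       dz_range = config$local_dz_range,
                       dz_step = config$local_dz_step,
                       dr_grid = config$local_dr_grid,
                       mask_radius = config$mask_radius,
                       anchor = models$anchor))
    names(fits) <- names(diff1)

    stage <- "quantify_rotations"
    key <- paste(fits$treated$subunit_label, fits$treated$strand)
    m <- match(key, paste(fits$free$subunit_label, fits$free$strand))
    rot <- data.frame(subunit_label = fits$treated$subunit_label,
                      strand = fits$treated$strand,
                      rotation = wrap_angle(fits$treated$azimuth -
                                            fits$free$azimuth[m]),
                      score = fits$treated$score,
                      stringsAsFactors = FALSE)
    rot$state <- classify_state(rot$rotation, config$thresholds)
    gm <- group_means(rot)
    report$fits <- list(free = fits$free, treated = fits$treated)
    report$rotations <- rot
    report$group_means <- list(barbed_abc = gm[[1]]$mean,
                               pointed_defg = gm[[2]]$mean,
                               difference = gm$difference)

    stage <- "stage2_difference"
    # rebuild tropomyosin at the fitted per-repeat azimuths, then subtract
    fitted_offsets <- vapply(letters[1:7], function(l)
      mean(rot$rotation[rot$subunit_label == l]), 0)
    fitted_offsets <- pmin(pmax(fitted_offsets, 0), 45)
    base <- build_actin_filament(config$n_subunits, models$params)
    fit_model <- list(
      free = models$free,
      treated = add_troponin(
        add_tropomyosin(base, repeat_azimuths(fitted_offsets),
                        anchor = models$anchor),
        stagger = config$stagger, anchor = models$anchor))
    diff2 <- lapply(names(diff1), function(st)
      subtract_component(maps[[st]]$noisy,
                         apply_transform(fit_model[[st]], gf[[st]]$transform),
                         "actin_tropomyosin"))
    names(diff2) <- names(diff1)
    report$stage2_scale <- lapply(diff2, attr, "scale_factor")

    stage <- "quantify_troponin"
    docked_free <- apply_transform(models$free, gf$free$transform)
    docked_treated <- apply_transform(fit_model$treated, gf$treated$transform)
    docked <- list(free = docked_free, treated = docked_treated)
    report$stagger <- lapply(names(diff2), function(st)
      troponin_stagger(diff2[[st]], docked[[st]], radius = config$tn_radius))
    names(report$stagger) <- names(diff2)
    # isolate the TnT1 tail: jointly scale the docked troponin core and
    # tail densities (they overlap), subtract the core contribution from
    # the stage-2 difference, then keep the strand-1 tail neighbourhood
    sub_model <- function(sel) {
      m <- docked$free[sel, , drop = FALSE]
      new_filament_model(as.data.frame(m), models$params)
    }
    core_map <- render_map(sub_model(select_particles(docked$free, "troponin",
                                                      tag = "core")),
                           config$voxel, config$resolution,
                           dim(diff2$free$grid), diff2$free$origin)
    tail_map <- render_map(sub_model(select_particles(docked$free, "troponin",
                                                      tag = "TnT1")),
                           config$voxel, config$resolution,
                           dim(diff2$free$grid), diff2$free$origin)
    sc <- amplitude_scales(diff2$free, list(core = core_map, tail = tail_map))
    diff3 <- diff2$free
    diff3$grid <- diff3$grid - sc["core"] * core_map$grid
    tnt1 <- segment_component(diff3, docked$free, "troponin",
                              radius = 14, strand = 1, tag = "TnT1")
    report$tnt1_span <- axial_span(tnt1, config$tnt1_threshold)
    report$tnt1_span_lattice <- 2 * 2 * models$params$rise

    if (isTRUE(config$half_maps)) {
      stage <- "fsc"
      hm <- half_map_pair(models$treated, config$voxel, config$resolution,
                          noise_spec(config$snr, seeds[3]), config$box)
      fc <- fsc(hm[[1]], hm[[2]], config$fsc_threshold)
      report$fsc_resolution <- fc$resolution
    }

    stage <- "outputs"
    if (!is.null(config$out_dir)) {
      dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
      p <- function(f) file.path(config$out_dir, f)
      write_mrc(maps$free$noisy, p("map_free.mrc"))
      write_mrc(maps$treated$noisy, p("map_treated.mrc"))
      write_mrc(diff1$treated, p("diff1_treated.mrc"))
      write_mrc(diff2$treated, p("diff2_treated.mrc"))
      write_model_pdb(docked$free, p("model_free.pdb"))
      write_model_pdb(docked$treated, p("model_treated_fitted.pdb"))
      write_fits_tsv(fits$treated, p("fits_treated.tsv"))
      write_fits_tsv(fits$free, p("fits_free.tsv"))
      jsonlite::write_json(report, p("report.json"), auto_unbox = TRUE,
                           digits = NA, null = "null", pretty = TRUE)
    }
    report
  }, error = function(e) {
    stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  })
}

#' Write small synthetic fixture maps with a ground-truth manifest
#'
#' Generates a Ca2+-free-like and a Ca2+-treated-like map pair (noisy,
#' envelope SNR 2) plus a JSON manifest recording the generator's
#' lattice, per-subunit azimuths, stagger and seeds.  Regeneration with
#' the same seed is byte-identical.
#'
#' @param seed Integer seed.
#' @param out_dir Writable output directory.
#' @param config Optional base [pipeline_config()] override.
#' @return Invisibly, the vector of file paths written.
#' @export
make_fixtures <- function(seed, out_dir, config = pipeline_config()) {
  config$seed <- as.integer(seed)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stopf("cannot create output directory '%s'", out_dir)
  models <- build_state_models(config)
  seeds <- derive_seeds(config$seed, 2)
  paths <- character(0)
  for (st in c("free", "treated")) {
    m <- models[[st]]
    clean <- render_map(m, config$voxel, config$resolution, config$box)
    noisy <- add_noise(clean, noise_spec(config$snr,
                                         seeds[if (st == "free") 1 else 2]))
    f <- file.path(out_dir, sprintf("map_%s.mrc", st))
    ok <- tryCatch(write_mrc(noisy, f), error = function(e)
      stopf("writing '%s' failed: %s", f, conditionMessage(e)))
    paths <- c(paths, f)
  }
  manifest <- list(
    seed = config$seed, sub_seeds = seeds,
    lattice = list(rise = config$rise, twist = config$twist,
                   actin_radius = config$actin_radius,
                   tm_radius = config$tm_radius),
    stagger = config$stagger,
    azimuths = list(free = config$azimuths_free,
                    treated = config$azimuths_treated),
    n_subunits = config$n_subunits,
    voxel = config$voxel, resolution = config$resolution,
    box = config$box, snr = config$snr)
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, mf))
}

#' Multi-seed recovery of the per-group tropomyosin rotations
#'
#' Runs the full pipeline once per seed and collects the recovered
#' barbed-side (a-c) and pointed-side (d-g) mean rotations, the troponin
#' staggers and the TnT1 span -- the quantities used to validate
#' parameter recovery against the generator's ground truth.
#'
#' @param seeds Integer vector of pipeline seeds.
#' @param config Base [pipeline_config()]; its `seed` is replaced per run.
#' @return Data frame with one row per seed: `seed`, `abc`, `defg`,
#'   `stagger_free`, `stagger_treated`, `tnt1_span`.
#' @export
parameter_recovery <- function(seeds = 1:20, config = pipeline_config()) {
  rows <- lapply(seeds, function(s) {
    config$seed <- as.integer(s)
    rep <- run_pipeline(config)
    data.frame(seed = s,
               abc = rep$group_means$barbed_abc,
               defg = rep$group_means$pointed_defg,
               stagger_free = rep$stagger$free,
               stagger_treated = rep$stagger$treated,
               tnt1_span = rep$tnt1_span)
  })
  do.call(rbind, rows)
}
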