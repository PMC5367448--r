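fit_stub <- function(label, strand, az) {
  structure(list(subunit_label = label, strand = strand, azimuth = az,
                 axial_shift = 0, radial_shift = 0, score = 0.9),
            class = "segment_fit")
}

test_that("rotation from blocked is a wrapped azimuth difference", {
  expect_equal(rotation_from_blocked(fit_stub("a", 1, 12),
                                     fit_stub("a", 1, 12)), 0)
  expect_equal(rotation_from_blocked(fit_stub("a", 1, 28),
                                     fit_stub("a", 1, 0)), 28)
  expect_equal(rotation_from_blocked(fit_stub("a", 1, -170),
                                     fit_stub("a", 1, 170)), 20)
  expect_error(rotation_from_blocked(fit_stub("a", 1, 0),
                                     fit_stub("b", 1, 0)),
               "invalid-argument")
})

test_that("state classification bands the rotation deterministically", {
  expect_equal(classify_state(0), "B")
  expect_equal(classify_state(18), "C")
  expect_equal(classify_state(28), "M")
  # boundary values assign to the more activated state
  expect_equal(classify_state(9), "C")
  expect_equal(classify_state(23), "M")

  # total, deterministic, and partitioning [0, 180)
  r <- seq(0, 179.5, by = 0.5)
  s <- classify_state(r)
  expect_true(all(s %in% c("B", "C", "M")))
  expect_identical(s, classify_state(r))
  expect_true(all(s[r < 9] == "B"))
  expect_true(all(s[r >= 9 & r < 23] == "C"))
  expect_true(all(s[r >= 23] == "M"))

  expect_error(classify_state(10, thresholds = c(23, 9)),
               "invalid-argument")
  sc <- state_call("c", 28, 0.7)
  expect_equal(sc$state, "M")
})

test_that("group means follow the barbed/pointed label grouping", {
  rot <- expand.grid(subunit_label = letters[1:7], strand = 1:2,
                     stringsAsFactors = FALSE)
  rot$rotation <- 20
  gm <- group_means(rot)
  expect_equal(gm[[1]]$mean, 20)
  expect_equal(gm[[2]]$mean, 20)
  expect_equal(gm$difference, 0)

  rot$rotation <- ifelse(rot$subunit_label %in% c("a", "b", "c"), 28, 18)
  gm <- group_means(rot)
  expect_equal(gm[[1]]$mean, 28)
  expect_equal(gm[[2]]$mean, 18)
  expect_equal(gm$difference, 10)

  expect_error(group_means(rot[rot$subunit_label != "d", ]),
               "invalid-argument")
})

test_that("troponin stagger is recovered over a ladder of true values", {
  p <- helical_params()
  base <- add_tropomyosin(build_actin_filament(18, p))
  for (true in c(0, 10, 20, 27.5, 40)) {
    model <- add_troponin(base, stagger = true)
    mp <- render_map(model, 4, 28, c(96, 96, 144))
    docked <- mark_docked(model)
    d2 <- subtract_component(mp, docked, "actin_tropomyosin")
    expect_equal(troponin_stagger(d2, docked), true, tolerance = 0.5)
  }

  # equivariance: shifting the whole map axially leaves the lag unchanged
  model <- add_troponin(base)
  mp <- render_map(model, 4, 28, c(96, 96, 144))
  docked <- mark_docked(model)
  d2 <- subtract_component(mp, docked, "actin_tropomyosin")
  shifted <- d2
  shifted$origin <- d2$origin + c(0, 0, 12)
  sh_model <- apply_transform(docked, rigid_transform(diag(3), c(0, 0, 12)))
  expect_equal(troponin_stagger(shifted, sh_model),
               troponin_stagger(d2, docked), tolerance = 1e-6)

  one <- model[!(model$component == "troponin" & model$strand == 2), ,
               drop = FALSE]
  one <- thinfilament:::new_filament_model(as.data.frame(one), p)
  expect_error(troponin_stagger(d2, one), "degenerate-input")
})

test_that("axial span measures blurred feature lengths", {
  # point blob: closed-form span of a Gaussian profile above 0.2 of max,
  # minus the rod-edge correction the measure applies
  sigma <- resolution_sigma(28)
  mp <- render_map(blob_model(), voxel = 2, resolution = 28,
                   box = c(48, 48, 48))
  expected <- 2 * sigma * sqrt(2 * log(1 / 0.2)) -
    2 * sigma * qnorm(1 - 0.2)
  expect_equal(axial_span(mp, 0.2), expected, tolerance = 2.5)

  # a TnT1-like rod of beads spanning 110 A measures 110 +/- 8
  model <- blocked_model()
  tail1 <- model[select_particles(model, "troponin", strand = 1,
                                  tag = "TnT1"), , drop = FALSE]
  tail1 <- thinfilament:::new_filament_model(as.data.frame(tail1),
                                             small_params())
  tm <- render_map(tail1, 4, 28, c(64, 64, 64))
  expect_equal(axial_span(tm, 0.2), 110, tolerance = 8)

  # the lattice closed form: two long-pitch subunits
  expect_equal(2 * 2 * small_params()$rise, 110)

  # reference value for the full-length alternative, for comparison only
  expect_gt(180, axial_span(tm, 0.2))

  empty <- tm
  empty$grid[] <- 0
  expect_error(axial_span(empty), "degenerate-input")
})

test_that("FSC is symmetric, affine-invariant and null-calibrated", {
  m <- stub_actin(6)
  hm <- half_map_pair(m, 4, 28, noise_spec(2, 21), c(48, 48, 48))
  f12 <- fsc(hm[[1]], hm[[2]])
  f21 <- fsc(hm[[2]], hm[[1]])
  expect_equal(f12$fsc, f21$fsc, tolerance = 1e-12)
  expect_gt(f12$fsc[1], 0.95)   # shared signal dominates the first shell

  a <- hm[[1]]; b <- hm[[2]]
  a$grid <- 2 * a$grid + 1; b$grid <- 2 * b$grid + 1
  fab <- fsc(a, b)
  expect_equal(fab$fsc[-1], f12$fsc[-1], tolerance = 1e-9)

  # two independent pure-noise maps: |FSC| <= 3/sqrt(n) in >= 95% of shells
  mk_noise <- function(seed) {
    g <- thinfilament:::with_seed(seed, array(rnorm(48^3), c(48, 48, 48)))
    density_map(g, 4)
  }
  fn <- fsc(mk_noise(1), mk_noise(2))
  ok <- abs(fn$fsc) <= 3 / sqrt(fn$n_voxels)
  expect_gte(mean(ok), 0.95)

  expect_error(fsc(hm[[1]], density_map(array(0.5, c(8, 8, 8)), 4)),
               "invalid-argument")
})

test_that("residue displacement uses the actin frame superposition", {
  m1 <- blocked_model()
  expect_equal(residue_displacement(m1, m1,
                                    list(component = "troponin",
                                         tag = "core", strand = 1)), 0)

  # a global rotation + translation of the whole model is nulled by the
  # frame superposition; an extra known displacement of the selection
  # survives it
  m2 <- apply_transform(m1, cylindrical_transform(25, 13), docked = FALSE)
  expect_equal(residue_displacement(m1, m2,
                                    list(component = "troponin",
                                         tag = "core", strand = 1)),
               0, tolerance = 1e-9)

  sel <- select_particles(m2, "troponin", tag = "core", strand = 1)
  m3 <- m2
  m3$x[sel] <- m3$x[sel] + 8
  m3$z[sel] <- m3$z[sel] + 6
  expect_equal(residue_displacement(m1, m3,
                                    list(component = "troponin",
                                         tag = "core", strand = 1)),
               10, tolerance = 1e-6)

  expect_error(residue_displacement(m1, m2, list(component = "myosin")),
               "invalid-argument")
})
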