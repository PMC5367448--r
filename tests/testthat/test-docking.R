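test_that("masked correlation scores behave like a correlation", {
  m <- stub_actin(8)
  mp <- stub_map(m)

  expect_equal(score_fit(mp, m), 1, tolerance = 1e-6)

  # affine intensity rescaling of the map leaves the score unchanged
  mp2 <- mp
  mp2$grid <- 3.7 * mp$grid + 0.2
  expect_equal(score_fit(mp2, m), score_fit(mp, m), tolerance = 1e-9)

  # a model displaced far beyond the mask radius scores ~ 0
  far <- apply_transform(m, rigid_transform(diag(3), c(60, 60, 0)),
                         docked = FALSE)
  expect_lt(abs(score_fit(mp, far)), 0.2)

  # posing the model outside the map leaves an empty mask
  gone <- apply_transform(m, rigid_transform(diag(3), c(500, 0, 0)),
                          docked = FALSE)
  expect_error(score_fit(mp, gone), "degenerate-input")
})

test_that("rigid transforms compose and validate", {
  a <- cylindrical_transform(30, 5)
  b <- cylindrical_transform(-10, 2)
  ab <- compose_transform(a, b)
  x <- matrix(rnorm(15), 5, 3)
  expect_equal(apply_transform(apply_transform(x, b), a),
               apply_transform(x, ab), tolerance = 1e-12)
  expect_error(rigid_transform(matrix(2 * diag(3), 3, 3)), "invalid-argument")
})

test_that("global fit recovers known poses", {
  m <- stub_actin(8)
  mp <- stub_map(m)

  # self-rendered noiseless map: identity within one grid step
  g0 <- global_fit(mp, m, az_range = c(-5, 5), az_step = 1)
  expect_lt(abs(g0$azimuth), 1)
  expect_lt(abs(g0$axial), 1)
  expect_gt(g0$score, 0.95)

  # a map rendered from the model rotated +10 deg about the axis
  mr <- apply_transform(m, cylindrical_transform(10, 0), docked = FALSE)
  mpr <- render_map(mr, 4, 28, c(48, 48, 64), origin = mp$origin)
  g10 <- global_fit(mpr, m, az_range = c(-15, 15), az_step = 1)
  expect_angle_equal(g10$azimuth, 10, 1)
})

test_that("global fit equals brute-force enumeration on a coarse grid", {
  m <- stub_actin(6)
  mp <- render_map(m, 4, 28, c(48, 48, 48))
  az_grid <- seq(-10, 10, by = 5)
  dz_grid <- seq(-4, 4, by = 2)

  # independent brute-force oracle over the same grid
  brute <- expand.grid(az = az_grid, dz = dz_grid)
  brute$score <- vapply(seq_len(nrow(brute)), function(i)
    score_fit(mp, m, cylindrical_transform(brute$az[i], brute$dz[i]),
              stride = 1L), 0)
  best <- brute[which.max(brute$score), ]

  g <- global_fit(mp, m, az_range = c(-10, 10), az_step = 5,
                  dz_range = c(-4, 4), dz_step = 2, stride = 1L,
                  refine = FALSE)
  expect_equal(g$azimuth, best$az)
  expect_equal(g$axial, best$dz)
})

test_that("pose recovery degrades monotonically with noise", {
  m <- stub_actin(8)
  clean <- stub_map(m)
  true_az <- 6
  mr <- apply_transform(m, cylindrical_transform(true_az, 0), docked = FALSE)
  sig <- render_map(mr, 4, 28, c(48, 48, 64), origin = clean$origin)

  err <- vapply(c(Inf, 2, 0.25), function(snr) {
    mean(vapply(1:5, function(s) {
      noisy <- add_noise(sig, noise_spec(snr, s))
      g <- global_fit(noisy, m, az_range = c(-12, 12), az_step = 2)
      abs(g$azimuth - true_az)
    }, 0))
  }, 0)
  expect_true(all(diff(err) >= -1e-9))
  # at SNR 2 the pose is still recovered within 2 deg / 2 A
  expect_lt(err[2], 2)
})

test_that("localised segment fits recover per-repeat azimuths", {
  # actin + tropomyosin only: troponin-density confounds are handled by
  # the pipeline's exclusion zones and exercised in the acceptance tests
  base <- build_actin_filament(18, small_params())
  blocked <- add_tropomyosin(base)
  mixed <- add_tropomyosin(base, repeat_azimuths(a = 28, b = 28, c = 28,
                                                 d = 18, e = 18, f = 18,
                                                 g = 18))
  box <- c(96, 96, 144)

  # blocked-state synthetic map: azimuth ~ 0 for every subunit
  mpb <- render_map(blocked, 4, 28, box)
  d1b <- subtract_component(mpb, mark_docked(blocked), "actin")
  fb <- fit_all_segments(d1b, blocked, az_range = c(-20, 50), az_step = 2)
  expect_lt(max(abs(fb$azimuth)), 1)

  # mixed-state map: azimuths cluster into two groups by subunit label
  mpm <- render_map(mixed, 4, 28, box, origin = mpb$origin)
  d1m <- subtract_component(mpm, mark_docked(blocked), "actin")
  fm <- fit_all_segments(d1m, blocked, az_range = c(-20, 50), az_step = 2)
  hi <- fm$azimuth[fm$subunit_label %in% c("a", "b", "c")]
  lo <- fm$azimuth[fm$subunit_label %in% c("e", "f")]
  expect_gt(min(hi), max(lo))
  expect_equal(mean(hi), 28, tolerance = 3)
  expect_equal(mean(lo), 18, tolerance = 3)

  # fits never exceed a correlation of 1 or leave the search bounds
  expect_true(all(abs(c(fb$score, fm$score)) <= 1))
  expect_true(all(fm$azimuth >= -20 & fm$azimuth <= 50))

  # a window covering the entire strand reproduces the global fit
  tm_only <- blocked[select_particles(blocked, "tropomyosin"), , drop = FALSE]
  tm_only <- thinfilament:::new_filament_model(as.data.frame(tm_only),
                                               small_params(),
                                               anchor = 6L)
  rot <- apply_transform(blocked, cylindrical_transform(8, 0), docked = FALSE)
  mprot <- render_map(rot, 4, 28, box, origin = mpb$origin)
  d1r <- subtract_component(mprot,
                            mark_docked(apply_transform(blocked[
                              select_particles(blocked, "actin"), ,
                              drop = FALSE],
                              cylindrical_transform(8, 0))), "actin")
  whole <- local_segment_fit(d1r, blocked, "d", 1, window = 21,
                             az_range = c(-5, 20), az_step = 1,
                             dz_range = c(0, 0), dz_step = 1,
                             dr_grid = 0, radial_band = Inf,
                             score_span = "window")
  gl <- global_fit(d1r, tm_only, az_range = c(-5, 20), az_step = 1,
                   dz_range = c(0, 0), stride = 1L)
  expect_angle_equal(whole$azimuth, gl$azimuth, 1)

  # terminal subunits need flanking context
  short <- blocked_model(14)
  mps <- render_map(short, 4, 28, c(96, 96, 120))
  expect_error(local_segment_fit(mps, short, "a", 1, anchor = 4),
               "flanking context")
})

test_that("candidate model ranking prefers the generating state", {
  blocked <- blocked_model()
  mixed <- mixed_model()
  box <- c(96, 96, 144)
  mpb <- render_map(blocked, 4, 28, box)
  mpm <- render_map(mixed, 4, 28, box, origin = mpb$origin)

  # true generator model versus a decoy rotated by 180 degrees
  decoy <- apply_transform(blocked, cylindrical_transform(180, 0),
                           docked = FALSE)
  rk <- rank_candidate_models(mpb, list(true = blocked, decoy = decoy),
                              az_range = c(-4, 4), az_step = 2,
                              dz_range = c(-2, 2), dz_step = 2)
  expect_equal(rk$id[1], "true")
  expect_gt(rk$score[1], rk$score[2])

  # identical candidates: equal scores, lexicographic stable order
  rk2 <- rank_candidate_models(mpb, list(b = blocked, a = blocked),
                               az_range = c(-2, 2), az_step = 2,
                               dz_range = c(0, 0))
  expect_equal(rk2$score[1], rk2$score[2])
  expect_equal(rk2$id, c("a", "b"))

  # cross-state scoring matrix: each map prefers its own state's model
  states <- list(blocked = blocked, mixed = mixed)
  sc <- sapply(states, function(cand) c(
    blocked = global_fit(mpb, cand, az_range = c(-2, 2), az_step = 1,
                         dz_range = c(0, 0))$score,
    mixed = global_fit(mpm, cand, az_range = c(-2, 2), az_step = 1,
                       dz_range = c(0, 0))$score))
  expect_gt(sc["blocked", "blocked"], sc["blocked", "mixed"])
  expect_gt(sc["mixed", "mixed"], sc["mixed", "blocked"])

  expect_error(rank_candidate_models(mpb, list(blocked)), "invalid-argument")
})
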