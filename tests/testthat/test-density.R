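test_that("rendering integrates to the particle weights", {
  b <- blob_model(c(0, 0, 0), weight = 10)
  mp <- render_map(b, voxel = 2, resolution = 20, box = c(48, 48, 48))

  # Gaussian peak centred on the particle
  peak <- which(mp$grid == max(mp$grid), arr.ind = TRUE)[1, ]
  pos <- mp$origin + mp$voxel * (peak - 1)
  expect_lt(max(abs(pos)), mp$voxel / 2 + 1e-9)
  expect_equal(sum(mp$grid) * mp$voxel^3, 10, tolerance = 0.01)

  # linearity: two equal particles integrate to exactly twice one
  b2 <- rbind(as.data.frame(b), as.data.frame(blob_model(c(10, 0, 4))))
  b2 <- thinfilament:::new_filament_model(b2, small_params())
  mp2 <- render_map(b2, voxel = 2, resolution = 20, box = c(48, 48, 48),
                    origin = mp$origin)
  one_a <- render_map(blob_model(c(0, 0, 0)), voxel = 2, resolution = 20,
                      box = c(48, 48, 48), origin = mp$origin)
  one_b <- render_map(blob_model(c(10, 0, 4)), voxel = 2, resolution = 20,
                      box = c(48, 48, 48), origin = mp$origin)
  expect_equal(mp2$grid, one_a$grid + one_b$grid, tolerance = 1e-12)

  expect_error(render_map(b, voxel = 4, resolution = 6), "Nyquist")
  expect_error(render_map(blob_model(c(500, 0, 0)), box = c(32, 32, 32)),
               "outside the box")
})

test_that("noise injection hits the requested envelope SNR and is seeded", {
  m <- stub_actin(8)
  mp <- render_map(m, voxel = 4, resolution = 28, box = c(64, 64, 64))

  expect_identical(add_noise(mp, noise_spec(Inf, 1)), mp)

  n1 <- add_noise(mp, noise_spec(2, 42))
  n2 <- add_noise(mp, noise_spec(2, 42))
  expect_identical(n1$grid, n2$grid)
  n3 <- add_noise(mp, noise_spec(2, 43))
  expect_false(identical(n1$grid, n3$grid))

  # realised variance ratio within the envelope (sample-variance oracle)
  env <- filament_envelope(mp)
  noise <- n1$grid - mp$grid
  snr_hat <- var(mp$grid[env]) / var(noise[env])
  expect_equal(snr_hat, 2, tolerance = 0.05 * 2)

  expect_error(noise_spec(-1, 1), "invalid-argument")
})

test_that("half maps share signal and lose correlation with noise", {
  m <- stub_actin(6)

  hm <- half_map_pair(m, voxel = 4, resolution = 28,
                      spec = noise_spec(Inf, 7), box = c(48, 48, 48))
  fc <- fsc(hm[[1]], hm[[2]])
  expect_true(all(abs(fc$fsc - 1) < 1e-9))

  # FSC-0.5 resolution degrades monotonically as SNR decreases
  res <- vapply(c(Inf, 2, 0.25), function(s)
    fsc(half_map_pair(m, 4, 28, noise_spec(s, 7), c(48, 48, 48))[[1]],
        half_map_pair(m, 4, 28, noise_spec(s, 7), c(48, 48, 48))[[2]],
        0.5)$resolution, 0)
  expect_true(all(diff(res) >= 0))
})

test_that("rendering is equivariant and bead granularity is invisible at 28 A", {
  m <- stub_actin(8)
  box <- c(48, 48, 80)
  origin <- c(-94, -94, -36)
  mp <- render_map(m, 4, 28, box, origin)

  # rotating the model about z by 90 deg equals rotating the grid
  mr <- apply_transform(m, cylindrical_transform(90, 0))
  mpr <- render_map(mr, 4, 28, box, origin)
  # grid rotated by 90 deg about z: (x, y) -> (-y, x); with a symmetric
  # origin this is index transpose + reverse
  rot_grid <- aperm(mp$grid, c(2, 1, 3))[dim(mp$grid)[2]:1, , ]
  expect_gt(cor(as.numeric(mpr$grid), as.numeric(rot_grid)), 0.999)

  # translating by whole voxels equals shifting the origin
  mt <- apply_transform(m, rigid_transform(diag(3), c(0, 0, 8)))
  mpt <- render_map(mt, 4, 28, box, origin + c(0, 0, 8))
  expect_equal(mpt$grid, mp$grid, tolerance = 1e-12)

  # map of the helix is invariant under its own symmetry operator: the
  # advanced lattice re-renders onto the same density away from the ends
  msym <- m
  xyz <- helical_operator(model_coords(m), small_params(), 2)
  msym$x <- xyz[, 1]; msym$y <- xyz[, 2]; msym$z <- xyz[, 3]
  mps <- render_map(msym, 4, 28, box, origin)
  lo <- 26; hi <- 55   # central region z ~ [55, 180] A, away from the ends
  expect_gt(cor(as.numeric(mps$grid[, , lo:hi]),
                as.numeric(mp$grid[, , lo:hi])), 0.99)

  # splitting every bead into a fine sub-bead cloud changes nothing at 28 A
  fine <- do.call(rbind, lapply(seq_len(nrow(m)), function(i) {
    off <- expand.grid(dx = c(-2, 2), dy = c(-2, 2), dz = c(-2, 2))
    data.frame(x = m$x[i] + off$dx, y = m$y[i] + off$dy, z = m$z[i] + off$dz,
               weight = m$weight[i] / 8, component = m$component[i],
               strand = m$strand[i], subunit_index = m$subunit_index[i],
               subunit_label = NA_character_, residue_tag = NA_character_,
               in_unit = FALSE, stringsAsFactors = FALSE)
  }))
  fine <- thinfilament:::new_filament_model(fine, small_params())
  mpf <- render_map(fine, 4, 28, box, origin)
  expect_gt(cor(as.numeric(mpf$grid), as.numeric(mp$grid)), 0.98)
})

test_that("MRC files round-trip and carry conformant headers", {
  m <- stub_actin(6)
  mp <- render_map(m, 4, 28, c(32, 32, 48))
  f <- tempfile(fileext = ".mrc")
  write_mrc(mp, f)

  rt <- read_mrc(f)
  expect_equal(dim(rt$grid), dim(mp$grid))
  expect_equal(rt$voxel, mp$voxel, tolerance = 1e-6)
  expect_equal(rt$origin, mp$origin, tolerance = 1e-4)
  # float32 quantisation is the only loss; a second round-trip is exact
  f2 <- tempfile(fileext = ".mrc")
  write_mrc(rt, f2)
  expect_identical(read_mrc(f2)$grid, rt$grid)

  # header fields per the MRC2014 layout
  con <- file(f, "rb")
  words <- readBin(con, "integer", 4, size = 4, endian = "little")
  close(con)
  expect_equal(words[1:3], dim(mp$grid))
  expect_equal(words[4], 2L)            # mode 2, 32-bit float
  hdr <- readBin(f, "raw", 1024)
  expect_equal(rawToChar(hdr[209:212]), "MAP ")
  expect_equal(as.integer(hdr[213:214]), c(0x44, 0x44))

  suppressWarnings(expect_error(read_mrc(tempfile()), "cannot open|No such"))
})

test_that("an independent MRC reader agrees with ours", {
  # gemmi (via the system python) as a cross-implementation oracle for
  # the header semantics: dimensions, voxel size, origin and data values
  m <- stub_actin(4)
  mp <- render_map(m, 4, 28, c(24, 24, 32))
  f <- tempfile(fileext = ".mrc")
  write_mrc(mp, f)
  py <- tempfile(fileext = ".py")
  writeLines(c(
    "import gemmi, json, sys",
    sprintf("g = gemmi.read_ccp4_map('%s')", f),
    "u = g.grid.unit_cell",
    "print(json.dumps({'nu': g.grid.nu, 'nv': g.grid.nv, 'nw': g.grid.nw,",
    "  'a': u.a, 'vsum': float(g.grid.array.sum())}))"), py)
  out <- suppressWarnings(system2("python", py, stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0)
    fail(paste("gemmi oracle failed:", paste(out, collapse = " ")))
  j <- jsonlite::fromJSON(out[length(out)])
  expect_equal(c(j$nu, j$nv, j$nw), dim(mp$grid))
  expect_equal(j$a, 24 * 4, tolerance = 1e-4)
  expect_equal(j$vsum, sum(mp$grid), tolerance = 1e-3 * abs(sum(mp$grid)))
})
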