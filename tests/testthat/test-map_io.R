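test_that("MRC write/read round-trips values, origin and spacing", {
  vals <- array(runif(4 * 5 * 6), dim = c(4, 5, 6))
  g <- density_grid(vals, origin = c(-3, 2.5, 7), spacing = c(1, 1.2, 0.8))
  f <- tempfile(fileext = ".mrc")
  write_mrc(g, f)
  g2 <- read_mrc(f)
  expect_equal(g2$values, g$values, tolerance = 1e-6)  # float32 precision
  expect_equal(g2$origin, g$origin, tolerance = 1e-6)
  expect_equal(g2$spacing, g$spacing, tolerance = 1e-6)

  # degenerate single-voxel map
  g1 <- density_grid(array(7, dim = c(1, 1, 1)), origin = c(1, 2, 3))
  f1 <- tempfile(fileext = ".mrc")
  write_mrc(g1, f1)
  r1 <- read_mrc(f1)
  expect_equal(dim(r1$values), c(1L, 1L, 1L))
  expect_equal(r1$values[1, 1, 1], 7, tolerance = 1e-6)
  expect_equal(r1$origin, c(1, 2, 3), tolerance = 1e-6)
})

test_that("permuted axis order is normalized, matching an independent reader", {
  # hand-craft a z,y,x-ordered MRC file (mapc=3, mapr=2, maps=1)
  dims_xyz <- c(2L, 3L, 4L)
  vals <- array(seq_len(prod(dims_xyz)), dim = dims_xyz)
  f <- tempfile(fileext = ".mrc")
  con <- file(f, "wb")
  nxyz_file <- dims_xyz[c(3, 2, 1)]   # z fastest in the file
  writeBin(as.integer(c(nxyz_file, 2L, 0L, 0L, 0L, dims_xyz)), con, size = 4,
           endian = "little")
  writeBin(as.numeric(c(dims_xyz, 90, 90, 90)), con, size = 4,
           endian = "little")
  writeBin(as.integer(c(3L, 2L, 1L)), con, size = 4, endian = "little")
  writeBin(as.numeric(c(min(vals), max(vals), mean(vals))), con, size = 4,
           endian = "little")
  writeBin(as.integer(c(1L, 0L)), con, size = 4, endian = "little")
  writeBin(integer(25), con, size = 4, endian = "little")
  writeBin(as.numeric(c(0, 0, 0)), con, size = 4, endian = "little")
  writeChar("MAP ", con, nchars = 4, eos = NULL)
  writeBin(as.raw(c(0x44, 0x44, 0, 0)), con)
  writeBin(as.numeric(stats::sd(vals)), con, size = 4, endian = "little")
  writeBin(0L, con, size = 4, endian = "little")
  writeBin(raw(800), con)
  # file order: first (fastest) index is z
  writeBin(as.numeric(as.vector(aperm(vals, c(3, 2, 1)))), con, size = 4,
           endian = "little")
  close(con)

  g <- read_mrc(f)
  expect_equal(dim(g$values), dims_xyz)
  expect_equal(g$values, vals, tolerance = 1e-6)

  # independent oracle: gemmi reorders the same file to x,y,z
  py <- sprintf(paste0(
    "import gemmi, json\n",
    "m = gemmi.read_ccp4_map('%s')\n",
    "m.setup(0.0, gemmi.MapSetup.ReorderOnly)\n",
    "g = m.grid\n",
    "out = [[i, j, k, g.get_value(i, j, k)]\n",
    "       for i in range(g.nu) for j in range(g.nv) for k in range(g.nw)]\n",
    "print(json.dumps(out))\n"), f)
  res <- system2("python", c("-c", shQuote(py)), stdout = TRUE)
  ref <- matrix(unlist(jsonlite::fromJSON(res, simplifyVector = TRUE)),
                ncol = 4)
  got <- g$values[ref[, 1:3] + 1]
  expect_equal(got, ref[, 4], tolerance = 1e-5)
})

test_that("simulated maps have the right peak, linearity and total mass", {
  one <- atomic_model(data.frame(element = "CA", resno = 1L, resid = "ALA",
                                 chain = "A", x = 0, y = 0, z = 0))
  g <- simulate_map(one, resolution = 5, spacing = 1)
  peak <- which(g$values == max(g$values), arr.ind = TRUE)
  expect_equal(g$origin + (as.integer(peak[1, ]) - 1) * g$spacing,
               c(0, 0, 0))

  # linearity: two far-apart atoms sum to twice one atom's mass
  two <- atomic_model(data.frame(element = "CA", resno = 1:2, resid = "ALA",
                                 chain = "A", x = c(0, 40), y = 0, z = 0))
  g2 <- simulate_map(two, resolution = 5, spacing = 1)
  expect_equal(sum(g2$values), 2 * sum(g$values), tolerance = 1e-6)

  # analytic Gaussian mass
  sigma <- 0.225 * 5
  expect_equal(sum(g$values), (2 * pi * sigma^2)^1.5, tolerance = 0.01)

  # translation equivariance by an integer number of voxels
  shifted <- atomic_model(data.frame(element = "CA", resno = 1L,
                                     resid = "ALA", chain = "A",
                                     x = 3, y = 0, z = 0))
  gs <- simulate_map(shifted, resolution = 5, spacing = 1)
  pk <- which(gs$values == max(gs$values), arr.ind = TRUE)
  expect_equal(gs$origin + (as.integer(pk[1, ]) - 1) * gs$spacing, c(3, 0, 0))

  expect_error(simulate_map(atomic_model(data.frame(
    element = character(0), resno = integer(0), resid = character(0),
    chain = character(0), x = numeric(0), y = numeric(0),
    z = numeric(0))), 5, 1))
})

test_that("synthetic chains have ideal geometry and are deterministic", {
  for (kind in c("helix", "strand", "mixed")) {
    ch <- make_synthetic_chain(kind, 12, seed = 7)
    xyz <- as.matrix(ch$atoms[, c("x", "y", "z")])
    expect_equal(nrow(xyz), 12L)
    d <- sqrt(rowSums(diff(xyz)^2))
    expect_true(all(abs(d - 3.8) < 0.01), info = kind)
    ch2 <- make_synthetic_chain(kind, 12, seed = 7)
    expect_identical(ch$atoms, ch2$atoms)
  }
  # closed-form helix: end-to-end of n=18 from the parametrization
  h <- make_synthetic_chain("helix", 18)
  xyz <- as.matrix(h$atoms[, c("x", "y", "z")])
  twist <- 100 * pi / 180
  radius <- sqrt(3.8^2 - 1.5^2) / (2 * sin(twist / 2))
  expected_e2e <- sqrt((radius * cos(17 * twist) - radius)^2 +
                       (radius * sin(17 * twist))^2 + (17 * 1.5)^2)
  expect_equal(sqrt(sum((xyz[18, ] - xyz[1, ])^2)), expected_e2e,
               tolerance = 1e-8)
  expect_error(make_synthetic_chain("helix", 2))
})

test_that("threshold_grid counts, nests and errors on empty selections", {
  g <- density_grid(array(c(0.1, 0.5, 0.9, 0, 0, 0, 0, 0),
                          dim = c(2, 2, 2)))
  expect_equal(nrow(threshold_grid(g, 0.5)), 2L)
  expect_equal(nrow(threshold_grid(g, 0)), 8L)
  expect_error(threshold_grid(g, 10), "threshold")

  # monotone nesting on a simulated map
  fx <- helix_fixture()
  counts <- vapply(c(0.02, 0.1, 0.3, 0.6) * max(fx$map$values),
                   function(th) nrow(threshold_grid(fx$map, th)), 1L)
  expect_true(all(diff(counts) < 0))
})

test_that("zone_mask keeps exactly the voxels within the radius", {
  g <- density_grid(array(1, dim = c(9, 9, 9)))
  m <- atomic_model(data.frame(element = "CA", resno = 1L, resid = "ALA",
                               chain = "A", x = 4, y = 4, z = 4))
  zm <- zone_mask(g, m, radius = 1.5)
  idx <- which(zm$values > 0, arr.ind = TRUE)
  d <- sqrt(rowSums(sweep(idx - 1, 2, c(4, 4, 4))^2))
  expect_true(all(d <= 1.5))
  # brute-force count over all voxels
  all_idx <- which(array(TRUE, dim(g$values)), arr.ind = TRUE)
  expected <- sum(sqrt(rowSums(sweep(all_idx - 1, 2, c(4, 4, 4))^2)) <= 1.5)
  expect_equal(nrow(idx), expected)

  # radius covering the whole grid leaves it unchanged
  zm2 <- zone_mask(g, m, radius = 100)
  expect_equal(zm2$values, g$values)

  # model far outside the map zeroes everything
  far <- atomic_model(data.frame(element = "CA", resno = 1L, resid = "ALA",
                                 chain = "A", x = 500, y = 500, z = 500))
  expect_true(all(zone_mask(g, far, radius = 2)$values == 0))
})

test_that("negative densities are clamped on construction", {
  g <- density_grid(array(c(-1, 2, -3, 4), dim = c(2, 2, 1)))
  expect_true(all(g$values >= 0))
  expect_equal(g$values[2, 1, 1], 2)
})
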