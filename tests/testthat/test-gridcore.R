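test_that("quaternion algebra: rotation, composition, group property", {
  q <- quat_from_axis_angle(c(0, 0, 1), pi / 2)
  v <- quat_to_matrix(q) %*% c(1, 0, 0)
  expect_equal(as.numeric(v), c(0, 1, 0), tolerance = 1e-9)
  expect_equal(quat_to_matrix(quat_identity()), diag(3))
  # composition: rotate(R2, rotate(R1, x)) == rotate(R2 o R1, x)
  set.seed(3)
  for (i in 1:5) {
    q1 <- quat_from_axis_angle(rnorm(3), runif(1, 0, pi))
    q2 <- quat_from_axis_angle(rnorm(3), runif(1, 0, pi))
    x <- matrix(rnorm(9), 3)
    a <- x %*% t(quat_to_matrix(q1)) %*% t(quat_to_matrix(q2))
    b <- x %*% t(quat_to_matrix(quat_multiply(q2, q1)))
    expect_equal(a, b, tolerance = 1e-9)
  }
  expect_error(quat_to_matrix(c(1, 1, 0, 0)), "unit quaternion")
  # q and -q are the same rotation
  expect_equal(quat_angle(q, -q), 0)
})

test_that("rotate_structure rotates coordinates and preserves parameters", {
  tc <- make_toy_complex(7, n_rec = 30, n_lig = 12)
  s <- tc$ligand
  q <- quat_from_axis_angle(c(1, 2, 3), 1.1)
  r <- rotate_structure(s, q, center = c(0, 0, 0))
  expect_equal(coords(r), coords(s) %*% t(quat_to_matrix(q)),
               tolerance = 1e-9)
  expect_identical(r$atoms$radius, s$atoms$radius)
  expect_identical(rotate_structure(s, quat_identity())$atoms, s$atoms)
})

test_that("single-atom core covers exactly the voxels within r - delta", {
  atoms <- data.frame(serial = 1, name = "CA", altloc = "", res_name = "ALA",
                      chain = "A", res_seq = 1, icode = "", x = 0.3, y = 0.2,
                      z = -0.1, occupancy = 1, element = "C",
                      is_hetero = FALSE)
  ps <- assign_params(dockmapr:::new_structure(atoms, "one"))
  g <- build_receptor_grids(ps, h = 1, margin = 5, delta = 0.5, sigma = 2)
  # enumerate voxel centers independently
  idx <- which(g$channels$core > 0, arr.ind = TRUE)
  centers <- sweep((idx - 0.5) * g$h, 2, g$origin, "+")
  d <- sqrt(rowSums(sweep(centers, 2, c(0.3, 0.2, -0.1))^2))
  expect_true(all(d <= 1.4))
  # and no voxel within 1.4 was missed
  all_idx <- as.matrix(expand.grid(1:g$dims[1], 1:g$dims[2], 1:g$dims[3]))
  all_cen <- sweep((all_idx - 0.5) * g$h, 2, g$origin, "+")
  inside <- sqrt(rowSums(sweep(all_cen, 2, c(0.3, 0.2, -0.1))^2)) <= 1.4
  expect_equal(sum(g$channels$core), sum(inside))
  # surface shell occupies (r - delta, r + sigma]
  sidx <- which(g$channels$surface > 0, arr.ind = TRUE)
  sd <- sqrt(rowSums(sweep(sweep((sidx - 0.5) * g$h, 2, g$origin, "+"),
                           2, c(0.3, 0.2, -0.1))^2))
  expect_true(all(sd > 1.4 & sd <= 3.9))
})

test_that("charge channel conserves total charge; empty input errors", {
  tc <- make_toy_complex(2, n_rec = 30, n_lig = 12)
  ps <- tc$receptor
  ps$atoms$charge <- rnorm(n_atoms(ps))
  g <- build_grids(ps, h = 1)
  expect_equal(sum(g$channels$charge), sum(ps$atoms$charge),
               tolerance = 1e-9)
  expect_error(build_grids(ps, h = -1), "h must be")
})

test_that("translating the structure by h shifts every channel one voxel", {
  tc <- make_toy_complex(3, n_rec = 40, n_lig = 12)
  ps <- tc$receptor
  g1 <- build_grids(ps, h = 1, origin = c(-20, -20, -20), dims = c(44, 44, 44))
  ps2 <- ps
  coords(ps2) <- sweep(coords(ps), 2, c(1, 0, 0), "+")
  g2 <- build_grids(ps2, h = 1, origin = c(-20, -20, -20), dims = c(44, 44, 44))
  expect_equal(g2$channels$core[2:44, , ], g1$channels$core[1:43, , ])
  expect_equal(g2$channels$surface[2:44, , ], g1$channels$surface[1:43, , ])
  expect_equal(g2$channels$charge[2:44, , ], g1$channels$charge[1:43, , ],
               tolerance = 1e-12)
  expect_equal(g2$channels$pair[2:44, , , ], g1$channels$pair[1:43, , , ],
               tolerance = 1e-12)
})

test_that("fft_correlate equals the brute-force oracle on random grids", {
  for (seed in 1:4) {
    rec <- random_gridset(c(14, 12, 10), seed = seed, density = 0.4)
    lig <- random_gridset(c(7, 8, 6), seed = seed + 100, density = 0.4)
    f <- fft_correlate(rec, lig)
    b <- brute_force_correlate(rec, lig)
    scale <- max(abs(b$values))
    expect_lt(max(abs(f$values - b$values)) / scale, 1e-10)
    for (ch in c("rep", "attr", "elec", "pair"))
      expect_equal(f$components[[ch]], b$components[[ch]], tolerance = 1e-9)
  }
})

test_that("delta-function surface grids give -w_attr at the alignment", {
  mk_delta <- function(dims, at) {
    z <- array(0, dims)
    ch <- list(core = z, surface = z, charge = z, pair = array(0, c(dims, 6)))
    ch$surface[at[1], at[2], at[3]] <- 1
    new_gridset(c(0, 0, 0), 1, ch)
  }
  rec <- mk_delta(c(6, 6, 6), c(4, 3, 5))
  lig <- mk_delta(c(4, 4, 4), c(2, 1, 2))
  w <- energy_weights()
  f <- fft_correlate(rec, lig, w)
  expect_equal(sum(abs(f$values) > 1e-9), 1)
  expect_equal(min(f$values), -w$w_attr, tolerance = 1e-9)
  # the nonzero translation aligns the two delta voxels
  i <- arrayInd(which.min(f$values), dim(f$values))
  expect_equal(as.integer(i) + f$t0 - 1L, c(4, 3, 5) - c(2, 1, 2))
})

test_that("zero ligand grids give an identically zero field", {
  rec <- random_gridset(c(8, 8, 8), seed = 5)
  lig <- random_gridset(c(4, 4, 4), seed = 6)
  for (nm in c("core", "surface", "charge")) lig$channels[[nm]][] <- 0
  lig$channels$pair[] <- 0
  expect_true(all(fft_correlate(rec, lig)$values == 0))
  expect_true(all(brute_force_correlate(rec, lig)$values == 0))
})

test_that("weight linearity: scaling a weight scales its component exactly", {
  rec <- random_gridset(c(8, 8, 8), seed = 7)
  lig <- random_gridset(c(5, 5, 5), seed = 8)
  w1 <- energy_weights()
  w2 <- w1; w2$w_elec <- w1$w_elec * 3
  f1 <- fft_correlate(rec, lig, w1)
  f2 <- fft_correlate(rec, lig, w2)
  d <- f2$values - f1$values
  expect_equal(d, 2 * w1$w_elec * f1$components$elec, tolerance = 1e-9)
})

test_that("score decomposition identity holds at every voxel", {
  rec <- random_gridset(c(9, 9, 9), seed = 9)
  lig <- random_gridset(c(5, 5, 5), seed = 10)
  w <- energy_weights()
  f <- fft_correlate(rec, lig, w)
  v <- w$w_rep * f$components$rep + w$w_attr * f$components$attr +
    w$w_elec * f$components$elec + w$w_pair * f$components$pair
  expect_equal(f$values, v, tolerance = 1e-9)
})

test_that("grid compatibility errors", {
  rec <- random_gridset(c(8, 8, 8), seed = 1)
  lig <- random_gridset(c(4, 4, 4), seed = 2)
  lig$h <- 0.8
  expect_error(fft_correlate(rec, lig), "spacing mismatch")
  big <- random_gridset(c(10, 10, 10), seed = 3)
  expect_error(fft_correlate(rec, big), "dimensions")
})
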