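small_complex <- function(seed = 9) make_toy_complex(seed, n_rec = 80, n_lig = 16)

test_that("rotation_set: identity first, deterministic, coverage improves", {
  expect_equal(rotation_set(1), list(quat_identity()))
  expect_identical(rotation_set(50, seed = 3), rotation_set(50, seed = 3))
  expect_false(identical(rotation_set(50, seed = 3), rotation_set(50, seed = 4)))
  for (q in rotation_set(25, seed = 5))
    expect_equal(sum(q^2), 1, tolerance = 1e-9)
  # Monte-Carlo coverage: mean distance to the nearest member shrinks
  set.seed(77)
  probes <- replicate(100, {
    q <- rnorm(4); q / sqrt(sum(q^2))
  }, simplify = FALSE)
  mean_nn <- vapply(c(10, 100, 1000), function(n) {
    rs <- rotation_set(n, seed = 11)
    mean(vapply(probes, function(p)
      min(vapply(rs, quat_angle, numeric(1), q2 = p)), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_nn) < 0))
})

test_that("identity-only docking recovers the planted translation", {
  tc <- make_toy_complex(9)
  pl <- dock_rigid(tc$receptor, tc$ligand,
                   dock_params(n_rotations = 1, retained = 5))
  expect_lte(ligand_rmsd(pl[[1]], tc$planted_pose, tc$ligand),
             sqrt(3))                      # within one voxel at h = 1
})

test_that("pose energies equal the brute-force field at their translations", {
  tc <- small_complex()
  p <- dock_params(n_rotations = 1, retained = 8, per_rotation_keep = 8)
  pl <- dock_rigid(tc$receptor, tc$ligand, p)
  # rebuild the exact grids dock_rigid used and correlate by brute force
  rg <- build_grids(tc$receptor, h = 1, margin = 5)
  lxyz <- coords(tc$ligand)
  center <- colMeans(lxyz)
  rmax <- max(sqrt(rowSums(sweep(lxyz, 2, center)^2)))
  lo <- floor(center - rmax - 5)
  side <- ceiling(2 * (rmax + 5)) + 1L
  lg <- build_grids(tc$ligand, h = 1, origin = lo, dims = rep(side, 3))
  bf <- brute_force_correlate(rg, lg)
  for (i in seq_len(length(pl))) {
    pose <- pl[[i]]
    idx <- matrix(pose$t_voxel - bf$t0 + 1L, 1)
    expect_equal(pose$energy, bf$values[idx], tolerance = 1e-6)
    w <- p$weights
    expect_equal(pose$energy,
                 w$w_rep * pose$components$rep + w$w_attr * pose$components$attr +
                   w$w_elec * pose$components$elec + w$w_pair * pose$components$pair,
                 tolerance = 1e-6)
  }
})

test_that("retention contract: min(candidates, N) poses, sorted, ranked", {
  tc <- small_complex()
  pl <- dock_rigid(tc$receptor, tc$ligand,
                   dock_params(n_rotations = 40, retained = 100,
                               per_rotation_keep = 5))
  expect_equal(length(pl), 100)            # 200 candidates -> 100 kept
  e <- vapply(pl$poses, `[[`, numeric(1), "energy")
  expect_true(all(diff(e) >= 0))
  expect_equal(vapply(pl$poses, `[[`, integer(1), "rank"), 1:100)
  # fewer candidates than N
  pl2 <- dock_rigid(tc$receptor, tc$ligand,
                    dock_params(n_rotations = 7, retained = 100))
  expect_equal(length(pl2), 7)
})

test_that("docking is deterministic under a fixed seed", {
  tc <- small_complex()
  p <- dock_params(n_rotations = 15, retained = 15, seed = 23)
  t1 <- pose_table(dock_rigid(tc$receptor, tc$ligand, p))
  t2 <- pose_table(dock_rigid(tc$receptor, tc$ligand, p))
  expect_identical(t1, t2)
})

test_that("energy ordering is invariant under rigid co-translation", {
  tc <- small_complex()
  p <- dock_params(n_rotations = 10, retained = 10)
  pl1 <- dock_rigid(tc$receptor, tc$ligand, p)
  rec2 <- tc$receptor; lig2 <- tc$ligand
  coords(rec2) <- sweep(coords(rec2), 2, c(3, -2, 5), "+")
  coords(lig2) <- sweep(coords(lig2), 2, c(3, -2, 5), "+")
  pl2 <- dock_rigid(rec2, lig2, p)
  e1 <- vapply(pl1$poses, `[[`, numeric(1), "energy")
  e2 <- vapply(pl2$poses, `[[`, numeric(1), "energy")
  expect_equal(e1, e2, tolerance = 1e-6)
})

test_that("restraint filtering is sound and can exclude the planted pose", {
  tc <- make_toy_complex(9)
  # the planted ligand centroid sits ~7 A from the receptor center on +x;
  # demand the first ligand residue stay far from receptor residue 1
  lig1 <- tc$ligand$atoms$res_seq[1]
  rs <- generate_restraints(sprintf("R.1.CA:L.%d.CA", lig1),
                            dmin = 25, dmax = 60, k = 1)
  pl <- dock_rigid(tc$receptor, tc$ligand,
                   dock_params(n_rotations = 5, retained = 20,
                               per_rotation_keep = 5), restraints = rs)
  for (i in seq_len(length(pl))) {
    ok <- satisfied(tc$receptor, tc$ligand, rs, pose = pl[[i]])
    expect_true(ok$ok)
    expect_gt(ligand_rmsd(pl[[i]], tc$planted_pose, tc$ligand), 2)
  }
  # infeasible restraints -> explicit error
  rs2 <- generate_restraints(sprintf("R.1.CA:L.%d.CA", lig1), 500, 600, 1)
  expect_error(dock_rigid(tc$receptor, tc$ligand,
                          dock_params(n_rotations = 2, retained = 5),
                          restraints = rs2), "no feasible pose")
})

test_that("filter_poses equals the per-pose predicate re-check", {
  tc <- small_complex()
  pl <- dock_rigid(tc$receptor, tc$ligand,
                   dock_params(n_rotations = 20, retained = 20))
  lig1 <- tc$ligand$atoms$res_seq[1]
  rs <- generate_restraints(sprintf("R.1.CA:L.%d.CA", lig1), 5, 18, 1)
  kept <- filter_poses(pl, tc$receptor, tc$ligand, rs)
  manual <- Filter(function(p) satisfied(tc$receptor, tc$ligand, rs,
                                         pose = p)$ok, pl$poses)
  expect_equal(length(kept), length(manual))
  if (length(kept) > 0)
    expect_equal(kept[[1]]$trans, manual[[1]]$trans)
})

test_that("refine_pose: no-clash minimum is stable; clashes never increase", {
  tc <- make_toy_complex(9)
  planted <- tc$planted_pose
  # refining the planted pose barely moves it
  m0 <- refine_pose(tc$receptor, tc$ligand, planted)
  expect_lte(ligand_rmsd(m0, planted, tc$ligand), 1.5)
  expect_lte(m0$energy_cont,
             continuous_energy(tc$receptor,
                               pose_apply(planted, coords(tc$ligand)),
                               tc$ligand) + 1e-9)
  # a pose pushed 1 A into the wall gains clashes; refinement removes them
  pushed <- planted
  pushed$trans <- planted$trans + c(-1, 0, 0)
  x_push <- pose_apply(pushed, coords(tc$ligand))
  e_before <- continuous_energy(tc$receptor, x_push, tc$ligand)
  cl_before <- clash_count(tc$receptor, x_push, tc$ligand)
  m1 <- refine_pose(tc$receptor, tc$ligand, pushed)
  x_after <- pose_apply(m1, coords(tc$ligand))
  expect_lte(m1$energy_cont, e_before)
  expect_lte(clash_count(tc$receptor, x_after, tc$ligand), cl_before)
  if (!is.null(m1$rmsd_moved)) expect_lte(m1$rmsd_moved, 3)
})
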