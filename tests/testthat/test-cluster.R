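toy_small <- function(seed = 4) make_toy_complex(seed, n_rec = 40, n_lig = 12)

mk_pose <- function(trans, energy = 0, q = quat_identity(),
                    center = c(0, 0, 0)) {
  dockmapr:::new_pose(q, center, c(0L, 0L, 0L), trans, energy)
}

mk_pose_list <- function(poses) {
  for (i in seq_along(poses)) poses[[i]]$rank <- i
  dockmapr:::new_pose_list(poses, dock_params(), "rec", "lig")
}

test_that("ligand_rmsd: identity, pure translation, and a hand case", {
  tc <- toy_small()
  p0 <- mk_pose(c(0, 0, 0))
  expect_equal(ligand_rmsd(p0, p0, tc$ligand), 0)
  # pure translation by 3 A -> exactly 3
  p3 <- mk_pose(c(0, 3, 0))
  expect_equal(ligand_rmsd(p0, p3, tc$ligand), 3, tolerance = 1e-9)
  # 3-atom hand case against the direct formula
  A <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 2, 0))
  B <- rbind(c(1, 0, 0), c(1, 1, 0), c(0, 2, 3))
  expect_equal(ligand_rmsd(A, B), sqrt(mean(c(1, 1, 9))))
  expect_error(ligand_rmsd(A[0, , drop = FALSE], B[0, , drop = FALSE]),
               "mask")
})

test_that("ligand_rmsd behaves as a metric on random pose triples", {
  tc <- toy_small()
  set.seed(21)
  for (i in 1:10) {
    ps <- lapply(1:3, function(j)
      mk_pose(rnorm(3, sd = 5),
              q = quat_from_axis_angle(rnorm(3), runif(1, 0, pi))))
    d12 <- ligand_rmsd(ps[[1]], ps[[2]], tc$ligand)
    d21 <- ligand_rmsd(ps[[2]], ps[[1]], tc$ligand)
    d13 <- ligand_rmsd(ps[[1]], ps[[3]], tc$ligand)
    d23 <- ligand_rmsd(ps[[2]], ps[[3]], tc$ligand)
    expect_equal(d12, d21, tolerance = 1e-9)
    expect_lte(d13, d12 + d23 + 1e-9)
  }
})

test_that("greedy clustering separates two wells and ranks by population", {
  tc <- toy_small()
  # well A: 5 poses within ~1 A of each other; well B: 2 poses, 30 A away
  poses <- c(lapply(1:5, function(i) mk_pose(c(0.2 * i, 0, 0), energy = -i)),
             lapply(1:2, function(i) mk_pose(c(30 + 0.2 * i, 0, 0),
                                             energy = -10 * i)))
  cl <- greedy_cluster(mk_pose_list(poses), tc$ligand,
                       cluster_params(radius = 5))
  expect_length(cl, 2)
  expect_equal(sapply(cl, `[[`, "population"), c(5, 2))
  expect_setequal(cl[[1]]$members, 1:5)
  expect_setequal(cl[[2]]$members, 6:7)
  # population conservation
  expect_equal(sum(sapply(cl, `[[`, "population")), 7)
})

test_that("all-identical poses form a single cluster", {
  tc <- toy_small()
  poses <- lapply(1:6, function(i) mk_pose(c(1, 2, 3), energy = i))
  cl <- greedy_cluster(mk_pose_list(poses), tc$ligand)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$population, 6)
})

test_that("clustering is invariant to input order (fixed tie-breaks)", {
  tc <- toy_small()
  set.seed(31)
  poses <- lapply(1:40, function(i)
    mk_pose(rnorm(3, sd = 6), energy = round(rnorm(1), 3)))
  pl1 <- mk_pose_list(poses)
  perm <- sample(40)
  pl2 <- mk_pose_list(poses[perm])
  cl1 <- greedy_cluster(pl1, tc$ligand, cluster_params(radius = 4))
  cl2 <- greedy_cluster(pl2, tc$ligand, cluster_params(radius = 4))
  sets1 <- lapply(cl1, function(cl) sort(cl$members))
  sets2 <- lapply(cl2, function(cl) sort(perm[cl$members]))
  expect_equal(sets1, sets2)
})

test_that("at most max_clusters clusters are returned on 2000 random poses", {
  tc <- toy_small()
  set.seed(41)
  poses <- lapply(1:2000, function(i) mk_pose(rnorm(3, sd = 25)))
  cl <- greedy_cluster(mk_pose_list(poses), tc$ligand, cluster_params())
  expect_lte(length(cl), 10)
  pops <- sapply(cl, `[[`, "population")
  expect_true(all(diff(pops) <= 0))
})

test_that("irmsd: identity is zero; empty interface errors", {
  tc <- make_toy_complex(6, n_rec = 60, n_lig = 20)
  ref <- dockmapr:::new_structure(
    rbind(tc$receptor$atoms,
          pose_ligand(tc$planted_pose, tc$ligand)$atoms), "ref")
  expect_equal(irmsd(ref, ref, "R", "L"), 0, tolerance = 1e-9)
  # chains far apart: empty interface
  far <- ref
  far$atoms$x[far$atoms$chain == "L"] <-
    far$atoms$x[far$atoms$chain == "L"] + 100
  expect_error(irmsd(ref, far, "R", "L"), "interface")
})

test_that("irmsd of a translated ligand matches the Horn oracle", {
  tc <- make_toy_complex(8, n_rec = 60, n_lig = 20)
  lig0 <- pose_ligand(tc$planted_pose, tc$ligand)
  ref <- dockmapr:::new_structure(rbind(tc$receptor$atoms, lig0$atoms), "ref")
  lig1 <- lig0
  coords(lig1) <- sweep(coords(lig0), 2, c(1, 0, 0), "+")
  model <- dockmapr:::new_structure(rbind(tc$receptor$atoms, lig1$atoms),
                                    "model")
  got <- irmsd(model, ref, "R", "L", cutoff = 10)
  # oracle: collect the same interface backbone atoms and superpose with
  # the quaternion method
  ir <- interface_residues(ref, "R", "L", cutoff = 10)
  keys <- c(paste(ir$a$chain, ir$a$res_seq), paste(ir$b$chain, ir$b$res_seq))
  pick <- function(s) {
    a <- s$atoms
    a <- a[paste(a$chain, a$res_seq) %in% keys & a$name %in% c("N", "CA", "C", "O"), ]
    as.matrix(a[order(a$chain, a$res_seq, a$name), c("x", "y", "z")])
  }
  expect_equal(got, horn_superpose_rmsd(pick(model), pick(ref)),
               tolerance = 1e-6)
  expect_gt(got, 0)     # translation is only partially removable
  expect_lt(got, 1)
})
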