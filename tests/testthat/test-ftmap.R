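mk_ppose <- function(center, e, probe = "ethane") {
  structure(list(probe = probe, rotation = quat_identity(),
                 center = center, trans = center, t_voxel = c(0L, 0L, 0L),
                 energy_grid = e, energy_min = e,
                 xyz = matrix(center, 1, 3), center_min = center),
            class = "ProbePose")
}

mk_pcluster <- function(center, avg_e, size = 3, probe = "ethane") {
  structure(list(probe = probe,
                 members = lapply(seq_len(size), function(i)
                   mk_ppose(center + rnorm(3, sd = 0.2), avg_e, probe)),
                 center = center, avg_energy = avg_e, size = size),
            class = "ProbeCluster")
}

mk_site <- function(center, population) {
  members <- lapply(seq_len(population), function(i)
    mk_pcluster(center + rnorm(3, sd = 0.3), -10 - i))
  structure(list(members = members, population = population,
                 center = center, mean_energy = -12, rank = NA,
                 strength_class = if (population >= 16) "strong" else
                   if (population > 10) "intermediate" else "weak"),
            class = "ConsensusSite")
}

test_that("probe library has the 16 published molecules, in order", {
  pl <- probe_library()
  expect_length(pl, 16)
  expect_equal(names(pl)[1], "ethanol")
  expect_equal(names(pl)[16], "N,N-dimethylformamide")
  expect_setequal(names(pl), c(
    "ethanol", "2-propanol", "isobutanol", "acetone", "acetaldehyde",
    "dimethyl ether", "cyclohexane", "ethane", "acetonitrile", "urea",
    "methylamine", "phenol", "benzaldehyde", "benzene", "acetamide",
    "N,N-dimethylformamide"))
})

test_that("probe templates are neutral, connected, with sane bonds", {
  for (p in probe_library()) {
    expect_lt(abs(sum(p$atoms$charge)), 1e-9)
    expect_true(all(p$atoms$radius > 0))
    expect_true(all(p$atoms$atype %in%
                      c("C_aliph", "C_arom", "N_don", "O_acc", "S", "P")))
    # connectivity under a 0.9-1.8 A bond criterion
    xyz <- coords(p)
    n <- nrow(xyz)
    if (n == 1) next
    D <- as.matrix(dist(xyz))
    bonds <- D > 0.9 & D < 1.8
    expect_true(all(D[bonds] > 0.9 & D[bonds] < 1.8))
    # BFS for connectedness
    seen <- logical(n); seen[1] <- TRUE; queue <- 1
    while (length(queue)) {
      i <- queue[1]; queue <- queue[-1]
      nb <- which(bonds[i, ] & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    expect_true(all(seen), label = paste("connected:", p$id))
    # no nonbonded pair closer than a bond
    expect_true(all(D[upper.tri(D)] > 0.9))
  }
})

test_that("probe checksums are stable across calls", {
  expect_identical(probe_checksums(), probe_checksums())
})

test_that("cluster_probe_poses: singleton, zero-radius limit, two lobes", {
  p <- map_params()
  one <- cluster_probe_poses(list(mk_ppose(c(0, 0, 0), -5)), p)
  expect_length(one, 1)
  expect_equal(one[[1]]$avg_energy, -5)
  expect_equal(cluster_probe_poses(list(), p), list())
  set.seed(61)
  poses <- lapply(1:12, function(i) mk_ppose(rnorm(3, sd = 8), -i))
  tiny <- map_params(probe_cluster_radius = 1e-9, clusters_kept = 100)
  each <- cluster_probe_poses(poses, tiny)
  expect_length(each, 12)
  # two lobes with known means: ranking follows average energy
  lobeA <- lapply(1:4, function(i) mk_ppose(c(0.1 * i, 0, 0), -10 - i))
  lobeB <- lapply(1:3, function(i) mk_ppose(c(20 + 0.1 * i, 0, 0), -30 - i))
  cl <- cluster_probe_poses(c(lobeA, lobeB), map_params(probe_cluster_radius = 3))
  expect_length(cl, 2)
  expect_equal(cl[[1]]$avg_energy, mean(c(-31, -32, -33)))
  expect_equal(cl[[1]]$size, 3)           # deeper lobe ranks first
  expect_equal(cl[[2]]$size, 4)
})

test_that("consensus_sites merges by locus, conserves clusters, ranks by population", {
  set.seed(62)
  p <- map_params()
  cls <- c(lapply(1:5, function(i) mk_pcluster(c(0, 0, 0) + rnorm(3, sd = 0.5),
                                               -20 - i)),
           lapply(1:3, function(i) mk_pcluster(c(20, 0, 0) + rnorm(3, sd = 0.5),
                                               -10 - i)))
  sites <- consensus_sites(cls, p)
  expect_length(sites, 2)
  expect_equal(vapply(sites, `[[`, numeric(1), "population"), c(5, 3))
  expect_equal(sum(vapply(sites, `[[`, numeric(1), "population")), length(cls))
  expect_equal(consensus_sites(list(), p), list())
  # monotonicity: larger consensus radius never increases the site count
  for (i in 1:5) {
    cls2 <- lapply(1:10, function(j) mk_pcluster(rnorm(3, sd = 6), -j))
    n1 <- length(consensus_sites(cls2, map_params(consensus_radius = 3)))
    n2 <- length(consensus_sites(cls2, map_params(consensus_radius = 6)))
    expect_lte(n2, n1)
  }
})

test_that("strength classes: strong >= 16, intermediate > 10, else weak", {
  expect_equal(consensus_site(16)$strength_class, "strong")
  expect_equal(consensus_site(15)$strength_class, "intermediate")
  expect_equal(consensus_site(11)$strength_class, "intermediate")
  expect_equal(consensus_site(10)$strength_class, "weak")
  expect_equal(consensus_site(3)$strength_class, "weak")
})

test_that("druggability verdicts reproduce the published worked examples", {
  # interleukin-2 interface hotspots: 18, 12, 5, 3 probe clusters
  il2 <- lapply(c(18, 12, 5, 3), consensus_site)
  r1 <- druggability_report(il2)
  expect_true(r1$druggable)
  expect_equal(r1$strongest, 18)
  # ZipA interface hotspots: 8, 3, 2 -> not druggable
  zipa <- lapply(c(8, 3, 2), consensus_site)
  r2 <- druggability_report(zipa)
  expect_false(r2$druggable)
  expect_equal(r2$strongest, 8)
  # threshold is inclusive at 16
  expect_true(druggability_report(list(consensus_site(16)))$druggable)
  expect_false(druggability_report(list(consensus_site(15)))$druggable)
})

test_that("predict_sites merges nearby hotspots and splits distant ones", {
  set.seed(63)
  tp <- make_toy_pocket(11)
  p <- map_params()
  near <- list(mk_site(c(0, 0, 0), 5), mk_site(c(3, 0, 0), 4))
  far <- list(mk_site(c(0, 0, 0), 5), mk_site(c(30, 0, 0), 4))
  s1 <- predict_sites(near, tp$receptor, p)
  expect_length(s1, 1)
  expect_equal(s1[[1]]$total_population, 9)
  s2 <- predict_sites(far, tp$receptor, p)
  expect_length(s2, 2)
  expect_equal(s2[[1]]$total_population, 5)   # ranked by population
})

test_that("single-probe mapping finds the designed cavity", {
  tp <- make_toy_pocket(1)
  p <- map_params(K = 200, n_rotations = 12, seed = 7)
  probe <- probe_library()$ethane
  poses <- map_probe(tp$receptor, probe, p)
  expect_lte(length(poses), 200)
  top50 <- poses[seq_len(50)]
  d <- vapply(top50, function(pp)
    sqrt(sum((pp$center_min - tp$cavity_center)^2)), numeric(1))
  expect_gte(mean(d < tp$cavity_radius), 0.8)
  # determinism
  poses2 <- map_probe(tp$receptor, probe, p)
  expect_equal(vapply(poses, `[[`, numeric(1), "energy_min"),
               vapply(poses2, `[[`, numeric(1), "energy_min"))
  # minimizer never worsens the continuous energy
  for (pp in poses[seq(1, 200, by = 25)]) {
    expect_lte(pp$energy_min,
               continuous_energy(tp$receptor,
                                 sweep(sweep(coords(probe), 2,
                                             colMeans(coords(probe))) %*%
                                         t(quat_to_matrix(pp$rotation)),
                                       2, colMeans(coords(probe)) + pp$trans,
                                       "+"),
                                 probe) + 1e-6)
  }
})

test_that("map_by_domains: identity case, overlap and empty-range errors", {
  tp <- make_toy_pocket(2)
  p <- map_params(K = 60, n_rotations = 6, clusters_kept = 3, seed = 7)
  probes <- probe_library()[c("ethane", "benzene")]
  whole <- map_structure(tp$receptor, p, probes)
  md <- map_by_domains(tp$receptor, list("R:1-150"), p, probes)
  expect_equal(hotspot_table(md$domains[[1]]$sites),
               hotspot_table(whole$sites))
  expect_true(all(c("whole", "R:1-150") %in% md$report$source))
  expect_error(map_by_domains(tp$receptor, list("R:1-80", "R:60-150"), p,
                              probes), "overlap")
  expect_error(map_by_domains(tp$receptor, list("R:30-10"), p, probes),
               "empty")
})
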