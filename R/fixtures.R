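# Deterministic synthetic test systems with built-in ground truth:
# a planted-pose complementary complex and a designed-cavity receptor.
# Pseudo-atoms are CA-only poly-alanine so every downstream parameter
# lookup works unmodified.

# rejection-sampled points in an arbitrary region with a minimum separation
dart_region <- function(n, inside, lo, hi, min_sep, max_tries = 800000) {
  pts <- matrix(NA_real_, n, 3)
  got <- 0
  tries <- 0
  while (got < n && tries < max_tries) {
    tries <- tries + 1
    x <- runif(3, lo, hi)
    if (!inside(x)) next
    if (got > 0 &&
        min(rowSums(sweep(pts[seq_len(got), , drop = FALSE], 2, x)^2)) <
          min_sep^2) next
    got <- got + 1
    pts[got, ] <- x
  }
  if (got < n)
    stop(sprintf("fixture sampling failed: placed %d of %d atoms", got, n))
  pts
}

point_segment_distance <- function(x, a, b) {
  ab <- b - a
  t <- min(1, max(0, sum((x - a) * ab) / sum(ab^2)))
  sqrt(sum((x - (a + t * ab))^2))
}

# rejection-sampled points in a ball with a minimum separation, optionally
# avoiding an exclusion point set within a clearance
dart_ball <- function(n, radius, min_sep, avoid = NULL, clearance = 0,
                      center = c(0, 0, 0), max_tries = 800000) {
  pts <- matrix(NA_real_, n, 3)
  got <- 0
  tries <- 0
  while (got < n && tries < max_tries) {
    tries <- tries + 1
    u <- runif(3, -1, 1)
    if (sum(u^2) > 1) next
    x <- center + radius * u
    if (!is.null(avoid) &&
        min(rowSums(sweep(avoid, 2, x)^2)) < clearance^2) next
    if (got > 0 &&
        min(rowSums(sweep(pts[seq_len(got), , drop = FALSE], 2, x)^2)) <
          min_sep^2) next
    got <- got + 1
    pts[got, ] <- x
  }
  if (got < n)
    stop(sprintf("fixture sampling failed: placed %d of %d atoms", got, n))
  pts
}

ca_structure <- function(xyz, chain, id) {
  n <- nrow(xyz)
  atoms <- data.frame(
    serial = seq_len(n), name = "CA", altloc = "", res_name = "ALA",
    chain = chain, res_seq = seq_len(n), icode = "",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occupancy = 1,
    element = "C", is_hetero = FALSE, stringsAsFactors = FALSE)
  assign_params(new_structure(atoms, id))
}

#' Planted-pose toy receptor-ligand complex
#'
#' Builds a compact pseudo-atom ligand, buries it partway into a
#' pseudo-atom receptor ball (the receptor is sampled around the ligand
#' with a fixed clearance, so the cavity is the ligand's exact
#' complement), then presents the ligand displaced by a recorded pure
#' translation.  The planted pose is the unique complementarity optimum:
#' at it, ligand atoms sit in the receptor's attractive shell with zero
#' core overlap.  Constructors self-validate these guarantees.
#'
#' @param seed integer; same seed, same coordinates
#' @param n_rec,n_lig atom counts (defaults 300 / 60; minimum 20 / 10)
#' @return a `ToyComplex`: `receptor`, `ligand` (both `ParamStructure`),
#'   `planted_pose` (a `Pose` mapping the presented ligand into the
#'   pocket), `seed`
#' @export
make_toy_complex <- function(seed = 1, n_rec = 300, n_lig = 60) {
  if (n_rec < 20 || n_lig < 10)
    stop("toy complex needs n_rec >= 20 and n_lig >= 10")
  set.seed(seed %% .Machine$integer.max)
  # The ligand is an asymmetric L-shaped blob (two arms of unequal
  # length): a round blob fits a round cavity in any orientation, so
  # shape asymmetry is what makes the planted orientation unique.
  # Tight packing (1.8-2.0 A separations) keeps pseudo-molecule
  # interiors solid on the grid; porous interiors are spuriously
  # attractive to the surface channel.
  # geometry scales with the atom counts so packing density (and hence
  # grid solidity) is size-independent
  ls <- (n_lig / 60)^(1 / 3)
  arm_r <- 3.4 * ls
  arm_a <- 9 * ls
  arm_b <- 6 * ls
  sep_l <- max(1.2, 1.8 * ls)
  inside_l <- function(x)
    point_segment_distance(x, c(0, 0, 0), c(arm_a, 0, 0)) <= arm_r ||
    point_segment_distance(x, c(0, 0, 0), c(0, arm_b, 0)) <= arm_r
  lig_xyz <- dart_region(n_lig, inside_l, c(-arm_r, -arm_r, -arm_r),
                         c(arm_a + arm_r, arm_b + arm_r, arm_r), sep_l)
  lig_xyz <- sweep(lig_xyz, 2, colMeans(lig_xyz))      # center at origin
  # bury the ligand partway into the receptor ball
  r_rec <- (4.08 * n_rec)^(1 / 3)
  bury <- c(0.65 * r_rec, 0, 0)
  lig_planted <- sweep(lig_xyz, 2, bury, "+")
  rec_xyz <- dart_ball(n_rec, r_rec, 2.0, avoid = lig_planted,
                       clearance = 3.2)
  receptor <- ca_structure(rec_xyz, "R", sprintf("toy-receptor-%d", seed))
  offset <- c(28, 6, -4)                               # presentation offset
  ligand <- ca_structure(sweep(lig_planted, 2, offset, "+"), "L",
                         sprintf("toy-ligand-%d", seed))
  planted <- new_pose(quat_identity(), colMeans(coords(ligand)),
                      t_voxel = c(NA, NA, NA), trans = -offset,
                      energy = NA_real_)
  out <- structure(list(receptor = receptor, ligand = ligand,
                        planted_pose = planted, seed = seed),
                   class = "ToyComplex")
  validate_toy_complex(out)
  out
}

# grid energy of the ligand placed at an arbitrary displacement
toy_grid_energy <- function(receptor, ligand, disp,
                            w = energy_weights(), h = 1.0) {
  rg <- build_grids(receptor, h = h)
  lig <- ligand
  coords(lig) <- sweep(coords(ligand), 2, disp, "+")
  lg <- build_grids(lig, h = h, origin = rg$origin, dims = rg$dims)
  comp <- components_at(rg, lg, c(0L, 0L, 0L), pair_contact_matrix())
  w$w_rep * comp$rep + w$w_attr * comp$attr + w$w_elec * comp$elec +
    w$w_pair * comp$pair
}

validate_toy_complex <- function(tc) {
  planted_xyz <- pose_apply(tc$planted_pose, coords(tc$ligand))
  # zero core overlap: no receptor-ligand pair inside the shrunk cores
  dmin <- min(as.matrix(stats::dist(rbind(coords(tc$receptor), planted_xyz)))[
    seq_len(n_atoms(tc$receptor)),
    n_atoms(tc$receptor) + seq_len(n_atoms(tc$ligand))])
  if (dmin < 2.8)
    stop("toy complex: core overlap at the planted pose (min dist ", dmin, ")")
  e0 <- toy_grid_energy(tc$receptor, tc$ligand, tc$planted_pose$trans)
  for (ax in 1:3) for (s in c(-5, 5)) {
    d <- tc$planted_pose$trans
    d[ax] <- d[ax] + s
    if (toy_grid_energy(tc$receptor, tc$ligand, d) <= e0)
      stop("toy complex: planted pose is not the energy optimum")
  }
  invisible(tc)
}

#' Designed-pocket toy receptor
#'
#' A roughly spherical pseudo-atom body with one concave cavity (radius
#' 5 A) opening to the surface; the cavity interior is devoid of atoms
#' and its lining residues are recorded.
#'
#' @param seed integer seed
#' @param n_atoms_target atoms attempted for the body (default 150)
#' @return a `ToyPocket`: `receptor`, `cavity_center`, `cavity_radius`,
#'   `lining_residues` (res_seq vector), `seed`
#' @export
make_toy_pocket <- function(seed = 1, n_atoms_target = 150) {
  set.seed(seed %% .Machine$integer.max)
  cavity_center <- c(5.5, 0, 0)
  cavity_radius <- 4.5
  body_radius <- 8.5
  xyz <- dart_ball(n_atoms_target, body_radius, 2.0,
                   avoid = matrix(cavity_center, 1, 3),
                   clearance = cavity_radius)
  receptor <- ca_structure(xyz, "R", sprintf("toy-pocket-%d", seed))
  d <- sqrt(rowSums(sweep(xyz, 2, cavity_center)^2))
  lining <- which(d <= cavity_radius + 2.5)
  if (min(d) < cavity_radius) stop("toy pocket: atom inside the cavity")
  if (length(lining) < 10) stop("toy pocket: cavity lining too sparse")
  structure(list(receptor = receptor, cavity_center = cavity_center,
                 cavity_radius = cavity_radius,
                 lining_residues = receptor$atoms$res_seq[lining],
                 seed = seed),
            class = "ToyPocket")
}

#' Write fixture structures to a directory
#' @param x a `ToyComplex` or `ToyPocket`
#' @param dir output directory
#' @export
write_fixture <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (inherits(x, "ToyComplex")) {
    write_pdb(x$receptor, file.path(dir, "REC.pdb"))
    write_pdb(x$ligand, file.path(dir, "LIG.pdb"))
    jsonlite::write_json(
      list(seed = x$seed, rotation = x$planted_pose$rotation,
           center = x$planted_pose$center, trans = x$planted_pose$trans),
      file.path(dir, "PLANTED.json"), auto_unbox = TRUE, digits = NA)
  } else {
    write_pdb(x$receptor, file.path(dir, "PROT.pdb"))
    jsonlite::write_json(
      list(seed = x$seed, cavity_center = x$cavity_center,
           cavity_radius = x$cavity_radius,
           lining_residues = x$lining_residues),
      file.path(dir, "POCKET.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
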