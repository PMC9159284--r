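# ---- rotations (unit quaternions, w-first) ----

#' Identity rotation quaternion
#' @export
quat_identity <- function() c(1, 0, 0, 0)

quat_check <- function(q) {
  if (length(q) != 4 || abs(sqrt(sum(q^2)) - 1) > 1e-9)
    stop("rotation must be a unit quaternion (|q| = 1 within 1e-9)")
  invisible(q)
}

#' Quaternion composition (q1 applied after q2)
#' @param q1,q2 unit quaternions `c(w, x, y, z)`
#' @export
quat_multiply <- function(q1, q2) {
  w1 <- q1[1]; x1 <- q1[2]; y1 <- q1[3]; z1 <- q1[4]
  w2 <- q2[1]; x2 <- q2[2]; y2 <- q2[3]; z2 <- q2[4]
  c(w1 * w2 - x1 * x2 - y1 * y2 - z1 * z2,
    w1 * x2 + x1 * w2 + y1 * z2 - z1 * y2,
    w1 * y2 - x1 * z2 + y1 * w2 + z1 * x2,
    w1 * z2 + x1 * y2 - y1 * x2 + z1 * w2)
}

#' Rotation matrix of a unit quaternion
#' @param q unit quaternion `c(w, x, y, z)`
#' @export
quat_to_matrix <- function(q) {
  quat_check(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

#' Quaternion from axis-angle
#' @param axis 3-vector (normalized internally); `angle` radians
#' @param angle rotation angle in radians
#' @export
quat_from_axis_angle <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  c(cos(angle / 2), sin(angle / 2) * axis)
}

#' Angular distance between two rotations (radians)
#'
#' `q` and `-q` denote the same rotation and have distance 0.
#' @param q1,q2 unit quaternions
#' @export
quat_angle <- function(q1, q2) {
  2 * acos(min(1, abs(sum(q1 * q2))))
}

#' Rotate a structure about a center
#'
#' Coordinates are rotated; all parameters are untouched.
#' @param ps a `Structure` or `ParamStructure`
#' @param q unit quaternion
#' @param center 3-vector rotation center (default: centroid)
#' @export
rotate_structure <- function(ps, q, center = NULL) {
  quat_check(q)
  xyz <- coords(ps)
  if (is.null(center)) center <- colMeans(xyz)
  R <- quat_to_matrix(q)
  coords(ps) <- sweep(sweep(xyz, 2, center) %*% t(R), 2, center, "+")
  ps
}

# ---- grids ----

#' Construct a raw grid set from channel arrays (testing/backdoor API)
#' @param origin 3-vector (A); `h` spacing; `channels` named list with
#'   `core`, `surface`, `charge` 3-D arrays and `pair` a 4-D array
#' @param h grid spacing in Angstrom
#' @param channels named list of channel arrays
#' @param atypes coarse-type labels for the pair channel slices
#' @export
new_gridset <- function(origin, h, channels, atypes = .atype_levels) {
  dims <- dim(channels$core)
  for (nm in c("surface", "charge"))
    stopifnot(identical(dim(channels[[nm]]), dims))
  stopifnot(identical(dim(channels$pair)[1:3], dims))
  structure(list(origin = as.numeric(origin), h = h, dims = dims,
                 channels = channels, atypes = atypes),
            class = "GridSet")
}

#' @export
print.GridSet <- function(x, ...) {
  cat(sprintf("<GridSet> %dx%dx%d voxels, h = %g A, origin (%.1f, %.1f, %.1f)\n",
              x$dims[1], x$dims[2], x$dims[3], x$h,
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Discretize a parameterized structure into multi-channel grids
#'
#' Channels: `core` = 1 at voxel centers inside any atom's van der Waals
#' sphere shrunk by the overlap tolerance `delta`; `surface` = 1 in the
#' shell `(r - delta, r + sigma]` around atoms (core voxels excluded);
#' `charge` = trilinearly spread partial charges; `pair` = trilinear
#' unit densities per coarse atom type.  Voxel ownership is half-open:
#' `index = floor((coord - origin) / h)`, voxel centers at
#' `origin + (index + 0.5) h`.
#'
#' @param ps a `ParamStructure`
#' @param h grid spacing, A (> 0)
#' @param margin padding beyond the structure extent, A.  The FFT path
#'   zero-pads to the full correlation size, so the margin only has to
#'   cover the surface-shell support, not the partner's diameter.
#' @param delta overlap tolerance, A (default 0.5)
#' @param sigma surface shell width, A (default 2.0)
#' @param origin,dims optional explicit lattice (both or neither); when
#'   omitted the origin is snapped to a multiple of `h` below
#'   `min(coord) - margin`
#' @return a `GridSet`
#' @export
build_receptor_grids <- function(ps, h = 1.0, margin = 5, delta = 0.5,
                                 sigma = 2.0, origin = NULL, dims = NULL) {
  if (h <= 0) stop("grid spacing h must be > 0")
  if (!n_atoms(ps)) stop("empty structure")
  if (!is_param_structure(ps)) stop("structure must be parameterized (assign_params)")
  xyz <- coords(ps)
  if (is.null(origin)) {
    origin <- h * floor((apply(xyz, 2, min) - margin) / h)
    top <- h * ceiling((apply(xyz, 2, max) + margin) / h)
    dims <- as.integer(round((top - origin) / h))
  } else {
    stopifnot(!is.null(dims))
    dims <- as.integer(dims)
  }
  type <- match(ps$atoms$atype, .atype_levels)
  type[is.na(type)] <- 0L
  ch <- cpp_rasterize(xyz, ps$atoms$radius, ps$atoms$charge, type,
                      as.numeric(origin), h, dims, delta, sigma,
                      length(.atype_levels))
  new_gridset(origin, h, ch)
}

#' @rdname build_receptor_grids
#' @export
build_grids <- build_receptor_grids

#' Energy coefficient sets
#'
#' Named weight sets applied to the channel correlations.  `balanced` is
#' the default set: `w_rep = 8, w_attr = 1, w_elec = 0.6, w_pair = 1`.
#' The repulsive weight is far above the attractive one because the core
#' channel is a sparse indicator (about 10 voxels per atom at 1 A spacing)
#' while the surface shell covers about 240 voxels per atom: a clashing
#' atom overlaps only 1-3 core voxels yet can buy tens of shell-overlap
#' voxels by burying deeper, so each core voxel must cost more than that
#' gain for clashes to be always penalized.
#' @param name one of `"balanced"`, `"electrostatic"`, `"hydrophobic"`
#' @export
energy_weights <- function(name = c("balanced", "electrostatic", "hydrophobic")) {
  name <- match.arg(name)
  w <- switch(name,
    balanced      = c(w_rep = 8, w_attr = 1,   w_elec = 0.6, w_pair = 1),
    electrostatic = c(w_rep = 8, w_attr = 1,   w_elec = 1.5, w_pair = 0.6),
    hydrophobic   = c(w_rep = 8, w_attr = 1.2, w_elec = 0.3, w_pair = 1.5))
  out <- as.list(w)
  out$name <- name
  class(out) <- "EnergyWeights"
  out
}

# smallest 5-smooth integer >= n (fast mixed-radix FFT sizes)
good_fft_size <- function(n) {
  k <- n
  repeat {
    m <- k
    for (p in c(2, 3, 5)) while (m %% p == 0) m <- m / p
    if (m == 1) return(k)
    k <- k + 1
  }
}

pad_array <- function(a, P) {
  out <- array(0, P)
  d <- dim(a)
  out[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- a
  out
}

# cross-correlation via zero-padded FFT:
# corr[t] = sum_v a[v] b[v - t], t in [-(db-1), da-1] per dimension;
# fb may be a precomputed fft of the padded b
corr_fft <- function(a = NULL, b = NULL, P, da, db, fa = NULL, fb = NULL) {
  if (is.null(fa)) fa <- stats::fft(pad_array(a, P))
  if (is.null(fb)) fb <- stats::fft(pad_array(b, P))
  cc <- Re(stats::fft(fa * Conj(fb), inverse = TRUE)) / prod(P)
  ix <- lapply(1:3, function(k)
    c(if (db[k] > 1) (P[k] - db[k] + 2):P[k], 1:da[k]))
  cc[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
}

check_grid_compat <- function(rec, lig) {
  if (abs(rec$h - lig$h) > 1e-12)
    stop("spacing mismatch between receptor and ligand grids")
  if (any(lig$dims > rec$dims))
    stop("ligand grid dimensions must not exceed receptor grid dimensions")
}

score_field_template <- function(rec, lig, rotation) {
  list(rotation = rotation, h = rec$h, rec_origin = rec$origin,
       lig_origin = lig$origin, rec_dims = rec$dims, lig_dims = lig$dims,
       t0 = -(lig$dims - 1L))
}

assemble_score_field <- function(tmpl, comps, w) {
  values <- w$w_rep * comps$rep + w$w_attr * comps$attr +
    w$w_elec * comps$elec + w$w_pair * comps$pair
  out <- c(tmpl, list(values = values, components = comps, weights = w))
  class(out) <- "ScoreField"
  out
}

#' Translational correlation score of two grid sets (FFT path)
#'
#' For every integer translation `t` of the ligand lattice against the
#' receptor lattice computes
#' `E(t) = w_rep corr(core, core) - w_attr corr(surf, surf) +
#'  w_elec corr(chg, chg) + w_pair sum_ij eps_ij corr(pair_i, pair_j)`
#' with zero-padding (no wrap-around aliasing anywhere in the reported
#' range).  Lower is better.
#'
#' @param rec,lig `GridSet`s with equal spacing
#' @param w an [energy_weights()] set
#' @param rotation rotation bookkeeping tag stored in the result
#' @param eps pairwise atom-type contact matrix
#' @return a `ScoreField` with `values` and per-channel `components`
#'   (`rep`, `attr`, `elec`, `pair`), each an array over translations
#'   `t = t0 .. t0 + dim - 1` per axis
#' @export
fft_correlate <- function(rec, lig, w = energy_weights(),
                          rotation = quat_identity(),
                          eps = pair_contact_matrix()) {
  check_grid_compat(rec, lig)
  da <- rec$dims; db <- lig$dims
  P <- vapply(da + db - 1L, good_fft_size, 1)
  comps <- list(
    rep = corr_fft(rec$channels$core, lig$channels$core, P, da, db),
    attr = -corr_fft(rec$channels$surface, lig$channels$surface, P, da, db),
    elec = corr_fft(rec$channels$charge, lig$channels$charge, P, da, db))
  m <- length(rec$atypes)
  pair <- array(0, da + db - 1L)
  for (j in seq_len(m)) {
    lj <- array(lig$channels$pair[, , , j], db)
    if (all(lj == 0)) next
    # receptor-side combination: R_j = sum_i eps_ij pair_i
    rj <- array(0, da)
    for (i in seq_len(m)) {
      if (eps[i, j] == 0) next
      ri <- array(rec$channels$pair[, , , i], da)
      if (all(ri == 0)) next
      rj <- rj + eps[i, j] * ri
    }
    if (all(rj == 0)) next
    pair <- pair + corr_fft(rj, lj, P, da, db)
  }
  comps$pair <- pair
  assemble_score_field(score_field_template(rec, lig, rotation), comps, w)
}

#' Translational correlation score by direct summation (oracle)
#'
#' Same contract as [fft_correlate()], computed by nested direct
#' summation.  Intended for small grids (<= 32^3) as the independent
#' verification oracle of the FFT path.
#' @inheritParams fft_correlate
#' @export
brute_force_correlate <- function(rec, lig, w = energy_weights(),
                                  rotation = quat_identity(),
                                  eps = pair_contact_matrix()) {
  check_grid_compat(rec, lig)
  da <- as.integer(rec$dims); db <- as.integer(lig$dims)
  bf <- function(a, b) cpp_corr_full(a, da, b, db)
  comps <- list(
    rep = bf(rec$channels$core, lig$channels$core),
    attr = -bf(rec$channels$surface, lig$channels$surface),
    elec = bf(rec$channels$charge, lig$channels$charge))
  m <- length(rec$atypes)
  pair <- array(0, da + db - 1L)
  for (j in seq_len(m)) {
    lj <- array(lig$channels$pair[, , , j], db)
    if (all(lj == 0)) next
    for (i in seq_len(m)) {
      if (eps[i, j] == 0) next
      ri <- array(rec$channels$pair[, , , i], da)
      if (all(ri == 0)) next
      pair <- pair + eps[i, j] * bf(ri, lj)
    }
  }
  comps$pair <- pair
  assemble_score_field(score_field_template(rec, lig, rotation), comps, w)
}

# Angstrom displacement of the ligand corresponding to voxel translation t
# (t given in the score-field's own indexing, i.e. already offset by t0)
translation_to_angstrom <- function(sf, t) {
  sf$rec_origin - sf$lig_origin + t * sf$h
}
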