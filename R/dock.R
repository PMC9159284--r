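# ---- rotation sampling ----

# Halton sequence in the unit cube with a seeded Cranley-Patterson shift
halton3 <- function(n, seed) {
  radical_inverse <- function(i, base) {
    f <- 1; r <- 0
    while (i > 0) {
      f <- f / base
      r <- r + f * (i %% base)
      i <- i %/% base
    }
    r
  }
  set.seed(seed %% .Machine$integer.max)
  shift <- runif(3)
  u <- vapply(seq_len(n), function(i)
    c(radical_inverse(i, 2), radical_inverse(i, 3), radical_inverse(i, 5)),
    numeric(3))
  (t(u) + rep(shift, each = n)) %% 1
}

#' Deterministic quasi-uniform rotation set
#'
#' Low-discrepancy cover of rotation space: Halton points in the unit cube
#' mapped to unit quaternions by the subgroup-algorithm (Shoemake) map,
#' with a seed-derived toroidal shift.  The identity rotation is always
#' the first element.
#'
#' @param n number of rotations (>= 1)
#' @param seed integer seed; the same `(n, seed)` always yields the same set
#' @return list of unit quaternions
#' @export
rotation_set <- function(n, seed = 17) {
  if (n < 1) stop("rotation_set: n must be >= 1")
  out <- vector("list", n)
  out[[1]] <- quat_identity()
  if (n > 1) {
    u <- halton3(n - 1, seed)
    for (i in seq_len(n - 1)) {
      u1 <- u[i, 1]; u2 <- u[i, 2]; u3 <- u[i, 3]
      q <- c(sqrt(1 - u1) * sin(2 * pi * u2),
             sqrt(1 - u1) * cos(2 * pi * u2),
             sqrt(u1) * sin(2 * pi * u3),
             sqrt(u1) * cos(2 * pi * u3))
      if (q[1] < 0) q <- -q          # canonical hemisphere
      out[[i + 1]] <- q / sqrt(sum(q^2))
    }
  }
  out
}

#' Docking parameters
#'
#' @param n_rotations rotations swept (desk default 500; server-scale runs
#'   use dense sets of ~70000)
#' @param retained total low-energy poses kept for clustering (default 1000)
#' @param per_rotation_keep best translations retained per rotation
#' @param weights an [energy_weights()] coefficient set
#' @param h grid spacing, A
#' @param margin grid margin, A
#' @param seed integer seed for the rotation set
#' @export
dock_params <- function(n_rotations = 500, retained = 1000,
                        per_rotation_keep = 1, weights = energy_weights(),
                        h = 1.0, margin = 5, seed = 17) {
  stopifnot(retained >= 1, per_rotation_keep >= 1, n_rotations >= 1)
  structure(list(n_rotations = n_rotations, retained = retained,
                 per_rotation_keep = per_rotation_keep, weights = weights,
                 h = h, margin = margin, seed = seed),
            class = "DockParams")
}

new_pose <- function(rotation, center, t_voxel, trans, energy,
                     components = NULL, rank = NA_integer_) {
  structure(list(rotation = rotation, center = center, t_voxel = t_voxel,
                 trans = trans, energy = energy, components = components,
                 rank = rank),
            class = "Pose")
}

#' Apply a pose transform to coordinates
#' @param pose a `Pose`
#' @param xyz n x 3 matrix in the input ligand frame
#' @export
pose_apply <- function(pose, xyz) {
  R <- quat_to_matrix(pose$rotation)
  sweep(sweep(xyz, 2, pose$center) %*% t(R), 2, pose$center + pose$trans, "+")
}

#' Posed copy of the ligand structure
#' @param pose a `Pose`; `lig` the ligand used for docking
#' @param lig the ligand `Structure`/`ParamStructure`
#' @export
pose_ligand <- function(pose, lig) {
  coords(lig) <- pose_apply(pose, coords(lig))
  lig
}

#' @export
print.Pose <- function(x, ...) {
  cat(sprintf("<Pose> rank %s  E = %.3f  t = (%.1f, %.1f, %.1f) A\n",
              ifelse(is.na(x$rank), "?", x$rank), x$energy,
              x$trans[1], x$trans[2], x$trans[3]))
  invisible(x)
}

new_pose_list <- function(poses, params, rec_id, lig_id) {
  structure(list(poses = poses, params = params,
                 rec_id = rec_id, lig_id = lig_id),
            class = "PoseList")
}

#' @export
length.PoseList <- function(x) length(x$poses)

#' @export
`[[.PoseList` <- function(x, i) x$poses[[i]]

#' @export
print.PoseList <- function(x, ...) {
  cat(sprintf("<PoseList> %d poses (%s vs %s), E in [%.3f, %.3f]\n",
              length(x$poses), x$rec_id, x$lig_id,
              x$poses[[1]]$energy, x$poses[[length(x$poses)]]$energy))
  invisible(x)
}

#' Pose table
#' @param x a `PoseList`
#' @export
pose_table <- function(x) {
  do.call(rbind, lapply(x$poses, function(p) {
    data.frame(rank = p$rank, energy = p$energy,
               e_rep = p$components[["rep"]], e_attr = p$components[["attr"]],
               e_elec = p$components[["elec"]], e_pair = p$components[["pair"]],
               qw = p$rotation[1], qx = p$rotation[2], qy = p$rotation[3],
               qz = p$rotation[4],
               tx = p$trans[1], ty = p$trans[2], tz = p$trans[3])
  }))
}

# per-channel correlation components of one translation, by direct sums
components_at <- function(rec, lig, tvox, eps) {
  da <- rec$dims; db <- lig$dims
  # receptor subarray overlapping the ligand grid shifted by tvox
  rrange <- lapply(1:3, function(k) {
    i0 <- max(0L, tvox[k]); i1 <- min(da[k] - 1L, tvox[k] + db[k] - 1L)
    if (i0 > i1) return(integer(0))
    (i0 + 1L):(i1 + 1L)
  })
  lrange <- lapply(1:3, function(k) rrange[[k]] - tvox[k])
  if (!all(lengths(rrange) > 0))
    return(list(rep = 0, attr = 0, elec = 0, pair = 0))
  sub <- function(a, rg) a[rg[[1]], rg[[2]], rg[[3]], drop = FALSE]
  comp <- list(
    rep = sum(sub(rec$channels$core, rrange) * sub(lig$channels$core, lrange)),
    attr = -sum(sub(rec$channels$surface, rrange) *
                  sub(lig$channels$surface, lrange)),
    elec = sum(sub(rec$channels$charge, rrange) *
                 sub(lig$channels$charge, lrange)))
  pr <- 0
  m <- length(rec$atypes)
  for (j in seq_len(m)) {
    ljfull <- array(lig$channels$pair[, , , j], db)
    lj <- sub(ljfull, lrange)
    if (all(lj == 0)) next
    for (i in seq_len(m)) {
      if (eps[i, j] == 0) next
      rifull <- array(rec$channels$pair[, , , i], da)
      pr <- pr + eps[i, j] * sum(sub(rifull, rrange) * lj)
    }
  }
  comp$pair <- pr
  comp
}

# feasible-translation mask for a restraint set at one ligand rotation;
# dims follow the (da+db-1) translation lattice with offset t0
restraint_mask <- function(rs, rec_ps, lig_xyz_rot, lig_sel_idx, rec_sel_xyz,
                           rec_origin, lig_origin, h, da, db) {
  nd <- da + db - 1L
  t0 <- -(db - 1L)
  ax <- (t0[1]:(da[1] - 1L)) * h
  ay <- (t0[2]:(da[2] - 1L)) * h
  az <- (t0[3]:(da[3] - 1L)) * h
  base <- rec_origin - lig_origin
  ok <- array(TRUE, nd)
  for (g in seq_along(rs$groups)) {
    grp <- rs$groups[[g]]
    cnt <- array(0L, nd)
    for (r in seq_along(grp$restraints)) {
      re <- grp$restraints[[r]]
      a <- rec_sel_xyz[[g]][[r]]
      b <- lig_xyz_rot[lig_sel_idx[[g]][[r]], ]
      # pose position of b is b + base + t*h; distance to a constrained
      d0 <- a - b - base
      dx2 <- (ax - d0[1])^2; dy2 <- (ay - d0[2])^2; dz2 <- (az - d0[3])^2
      d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
      cnt <- cnt + ((d2 >= re$dmin^2) & (d2 <= re$dmax^2))
    }
    ok <- ok & (cnt >= grp$required)
  }
  ok
}

#' Exhaustive rigid-body docking by FFT correlation
#'
#' Sweeps a quasi-uniform rotation set; for each rotation scores every
#' ligand translation on the grid by multi-channel FFT correlation, keeps
#' the best `per_rotation_keep` translations (translations failing the
#' restraints, when given, are discarded before retention), then globally
#' sorts and retains the `retained` lowest-energy poses.
#'
#' @param rec,lig `ParamStructure`s (receptor fixed, ligand mobile)
#' @param params a [dock_params()] object
#' @param restraints optional `RestraintSet` (see [parse_restraints()])
#' @param eps pairwise contact matrix
#' @return a `PoseList`, ranked by increasing energy
#' @export
dock_rigid <- function(rec, lig, params = dock_params(), restraints = NULL,
                       eps = pair_contact_matrix()) {
  stopifnot(is_param_structure(rec), is_param_structure(lig))
  h <- params$h; w <- params$weights
  rgrid <- build_grids(rec, h = h, margin = params$margin)
  lxyz <- coords(lig)
  center <- colMeans(lxyz)
  # fixed cubic ligand lattice so every rotation shares grid dims
  rmax <- max(sqrt(rowSums(sweep(lxyz, 2, center)^2)))
  lo <- h * floor((center - rmax - params$margin) / h)
  ldims <- as.integer(rep(ceiling((2 * (rmax + params$margin)) / h) + 1L, 3))
  da <- rgrid$dims; db <- ldims
  P <- vapply(da + db - 1L, good_fft_size, 1)
  # receptor-side Fourier combinations (conjugated ligand side applied later)
  Fr <- function(a) stats::fft(pad_array(a, P))
  A_core <- w$w_rep * Fr(rgrid$channels$core)
  A_surf <- -w$w_attr * Fr(rgrid$channels$surface)
  A_chg <- if (all(rgrid$channels$charge == 0)) NULL else
    w$w_elec * Fr(rgrid$channels$charge)
  m <- length(rgrid$atypes)
  Fpair <- vector("list", m)
  for (i in seq_len(m)) {
    ri <- rgrid$channels$pair[, , , i]
    if (!all(ri == 0)) Fpair[[i]] <- Fr(ri)
  }
  A_pair <- vector("list", m)   # per ligand type j
  for (j in seq_len(m)) {
    acc <- NULL
    for (i in seq_len(m)) {
      if (eps[i, j] == 0 || is.null(Fpair[[i]])) next
      acc <- if (is.null(acc)) eps[i, j] * Fpair[[i]] else
        acc + eps[i, j] * Fpair[[i]]
    }
    if (!is.null(acc)) A_pair[[j]] <- w$w_pair * acc
  }
  rots <- rotation_set(params$n_rotations, params$seed)
  # pre-resolve restraint selections
  if (!is.null(restraints)) {
    sel <- resolve_restraint_selections(restraints, rec, lig)
  }
  type <- match(lig$atoms$atype, .atype_levels)
  type[is.na(type)] <- 0L
  cand <- vector("list", length(rots))
  nd <- da + db - 1L
  t0 <- -(db - 1L)
  for (ri in seq_along(rots)) {
    q <- rots[[ri]]
    R <- quat_to_matrix(q)
    xyz <- sweep(sweep(lxyz, 2, center) %*% t(R), 2, center, "+")
    ch <- cpp_rasterize(xyz, lig$atoms$radius, lig$atoms$charge, type,
                        as.numeric(lo), h, db, rgrid_delta(), rgrid_sigma(), m)
    tot <- A_core * Conj(Fr2(ch$core, P))
    if (!all(ch$surface == 0)) tot <- tot + A_surf * Conj(Fr2(ch$surface, P))
    if (!is.null(A_chg) && !all(ch$charge == 0))
      tot <- tot + A_chg * Conj(Fr2(ch$charge, P))
    nvox <- prod(db)
    for (j in seq_len(m)) {
      if (is.null(A_pair[[j]])) next
      pj <- ch$pair[(1 + (j - 1) * nvox):(j * nvox)]
      if (all(pj == 0)) next
      dim(pj) <- db
      tot <- tot + A_pair[[j]] * Conj(Fr2(pj, P))
    }
    vals <- Re(stats::fft(tot, inverse = TRUE)) / prod(P)
    ix <- lapply(1:3, function(k)
      c(if (db[k] > 1) (P[k] - db[k] + 2):P[k], 1:da[k]))
    vals <- vals[ix[[1]], ix[[2]], ix[[3]]]
    if (!is.null(restraints)) {
      ok <- restraint_mask(restraints, rec, xyz, sel$lig_idx, sel$rec_xyz,
                           rgrid$origin, lo, h, da, db)
      if (!any(ok)) next
      vals[!ok] <- Inf
    }
    k <- params$per_rotation_keep
    v <- as.vector(vals)
    if (k == 1) {
      b <- which.min(v)
      b <- b[is.finite(v[b])]
    } else {
      # diverse retention: the k best translations that are pairwise at
      # least 3 voxels apart (one entry per local well, not one well's
      # flat bottom)
      ncand <- min(length(v), k * 10L)
      thr <- sort(v, partial = ncand)[ncand]
      b0 <- which(v <= thr & is.finite(v))
      b0 <- b0[order(v[b0])]
      ti <- arrayInd(b0, nd)
      b <- integer(0)
      taken <- matrix(0L, 0, 3)
      for (jj in seq_along(b0)) {
        if (nrow(taken) &&
            any(pmax(abs(taken[, 1] - ti[jj, 1]), abs(taken[, 2] - ti[jj, 2]),
                     abs(taken[, 3] - ti[jj, 3])) < 3L)) next
        b <- c(b, b0[jj])
        taken <- rbind(taken, ti[jj, , drop = FALSE])
        if (length(b) >= k) break
      }
    }
    if (!length(b)) next
    tv <- arrayInd(b, nd) - 1L + rep(t0, each = length(b))
    cand[[ri]] <- list(rot = ri, t = tv, e = v[b])
  }
  cand <- cand[!vapply(cand, is.null, TRUE)]
  if (!length(cand)) stop("no feasible pose: all translations rejected")
  all_e <- unlist(lapply(cand, `[[`, "e"))
  src <- rep(seq_along(cand), vapply(cand, function(x) length(x$e), 1L))
  row <- unlist(lapply(cand, function(x) seq_along(x$e)))
  ord <- order(all_e)[seq_len(min(params$retained, length(all_e)))]
  poses <- vector("list", length(ord))
  lig_grid_cache <- new.env(parent = emptyenv())
  for (ii in seq_along(ord)) {
    o <- ord[ii]
    cd <- cand[[src[o]]]
    q <- rots[[cd$rot]]
    key <- as.character(cd$rot)
    lg <- lig_grid_cache[[key]]
    if (is.null(lg)) {
      R <- quat_to_matrix(q)
      xyz <- sweep(sweep(lxyz, 2, center) %*% t(R), 2, center, "+")
      ch <- cpp_rasterize(xyz, lig$atoms$radius, lig$atoms$charge, type,
                          as.numeric(lo), h, db, rgrid_delta(), rgrid_sigma(), m)
      lg <- new_gridset(lo, h, ch)
      lig_grid_cache[[key]] <- lg
    }
    tvox <- cd$t[row[o], ]
    comp <- components_at(rgrid, lg, tvox, eps)
    energy <- w$w_rep * comp$rep + w$w_attr * comp$attr +
      w$w_elec * comp$elec + w$w_pair * comp$pair
    poses[[ii]] <- new_pose(q, center, tvox,
                            rgrid$origin - lo + tvox * h,
                            energy, comp, rank = ii)
  }
  new_pose_list(poses, params, rec$id, lig$id)
}

# channel-shape defaults shared by docking and mapping
rgrid_delta <- function() 0.5
rgrid_sigma <- function() 2.0

Fr2 <- function(a, P) stats::fft(pad_array(a, P))

#' Continuous inter-molecular energy of a posed ligand
#'
#' Soft-core 12-6 plus screened Coulomb; the off-grid energy used by
#' refinement and probe minimization.
#' @param rec receptor `ParamStructure`
#' @param lig_xyz posed ligand coordinates (n x 3)
#' @param lig ligand `ParamStructure` (charges/radii)
#' @param opts see [minimizer_options()]
#' @export
continuous_energy <- function(rec, lig_xyz, lig, opts = minimizer_options()) {
  cpp_pair_energy(coords(rec), rec$atoms$charge,
                  rec$atoms$radius * opts$contact_scale,
                  lig_xyz, lig$atoms$charge,
                  lig$atoms$radius * opts$contact_scale,
                  opts$e0, opts$soft, opts$kappa, opts$eps_d, opts$cutoff)
}

# deterministic low-discrepancy start perturbations for refine_pose
# (0.8 A translations, 0.15 rad rotations; first row = no perturbation)
refine_starts <- function(n) {
  rinv <- function(i, base) {
    f <- 1; r <- 0
    while (i > 0) {
      f <- f / base
      r <- r + f * (i %% base)
      i <- i %/% base
    }
    r
  }
  out <- matrix(0, n, 6)
  bases <- c(2, 3, 5, 7, 11, 13)
  for (i in 2:n)
    out[i, ] <- (vapply(bases, function(b) rinv(i - 1, b), 1) - 0.5) *
      c(1.6, 1.6, 1.6, 0.3, 0.3, 0.3)
  out
}

#' Options of the continuous-energy model and rigid minimizer
#'
#' @param e0 well depth of the soft-core 12-6 term (kcal/mol)
#' @param soft softening length (A) added in quadrature to r
#' @param kappa screening constant (1/A) of the Coulomb term
#' @param eps_d dielectric divisor
#' @param cutoff pair cutoff (A)
#' @param maxit maximum descent iterations
#' @param max_rmsd cap on the displacement from the input pose (A RMSD)
#' @param contact_scale factor on the vdW contact distance of the 12-6
#'   term.  The grids tolerate overlaps of `delta` (0.5 A) per atom; the
#'   off-grid energy mirrors that tolerance by shifting its contact
#'   optimum inward by the same amount (0.87 ~ (1.9 - 0.25) / 1.9),
#'   keeping the two energy worlds consistent.
#' @export
minimizer_options <- function(e0 = 0.15, soft = 0.4, kappa = 0.25, eps_d = 4,
                              cutoff = 10, maxit = 200, max_rmsd = 2.9,
                              contact_scale = 0.87) {
  list(e0 = e0, soft = soft, kappa = kappa, eps_d = eps_d, cutoff = cutoff,
       maxit = maxit, max_rmsd = max_rmsd, contact_scale = contact_scale)
}

#' Count clashing heavy-atom pairs
#'
#' A clash is a receptor-ligand pair closer than `factor` times the sum of
#' the van der Waals radii.
#' @param rec receptor `ParamStructure`
#' @param lig_xyz posed ligand coordinates
#' @param lig ligand `ParamStructure`
#' @param factor clash threshold factor (default 0.75)
#' @export
clash_count <- function(rec, lig_xyz, lig, factor = 0.75) {
  cpp_clash_count(coords(rec), rec$atoms$radius, lig_xyz, lig$atoms$radius,
                  factor)
}

#' Rigid-body local refinement of a pose
#'
#' Minimizes the continuous clash-plus-attraction energy over rigid
#' translations and small rotations.  The returned pose never has higher
#' continuous energy, never more clashes, and never moves more than the
#' RMSD cap from the input; if no improving step exists the input pose is
#' returned with `refine_flag = "unchanged"`.
#'
#' @param rec,lig `ParamStructure`s used for docking
#' @param pose the `Pose` to refine
#' @param opts [minimizer_options()]
#' @return the refined `Pose` with fields `energy_cont`, `clashes`,
#'   `refine_flag` added
#' @export
refine_pose <- function(rec, lig, pose, opts = minimizer_options()) {
  x0 <- pose_apply(pose, coords(lig))
  rr <- rec$atoms$radius * opts$contact_scale
  rl <- lig$atoms$radius * opts$contact_scale
  cl0 <- clash_count(rec, x0, lig)
  res <- cpp_minimize_rigid(coords(rec), rec$atoms$charge, rr,
                            x0, lig$atoms$charge, rl,
                            opts$e0, opts$soft, opts$kappa, opts$eps_d,
                            opts$cutoff, opts$maxit, opts$max_rmsd)
  # gradient descent can jam against the displacement cap in clashed
  # starts; a deterministic multi-start simplex search over the 6 rigid
  # parameters can hop such barriers.  Candidates violating the contract
  # (more clashes, higher energy, over the displacement cap) are ignored.
  c1 <- colMeans(x0)
  xl0 <- sweep(x0, 2, c1)
  obj <- function(par) {
    th <- par[4:6]
    ang <- sqrt(sum(th^2))
    Rm <- if (ang > 1e-12) quat_to_matrix(quat_from_axis_angle(th, ang))
      else diag(3)
    xt <- sweep(xl0 %*% t(Rm), 2, c1 + par[1:3], "+")
    if (sqrt(mean(rowSums((xt - x0)^2))) > opts$max_rmsd)
      return(1e9)
    cpp_pair_energy(coords(rec), rec$atoms$charge, rr,
                    xt, lig$atoms$charge, rl,
                    opts$e0, opts$soft, opts$kappa, opts$eps_d, opts$cutoff)
  }
  starts <- refine_starts(10)
  best <- list(energy = res$energy, theta = res$theta, trans = res$trans,
               xyz = res$xyz)
  for (i in seq_len(nrow(starts))) {
    o <- stats::optim(starts[i, ], obj, method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-8))
    if (o$value < best$energy) {
      th <- o$par[4:6]
      ang <- sqrt(sum(th^2))
      Rm <- if (ang > 1e-12) quat_to_matrix(quat_from_axis_angle(th, ang))
        else diag(3)
      xt <- sweep(xl0 %*% t(Rm), 2, c1 + o$par[1:3], "+")
      if (clash_count(rec, xt, lig) > max(cl0, clash_count(rec, best$xyz, lig)))
        next
      best <- list(energy = o$value, theta = o$par[4:6], trans = o$par[1:3],
                   xyz = xt)
    }
  }
  res <- list(energy_init = res$energy_init, energy = best$energy,
              theta = best$theta, trans = best$trans, xyz = best$xyz,
              rmsd_moved = sqrt(mean(rowSums((best$xyz - x0)^2))))
  cl1 <- clash_count(rec, res$xyz, lig)
  if (res$energy > res$energy_init + 1e-12 || cl1 > cl0) {
    pose$energy_cont <- res$energy_init
    pose$clashes <- cl0
    pose$refine_flag <- "unchanged"
    return(pose)
  }
  # compose the minimizer's increment (rotation about the posed centroid
  # plus translation) with the original pose transform
  th <- res$theta
  ang <- sqrt(sum(th^2))
  dq <- if (ang > 1e-12) quat_from_axis_angle(th, ang) else quat_identity()
  qnew <- quat_multiply(dq, pose$rotation)
  qnew <- qnew / sqrt(sum(qnew^2))
  Rdq <- quat_to_matrix(dq)
  tr_new <- as.numeric(Rdq %*% (pose$center + pose$trans - c1)) + c1 +
    res$trans - pose$center
  out <- pose
  out$rotation <- qnew
  out$trans <- tr_new
  out$energy_cont <- res$energy
  out$clashes <- cl1
  out$rmsd_moved <- res$rmsd_moved
  out$refine_flag <- if (res$energy < res$energy_init) "refined" else "unchanged"
  out
}
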