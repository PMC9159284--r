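# Whole-surface computational solvent mapping: sweep small organic probes
# over the entire protein surface with the FFT engine, minimize retained
# poses off-grid, cluster per probe by average energy, merge across probe
# types into consensus sites (hotspots), classify druggability, and
# assemble predicted binding sites.

.element_radius <- c(C = 1.9, N = 1.7, O = 1.6, S = 2.0, P = 2.1)

# geometry helpers (idealized bond lengths/angles, heavy atoms only)
.rotz <- function(v, deg) {
  a <- deg * pi / 180
  c(cos(a) * v[1] - sin(a) * v[2], sin(a) * v[1] + cos(a) * v[2], v[3])
}
.tet <- local({
  d <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) / sqrt(3)
  d
})
.ring6 <- function(L = 1.39) {
  th <- (0:5) * pi / 3
  cbind(L * cos(th), L * sin(th), 0)
}
.sp2 <- function(deg, L) L * c(cos(deg * pi / 180), sin(deg * pi / 180), 0)

.mk_probe <- function(name, el, xyz, charge, atype) {
  xyz <- matrix(xyz, ncol = 3, byrow = TRUE)
  n <- nrow(xyz)
  cnt <- stats::ave(seq_len(n), el, FUN = seq_along)
  atoms <- data.frame(
    serial = seq_len(n), name = paste0(el, cnt), altloc = "",
    res_name = "PRB", chain = "X", res_seq = 1L, icode = "",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], occupancy = 1,
    element = el, is_hetero = TRUE,
    radius = unname(.element_radius[el]), charge = charge, atype = atype,
    stringsAsFactors = FALSE)
  s <- new_structure(atoms, name)
  class(s) <- c("ParamStructure", "Structure")
  s
}

.build_probes <- function() {
  p <- list()
  ang <- 70.529 * pi / 180          # pi - tetrahedral angle
  p$ethanol <- .mk_probe("ethanol", c("C", "C", "O"), c(
    0, 0, 0,  1.53, 0, 0,  1.53 + 1.43 * cos(ang), 1.43 * sin(ang), 0),
    c(0, 0.3, -0.3), c("C_aliph", "C_aliph", "O_acc"))
  p[["2-propanol"]] <- .mk_probe("2-propanol", c("C", "C", "C", "O"), c(
    0, 0, 0, 1.53 * .tet[1, ], 1.53 * .tet[2, ], 1.43 * .tet[3, ]),
    c(0.3, 0, 0, -0.3), c("C_aliph", "C_aliph", "C_aliph", "O_acc"))
  # isobutanol: central CH, two methyls, CH2-OH arm
  u <- .tet[3, ]
  perp <- c(u[2], -u[1], 0); perp <- perp / sqrt(sum(perp^2))
  odir <- cos(ang) * u + sin(ang) * perp
  c4 <- 1.53 * u
  p$isobutanol <- .mk_probe("isobutanol", c("C", "C", "C", "C", "O"), c(
    0, 0, 0, 1.53 * .tet[1, ], 1.53 * .tet[2, ], c4, c4 + 1.43 * odir),
    c(0, 0, 0, 0.3, -0.3), c(rep("C_aliph", 4), "O_acc"))
  p$acetone <- .mk_probe("acetone", c("C", "O", "C", "C"), c(
    0, 0, 0, .sp2(90, 1.22), .sp2(210, 1.50), .sp2(330, 1.50)),
    c(0.4, -0.4, 0, 0), c("C_aliph", "O_acc", "C_aliph", "C_aliph"))
  p$acetaldehyde <- .mk_probe("acetaldehyde", c("C", "O", "C"), c(
    0, 0, 0, .sp2(90, 1.22), .sp2(210, 1.50)),
    c(0.4, -0.4, 0), c("C_aliph", "O_acc", "C_aliph"))
  th <- 55.75 * pi / 180            # half of the C-O-C angle
  p[["dimethyl ether"]] <- .mk_probe("dimethyl ether", c("O", "C", "C"), c(
    0, 0, 0, 1.43 * cos(th), 1.43 * sin(th), 0,
    1.43 * cos(th), -1.43 * sin(th), 0),
    c(-0.4, 0.2, 0.2), c("O_acc", "C_aliph", "C_aliph"))
  r6 <- .ring6(1.53)
  p$cyclohexane <- .mk_probe("cyclohexane", rep("C", 6), t(r6),
                             rep(0, 6), rep("C_aliph", 6))
  p$ethane <- .mk_probe("ethane", c("C", "C"), c(0, 0, 0, 1.53, 0, 0),
                        c(0, 0), rep("C_aliph", 2))
  p$acetonitrile <- .mk_probe("acetonitrile", c("C", "C", "N"), c(
    0, 0, 0, 1.46, 0, 0, 2.62, 0, 0),
    c(0, 0.4, -0.4), c("C_aliph", "C_aliph", "N_don"))
  p$urea <- .mk_probe("urea", c("C", "O", "N", "N"), c(
    0, 0, 0, .sp2(90, 1.22), .sp2(210, 1.34), .sp2(330, 1.34)),
    c(0.7, -0.45, -0.125, -0.125), c("C_aliph", "O_acc", "N_don", "N_don"))
  p$methylamine <- .mk_probe("methylamine", c("C", "N"),
                             c(0, 0, 0, 1.47, 0, 0),
                             c(0.3, -0.3), c("C_aliph", "N_don"))
  ar <- .ring6(1.39)
  p$phenol <- .mk_probe("phenol", c(rep("C", 6), "O"),
                        c(t(ar), (1.39 + 1.36), 0, 0),
                        c(0.4, rep(0, 5), -0.4),
                        c(rep("C_arom", 6), "O_acc"))
  c7 <- c(1.39 + 1.48, 0, 0)
  p$benzaldehyde <- .mk_probe("benzaldehyde", c(rep("C", 6), "C", "O"),
                              c(t(ar), c7, c7 + 1.22 * c(0.5, sqrt(3) / 2, 0)),
                              c(rep(0, 6), 0.4, -0.4),
                              c(rep("C_arom", 6), "C_aliph", "O_acc"))
  p$benzene <- .mk_probe("benzene", rep("C", 6), t(ar),
                         rep(0, 6), rep("C_arom", 6))
  p$acetamide <- .mk_probe("acetamide", c("C", "O", "C", "N"), c(
    0, 0, 0, .sp2(90, 1.22), .sp2(210, 1.50), .sp2(330, 1.34)),
    c(0.55, -0.4, 0, -0.15), c("C_aliph", "O_acc", "C_aliph", "N_don"))
  nn <- .sp2(330, 1.34)
  un <- -nn / sqrt(sum(nn^2))       # direction N -> C1
  p[["N,N-dimethylformamide"]] <- .mk_probe(
    "N,N-dimethylformamide", c("C", "O", "N", "C", "C"), c(
      0, 0, 0, .sp2(90, 1.22), nn,
      nn + 1.45 * .rotz(un, 120), nn + 1.45 * .rotz(un, -120)),
    c(0.45, -0.4, -0.25, 0.1, 0.1),
    c("C_aliph", "O_acc", "N_don", "C_aliph", "C_aliph"))
  p
}

#' The 16-probe library of the solvent-mapping engine
#'
#' Sixteen small organic molecules spanning size, shape and polarity,
#' each as an idealized heavy-atom template with radii, partial charges
#' (neutral overall) and coarse atom types.  Order and names are stable.
#'
#' @return named list of 16 `ParamStructure` templates
#' @export
probe_library <- function() .build_probes()

#' Checksums of the probe templates
#'
#' md5 of a canonical text rendering (names, elements, coordinates to
#' 3 decimals, charges, types); guards template stability.
#' @export
probe_checksums <- function() {
  vapply(probe_library(), function(p) {
    txt <- paste(apply(p$atoms, 1, function(r)
      paste(r["name"], r["element"],
            sprintf("%.3f", as.numeric(r[c("x", "y", "z")])),
            r["charge"], r["atype"], collapse = " ")), collapse = "\n")
    f <- tempfile()
    on.exit(unlink(f))
    writeLines(txt, f)
    unname(tools::md5sum(f))
  }, character(1))
}

#' Solvent-mapping parameters
#'
#' @param K grid poses retained (and minimized) per probe type
#' @param probe_cluster_radius per-probe clustering radius on probe
#'   centers, A
#' @param clusters_kept clusters kept per probe type
#' @param consensus_radius center-to-center merge radius across probe
#'   types, A
#' @param strong_threshold probe-cluster population making a hotspot
#'   "strong"
#' @param intermediate_threshold population above which a hotspot is
#'   "intermediate"
#' @param site_merge_cutoff hotspot merge distance of the binding-site
#'   assembly stage, A
#' @param h grid spacing, A (mapping default 0.8)
#' @param margin grid margin, A
#' @param n_rotations probe rotations swept
#' @param weights an [energy_weights()] set
#' @param minimizer [minimizer_options()]
#' @param seed integer seed
#' @export
map_params <- function(K = 2000, probe_cluster_radius = 3, clusters_kept = 6,
                       consensus_radius = 4, strong_threshold = 16,
                       intermediate_threshold = 10, site_merge_cutoff = 8,
                       h = 0.8, margin = 5, n_rotations = 256,
                       weights = energy_weights(),
                       minimizer = minimizer_options(), seed = 7) {
  stopifnot(probe_cluster_radius > 0, consensus_radius > 0,
            site_merge_cutoff > 0, strong_threshold >= 1, K >= 1)
  structure(list(K = K, probe_cluster_radius = probe_cluster_radius,
                 clusters_kept = clusters_kept,
                 consensus_radius = consensus_radius,
                 strong_threshold = strong_threshold,
                 intermediate_threshold = intermediate_threshold,
                 site_merge_cutoff = site_merge_cutoff, h = h,
                 margin = margin, n_rotations = n_rotations,
                 weights = weights, minimizer = minimizer, seed = seed),
            class = "MapParams")
}

# receptor-side FFT precomputation shared by all probes of one run;
# db is the common (cubic) probe lattice dimension
map_engine <- function(rec, p, db, eps = pair_contact_matrix()) {
  rgrid <- build_grids(rec, h = p$h, margin = p$margin)
  w <- p$weights
  da <- rgrid$dims
  P <- vapply(da + db - 1L, good_fft_size, 1)
  Fr <- function(a) stats::fft(pad_array(a, P))
  m <- length(rgrid$atypes)
  Fpair <- vector("list", m)
  for (i in seq_len(m)) {
    ri <- array(rgrid$channels$pair[, , , i], da)
    if (!all(ri == 0)) Fpair[[i]] <- Fr(ri)
  }
  A_pair <- vector("list", m)
  for (j in seq_len(m)) {
    acc <- NULL
    for (i in seq_len(m)) {
      if (eps[i, j] == 0 || is.null(Fpair[[i]])) next
      acc <- if (is.null(acc)) eps[i, j] * Fpair[[i]] else
        acc + eps[i, j] * Fpair[[i]]
    }
    if (!is.null(acc)) A_pair[[j]] <- w$w_pair * acc
  }
  list(rgrid = rgrid, P = P, da = da, db = db, m = m, w = w,
       A_core = w$w_rep * Fr(rgrid$channels$core),
       A_surf = -w$w_attr * Fr(rgrid$channels$surface),
       A_chg = if (all(rgrid$channels$charge == 0)) NULL else
         w$w_elec * Fr(rgrid$channels$charge),
       A_pair = A_pair)
}

# score one rotated probe placement field; returns values over the full
# translation lattice (t0 = -(db-1))
map_score_rotation <- function(eng, xyz, probe, lo) {
  db <- eng$db; P <- eng$P; m <- eng$m
  type <- match(probe$atoms$atype, .atype_levels)
  type[is.na(type)] <- 0L
  ch <- cpp_rasterize(xyz, probe$atoms$radius, probe$atoms$charge, type,
                      as.numeric(lo), eng$rgrid$h, db,
                      rgrid_delta(), rgrid_sigma(), m)
  tot <- eng$A_core * Conj(Fr2(ch$core, P))
  if (!all(ch$surface == 0)) tot <- tot + eng$A_surf * Conj(Fr2(ch$surface, P))
  if (!is.null(eng$A_chg) && !all(ch$charge == 0))
    tot <- tot + eng$A_chg * Conj(Fr2(ch$charge, P))
  nvox <- prod(db)
  for (j in seq_len(m)) {
    if (is.null(eng$A_pair[[j]])) next
    pj <- ch$pair[(1 + (j - 1) * nvox):(j * nvox)]
    if (all(pj == 0)) next
    dim(pj) <- db
    tot <- tot + eng$A_pair[[j]] * Conj(Fr2(pj, P))
  }
  vals <- Re(stats::fft(tot, inverse = TRUE)) / prod(P)
  ix <- lapply(1:3, function(k)
    c(if (db[k] > 1) (P[k] - db[k] + 2):P[k], 1:eng$da[k]))
  vals[ix[[1]], ix[[2]], ix[[3]]]
}

probe_lattice <- function(probe, p) {
  xyz <- coords(probe)
  center <- colMeans(xyz)
  rmax <- max(sqrt(rowSums(sweep(xyz, 2, center)^2)))
  side <- ceiling((2 * (rmax + p$margin)) / p$h) + 1L
  list(center = center, rmax = rmax, side = as.integer(side))
}

#' Map one probe type over the whole surface
#'
#' FFT sweep of the probe over all rotations and translations (no pocket
#' prior), retention of the `K` best grid poses, rigid off-grid
#' minimization of each retained pose with the continuous energy, and
#' sorting by minimized energy.
#'
#' @param rec receptor `ParamStructure`
#' @param probe a probe template from [probe_library()]
#' @param p [map_params()]
#' @param eng optional shared engine (internal reuse across probes)
#' @param eps contact matrix
#' @return list of `ProbePose`s: `probe`, `rotation`, `center`, `trans`,
#'   `energy_grid`, `energy_min`, `xyz` (minimized atom coordinates),
#'   `center_min`
#' @export
map_probe <- function(rec, probe, p = map_params(), eng = NULL,
                      eps = pair_contact_matrix()) {
  lat <- probe_lattice(probe, p)
  if (is.null(eng)) eng <- map_engine(rec, p, rep(lat$side, 3L), eps)
  if (any(eng$db > eng$da)) stop("probe grid larger than receptor grid")
  db <- eng$db; da <- eng$da
  lo <- p$h * floor((lat$center - (db[1] * p$h) / 2) / p$h)
  rots <- rotation_set(p$n_rotations, p$seed)
  keep <- max(1L, ceiling(2 * p$K / length(rots)))
  xyz0 <- coords(probe)
  nd <- da + db - 1L
  t0 <- -(db - 1L)
  cand_t <- vector("list", length(rots))
  cand_e <- vector("list", length(rots))
  for (ri in seq_along(rots)) {
    R <- quat_to_matrix(rots[[ri]])
    xyz <- sweep(sweep(xyz0, 2, lat$center) %*% t(R), 2, lat$center, "+")
    v <- as.vector(map_score_rotation(eng, xyz, probe, lo))
    if (keep == 1) {
      b <- which.min(v)
    } else {
      thr <- sort(v, partial = keep)[keep]
      b <- which(v <= thr)
      b <- b[order(v[b])][seq_len(keep)]
    }
    cand_t[[ri]] <- arrayInd(b, nd) - 1L + rep(t0, each = length(b))
    cand_e[[ri]] <- v[b]
  }
  all_e <- unlist(cand_e)
  rot_of <- rep(seq_along(rots), vapply(cand_e, length, 1L))
  row_of <- unlist(lapply(cand_e, seq_along))
  ord <- order(all_e)[seq_len(min(p$K, length(all_e)))]
  opts <- p$minimizer
  rxyz <- coords(rec); rq <- rec$atoms$charge
  rr <- rec$atoms$radius * opts$contact_scale
  pq <- probe$atoms$charge
  pr <- probe$atoms$radius * opts$contact_scale
  poses <- vector("list", length(ord))
  for (ii in seq_along(ord)) {
    o <- ord[ii]
    q <- rots[[rot_of[o]]]
    tvox <- cand_t[[rot_of[o]]][row_of[o], ]
    R <- quat_to_matrix(q)
    xyz <- sweep(sweep(xyz0, 2, lat$center) %*% t(R), 2, lat$center, "+")
    disp <- eng$rgrid$origin - lo + tvox * p$h
    xyzp <- sweep(xyz, 2, disp, "+")
    res <- cpp_minimize_rigid(rxyz, rq, rr, xyzp, pq, pr,
                              opts$e0, opts$soft, opts$kappa, opts$eps_d,
                              opts$cutoff, opts$maxit, opts$max_rmsd)
    poses[[ii]] <- structure(
      list(probe = probe$id, rotation = q, center = lat$center,
           trans = disp, t_voxel = tvox, energy_grid = all_e[o],
           energy_min = min(res$energy, res$energy_init),
           xyz = if (res$energy <= res$energy_init) res$xyz else xyzp,
           center_min = colMeans(if (res$energy <= res$energy_init)
             res$xyz else xyzp)),
      class = "ProbePose")
  }
  poses[order(vapply(poses, `[[`, numeric(1), "energy_min"))]
}

#' Cluster the poses of one probe type
#'
#' Greedy clustering on probe centers (most neighbors first, ties to the
#' lower minimized energy); clusters are ranked ascending by their
#' average minimized energy and at most `clusters_kept` are returned.
#'
#' @param poses `ProbePose` list from [map_probe()] (one probe type)
#' @param p [map_params()]
#' @return list of `ProbeCluster`s: `probe`, `members`, `center`
#'   (mean member center), `avg_energy`, `size`, `rank`
#' @export
cluster_probe_poses <- function(poses, p = map_params()) {
  if (!length(poses)) return(list())
  stopifnot(length(unique(vapply(poses, `[[`, "", "probe"))) == 1)
  centers <- t(vapply(poses, `[[`, numeric(3), "center_min"))
  energy <- vapply(poses, `[[`, numeric(1), "energy_min")
  n <- length(poses)
  D <- as.matrix(stats::dist(centers))
  remaining <- rep(TRUE, n)
  out <- list()
  while (any(remaining)) {
    idx <- which(remaining)
    nb <- D[idx, idx, drop = FALSE] <= p$probe_cluster_radius
    counts <- rowSums(nb)
    best <- order(-counts, energy[idx], idx)[1]
    members <- idx[nb[best, ]]
    out[[length(out) + 1]] <- structure(
      list(probe = poses[[members[1]]]$probe,
           members = poses[members],
           center = colMeans(centers[members, , drop = FALSE]),
           avg_energy = mean(energy[members]),
           size = length(members)),
      class = "ProbeCluster")
    remaining[members] <- FALSE
  }
  out <- out[order(vapply(out, `[[`, numeric(1), "avg_energy"))]
  out <- head(out, p$clusters_kept)
  for (i in seq_along(out)) out[[i]]$rank <- i
  out
}

#' Merge probe clusters across probe types into consensus sites
#'
#' Greedy merge of probe-cluster centers within `consensus_radius`: the
#' cluster with the most neighbors (ties to lower average energy) seeds a
#' site; every cluster is assigned to exactly one site.  Sites are ranked
#' by population (number of member probe clusters), ties by lower mean
#' average energy, and classified `strong` (population >=
#' `strong_threshold`), `intermediate` (> `intermediate_threshold`) or
#' `weak`.
#'
#' @param clusters flat list of `ProbeCluster`s across probe types
#' @param p [map_params()]
#' @return list of `ConsensusSite`s: `members`, `population`, `center`
#'   (pose-count-weighted mean), `mean_energy`, `rank`, `strength_class`
#' @export
consensus_sites <- function(clusters, p = map_params()) {
  if (!length(clusters)) return(list())
  centers <- t(vapply(clusters, `[[`, numeric(3), "center"))
  energy <- vapply(clusters, `[[`, numeric(1), "avg_energy")
  sizes <- vapply(clusters, `[[`, numeric(1), "size")
  n <- length(clusters)
  D <- as.matrix(stats::dist(centers))
  remaining <- rep(TRUE, n)
  sites <- list()
  while (any(remaining)) {
    idx <- which(remaining)
    nb <- D[idx, idx, drop = FALSE] <= p$consensus_radius
    counts <- rowSums(nb)
    best <- order(-counts, energy[idx], idx)[1]
    members <- idx[nb[best, ]]
    wt <- sizes[members] / sum(sizes[members])
    sites[[length(sites) + 1]] <- structure(
      list(members = clusters[members],
           population = length(members),
           center = colSums(centers[members, , drop = FALSE] * wt),
           mean_energy = mean(energy[members])),
      class = "ConsensusSite")
    remaining[members] <- FALSE
  }
  ord <- order(-vapply(sites, `[[`, numeric(1), "population"),
               vapply(sites, `[[`, numeric(1), "mean_energy"))
  sites <- sites[ord]
  for (i in seq_along(sites)) {
    sites[[i]]$rank <- i
    pop <- sites[[i]]$population
    sites[[i]]$strength_class <-
      if (pop >= p$strong_threshold) "strong"
      else if (pop > p$intermediate_threshold) "intermediate"
      else "weak"
  }
  sites
}

#' Build a consensus site from summary values
#'
#' Constructor used to express literature hotspot tables (populations and
#' centers) as site objects, e.g. for druggability classification of
#' published mappings.
#' @param population number of member probe clusters
#' @param center 3-vector, A
#' @param mean_energy mean member average energy
#' @param strong_threshold,intermediate_threshold class boundaries
#' @export
consensus_site <- function(population, center = c(0, 0, 0),
                           mean_energy = NA_real_, strong_threshold = 16,
                           intermediate_threshold = 10) {
  structure(list(members = NULL, population = population,
                 center = center, mean_energy = mean_energy, rank = NA,
                 strength_class = if (population >= strong_threshold) "strong"
                 else if (population > intermediate_threshold) "intermediate"
                 else "weak"),
            class = "ConsensusSite")
}

site_touches_residues <- function(site, rec, residues, contact_cutoff = 5) {
  a <- rec$atoms
  sel <- paste(a$chain, a$res_seq) %in% paste(residues$chain, residues$res_seq)
  if (!any(sel)) return(FALSE)
  xyz <- as.matrix(a[sel, c("x", "y", "z")])
  min(sqrt(rowSums(sweep(xyz, 2, site$center)^2))) <= contact_cutoff
}

#' Druggability verdict from ranked consensus sites
#'
#' A site collection is called druggable when its strongest (most
#' populated) retained site reaches the strong-hotspot threshold
#' (population >= 16 by default).  An optional residue filter restricts
#' the assessment to sites contacting a region of interest, e.g. a
#' protein-protein interface.
#'
#' @param sites ranked `ConsensusSite` list
#' @param rec receptor (required with `interface_filter`)
#' @param interface_filter optional data frame (`chain`, `res_seq`) of
#'   residues of interest
#' @param strong_threshold population threshold (default 16)
#' @param contact_cutoff site-center-to-residue contact distance, A
#' @return list: `druggable`, `strongest` (population), `table`
#' @export
druggability_report <- function(sites, rec = NULL, interface_filter = NULL,
                                strong_threshold = 16, contact_cutoff = 5) {
  if (!is.null(interface_filter)) {
    stopifnot(!is.null(rec))
    keep <- vapply(sites, site_touches_residues, logical(1), rec = rec,
                   residues = interface_filter,
                   contact_cutoff = contact_cutoff)
    sites <- sites[keep]
  }
  pops <- vapply(sites, `[[`, numeric(1), "population")
  tab <- data.frame(
    rank = seq_along(sites), population = pops,
    class = vapply(sites, function(s)
      if (is.null(s$strength_class)) NA_character_ else s$strength_class, ""))
  strongest <- if (length(pops)) max(pops) else 0
  list(druggable = strongest >= strong_threshold, strongest = strongest,
       table = tab)
}

site_probe_atoms <- function(site) {
  do.call(rbind, lapply(site$members, function(cl)
    do.call(rbind, lapply(cl$members, `[[`, "xyz"))))
}

#' Assemble binding sites from nearby hotspots
#'
#' Single-linkage merge of consensus sites whose centers lie within
#' `site_merge_cutoff`; merged sites are ranked by total population and
#' annotated with the receptor residues within 4 A of any member probe
#' pose.
#'
#' @param sites `ConsensusSite` list (from a real mapping: member poses
#'   are needed for residue contacts)
#' @param rec receptor `ParamStructure`
#' @param p [map_params()]
#' @return list of `BindingSite`s: `hotspots`, `total_population`,
#'   `center`, `residues` (data frame), `rank`
#' @export
predict_sites <- function(sites, rec, p = map_params()) {
  if (!length(sites)) return(list())
  centers <- t(vapply(sites, `[[`, numeric(3), "center"))
  n <- length(sites)
  # union-find single linkage on center distances
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1) {
    D <- as.matrix(stats::dist(centers))
    for (i in 1:(n - 1)) for (j in (i + 1):n)
      if (D[i, j] <= p$site_merge_cutoff) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
  }
  comp <- vapply(seq_len(n), find, 1L)
  groups <- split(seq_len(n), comp)
  axyz <- coords(rec)
  out <- lapply(groups, function(g) {
    hs <- sites[g]
    pop <- sum(vapply(hs, `[[`, numeric(1), "population"))
    pxyz <- do.call(rbind, lapply(hs, site_probe_atoms))
    resid <- NULL
    if (!is.null(pxyz) && nrow(pxyz)) {
      d2min <- vapply(seq_len(nrow(axyz)), function(i)
        min(colSums((t(pxyz) - axyz[i, ])^2)), numeric(1))
      near <- d2min <= 16
      sub <- rec$atoms[near, c("chain", "res_seq"), drop = FALSE]
      resid <- unique(sub[order(sub$chain, sub$res_seq), , drop = FALSE])
    }
    wt <- vapply(hs, `[[`, numeric(1), "population")
    structure(list(hotspots = hs, total_population = pop,
                   center = colSums(t(vapply(hs, `[[`, numeric(3),
                                             "center")) * wt / sum(wt)),
                   residues = resid),
              class = "BindingSite")
  })
  out <- out[order(-vapply(out, `[[`, numeric(1), "total_population"))]
  for (i in seq_along(out)) out[[i]]$rank <- i
  out
}

# core mapping run shared by the pipeline and per-domain mapping
map_structure <- function(prot, p = map_params(), probes = probe_library(),
                          eps = pair_contact_matrix()) {
  side <- max(vapply(probes, function(pr) probe_lattice(pr, p)$side, 1L))
  eng <- map_engine(prot, p, rep(as.integer(side), 3L), eps)
  per_probe <- lapply(probes, function(pr) {
    poses <- map_probe(prot, pr, p, eng = eng, eps = eps)
    list(poses = poses, clusters = cluster_probe_poses(poses, p))
  })
  clusters <- unlist(lapply(per_probe, `[[`, "clusters"), recursive = FALSE)
  sites <- consensus_sites(clusters, p)
  list(per_probe = per_probe, clusters = clusters, sites = sites)
}

parse_domain <- function(d) {
  # "A:12-120" or list(chain=, range=c(lo, hi))
  if (is.character(d)) {
    mt <- regmatches(d, regexec("^([A-Za-z0-9]):([0-9]+)-([0-9]+)$", d))[[1]]
    if (length(mt) != 4) stop("bad domain spec '", d, "' (expect C:lo-hi)")
    list(chain = mt[2], range = c(as.integer(mt[3]), as.integer(mt[4])))
  } else d
}

#' Map a multi-domain protein whole and per domain
#'
#' Maps the entire structure and each residue-range domain independently,
#' and returns a merged site report labelling each site with its source.
#'
#' @param rec `ParamStructure`
#' @param domains list of `"A:1-120"` strings or
#'   `list(chain=, range=c(lo, hi))`
#' @param p [map_params()]
#' @param probes probe set
#' @return list: `whole` (mapping result), `domains` (named mapping
#'   results), `report` (data frame: source, rank, population, class,
#'   center)
#' @export
map_by_domains <- function(rec, domains, p = map_params(),
                           probes = probe_library()) {
  domains <- lapply(domains, parse_domain)
  for (d in domains) {
    if (d$range[1] > d$range[2]) stop("empty domain range")
  }
  if (length(domains) > 1) {
    for (i in 1:(length(domains) - 1)) for (j in (i + 1):length(domains)) {
      a <- domains[[i]]; b <- domains[[j]]
      if (a$chain == b$chain &&
          a$range[1] <= b$range[2] && b$range[1] <= a$range[2])
        stop("overlapping domain ranges")
    }
  }
  whole <- map_structure(rec, p, probes)
  dom_names <- vapply(domains, function(d)
    sprintf("%s:%d-%d", d$chain, d$range[1], d$range[2]), "")
  dres <- lapply(domains, function(d) {
    sub <- select_atoms(rec, chains = d$chain, res_range = d$range)
    class(sub) <- class(rec)
    map_structure(sub, p, probes)
  })
  names(dres) <- dom_names
  rep_rows <- function(src, sites) {
    if (!length(sites)) return(NULL)
    data.frame(source = src,
               rank = vapply(sites, `[[`, numeric(1), "rank"),
               population = vapply(sites, `[[`, numeric(1), "population"),
               class = vapply(sites, `[[`, "", "strength_class"),
               cx = vapply(sites, function(s) s$center[1], 1),
               cy = vapply(sites, function(s) s$center[2], 1),
               cz = vapply(sites, function(s) s$center[3], 1))
  }
  report <- do.call(rbind, c(list(rep_rows("whole", whole$sites)),
                             lapply(dom_names, function(nm)
                               rep_rows(nm, dres[[nm]]$sites))))
  list(whole = whole, domains = dres, report = report)
}

#' Hotspot summary table of a mapping run
#' @param sites `ConsensusSite` list
#' @export
hotspot_table <- function(sites) {
  if (!length(sites))
    return(data.frame(rank = integer(), population = integer(),
                      class = character(), mean_energy = numeric(),
                      cx = numeric(), cy = numeric(), cz = numeric()))
  data.frame(rank = vapply(sites, `[[`, numeric(1), "rank"),
             population = vapply(sites, `[[`, numeric(1), "population"),
             class = vapply(sites, `[[`, "", "strength_class"),
             mean_energy = vapply(sites, `[[`, numeric(1), "mean_energy"),
             cx = vapply(sites, function(s) s$center[1], 1),
             cy = vapply(sites, function(s) s$center[2], 1),
             cz = vapply(sites, function(s) s$center[3], 1))
}
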