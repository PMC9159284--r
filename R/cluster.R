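# Greedy RMSD clustering of docked poses and CAPRI-style metrics.

#' Clustering parameters
#' @param radius ligand-RMSD cluster radius, A (default 9)
#' @param max_clusters maximum clusters reported (default 10)
#' @param atom_mask `"heavy"` (all ligand heavy atoms) or `"CA"`
#' @export
cluster_params <- function(radius = 9, max_clusters = 10,
                           atom_mask = c("heavy", "CA")) {
  stopifnot(radius > 0, max_clusters >= 1)
  structure(list(radius = radius, max_clusters = max_clusters,
                 atom_mask = match.arg(atom_mask)),
            class = "ClusterParams")
}

mask_indices <- function(lig, atom_mask) {
  idx <- if (identical(atom_mask, "CA")) which(lig$atoms$name == "CA")
         else seq_len(n_atoms(lig))
  if (!length(idx)) stop("empty atom mask")
  idx
}

#' Ligand RMSD between two poses (receptor frame fixed)
#'
#' No re-superposition is performed: the deviation is measured in the
#' shared receptor frame, the docking convention.
#' @param poseA,poseB `Pose`s, or n x 3 coordinate matrices
#' @param lig ligand structure (needed when poses are given)
#' @param atom_mask `"heavy"` or `"CA"`
#' @return RMSD in Angstrom
#' @export
ligand_rmsd <- function(poseA, poseB, lig = NULL, atom_mask = "heavy") {
  if (is.matrix(poseA)) {
    A <- poseA; B <- poseB
  } else {
    idx <- mask_indices(lig, atom_mask)
    x <- coords(lig)[idx, , drop = FALSE]
    A <- pose_apply(poseA, x)
    B <- pose_apply(poseB, x)
  }
  if (!nrow(A)) stop("empty atom mask")
  stopifnot(nrow(A) == nrow(B))
  sqrt(mean(rowSums((A - B)^2)))
}

# n_poses x 3m coordinate matrix of the masked ligand atoms under each pose
pose_coord_matrix <- function(poses, lig, atom_mask) {
  idx <- mask_indices(lig, atom_mask)
  x <- coords(lig)[idx, , drop = FALSE]
  t(vapply(poses$poses, function(p) as.vector(pose_apply(p, x)),
           numeric(3 * length(idx))))
}

#' Greedy RMSD clustering of a pose list
#'
#' Repeatedly selects the pose with the most neighbors within the RMSD
#' radius (ties to the lower-energy pose, then input order), forms a
#' cluster from it and its neighbors, removes them, and continues until
#' the poses are exhausted or `max_clusters` clusters exist.  Clusters are
#' ranked by population, ties by lower center energy.
#'
#' @param poses a `PoseList`
#' @param lig the ligand `ParamStructure` used for docking
#' @param params a [cluster_params()] object
#' @return list of `PoseCluster`s: `members` (indices into `poses`),
#'   `representative`, `population`, `center_energy`, `rank`
#' @export
greedy_cluster <- function(poses, lig, params = cluster_params()) {
  n <- length(poses)
  stopifnot(n >= 1)
  cm <- pose_coord_matrix(poses, lig, params$atom_mask)
  m <- ncol(cm) / 3
  D <- as.matrix(stats::dist(cm)) / sqrt(m)
  energy <- vapply(poses$poses, `[[`, numeric(1), "energy")
  remaining <- rep(TRUE, n)
  clusters <- list()
  while (any(remaining) && length(clusters) < params$max_clusters) {
    idx <- which(remaining)
    nb <- D[idx, idx, drop = FALSE] <= params$radius
    counts <- rowSums(nb)
    best <- order(-counts, energy[idx], idx)[1]
    members <- idx[nb[best, ]]
    rep_pose <- idx[best]
    clusters[[length(clusters) + 1]] <-
      list(members = members, representative = rep_pose,
           population = length(members), center_energy = energy[rep_pose])
    remaining[members] <- FALSE
  }
  ord <- order(-vapply(clusters, `[[`, numeric(1), "population"),
               vapply(clusters, `[[`, numeric(1), "center_energy"))
  clusters <- clusters[ord]
  for (i in seq_along(clusters)) {
    clusters[[i]]$rank <- i
    class(clusters[[i]]) <- "PoseCluster"
  }
  structure(clusters, class = "PoseClusterList")
}

#' @export
print.PoseClusterList <- function(x, ...) {
  cat(sprintf("<PoseClusterList> %d cluster(s); populations: %s\n", length(x),
              paste(vapply(x, `[[`, numeric(1), "population"), collapse = ", ")))
  invisible(x)
}

#' Cluster report table
#' @param clusters a `PoseClusterList`; `poses` the clustered `PoseList`
#' @param poses the clustered `PoseList`
#' @export
cluster_table <- function(clusters, poses) {
  do.call(rbind, lapply(clusters, function(cl)
    data.frame(rank = cl$rank, population = cl$population,
               center_energy = cl$center_energy,
               representative = cl$representative)))
}

# least-squares superposition (Kabsch); returns rotation R, translation t
# such that P %*% t(R) + t approximates Q
kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  H <- t(sweep(P, 2, cp)) %*% sweep(Q, 2, cq)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(R = R, t = as.numeric(cq - R %*% cp))
}

backbone_names <- c("N", "CA", "C", "O")

residue_key <- function(a) paste(a$chain, a$res_seq, a$icode, sep = "|")

#' Interface RMSD between a model and a reference complex
#'
#' Interface residues are defined on the reference: residues of either
#' side with any heavy atom within `cutoff` of the other side.  Backbone
#' atoms (N, CA, C, O) of those residues are matched between model and
#' reference by (chain, residue, atom name), least-squares superposed,
#' and the RMSD reported (the CAPRI iRMSD convention).
#'
#' @param model,reference `Structure`s containing both chains
#' @param chains_a,chains_b chain identifiers of the two sides
#' @param cutoff interface distance cutoff in A (default 10)
#' @return RMSD in Angstrom
#' @export
irmsd <- function(model, reference, chains_a, chains_b, cutoff = 10) {
  ir <- interface_residues(reference, chains_a, chains_b, cutoff = cutoff)
  keys <- unique(c(paste(ir$a$chain, ir$a$res_seq, ir$a$icode, sep = "|"),
                   paste(ir$b$chain, ir$b$res_seq, ir$b$icode, sep = "|")))
  pick <- function(s) {
    a <- s$atoms
    sel <- residue_key(a) %in% keys & a$name %in% backbone_names
    a <- a[sel, , drop = FALSE]
    a[order(a$chain, a$res_seq, a$icode, match(a$name, backbone_names)), ]
  }
  am <- pick(model); ar <- pick(reference)
  km <- paste(residue_key(am), am$name)
  kr <- paste(residue_key(ar), ar$name)
  common <- intersect(km, kr)
  if (length(common) < 3)
    stop("interface backbone correspondence model-reference too small")
  P <- as.matrix(am[match(common, km), c("x", "y", "z")])
  Q <- as.matrix(ar[match(common, kr), c("x", "y", "z")])
  fit <- kabsch(P, Q)
  Pf <- sweep(P %*% t(fit$R), 2, fit$t, "+")
  sqrt(mean(rowSums((Pf - Q)^2)))
}
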