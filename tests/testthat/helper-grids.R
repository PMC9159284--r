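# shared test helpers

random_gridset <- function(dims, seed = NULL, ntypes = 6, density = 1) {
  if (!is.null(seed)) set.seed(seed)
  nv <- prod(dims)
  mk <- function() {
    a <- array(runif(nv), dims)
    if (density < 1) a[runif(nv) > density] <- 0
    a
  }
  ch <- list(core = mk(), surface = mk(),
             charge = array(rnorm(nv), dims),
             pair = array(runif(nv * ntypes) *
                            (runif(nv * ntypes) < density), c(dims, ntypes)))
  new_gridset(c(0, 0, 0), 1, ch)
}

# minimal PDB text: one ATOM line per row of a data frame
pdb_line <- function(serial, name, res, chain, seq, x, y, z,
                     occ = 1, alt = "", el = substr(name, 1, 1),
                     record = "ATOM") {
  nm <- if (nchar(name) >= 4) substr(name, 1, 4) else
    paste0(" ", formatC(name, width = -3))
  sprintf("%-6s%5d %4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, nm, alt, res, chain, seq, x, y, z, occ, 0, el)
}

# independent quaternion-based superposition (Horn) used as the oracle
# against the package's SVD path
horn_superpose_rmsd <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  A <- sweep(P, 2, cp); B <- sweep(Q, 2, cq)
  S <- t(A) %*% B
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  lam <- max(eigen(K, symmetric = TRUE)$values)
  msd <- (sum(A^2) + sum(B^2) - 2 * lam) / nrow(P)
  sqrt(max(0, msd))
}

# brute-force interface scan oracle
scan_interface <- function(model, chains_a, chains_b, cutoff = 10) {
  a <- model$atoms
  ia <- which(a$chain %in% chains_a); ib <- which(a$chain %in% chains_b)
  hits_a <- character(); hits_b <- character()
  for (i in ia) for (j in ib) {
    d <- sqrt((a$x[i] - a$x[j])^2 + (a$y[i] - a$y[j])^2 + (a$z[i] - a$z[j])^2)
    if (d <= cutoff) {
      hits_a <- c(hits_a, paste(a$chain[i], a$res_seq[i]))
      hits_b <- c(hits_b, paste(a$chain[j], a$res_seq[j]))
    }
  }
  list(a = sort(unique(hits_a)), b = sort(unique(hits_b)))
}
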