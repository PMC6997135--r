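# Independent oracles used to cross-check the package's implementations.
# Each deliberately takes a different algorithmic route than the code it
# verifies.

# Quaternion-based optimal superposition (Horn's closed form): builds the
# 4x4 key matrix from the cross-covariance and extracts the optimal
# rotation from its top eigenvector.
oracle_quaternion_rmsd <- function(mobile, reference) {
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(reference, 2, colMeans(reference))
  S <- crossprod(A, B)
  Sxx <- S[1, 1]; Sxy <- S[1, 2]; Sxz <- S[1, 3]
  Syx <- S[2, 1]; Syy <- S[2, 2]; Syz <- S[2, 3]
  Szx <- S[3, 1]; Szy <- S[3, 2]; Szz <- S[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz),
    4, 4, byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE)$values)
  msd <- (sum(A^2) + sum(B^2) - 2 * lam) / nrow(A)
  sqrt(max(msd, 0))
}

# Union-find connected components of a thresholded distance matrix.
oracle_union_find <- function(m, threshold) {
  n <- nrow(m)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    if (m[i, j] <= threshold) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# Exhaustive residue contact enumeration: all heavy-atom pairs, no grid.
oracle_contacts <- function(traj, cutoff = 4.5, neighbor_exclusion = 2L,
                            frame_index = 1L) {
  topo <- traj$topology
  xyz <- frame_coords(traj, frame_index)
  keep <- topo$is_heavy
  res <- unique(topo$resid[keep])
  out <- list()
  for (ii in seq_along(res)) for (jj in seq_along(res)) {
    if (jj <= ii) next
    if (abs(ii - jj) < neighbor_exclusion) next
    ai <- which(keep & topo$resid == res[ii])
    aj <- which(keep & topo$resid == res[jj])
    dmin <- min(apply(xyz[ai, , drop = FALSE], 1, function(p)
      min(sqrt(rowSums(sweep(xyz[aj, , drop = FALSE], 2, p)^2)))))
    if (dmin < cutoff)
      out[[length(out) + 1L]] <- c(res[ii], res[jj])
  }
  if (!length(out)) return(matrix(integer(0), ncol = 2))
  m <- do.call(rbind, out)
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

# Naive double-loop Coulomb + Lennard-Jones.
oracle_coulomb_lj <- function(xa, xb, qa, qb, sa, sb, ea, eb,
                              dielectric = 1) {
  f <- 1389.35458
  ele <- 0; vdw <- 0
  for (i in seq_len(nrow(xa))) for (j in seq_len(nrow(xb))) {
    r <- sqrt(sum((xa[i, ] - xb[j, ])^2))
    ele <- ele + f * qa[i] * qb[j] / (dielectric * r)
    sig <- (sa[i] + sb[j]) / 2
    eps <- sqrt(ea[i] * eb[j])
    vdw <- vdw + 4 * eps * ((sig / r)^12 - (sig / r)^6)
  }
  list(ele = ele, vdw = vdw)
}

# Random compact cluster of residues for contact-map fuzzing: n_res
# residues of 2-4 heavy atoms in a box small enough to guarantee contacts.
random_residue_cluster <- function(n_res, seed, box = 12) {
  set.seed(seed)
  rows <- list()
  serial <- 0L
  for (r in seq_len(n_res)) {
    center <- runif(3, 0, box)
    na <- sample(2:4, 1)
    for (a in seq_len(na)) {
      serial <- serial + 1L
      rows[[serial]] <- data.frame(
        serial = serial, name = paste0("C", a), element = "C",
        resname = "GLY", resid = r, chain = "A", occupancy = 1,
        bfactor = 0, is_heavy = TRUE, stringsAsFactors = FALSE)
    }
  }
  topo <- do.call(rbind, rows)
  xyz <- matrix(0, nrow(topo), 3)
  set.seed(seed + 1L)
  for (r in seq_len(n_res)) {
    idx <- which(topo$resid == r)
    center <- runif(3, 0, box)
    xyz[idx, ] <- matrix(rep(center, length(idx)), ncol = 3, byrow = TRUE) +
      matrix(runif(3 * length(idx), -1, 1), ncol = 3)
  }
  trajectory(topo, xyz)
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}
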