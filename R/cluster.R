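# RMSD-threshold conformational clustering and time-dependent growth.
#
# The pairwise same-cluster indicator (1 when the superposed RMSD of two
# frames is at or below the threshold) does not by itself define a
# partition, since it is not transitive; clusters are its minimal
# completion, the connected components of the indicator graph
# (single-linkage at the threshold).

#' Pairwise superposed RMSD matrix
#'
#' @param traj a `trajectory` with >= 2 frames.
#' @param sel atom indices used for fitting and RMSD (default all).
#' @return symmetric `n_frames x n_frames` matrix in A with zero diagonal.
#' @export
pairwise_rmsd_matrix <- function(traj, sel = NULL) {
  if (n_frames(traj) < 2L) stop("need >= 2 frames")
  if (is.null(sel)) sel <- seq_len(n_atoms(traj))
  if (length(sel) == 0L) stop("empty selection")
  nf <- n_frames(traj)
  # pre-center each frame once; pairwise RMSD from the SVD identity
  X <- lapply(seq_len(nf), function(f) {
    xa <- traj$coords[sel, , f, drop = TRUE]
    sweep(xa, 2, colMeans(xa))
  })
  ssq <- vapply(X, function(m) sum(m^2), numeric(1))
  k <- length(sel)
  m <- matrix(0, nf, nf)
  for (i in seq_len(nf - 1L)) {
    for (j in seq.int(i + 1L, nf)) {
      sv <- svd(crossprod(X[[i]], X[[j]]))
      s <- sv$d
      s[3] <- s[3] * sign(det(sv$u) * det(sv$v))
      v <- sqrt(max((ssq[i] + ssq[j] - 2 * sum(s)) / k, 0))
      m[i, j] <- v
      m[j, i] <- v
    }
  }
  m
}

components_from_adjacency <- function(adj) {
  # BFS flood fill; adj is a logical matrix (diagonal ignored)
  n <- nrow(adj)
  labels <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (labels[s] > 0L) next
    cur <- cur + 1L
    queue <- s
    labels[s] <- cur
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      nb <- which(adj[v, ] & labels == 0L)
      labels[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  labels
}

#' Threshold clustering of an RMSD matrix
#'
#' Frames i, j are joined when `matrix[i, j] <= threshold`; clusters are
#' the connected components of that graph. Cluster ids are ordered by first
#' occurring frame. The representative of each cluster is the
#' lowest-energy member when per-frame energies are supplied, otherwise
#' the medoid (minimum mean RMSD to the other members).
#'
#' @param matrix symmetric pairwise RMSD matrix (A).
#' @param threshold RMSD threshold in A (> 0). Presets in common use:
#'   2.4 (coarse) and 1.5 (fine).
#' @param energies optional per-frame energy series.
#' @return list of class `cluster_assignment`: `labels`, `threshold`,
#'   `representatives`, `occupancy`, `n_clusters`.
#' @export
threshold_cluster <- function(matrix, threshold, energies = NULL) {
  if (!is.matrix(matrix) || nrow(matrix) != ncol(matrix))
    stop("shape error: matrix must be square")
  if (threshold <= 0) stop("threshold must be > 0")
  n <- nrow(matrix)
  adj <- matrix <= threshold
  labels <- components_from_adjacency(adj)
  # relabel in order of first occurrence
  labels <- match(labels, unique(labels))
  ids <- sort(unique(labels))
  reps <- vapply(ids, function(cid) {
    members <- which(labels == cid)
    if (!is.null(energies)) return(members[which.min(energies[members])])
    if (length(members) == 1L) return(members)
    sub <- matrix[members, members, drop = FALSE]
    members[which.min(rowMeans(sub))]
  }, integer(1))
  occ <- as.numeric(table(factor(labels, levels = ids))) / n
  structure(list(labels = labels, threshold = threshold,
                 representatives = reps, occupancy = occ,
                 n_clusters = length(ids)),
            class = "cluster_assignment")
}

#' Time-dependent cluster growth
#'
#' Number of clusters found on each prefix of the trajectory (every
#' `stride` frames). A plateau indicates converged conformational
#' sampling.
#'
#' @param traj a `trajectory` (or a precomputed RMSD matrix).
#' @param sel atom indices (ignored when a matrix is given).
#' @param threshold RMSD threshold in A.
#' @param stride prefix step in frames (>= 1).
#' @return data.frame with `frame` (prefix end) and `n_clusters`
#'   (non-decreasing).
#' @export
cluster_growth <- function(traj, sel = NULL, threshold = 1.5, stride = 1L) {
  if (stride < 1L) stop("stride must be >= 1")
  m <- if (is.matrix(traj)) traj else pairwise_rmsd_matrix(traj, sel)
  n <- nrow(m)
  ends <- unique(c(seq.int(stride, n, by = stride), n))
  adj <- m <= threshold
  counts <- vapply(ends, function(e) {
    sub <- adj[seq_len(e), seq_len(e), drop = FALSE]
    max(components_from_adjacency(sub))
  }, integer(1))
  data.frame(frame = ends, n_clusters = counts)
}
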