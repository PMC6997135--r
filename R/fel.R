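# PCA of superposed Cartesian coordinates and Boltzmann-inverted
# free-energy landscapes over (PC1, PC2).

KB_KJ <- 0.0083145  # Boltzmann constant, kJ/mol/K

#' Principal component analysis of a trajectory
#'
#' Frames are superposed onto the ensemble mean structure (two fit/re-mean
#' iterations), then the covariance of the flattened `3k`-dimensional
#' coordinates is eigendecomposed. Eigenvector signs follow a fixed
#' convention (largest-magnitude component positive) so projections are
#' reproducible.
#'
#' @param traj a `trajectory` with >= 3 frames.
#' @param sel atom indices (commonly the Cα set).
#' @return list of class `pca_model`: `mean` (k x 3), `eigenvalues` (A^2,
#'   non-increasing), `eigenvectors` (3k x m, orthonormal columns),
#'   `projections` (frames x m).
#' @export
pca_traj <- function(traj, sel = NULL) {
  if (n_frames(traj) < 3L) stop("insufficient frames: PCA needs >= 3")
  if (is.null(sel)) sel <- seq_len(n_atoms(traj))
  fit <- superpose_onto_mean(traj$coords[sel, , , drop = FALSE])
  k <- length(sel); nf <- n_frames(traj)
  # flatten frames to nf x 3k (atom-major: x1 y1 z1 x2 ...)
  M <- t(matrix(aperm(fit$fitted, c(2, 1, 3)), nrow = 3L * k, ncol = nf))
  mu <- colMeans(M)
  Mc <- sweep(M, 2, mu)
  cv <- crossprod(Mc) / (nf - 1L)
  eig <- eigen(cv, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  vecs <- eig$vectors
  for (j in seq_len(ncol(vecs))) {
    i <- which.max(abs(vecs[, j]))
    if (vecs[i, j] < 0) vecs[, j] <- -vecs[, j]
  }
  structure(list(mean = fit$mean, eigenvalues = vals, eigenvectors = vecs,
                 projections = Mc %*% vecs, center = mu),
            class = "pca_model")
}

#' Free-energy landscape over two principal components
#'
#' 2-D histogram of the projections converted to free energies by
#' Boltzmann inversion, `dG(X) = -kB T ln P(X)`, shifted so the sampled
#' minimum is zero. Unsampled bins are `NA` ("unsampled"), never a finite
#' energy, since the inversion diverges at zero probability.
#'
#' @param projections matrix with >= 2 columns (PC1, PC2 used) or a
#'   `pca_model`.
#' @param T temperature in K (default 300).
#' @param bins bins per axis (default 50); range padded by 2%.
#' @param kB Boltzmann constant in kJ/mol/K.
#' @return list of class `fel_grid`: `p` (probability matrix), `dg`
#'   (kJ/mol, NA where unsampled), `x_edges`, `y_edges`, `T`, `kB`,
#'   `bin_of_frame` (frames x 2 bin indices).
#' @export
fel_grid <- function(projections, T = 300, bins = 50L, kB = KB_KJ) {
  if (inherits(projections, "pca_model")) projections <- projections$projections
  if (T <= 0) stop("temperature must be > 0")
  if (bins < 2L) stop("need at least 2 bins per axis")
  x <- projections[, 1]; y <- projections[, 2]
  pad <- function(v) {
    r <- range(v); w <- diff(r)
    if (w == 0) {
      warning("degenerate surface: all projections in one bin")
      w <- 1
    }
    c(r[1] - 0.02 * w, r[2] + 0.02 * w)
  }
  xr <- pad(x); yr <- pad(y)
  xe <- seq(xr[1], xr[2], length.out = bins + 1L)
  ye <- seq(yr[1], yr[2], length.out = bins + 1L)
  ix <- pmin(pmax(findInterval(x, xe, rightmost.closed = TRUE), 1L), bins)
  iy <- pmin(pmax(findInterval(y, ye, rightmost.closed = TRUE), 1L), bins)
  counts <- matrix(0, bins, bins)
  tab <- table(factor(ix, levels = seq_len(bins)),
               factor(iy, levels = seq_len(bins)))
  counts <- matrix(as.numeric(tab), bins, bins)
  p <- counts / length(x)
  dg <- matrix(NA_real_, bins, bins)
  sampled <- p > 0
  dg[sampled] <- -kB * T * log(p[sampled])
  dg <- dg - min(dg, na.rm = TRUE)
  structure(list(p = p, dg = dg, x_edges = xe, y_edges = ye, T = T,
                 kB = kB, bin_of_frame = cbind(ix, iy)),
            class = "fel_grid")
}

#' Extract basins from a free-energy landscape
#'
#' Basins are 8-connected regions of sampled bins with `dG <= depth_cut`.
#' Regions holding less than `min_occupancy` of all frames are discarded
#' as sampling noise (isolated low-count bins clear any energy cut once
#' the histogram is sparse). Each basin reports its floor energy, member
#' frames, and the smallest set of contiguous frame-index runs covering
#' at least 80% of those frames (the dwell periods).
#'
#' @param grid a `fel_grid`.
#' @param depth_cut energy cut in kJ/mol (> 0).
#' @param min_occupancy minimum fraction of frames a region must hold to
#'   count as a basin (default 0.01).
#' @return list of basins, each with `bins` (2-col matrix), `floor_dg`,
#'   `frames`, `occupancy`, `intervals` (data.frame from/to frame
#'   indices).
#' @export
find_basins <- function(grid, depth_cut, min_occupancy = 0.01) {
  if (depth_cut <= 0) stop("argument error: depth_cut must be > 0")
  sel <- !is.na(grid$dg) & grid$dg <= depth_cut
  bins <- nrow(grid$p)
  lab <- matrix(0L, bins, bins)
  cur <- 0L
  for (i in seq_len(bins)) for (j in seq_len(bins)) {
    if (!sel[i, j] || lab[i, j] > 0L) next
    cur <- cur + 1L
    stack <- list(c(i, j))
    lab[i, j] <- cur
    while (length(stack)) {
      v <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (di in -1:1) for (dj in -1:1) {
        a <- v[1] + di; b <- v[2] + dj
        if (a < 1 || b < 1 || a > bins || b > bins) next
        if (sel[a, b] && lab[a, b] == 0L) {
          lab[a, b] <- cur
          stack[[length(stack) + 1L]] <- c(a, b)
        }
      }
    }
  }
  if (cur == 0L) return(list())
  frame_lab <- lab[cbind(grid$bin_of_frame[, 1], grid$bin_of_frame[, 2])]
  n_total <- nrow(grid$bin_of_frame)
  basins <- lapply(seq_len(cur), function(cid) {
    cells <- which(lab == cid, arr.ind = TRUE)
    frames <- which(frame_lab == cid)
    runs <- split(frames, cumsum(c(1L, diff(frames) != 1L)))
    runs <- runs[order(-lengths(runs))]
    need <- ceiling(0.8 * length(frames))
    takes <- which(cumsum(lengths(runs)) >= need)[1]
    iv <- do.call(rbind, lapply(runs[seq_len(takes)], function(r)
      data.frame(from = r[1], to = r[length(r)])))
    iv <- iv[order(iv$from), , drop = FALSE]
    rownames(iv) <- NULL
    list(bins = cells, floor_dg = min(grid$dg[cells], na.rm = TRUE),
         frames = frames, occupancy = length(frames) / n_total,
         intervals = iv)
  })
  basins <- basins[vapply(basins, `[[`, numeric(1), "occupancy") >=
                     min_occupancy]
  basins[order(vapply(basins, `[[`, numeric(1), "floor_dg"))]
}

#' Non-Gaussianity of a principal-component projection
#'
#' Sample excess kurtosis and Sarle's bimodality coefficient
#' `b = (skewness^2 + 1) / kurtosis`. Reported, not thresholded: strongly
#' non-Gaussian PC distributions mark functional slow motions.
#'
#' @param x projection series with >= 20 samples and nonzero variance.
#' @return list: `excess_kurtosis`, `skewness`, `bimodality`.
#' @export
pc_gaussianity <- function(x) {
  if (length(x) < 20L) stop("need at least 20 samples")
  m2 <- mean((x - mean(x))^2)
  if (m2 == 0) stop("undefined moments: constant series")
  m3 <- mean((x - mean(x))^3)
  m4 <- mean((x - mean(x))^4)
  skew <- m3 / m2^1.5
  kurt <- m4 / m2^2
  list(excess_kurtosis = kurt - 3, skewness = skew,
       bimodality = (skew^2 + 1) / kurt)
}

#' Reconstruct superposed coordinates from a PCA model
#'
#' Inverts the projection onto all modes, recovering the fitted
#' coordinates of the requested frame.
#'
#' @param model a `pca_model`.
#' @param frame frame index.
#' @return `k x 3` coordinate matrix.
#' @export
pca_reconstruct <- function(model, frame) {
  flat <- model$center +
    as.vector(model$projections[frame, ] %*% t(model$eigenvectors))
  matrix(flat, ncol = 3L, byrow = TRUE)
}
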