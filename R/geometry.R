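# Superposition and basic conformational descriptors.

#' Kabsch superposition of two frames
#'
#' Least-squares rigid-body fit of `mobile` onto `reference` over the
#' selected atoms (SVD of the cross-covariance; the reflection branch is
#' corrected so the rotation is proper, det = +1). The RMSD is computed
#' after applying the transform.
#'
#' @param mobile,reference `n x 3` coordinate matrices (or single-frame
#'   trajectories).
#' @param sel atom indices used for the fit (default all); needs >= 3
#'   non-collinear atoms.
#' @return list with `rotation` (3x3), `translation` (length 3; the fitted
#'   coordinates are `mobile %*% rotation + translation`), `rmsd`, `n_atoms`,
#'   `per_atom_deviation` and `fitted` (all mobile atoms transformed).
#' @export
kabsch_superpose <- function(mobile, reference, sel = NULL) {
  if (inherits(mobile, "trajectory")) mobile <- frame_coords(mobile, 1L)
  if (inherits(reference, "trajectory")) reference <- frame_coords(reference, 1L)
  if (is.null(sel)) sel <- seq_len(nrow(mobile))
  if (length(sel) < 3L) stop("superposition needs at least 3 atoms")
  A <- mobile[sel, , drop = FALSE]
  B <- reference[sel, , drop = FALSE]
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  sv <- svd(crossprod(A0, B0))
  if (sv$d[2] < 1e-10 * max(sv$d[1], 1))
    stop("degenerate geometry: selection is collinear or coincident")
  d <- sign(det(sv$u %*% t(sv$v)))
  D <- diag(c(1, 1, d))
  R <- sv$u %*% D %*% t(sv$v)
  tr <- cb - as.vector(ca %*% R)
  fitted <- sweep(mobile %*% R, 2, tr, `+`)
  dev <- sqrt(rowSums((fitted[sel, , drop = FALSE] - B)^2))
  list(rotation = R, translation = tr,
       rmsd = sqrt(mean(dev^2)), n_atoms = length(sel),
       per_atom_deviation = dev, fitted = fitted)
}

superpose_rmsd <- function(xa, xb) {
  # fit-selection RMSD only (both matrices already restricted to selection)
  ca <- colMeans(xa); cb <- colMeans(xb)
  A0 <- sweep(xa, 2, ca); B0 <- sweep(xb, 2, cb)
  sv <- svd(crossprod(A0, B0))
  d <- sign(det(sv$u) * det(sv$v))
  s <- sv$d; s[3] <- s[3] * d
  msd <- (sum(A0^2) + sum(B0^2) - 2 * sum(s)) / nrow(xa)
  sqrt(max(msd, 0))
}

#' Per-frame RMSD against a reference
#'
#' Superposes every frame onto the reference over the selection and reports
#' the selection RMSD, plus mean and s.d. over an equilibrated window
#' (frames after `discard_frac` of the run, mirroring the common practice
#' of dropping the approach to equilibrium).
#'
#' @param traj a `trajectory`.
#' @param reference `n x 3` matrix or single-frame trajectory (default:
#'   first frame).
#' @param sel atom indices (default all).
#' @param discard_frac fraction of initial frames excluded from the
#'   mean/s.d. summary (default 0.1).
#' @return list with `rmsd` (per-frame, A), `mean`, `sd`, `window` (frame
#'   indices summarized).
#' @export
rmsd_series <- function(traj, reference = NULL, sel = NULL,
                        discard_frac = 0.1) {
  if (is.null(sel)) sel <- seq_len(n_atoms(traj))
  if (length(sel) == 0L) stop("empty selection")
  if (is.null(reference)) reference <- frame_coords(traj, 1L)
  if (inherits(reference, "trajectory")) reference <- frame_coords(reference, 1L)
  ref <- reference[sel, , drop = FALSE]
  nf <- n_frames(traj)
  out <- vapply(seq_len(nf), function(f)
    superpose_rmsd(traj$coords[sel, , f, drop = TRUE], ref), numeric(1))
  win <- seq.int(floor(discard_frac * nf) + 1L, nf)
  list(rmsd = out, mean = mean(out[win]),
       sd = if (length(win) > 1L) sd(out[win]) else NA_real_,
       window = win)
}

superpose_onto_mean <- function(X, iterations = 2L) {
  # X: k x 3 x nf selected coordinates; returns fitted array and mean
  nf <- dim(X)[3]
  ref <- X[, , 1, drop = TRUE]
  for (it in seq_len(iterations)) {
    for (f in seq_len(nf)) {
      xa <- X[, , f, drop = TRUE]
      ca <- colMeans(xa); cb <- colMeans(ref)
      A0 <- sweep(xa, 2, ca); B0 <- sweep(ref, 2, cb)
      sv <- svd(crossprod(A0, B0))
      d <- sign(det(sv$u %*% t(sv$v)))
      R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
      X[, , f] <- sweep(A0 %*% R, 2, cb, `+`)
    }
    ref <- apply(X, c(1, 2), mean)
  }
  list(fitted = X, mean = ref)
}

#' Root-mean-square fluctuation per atom
#'
#' Frames are superposed onto the ensemble mean structure (two fit/re-mean
#' iterations), then `RMSF_i = sqrt(mean_f |r_i(f) - <r_i>|^2)`.
#'
#' @param traj a `trajectory` with >= 2 frames.
#' @param sel atom indices (default all).
#' @return numeric vector of per-atom RMSF in A (ordered as `sel`).
#' @export
rmsf <- function(traj, sel = NULL) {
  if (n_frames(traj) < 2L) stop("insufficient frames: RMSF needs >= 2")
  if (is.null(sel)) sel <- seq_len(n_atoms(traj))
  fit <- superpose_onto_mean(traj$coords[sel, , , drop = FALSE])
  dev2 <- sweep(fit$fitted, c(1, 2), fit$mean)^2
  per_frame_sq <- apply(dev2, 3, rowSums)          # k x nf
  if (is.null(dim(per_frame_sq)))
    per_frame_sq <- matrix(per_frame_sq, nrow = 1)
  sqrt(rowMeans(per_frame_sq))
}

#' Convert RMSF to a crystallographic B-factor
#'
#' `B = (8 pi^2 / 3) * rmsf^2`, in A^2.
#'
#' @param rmsf per-atom RMSF in A (>= 0).
#' @return B-factors in A^2.
#' @export
bfactor_from_rmsf <- function(rmsf) {
  if (any(rmsf < 0)) stop("domain error: rmsf must be >= 0")
  (8 * pi^2 / 3) * rmsf^2
}

#' Radius of gyration
#'
#' Mass-weighted Rg about the center of mass; masses default to unit
#' (geometric Rg). `masses = "element"` uses a built-in element mass table.
#'
#' @param frame `n x 3` matrix or single-frame trajectory.
#' @param sel atom indices (default all).
#' @param masses `NULL` (unit), `"element"`, or a numeric vector per
#'   selected atom.
#' @param topology required when `masses = "element"` and `frame` is a bare
#'   matrix.
#' @return Rg in A.
#' @export
radius_of_gyration <- function(frame, sel = NULL, masses = NULL,
                               topology = NULL) {
  if (inherits(frame, "trajectory")) {
    if (is.null(topology)) topology <- frame$topology
    frame <- frame_coords(frame, 1L)
  }
  if (is.null(sel)) sel <- seq_len(nrow(frame))
  if (length(sel) == 0L) stop("empty selection")
  X <- frame[sel, , drop = FALSE]
  m <- if (is.null(masses)) rep(1, length(sel))
  else if (identical(masses, "element")) {
    el <- topology$element[sel]
    mm <- ELEMENT_MASS[el]
    mm[is.na(mm)] <- 12
    as.numeric(mm)
  } else masses
  if (any(m <= 0) || sum(m) <= 0) stop("domain error: masses must be positive")
  com <- colSums(X * m) / sum(m)
  sqrt(sum(m * rowSums(sweep(X, 2, com)^2)) / sum(m))
}

#' Interatomic distance time series
#'
#' @param traj a `trajectory`.
#' @param i,j distinct atom indices.
#' @return per-frame Euclidean distance in A.
#' @export
distance_series <- function(traj, i, j) {
  if (i == j) stop("argument error: atoms must be distinct")
  if (max(i, j) > n_atoms(traj) || min(i, j) < 1) stop("atom index out of range")
  d <- traj$coords[i, , , drop = TRUE] - traj$coords[j, , , drop = TRUE]
  if (is.null(dim(d))) d <- matrix(d, ncol = 1)
  sqrt(colSums(d^2))
}

#' Angle time series (vertex at the middle atom)
#'
#' @param traj a `trajectory`.
#' @param i,j,k three distinct atom indices; the angle is at `j`.
#' @return per-frame angle in degrees, in [0, 180].
#' @export
angle_series <- function(traj, i, j, k) {
  ids <- c(i, j, k)
  if (anyDuplicated(ids)) stop("argument error: atoms must be distinct")
  if (max(ids) > n_atoms(traj) || min(ids) < 1) stop("atom index out of range")
  u <- traj$coords[i, , , drop = TRUE] - traj$coords[j, , , drop = TRUE]
  v <- traj$coords[k, , , drop = TRUE] - traj$coords[j, , , drop = TRUE]
  if (is.null(dim(u))) { u <- matrix(u, ncol = 1); v <- matrix(v, ncol = 1) }
  cosang <- colSums(u * v) / sqrt(colSums(u^2) * colSums(v^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Pearson correlation with validation
#'
#' @param x,y numeric series of equal length >= 3 with nonzero variance.
#' @return Pearson r in [-1, 1].
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("series lengths differ")
  if (length(x) < 3L) stop("need at least 3 points")
  if (var(x) == 0 || var(y) == 0)
    stop("undefined correlation: zero variance")
  cor(x, y)
}
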