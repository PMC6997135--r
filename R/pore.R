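# HOLE-style pore radius profiling: at stations along a channel axis, the
# largest probe sphere not overlapping any atom is found by maximizing the
# clearance over the perpendicular plane (coarse grid + deterministic
# pattern search). Classification follows the water-passage convention:
# below 1.15 A (one water radius) the pore is blocked, 1.15-2.30 A passes
# single-file water, above 2.30 A two or more waters abreast.

PORE_CLASS_SINGLE <- 1.15
PORE_CLASS_BULK <- 2.30

vdw_radii_for <- function(topology, table = NULL) {
  if (!is.null(table)) {
    key_t <- paste(topology$chain, topology$resid, topology$name, sep = "|")
    key_p <- paste(table$chain, table$residue_index, table$atom_name,
                   sep = "|")
    idx <- match(key_t, key_p)
    if (!anyNA(idx)) return(table$vdw_radius[idx])
  }
  r <- ELEMENT_VDW[topology$element]
  r[is.na(r)] <- 1.7
  as.numeric(r)
}

#' Probe radius at a point
#'
#' The radius of the largest sphere centered at `point` that overlaps no
#' atom: `min_i (|point - x_i| - vdw_i)`. Negative when the point lies
#' inside an atom's van der Waals sphere.
#'
#' @param point length-3 position (A).
#' @param atoms `n x 3` coordinates.
#' @param radii per-atom vdW radii (A).
#' @return radius in A (may be negative).
#' @export
probe_radius_at <- function(point, atoms, radii) {
  if (!nrow(atoms)) stop("domain error: empty atom set")
  min(sqrt(colSums((t(atoms) - point)^2)) - radii)
}

#' Optimize the probe center within a plane
#'
#' Maximizes the probe radius over the plane perpendicular to the axis at
#' one station, within `search_radius` of the axis point: a 0.5 A coarse
#' grid seeds a compass pattern search refined to 0.05 A. Fully
#' deterministic (grid ordering breaks ties).
#'
#' @param station axial position (A along the axis from its start).
#' @param origin axis start point (length 3).
#' @param axis unit axis direction (length 3).
#' @param atoms,radii atom coordinates and vdW radii.
#' @param search_radius in-plane search extent (A, > 0).
#' @param seed optional in-plane seed `(a, b)`; when given the coarse grid
#'   is skipped and the pattern search starts from the better of the seed
#'   and the axis point (used for channel tracking, so the optimum cannot
#'   leak out of a constricted pore into open space).
#' @return list: `center` (length 3), `radius` (A), `ab` (in-plane
#'   coordinates of the optimum).
#' @export
optimize_center <- function(station, origin, axis, atoms, radii,
                            search_radius = 5, seed = NULL) {
  if (search_radius <= 0) stop("search_radius must be > 0")
  axis <- axis / sqrt(sum(axis^2))
  # in-plane orthonormal basis, deterministic choice
  ref <- if (abs(axis[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * axis) * axis
  u <- u / sqrt(sum(u^2))
  v <- c(axis[2] * u[3] - axis[3] * u[2],
         axis[3] * u[1] - axis[1] * u[3],
         axis[1] * u[2] - axis[2] * u[1])
  p0 <- origin + station * axis
  at_plane <- function(a, b) p0 + a * u + b * v
  eval_ab <- function(a, b) probe_radius_at(at_plane(a, b), atoms, radii)
  if (is.null(seed)) {
    g <- seq(-search_radius, search_radius, by = 0.5)
    grid <- expand.grid(a = g, b = g)
    grid <- grid[grid$a^2 + grid$b^2 <= search_radius^2 + 1e-12, ]
    vals <- mapply(eval_ab, grid$a, grid$b)
    best <- which.max(vals)
    a <- grid$a[best]; b <- grid$b[best]; fbest <- vals[best]
  } else {
    f_seed <- eval_ab(seed[1], seed[2])
    f_axis <- eval_ab(0, 0)
    if (f_axis > f_seed) { a <- 0; b <- 0; fbest <- f_axis }
    else { a <- seed[1]; b <- seed[2]; fbest <- f_seed }
  }
  step <- if (is.null(seed)) 0.25 else 0.5
  while (step >= 0.05 / 2) {
    moved <- FALSE
    for (d in list(c(step, 0), c(-step, 0), c(0, step), c(0, -step))) {
      na <- a + d[1]; nb <- b + d[2]
      if (na^2 + nb^2 > search_radius^2) next
      f <- eval_ab(na, nb)
      if (f > fbest + 1e-12) {
        a <- na; b <- nb; fbest <- f; moved <- TRUE
        break
      }
    }
    if (!moved) step <- step / 2
  }
  list(center = at_plane(a, b), radius = fbest, ab = c(a, b))
}

classify_radius <- function(r) {
  ifelse(r < PORE_CLASS_SINGLE, "blocked",
         ifelse(r <= PORE_CLASS_BULK, "single-file", "bulk"))
}

#' Pore radius profile along a channel axis
#'
#' Samples stations every `step` A between the axis endpoints, optimizes
#' the probe center in each perpendicular plane, classifies each station
#' by water passage and reports the residue of the atom realizing the
#' limiting contact.
#'
#' @param structure a `trajectory` (first frame used unless
#'   `frame_index` given).
#' @param axis either a 2-row matrix of endpoints, or `"auto"` to use the
#'   principal axis of `lining_sel`.
#' @param step station spacing in A (default 0.25).
#' @param search_radius in-plane search extent (default 5 A).
#' @param radii per-atom vdW radii; default from the topology's elements.
#' @param topology_table optional `topology_table` supplying vdW radii.
#' @param lining_sel atom indices of the channel lining (for
#'   `axis = "auto"`).
#' @param frame_index which frame to profile.
#' @return data.frame of class `pore_profile`: `z`, `center_x/y/z`,
#'   `radius`, `class`, `nearest_residue`.
#' @export
pore_profile <- function(structure, axis, step = 0.25, search_radius = 5,
                         radii = NULL, topology_table = NULL,
                         lining_sel = NULL, frame_index = 1L) {
  xyz <- frame_coords(structure, frame_index)
  topo <- structure$topology
  if (is.null(radii)) radii <- vdw_radii_for(topo, topology_table)
  if (identical(axis, "auto")) {
    if (is.null(lining_sel)) stop("axis='auto' needs lining_sel")
    X <- xyz[lining_sel, , drop = FALSE]
    ctr <- colMeans(X)
    ev <- eigen(cov(X), symmetric = TRUE)$vectors[, 1]
    span <- range((X %*% ev) - sum(ctr * ev))
    axis <- rbind(ctr + span[1] * ev, ctr + span[2] * ev)
  }
  p1 <- as.numeric(axis[1, ]); p2 <- as.numeric(axis[2, ])
  len <- sqrt(sum((p2 - p1)^2))
  if (len < 1e-9) stop("axis error: endpoints must be distinct")
  dirv <- (p2 - p1) / len
  stations <- seq(0, len, by = step)
  seed <- NULL  # previous station's center: tracks the channel
  rows <- vector("list", length(stations))
  for (si in seq_along(stations)) {
    s <- stations[si]
    opt <- optimize_center(s, p1, dirv, xyz, radii, search_radius,
                           seed = seed)
    seed <- opt$ab
    dists <- sqrt(colSums((t(xyz) - opt$center)^2)) - radii
    nearest <- which.min(dists)
    rows[[si]] <- data.frame(
      z = s, center_x = opt$center[1], center_y = opt$center[2],
      center_z = opt$center[3], radius = opt$radius,
      class = classify_radius(opt$radius),
      nearest_residue = topo$resid[nearest],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("pore_profile", "data.frame")
  out
}
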