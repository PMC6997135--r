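# Geometric hydrogen-bond detection and radial distribution functions.
#
# Criterion: hydrogen...acceptor distance < 3.5 A and acceptor-H-donor
# angle (vertex at the hydrogen) > 135 degrees; both thresholds
# configurable. Donor-H covalency is assigned by a 1.2 A proximity rule.

#' Enumerate donor-H/acceptor candidate triples
#'
#' Donors are N/O/S heavy atoms with a hydrogen within 1.2 A; acceptors
#' are N/O atoms (protein or ligand). All donor-H x acceptor combinations
#' whose H...A distance in the given frame is within `prefilter` are
#' returned.
#'
#' @param structure a `trajectory` (the first frame is used for the
#'   prefilter geometry) containing explicit hydrogens.
#' @param prefilter H...A enumeration cutoff in A (default 5).
#' @return data.frame with `donor`, `hydrogen`, `acceptor` atom indices and
#'   a `label` like "G380-O/R231-HH22" (acceptor residue-atom / donor
#'   residue-atom).
#' @export
find_hbond_candidates <- function(structure, prefilter = 5) {
  topo <- structure$topology
  xyz <- frame_coords(structure, 1L)
  hyd <- which(topo$element == "H")
  if (!length(hyd))
    stop("no hydrogens in structure; hydrogen-bond detection needs explicit-H input")
  don <- which(topo$element %in% c("N", "O", "S"))
  acc <- which(topo$element %in% c("N", "O"))
  out <- list()
  one <- substr
  res_tag <- function(i)
    paste0(one(topo$resname[i], 1, 1), topo$resid[i], "-", topo$name[i])
  for (h in hyd) {
    dh <- sqrt(colSums((t(xyz[don, , drop = FALSE]) - xyz[h, ])^2))
    if (!any(dh <= 1.2)) next
    d <- don[which.min(dh)]
    ha <- sqrt(colSums((t(xyz[acc, , drop = FALSE]) - xyz[h, ])^2))
    ok <- acc[ha <= prefilter & acc != d]
    for (a in ok)
      out[[length(out) + 1L]] <- data.frame(
        donor = d, hydrogen = h, acceptor = a,
        label = paste0(res_tag(a), "/", res_tag(h)),
        stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), label = character(0)))
  do.call(rbind, out)
}

#' Geometric hydrogen-bond criterion
#'
#' @param d_ha hydrogen...acceptor distance in A (> 0).
#' @param angle_at_h acceptor-H-donor angle in degrees, vertex at the
#'   hydrogen.
#' @param d_max distance threshold (default 3.5 A, strict `<`).
#' @param angle_min angle threshold (default 135 deg, strict `>`).
#' @return logical.
#' @export
hbond_check <- function(d_ha, angle_at_h, d_max = 3.5, angle_min = 135) {
  stopifnot(all(d_ha > 0), all(angle_at_h >= 0), all(angle_at_h <= 180))
  d_ha < d_max & angle_at_h > angle_min
}

#' Hydrogen-bond occupancy over a trajectory
#'
#' Applies the geometric criterion per frame; mean distance and angle are
#' computed over the satisfying frames only.
#'
#' @param traj a `trajectory`.
#' @param triple vector or list with `donor`, `hydrogen`, `acceptor` atom
#'   indices (as from [find_hbond_candidates()]).
#' @param d_max,angle_min criterion thresholds.
#' @return list of class `hbond_stats`: `frequency`, `mean_distance`,
#'   `mean_angle` (NA when never bonded), `series` (data.frame
#'   frame/distance/angle/bonded).
#' @export
hbond_occupancy <- function(traj, triple, d_max = 3.5, angle_min = 135) {
  if (n_frames(traj) < 1L) stop("insufficient frames")
  d <- triple[["donor"]]; h <- triple[["hydrogen"]]; a <- triple[["acceptor"]]
  dist <- distance_series(traj, h, a)
  ang <- angle_series(traj, a, h, d)
  bonded <- hbond_check(dist, ang, d_max, angle_min)
  structure(list(
    frequency = mean(bonded),
    mean_distance = if (any(bonded)) mean(dist[bonded]) else NA_real_,
    mean_angle = if (any(bonded)) mean(ang[bonded]) else NA_real_,
    series = data.frame(frame = seq_along(dist), distance = dist,
                        angle = ang, bonded = bonded)),
    class = "hbond_stats")
}

#' Classify a side-chain geometry series as folded or stretched
#'
#' A frame is "stretched" when both the probe angle and the probe distance
#' are at or above their split values, otherwise "folded". The split
#' values carry no defaults: they are a modelling choice the caller must
#' state.
#'
#' @param angle per-frame angle series (degrees).
#' @param distance per-frame distance series (A).
#' @param angle_split,distance_split classification thresholds.
#' @return list: `state` (factor per frame), `freq_folded`,
#'   `freq_stretched`.
#' @export
classify_sidechain_state <- function(angle, distance, angle_split,
                                     distance_split) {
  if (missing(angle_split) || missing(distance_split))
    stop("angle_split and distance_split must be supplied")
  stretched <- angle >= angle_split & distance >= distance_split
  state <- factor(ifelse(stretched, "stretched", "folded"),
                  levels = c("folded", "stretched"))
  list(state = state,
       freq_folded = mean(state == "folded"),
       freq_stretched = mean(state == "stretched"))
}

#' Radial distribution function
#'
#' Pair-distance histogram between two atom groups, normalized by the
#' spherical shell volume and the mean pair density. With `box` supplied
#' the minimum-image convention is applied (periodic cube) and the volume
#' is `box^3`; otherwise distances are plain Euclidean and `volume` must
#' be given, which under-counts long-range pairs near an open boundary.
#'
#' @param traj a `trajectory`.
#' @param group_a,group_b atom index sets (disjoint, or identical for a
#'   self-RDF).
#' @param bin_width histogram bin width in A.
#' @param r_max maximum distance in A (> bin_width).
#' @param volume normalization volume in A^3 (ignored when `box` given).
#' @param box optional cubic box edge for periodic minimum-image distances.
#' @return data.frame: `r` (bin centers), `g` (pair correlation),
#'   `count` (raw pair counts).
#' @export
rdf <- function(traj, group_a, group_b, bin_width, r_max, volume = NULL,
                box = NULL) {
  if (!length(group_a) || !length(group_b)) stop("empty group")
  if (!(r_max > bin_width && bin_width > 0)) stop("need r_max > bin_width > 0")
  same <- identical(sort(group_a), sort(group_b))
  if (!same && length(intersect(group_a, group_b)))
    stop("groups must be disjoint or identical")
  if (is.null(box)) {
    if (is.null(volume) || volume <= 0)
      stop("domain error: positive normalization volume required")
  } else volume <- box^3
  edges <- seq(0, r_max, by = bin_width)
  if (tail(edges, 1) < r_max) edges <- c(edges, tail(edges, 1) + bin_width)
  counts <- numeric(length(edges) - 1L)
  nf <- n_frames(traj)
  for (f in seq_len(nf)) {
    xyz <- traj$coords[, , f, drop = TRUE]
    if (same) {
      pa <- xyz[group_a, , drop = FALSE]
      dvec <- if (is.null(box)) as.numeric(dist(pa)) else {
        pr <- t(combn(length(group_a), 2L))
        dd <- pa[pr[, 1], , drop = FALSE] - pa[pr[, 2], , drop = FALSE]
        dd <- dd - box * round(dd / box)
        sqrt(rowSums(dd^2))
      }
    } else {
      pa <- xyz[group_a, , drop = FALSE]
      pb <- xyz[group_b, , drop = FALSE]
      dd <- pa[rep(seq_len(nrow(pa)), each = nrow(pb)), , drop = FALSE] -
        pb[rep(seq_len(nrow(pb)), nrow(pa)), , drop = FALSE]
      if (!is.null(box)) dd <- dd - box * round(dd / box)
      dvec <- sqrt(rowSums(dd^2))
    }
    h <- graphics::hist(dvec[dvec < max(edges)], breaks = edges,
                        plot = FALSE)
    counts <- counts + h$counts
  }
  centers <- (edges[-1] + edges[-length(edges)]) / 2
  shell <- 4 * pi * centers^2 * bin_width
  n_pairs <- if (same) length(group_a) * (length(group_a) - 1) / 2
  else length(group_a) * length(group_b)
  density <- n_pairs / volume
  g <- counts / (nf * shell * density)
  data.frame(r = centers, g = g, count = counts)
}
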