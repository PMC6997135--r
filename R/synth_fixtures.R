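# Seeded generators with analytic ground truth. All randomness flows through
# an explicit seed; the caller's RNG state is saved and restored.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

backbone_topology <- function(n_res, chain = "A", resname = "ALA") {
  names4 <- c("N", "CA", "C", "O")
  el4 <- c("N", "C", "C", "O")
  data.frame(serial = seq_len(4L * n_res),
             name = rep(names4, n_res),
             element = rep(el4, n_res),
             resname = resname, resid = rep(seq_len(n_res), each = 4L),
             chain = chain, occupancy = 1, bfactor = 0,
             is_heavy = TRUE, stringsAsFactors = FALSE)
}

#' Ideal alpha-helix backbone
#'
#' Builds an N/CA/C/O backbone on an ideal helix: CA trace of radius 2.3 A,
#' rise 1.5 A per residue and 100 degree twist, giving the canonical
#' ~3.8 A CA-CA distance. Deterministic; one frame.
#'
#' @param n_res number of residues (>= 2).
#' @return a single-frame `trajectory` with 4 atoms per residue.
#' @export
make_helix <- function(n_res) {
  if (n_res < 2L) stop("make_helix needs n_res >= 2")
  twist <- 100 * pi / 180
  rise <- 1.5
  place <- function(radius, phase_offset, z_offset) {
    ang <- (seq_len(n_res) - 1L) * twist + phase_offset
    cbind(radius * cos(ang), radius * sin(ang),
          (seq_len(n_res) - 1L) * rise + z_offset)
  }
  ca <- place(2.3, 0, 0)
  nn <- place(1.6, -28 * pi / 180, -0.9)
  cc <- place(1.7, 28 * pi / 180, 0.9)
  oo <- place(2.9, 36 * pi / 180, 1.1)
  xyz <- matrix(0, nrow = 4L * n_res, ncol = 3L)
  xyz[seq(1, 4 * n_res, 4), ] <- nn
  xyz[seq(2, 4 * n_res, 4), ] <- ca
  xyz[seq(3, 4 * n_res, 4), ] <- cc
  xyz[seq(4, 4 * n_res, 4), ] <- oo
  trajectory(backbone_topology(n_res), xyz)
}

#' Two-state conformational ensemble with known populations
#'
#' Emulates a protein switching between two basins: the terminal segment of
#' an ideal helix is rigidly displaced along +x by 0 (state 1) or
#' `displacement` (state 2), the state drawn per frame from the stated
#' populations, plus isotropic Gaussian coordinate noise on every atom. The
#' per-frame state labels are returned as ground truth.
#'
#' @param populations length-2 fractions summing to 1 (state 1, state 2).
#' @param n_frames number of frames.
#' @param displacement rigid displacement of the moving segment in A (> 0).
#' @param noise_sigma isotropic Gaussian noise s.d. in A (>= 0).
#' @param seed RNG seed.
#' @param n_res helix length (default 30).
#' @param n_moving number of terminal residues displaced (default 6).
#' @return list with `traj` (a `trajectory`), `states` (per-frame 1/2),
#'   `moving_atoms` (indices of displaced atoms).
#' @export
make_two_state_ensemble <- function(populations, n_frames, displacement,
                                    noise_sigma, seed, n_res = 30L,
                                    n_moving = 6L) {
  if (length(populations) != 2L)
    stop("spec error: populations must have length 2")
  if (abs(sum(populations) - 1) > 1e-9)
    stop("spec error: populations must sum to 1")
  if (displacement <= 0) stop("spec error: displacement must be > 0")
  if (noise_sigma < 0) stop("spec error: noise_sigma must be >= 0")
  if (n_frames < 1L) stop("spec error: n_frames >= 1")
  base <- make_helix(n_res)
  xyz0 <- frame_coords(base, 1L)
  moving <- which(base$topology$resid > n_res - n_moving)
  na <- nrow(xyz0)
  with_seed(seed, {
    states <- 1L + (runif(n_frames) < populations[2])
    coords <- array(rep(as.vector(xyz0), n_frames),
                    dim = c(na, 3L, n_frames))
    disp <- ifelse(states == 2L, displacement, 0)
    coords[moving, 1, ] <- coords[moving, 1, ] +
      rep(disp, each = length(moving))
    if (noise_sigma > 0)
      coords <- coords + rnorm(length(coords), sd = noise_sigma)
    list(traj = trajectory(base$topology, coords,
                           times = seq_len(n_frames) * 1e-3),
         states = states, moving_atoms = moving)
  })
}

#' Stacked-ring pore fixture with analytic radius profile
#'
#' Rings of pseudo-atoms centered on the z-axis, one ring per residue, with
#' the analytic maximal probe radius at each ring plane equal to
#' `ring_radius - atom_vdw`.
#'
#' @param ring_radii ring radii in A (each must exceed `atom_vdw`).
#' @param atoms_per_ring atoms per ring.
#' @param atom_vdw van der Waals radius assigned to every pseudo-atom (A).
#' @param spacing axial distance between consecutive rings (A).
#' @return list with `traj` (one frame), `z` (ring plane positions),
#'   `analytic_radius` (per-ring ground truth), `vdw` (per-atom radii).
#' @export
make_pore_cylinder <- function(ring_radii, atoms_per_ring = 12L,
                               atom_vdw = 1.5, spacing = 4) {
  if (any(ring_radii <= atom_vdw))
    stop("spec error: every ring radius must exceed atom_vdw")
  n_ring <- length(ring_radii)
  ang <- 2 * pi * (seq_len(atoms_per_ring) - 1L) / atoms_per_ring
  xyz <- do.call(rbind, lapply(seq_len(n_ring), function(k)
    cbind(ring_radii[k] * cos(ang), ring_radii[k] * sin(ang),
          (k - 1L) * spacing)))
  na <- nrow(xyz)
  topo <- data.frame(serial = seq_len(na), name = "C", element = "C",
                     resname = "RNG",
                     resid = rep(seq_len(n_ring), each = atoms_per_ring),
                     chain = "A", occupancy = 1, bfactor = 0,
                     is_heavy = TRUE, stringsAsFactors = FALSE)
  topo$name <- paste0("C", rep(seq_len(atoms_per_ring), n_ring))
  list(traj = trajectory(topo, xyz),
       z = (seq_len(n_ring) - 1L) * spacing,
       analytic_radius = ring_radii - atom_vdw,
       vdw = rep(atom_vdw, na))
}

#' Donor-H-acceptor trajectory with prescribed bond occupancy
#'
#' One N-H donor and one carbonyl O acceptor. In "on" frames the triple has
#' bonded geometry (H...A 2.9 A, acceptor-H-donor angle 165 deg); in "off"
#' frames broken geometry (4.5 A, 120 deg). Frame states are Bernoulli with
#' probability `p_on`.
#'
#' @param p_on per-frame probability of the bonded geometry, in [0, 1].
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @return list with `traj`, `states` (logical on/off),
#'   `triple` (donor, hydrogen, acceptor indices).
#' @export
make_hbond_trajectory <- function(p_on, n_frames, seed) {
  if (p_on < 0 || p_on > 1) stop("p_on must be in [0, 1]")
  topo <- data.frame(serial = 1:3, name = c("N", "H", "O"),
                     element = c("N", "H", "O"),
                     resname = c("ALA", "ALA", "GLY"),
                     resid = c(1L, 1L, 2L), chain = "A",
                     occupancy = 1, bfactor = 0,
                     is_heavy = c(TRUE, FALSE, TRUE),
                     stringsAsFactors = FALSE)
  geom <- function(d_ha, angle_deg) {
    # H at origin; donor at distance 1.0 along +x; acceptor at angle
    # (vertex H) from the H->D direction.
    a <- angle_deg * pi / 180
    rbind(c(1, 0, 0), c(0, 0, 0), d_ha * c(cos(a), sin(a), 0))
  }
  on_xyz <- geom(2.9, 165)
  off_xyz <- geom(4.5, 120)
  with_seed(seed, {
    states <- runif(n_frames) < p_on
    coords <- array(0, dim = c(3L, 3L, n_frames))
    for (f in seq_len(n_frames))
      coords[, , f] <- if (states[f]) on_xyz else off_xyz
    list(traj = trajectory(topo, coords, times = seq_len(n_frames) * 1e-3),
         states = states, triple = c(donor = 1L, hydrogen = 2L,
                                     acceptor = 3L))
  })
}

#' Uniform ideal-gas frame for RDF baselines
#'
#' @param n number of particles (>= 2).
#' @param box cubic box edge in A (> 0).
#' @param seed RNG seed.
#' @return single-frame `trajectory` of `n` pseudo-atoms uniform in
#'   `[0, box)^3`.
#' @export
make_uniform_gas <- function(n, box, seed) {
  if (n < 2L) stop("make_uniform_gas needs n >= 2")
  if (box <= 0) stop("box must be > 0")
  with_seed(seed, {
    xyz <- matrix(runif(3L * n, 0, box), ncol = 3L)
    topo <- data.frame(serial = seq_len(n), name = "AR", element = "X",
                       resname = "GAS", resid = seq_len(n), chain = "A",
                       occupancy = 1, bfactor = 0, is_heavy = TRUE,
                       stringsAsFactors = FALSE)
    trajectory(topo, xyz)
  })
}

#' Two toy conformations with hand-enumerated contact sets
#'
#' Six single-atom residues laid out on a line with two residues folded
#' back, so the heavy-atom minimum-distance contacts at a 4.5 A cutoff
#' (sequence separation >= 2) can be read off the coordinates:
#' frame A places residue 5 near residues 1-2 and residue 6 near residue 1;
#' frame B places residue 5 near residues 2-3 instead. The documented sets
#' (ground truth, residue-id pairs):
#' A = \{1-5, 2-5, 1-6\}; B = \{2-5, 3-5\}. Common: \{2-5\};
#' A-specific: \{1-5, 1-6\}; B-specific: \{3-5\}.
#'
#' @return list with `frame_a`, `frame_b` (single-frame trajectories) and
#'   `contacts_a`, `contacts_b` (2-column matrices of residue-id pairs).
#' @export
make_contact_pair <- function() {
  topo <- data.frame(serial = 1:6, name = "CA", element = "C",
                     resname = "GLY", resid = 1:6, chain = "A",
                     occupancy = 1, bfactor = 0, is_heavy = TRUE,
                     stringsAsFactors = FALSE)
  # residues 1-4 strung out along x at 6 A so only engineered pairs touch
  base <- rbind(c(0, 0, 0), c(6, 0, 0), c(12, 0, 0), c(18, 0, 0))
  xyz_a <- rbind(base, c(3, 3, 0),   # res5: 4.24 A from res1 and res2
                 c(0, 4, 0))         # res6: 4.0 A from res1
  xyz_b <- rbind(base, c(9, 3, 0),   # res5: 4.24 A from res2 and res3
                 c(0, 40, 0))        # res6: far from everything
  list(frame_a = trajectory(topo, xyz_a),
       frame_b = trajectory(topo, xyz_b),
       contacts_a = rbind(c(1L, 5L), c(2L, 5L), c(1L, 6L)),
       contacts_b = rbind(c(2L, 5L), c(3L, 5L)))
}
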