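# Interaction energies, SASA-based nonpolar solvation, and the
# binding-free-energy ledger dG_bind = dH - TdS with
# dH = dE_vdw + dE_ele + dG_polar_solv + dG_nonpolar_solv.
#
# Polar (PB/GB) solvation and the normal-mode entropy term are inputs
# ingested from tables, not computed here: the ledger and the vacuum
# molecular-mechanics terms are what this module owns.

COULOMB_KJ <- 1389.35458  # kJ/mol * A / e^2

#' Coulomb and Lennard-Jones cross-interaction energy
#'
#' Sums over all receptor x ligand atom pairs:
#' electrostatics `f q_i q_j / (eps r)` with `f = 1389.35458`
#' kJ mol^-1 A e^-2, and 12-6 Lennard-Jones with Lorentz-Berthelot
#' combination (arithmetic sigma, geometric epsilon). No cutoff by
#' default.
#'
#' @param receptor_sel,ligand_sel disjoint atom index sets.
#' @param frame `n x 3` coordinates or a single-frame `trajectory`.
#' @param traj the `trajectory` whose topology keys the parameter table
#'   (needed when `frame` is a bare matrix).
#' @param topology_table a `topology_table` parameterizing every selected
#'   atom.
#' @param dielectric relative dielectric (default 1).
#' @param cutoff optional pair-distance cutoff in A.
#' @return list: `ele`, `vdw` (kJ/mol).
#' @export
coulomb_lj_interaction <- function(receptor_sel, ligand_sel, frame,
                                   topology_table, traj = NULL,
                                   dielectric = 1, cutoff = NULL) {
  if (inherits(frame, "trajectory")) {
    traj <- frame
    frame <- frame_coords(frame, 1L)
  }
  if (is.null(traj)) stop("a trajectory (for topology keys) is required")
  if (length(intersect(receptor_sel, ligand_sel)))
    stop("receptor and ligand selections overlap")
  pr <- match_parameters(traj, topology_table, receptor_sel)
  pl <- match_parameters(traj, topology_table, ligand_sel)
  A <- frame[receptor_sel, , drop = FALSE]
  B <- frame[ligand_sel, , drop = FALSE]
  na <- nrow(A); nb <- nrow(B)
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * A %*% t(B)
  d <- sqrt(pmax(d2, 0))
  if (any(d < 0.1)) stop("clash error: pair distance below 0.1 A")
  mask <- if (is.null(cutoff)) TRUE else d <= cutoff
  qq <- outer(pr$charge, pl$charge)
  ele <- sum((COULOMB_KJ * qq / (dielectric * d))[mask])
  sig <- outer(pr$lj_sigma, pl$lj_sigma, `+`) / 2
  eps <- sqrt(outer(pr$lj_epsilon, pl$lj_epsilon))
  sr6 <- (sig / d)^6
  vdw <- sum((4 * eps * (sr6^2 - sr6))[mask])
  list(ele = ele, vdw = vdw)
}

fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1L)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(1 - z^2, 0))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Per-atom SASA by point sampling on the solvent-expanded sphere using a
#' deterministic Fibonacci lattice: a point is exposed when it lies
#' outside every other atom's expanded sphere.
#'
#' @param frame `n x 3` coordinates or single-frame `trajectory`.
#' @param sel atom indices (default all).
#' @param radii per-atom vdW radii in A (for the whole structure).
#' @param probe probe radius in A (default 1.4, water).
#' @param n_points lattice points per atom (>= 50; default 960).
#' @return per-atom SASA in A^2 (ordered as `sel`).
#' @export
shrake_rupley_sasa <- function(frame, sel = NULL, radii, probe = 1.4,
                               n_points = 960L) {
  if (inherits(frame, "trajectory")) frame <- frame_coords(frame, 1L)
  if (n_points < 50L) stop("resolution error: n_points must be >= 50")
  if (any(radii <= 0)) stop("radii must be positive")
  if (is.null(sel)) sel <- seq_len(nrow(frame))
  pts <- fibonacci_sphere(n_points)
  exp_r <- radii + probe
  vapply(sel, function(i) {
    ri <- exp_r[i]
    surf <- sweep(pts * ri, 2, frame[i, ], `+`)
    # neighbors that can occlude
    d2 <- rowSums(sweep(frame, 2, frame[i, ])^2)
    nb <- which(d2 < (ri + exp_r)^2 & seq_along(d2) != i)
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      dj2 <- rowSums(sweep(surf, 2, frame[j, ])^2)
      exposed <- exposed & dj2 > exp_r[j]^2
      if (!any(exposed)) break
    }
    4 * pi * ri^2 * mean(exposed)
  }, numeric(1))
}

#' SASA-proportional nonpolar solvation energy
#'
#' `gamma * SASA + beta`; for a complex the binding contribution is
#' `value(complex) - value(receptor) - value(ligand)`.
#'
#' @param sasa_total total SASA in A^2 (>= 0).
#' @param gamma surface tension coefficient, kJ/mol/A^2 (default 0.0227,
#'   the common 0.00542 kcal value converted).
#' @param beta offset, kJ/mol (default 3.849, i.e. 0.92 kcal).
#' @return energy in kJ/mol.
#' @export
nonpolar_solvation <- function(sasa_total, gamma = 0.0227, beta = 3.849) {
  if (any(sasa_total < 0)) stop("sasa must be >= 0")
  gamma * sasa_total + beta
}

#' Binding free-energy ledger
#'
#' `dH = vdw + ele + polar_solv + nonpolar_solv`;
#' `dG_bind = dH - entropy_term` (the entropy term is `T dS`). Also
#' reports the polar/nonpolar driving-force split: polar
#' `= ele + polar_solv`, nonpolar `= vdw + nonpolar_solv`.
#'
#' @param vdw,ele,polar_solv,nonpolar_solv energy components in kJ/mol.
#' @param entropy_term `T dS` in kJ/mol.
#' @param T temperature in K.
#' @return list of class `energy_components` with the components,
#'   `enthalpy`, `binding`, `polar_total`, `nonpolar_total`, `temperature`.
#' @export
binding_free_energy <- function(vdw, ele, polar_solv, nonpolar_solv,
                                entropy_term, T = 300) {
  vals <- c(vdw, ele, polar_solv, nonpolar_solv, entropy_term, T)
  if (!all(is.finite(vals))) stop("all inputs must be finite")
  enthalpy <- vdw + ele + polar_solv + nonpolar_solv
  out <- list(vdw = vdw, ele = ele, polar_solv = polar_solv,
              nonpolar_solv = nonpolar_solv, enthalpy = enthalpy,
              entropy_term = entropy_term,
              binding = enthalpy - entropy_term,
              polar_total = ele + polar_solv,
              nonpolar_total = vdw + nonpolar_solv,
              temperature = T)
  stopifnot(abs(out$enthalpy - (vdw + ele + polar_solv + nonpolar_solv)) < 1e-6,
            abs(out$binding - (enthalpy - entropy_term)) < 1e-6)
  class(out) <- "energy_components"
  out
}

#' @export
print.energy_components <- function(x, ...) {
  cat(sprintf("dH = %.2f (vdw %.2f + ele %.2f + polar %.2f + nonpolar %.2f) kJ/mol\n",
              x$enthalpy, x$vdw, x$ele, x$polar_solv, x$nonpolar_solv))
  cat(sprintf("TdS = %.2f; dG_bind = %.2f kJ/mol\n", x$entropy_term,
              x$binding))
  invisible(x)
}

default_frame_schedule <- function(nf, discard_frac = 0.1, k = NULL) {
  start <- floor(discard_frac * nf) + 1L
  if (is.null(k)) k <- max(1L, (nf - start + 1L) %/% 180L)
  seq.int(start, nf, by = k)
}

#' Per-residue decomposition of the receptor-ligand interaction
#'
#' For each receptor residue and each sampled frame, the vacuum
#' Coulomb/LJ energy of that residue's atoms against the ligand; the
#' GB polar and surface terms are joined from optional per-residue tables
#' (zero and flagged when absent). Residues are ranked by mean total
#' ascending (most favorable first). The default frame schedule discards
#' the first 10% of the run and strides to about 180 frames, mirroring
#' end-state sampling practice.
#'
#' @param receptor_sel,ligand_sel atom index sets.
#' @param traj a `trajectory`.
#' @param topology_table a `topology_table`.
#' @param solvation_table optional data.frame `residue,e_gb,e_gbsur`
#'   (means) or `residue,frame,e_gb,e_gbsur` (per frame).
#' @param frames frame indices to sample (default schedule above).
#' @param dielectric relative dielectric.
#' @return data.frame of class `residue_decomposition`: per residue
#'   `e_vdw`, `e_ele`, `e_gb`, `e_gbsur` (means with `_sd` columns),
#'   `e_tot`, `e_tot_sd`, `rank`; attribute `solvation_supplied`.
#' @export
per_residue_decomposition <- function(receptor_sel, ligand_sel, traj,
                                      topology_table,
                                      solvation_table = NULL,
                                      frames = NULL, dielectric = 1) {
  if (is.null(frames)) frames <- default_frame_schedule(n_frames(traj))
  topo <- traj$topology
  res_key <- paste(topo$chain[receptor_sel], topo$resid[receptor_sel],
                   sep = "|")
  groups <- split(receptor_sel, factor(res_key, levels = unique(res_key)))
  resids <- topo$resid[vapply(groups, `[`, integer(1), 1L)]
  nr <- length(groups)
  e_vdw <- matrix(0, nr, length(frames))
  e_ele <- matrix(0, nr, length(frames))
  for (fi in seq_along(frames)) {
    xyz <- frame_coords(traj, frames[fi])
    for (g in seq_len(nr)) {
      e <- coulomb_lj_interaction(groups[[g]], ligand_sel, xyz,
                                  topology_table, traj = traj,
                                  dielectric = dielectric)
      e_vdw[g, fi] <- e$vdw
      e_ele[g, fi] <- e$ele
    }
  }
  row_sd <- function(m) apply(m, 1, sd)
  out <- data.frame(residue = resids,
                    e_vdw = rowMeans(e_vdw), e_vdw_sd = row_sd(e_vdw),
                    e_ele = rowMeans(e_ele), e_ele_sd = row_sd(e_ele),
                    e_gb = 0, e_gb_sd = 0, e_gbsur = 0, e_gbsur_sd = 0)
  supplied <- FALSE
  if (!is.null(solvation_table)) {
    idx <- match(out$residue, solvation_table$residue)
    if (anyNA(idx))
      stop("join error: solvation table missing residue ",
           out$residue[which(is.na(idx))[1]])
    out$e_gb <- solvation_table$e_gb[idx]
    out$e_gbsur <- solvation_table$e_gbsur[idx]
    supplied <- TRUE
  }
  out$e_tot <- out$e_vdw + out$e_ele + out$e_gb + out$e_gbsur
  out$e_tot_sd <- sqrt(out$e_vdw_sd^2 + out$e_ele_sd^2)
  out <- out[order(out$e_tot), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "solvation_supplied") <- supplied
  class(out) <- c("residue_decomposition", "data.frame")
  out
}

#' Load a per-frame energy-component table
#'
#' CSV with header `frame,vdw,ele,polar_solv,nonpolar_solv,entropy_term`
#' (an `enthalpy` column, if present, is validated; otherwise it is
#' reconstructed from the components). Returns the per-frame series and
#' the ledger applied to the means.
#'
#' @param file path or content lines (`text = TRUE`).
#' @param text treat `file` as content.
#' @param T temperature in K for the ledger.
#' @return list: `series` (data.frame), `mean` (`energy_components` of the
#'   column means), `sd` (named numeric).
#' @export
load_component_table <- function(file, text = FALSE, T = 300) {
  lines <- if (text) {
    if (length(file) == 1L) strsplit(file, "\n", fixed = TRUE)[[1]] else file
  } else readLines(file, warn = FALSE)
  con <- textConnection(lines)
  on.exit(close(con))
  df <- utils::read.csv(con, stringsAsFactors = FALSE)
  need <- c("frame", "vdw", "ele", "polar_solv", "nonpolar_solv",
            "entropy_term")
  missing_col <- setdiff(need, names(df))
  if (length(missing_col))
    stop("schema error: missing column(s) ", paste(missing_col, collapse = ", "))
  for (cn in setdiff(names(df), character(0))) {
    if (!is.numeric(df[[cn]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[cn]]))))[1]
      stop(sprintf("parse error at row %d, column %s", bad, cn))
    }
  }
  df$enthalpy <- df$vdw + df$ele + df$polar_solv + df$nonpolar_solv
  df$binding <- df$enthalpy - df$entropy_term
  mu <- colMeans(df[setdiff(names(df), "frame")])
  sds <- vapply(df[setdiff(names(df), "frame")], sd, numeric(1))
  list(series = df,
       mean = binding_free_energy(mu[["vdw"]], mu[["ele"]],
                                  mu[["polar_solv"]],
                                  mu[["nonpolar_solv"]],
                                  mu[["entropy_term"]], T = T),
       sd = sds)
}
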