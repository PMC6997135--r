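param_table_for <- function(traj, charge = 0, sigma = 3.4, eps = 0.36,
                            vdw = 1.7) {
  topo <- traj$topology
  tab <- data.frame(chain = topo$chain, residue_index = topo$resid,
                    atom_name = topo$name,
                    charge = rep_len(charge, nrow(topo)),
                    lj_sigma = rep_len(sigma, nrow(topo)),
                    lj_epsilon = rep_len(eps, nrow(topo)),
                    vdw_radius = rep_len(vdw, nrow(topo)),
                    stringsAsFactors = FALSE)
  class(tab) <- c("topology_table", "data.frame")
  tab
}

two_particle_system <- function(d, q1, q2) {
  topo <- data.frame(serial = 1:2, name = c("Q1", "Q2"), element = "C",
                     resname = c("REC", "LIG"), resid = 1:2, chain = "A",
                     occupancy = 1, bfactor = 0, is_heavy = TRUE,
                     stringsAsFactors = FALSE)
  tr <- trajectory(topo, rbind(c(0, 0, 0), c(d, 0, 0)))
  tab <- param_table_for(tr)
  tab$charge <- c(q1, q2)
  list(traj = tr, tab = tab)
}

test_that("Coulomb energy matches the closed form and the double-loop oracle", {
  sys <- two_particle_system(3, 1, -1)
  e <- coulomb_lj_interaction(1L, 2L, sys$traj, sys$tab)
  expect_equal(e$ele, -1389.35458 / 3, tolerance = 1e-9)
  # zero charges: zero electrostatics
  sys0 <- two_particle_system(3, 0, 0)
  expect_equal(coulomb_lj_interaction(1L, 2L, sys0$traj, sys0$tab)$ele, 0)
  # random 10-atom sets vs naive double loop
  set.seed(42)
  topo <- data.frame(serial = 1:10, name = paste0("X", 1:10), element = "C",
                     resname = rep(c("REC", "LIG"), each = 5),
                     resid = rep(1:2, each = 5), chain = "A", occupancy = 1,
                     bfactor = 0, is_heavy = TRUE, stringsAsFactors = FALSE)
  xyz <- rbind(matrix(rnorm(15, sd = 2), ncol = 3),
               matrix(rnorm(15, sd = 2) + 8, ncol = 3))
  tr <- trajectory(topo, xyz)
  tab <- param_table_for(tr)
  tab$charge <- round(runif(10, -1, 1), 3)
  tab$lj_sigma <- round(runif(10, 3, 3.8), 3)
  tab$lj_epsilon <- round(runif(10, 0.1, 0.9), 3)
  mine <- coulomb_lj_interaction(1:5, 6:10, tr, tab)
  ora <- oracle_coulomb_lj(xyz[1:5, ], xyz[6:10, ], tab$charge[1:5],
                           tab$charge[6:10], tab$lj_sigma[1:5],
                           tab$lj_sigma[6:10], tab$lj_epsilon[1:5],
                           tab$lj_epsilon[6:10])
  expect_equal(mine$ele, ora$ele, tolerance = 1e-9)
  expect_equal(mine$vdw, ora$vdw, tolerance = 1e-9)
  # clash and missing-parameter errors
  clash <- two_particle_system(0.05, 1, 1)
  expect_error(coulomb_lj_interaction(1L, 2L, clash$traj, clash$tab),
               "clash")
  short <- sys$tab[1, , drop = FALSE]
  expect_error(coulomb_lj_interaction(1L, 2L, sys$traj, short),
               "missing parameter")
  expect_error(coulomb_lj_interaction(1L, 1L, sys$traj, sys$tab),
               "overlap")
})

test_that("Shrake-Rupley SASA matches sphere closed forms", {
  one <- matrix(0, 1, 3)
  s <- shrake_rupley_sasa(one, radii = 1.7, probe = 1.4, n_points = 960)
  expect_lt(abs(s - 4 * pi * 3.1^2) / (4 * pi * 3.1^2), 0.005)
  # two distant atoms: additive
  two <- rbind(c(0, 0, 0), c(100, 0, 0))
  s2 <- shrake_rupley_sasa(two, radii = c(1.7, 1.5), probe = 1.4)
  expect_equal(s2[1], 4 * pi * 3.1^2, tolerance = 0.05 * 4 * pi * 3.1^2)
  expect_equal(sum(s2),
               4 * pi * 3.1^2 + 4 * pi * 2.9^2, tolerance = 1)
  # atom fully enclosed in a larger sphere: zero exposure
  nested <- rbind(c(0, 0, 0), c(0, 0, 0.1))
  s3 <- shrake_rupley_sasa(nested, radii = c(1.0, 4.0), probe = 1.4)
  expect_equal(s3[1], 0)
  # convergence: 960 vs 4000 points within 1%
  set.seed(3)
  blob <- matrix(rnorm(30, sd = 2), ncol = 3)
  rr <- runif(10, 1.4, 1.9)
  a <- sum(shrake_rupley_sasa(blob, radii = rr, n_points = 960))
  b <- sum(shrake_rupley_sasa(blob, radii = rr, n_points = 4000))
  expect_lt(abs(a - b) / b, 0.01)
  expect_error(shrake_rupley_sasa(one, radii = 1.7, n_points = 40),
               "resolution")
})

test_that("nonpolar solvation is affine in SASA", {
  expect_equal(nonpolar_solvation(0), 3.849)
  expect_equal(nonpolar_solvation(1000), 0.0227 * 1000 + 3.849)
  expect_equal(nonpolar_solvation(1000), 26.549, tolerance = 1e-9)
  expect_error(nonpolar_solvation(-1), ">= 0")
})

test_that("the free-energy ledger reproduces the published totals", {
  # polar 15.93 + nonpolar -56.4 combine to dH -40.47; with TdS -19.46
  # the binding free energy is -21.01 kJ/mol
  b <- binding_free_energy(vdw = 0, ele = 15.93, polar_solv = 0,
                           nonpolar_solv = -56.4, entropy_term = -19.46)
  expect_equal(b$enthalpy, -40.47, tolerance = 1e-9)
  expect_equal(b$binding, -21.01, tolerance = 1e-9)
  expect_equal(b$polar_total + b$nonpolar_total, b$enthalpy,
               tolerance = 1e-9)
  z <- binding_free_energy(0, 0, 0, 0, 0)
  expect_equal(z$binding, 0)
  expect_error(binding_free_energy(NA, 0, 0, 0, 0), "finite")
})

test_that("per-residue totals sum their components as in the published table", {
  # rows whose printed components sum exactly to the printed total
  rows <- list(R231 = c(-1.63, -11.59, 8.03, -0.16, -5.35),
               L234 = c(-2.40, -1.31, 1.46, -0.12, -2.37),
               A264 = c(-1.44, -0.13, 0.28, -0.17, -1.46),
               Y126 = c(-1.25, 0.00, 0.22, -0.06, -1.09),
               G262 = c(-1.47, -2.93, 3.84, -0.15, -0.71))
  for (r in rows)
    expect_equal(sum(r[1:4]), r[5], tolerance = 0.005)
})

test_that("residue decomposition partitions the whole-receptor interaction", {
  set.seed(9)
  n_rec <- 9
  topo <- data.frame(serial = 1:(n_rec + 2),
                     name = paste0("X", 1:(n_rec + 2)), element = "C",
                     resname = c(rep("GLY", n_rec), "LIG", "LIG"),
                     resid = c(rep(1:3, each = 3), 4L, 4L), chain = "A",
                     occupancy = 1, bfactor = 0, is_heavy = TRUE,
                     stringsAsFactors = FALSE)
  xyz <- rbind(matrix(rnorm(3 * n_rec, sd = 3), ncol = 3),
               matrix(rnorm(6, sd = 1) + 10, ncol = 3))
  coords <- array(rep(xyz, 5), dim = c(n_rec + 2, 3, 5))
  coords <- coords + array(rnorm(length(coords), sd = 0.05), dim = dim(coords))
  tr <- trajectory(topo, coords)
  tab <- param_table_for(tr)
  tab$charge <- round(runif(n_rec + 2, -0.5, 0.5), 3)
  dec <- per_residue_decomposition(1:n_rec, (n_rec + 1):(n_rec + 2), tr,
                                   tab, frames = 1:5)
  whole_by_frame <- vapply(1:5, function(f)
    unlist(coulomb_lj_interaction(1:n_rec, (n_rec + 1):(n_rec + 2),
                                  frame_coords(tr, f), tab, traj = tr)),
    numeric(2))
  expect_equal(sum(dec$e_ele), mean(whole_by_frame["ele", ]),
               tolerance = 1e-6)
  expect_equal(sum(dec$e_vdw), mean(whole_by_frame["vdw", ]),
               tolerance = 1e-6)
  # ranking ascends in e_tot; totals sum the four components
  expect_true(all(diff(dec$e_tot) >= 0))
  expect_equal(dec$e_tot, dec$e_vdw + dec$e_ele + dec$e_gb + dec$e_gbsur)
  expect_false(attr(dec, "solvation_supplied"))
  # supplied solvation joins by residue and flags mismatch
  solv <- data.frame(residue = 1:3, e_gb = c(1, 2, 3),
                     e_gbsur = c(-0.1, -0.2, -0.3))
  dec2 <- per_residue_decomposition(1:n_rec, (n_rec + 1):(n_rec + 2), tr,
                                    tab, solvation_table = solv,
                                    frames = 1:5)
  expect_true(attr(dec2, "solvation_supplied"))
  expect_equal(sort(dec2$e_gb), c(1, 2, 3))
  bad <- solv[1:2, ]
  expect_error(per_residue_decomposition(1:n_rec, (n_rec + 1):(n_rec + 2),
                                         tr, tab, solvation_table = bad,
                                         frames = 1:5), "join error")
  # inert ligand: all residue totals zero
  tab0 <- param_table_for(tr, charge = 0, eps = 0)
  dec0 <- per_residue_decomposition(1:n_rec, (n_rec + 1):(n_rec + 2), tr,
                                    tab0, frames = 1:5)
  expect_true(all(abs(dec0$e_tot) < 1e-12))
})

test_that("component tables load, validate, and aggregate through the ledger", {
  txt <- c("frame,vdw,ele,polar_solv,nonpolar_solv,entropy_term",
           "1,-50,-10,20,-0.5,-19",
           "2,-52,-12,24,-0.7,-21",
           "3,-54,-8,22,-0.6,-20")
  lc <- load_component_table(txt, text = TRUE)
  expect_equal(lc$mean$vdw, -52)
  expect_equal(lc$mean$enthalpy, mean(c(-50 - 10 + 20 - 0.5,
                                        -52 - 12 + 24 - 0.7,
                                        -54 - 8 + 22 - 0.6)))
  expect_equal(lc$mean$binding, lc$mean$enthalpy - lc$mean$entropy_term,
               tolerance = 1e-9)
  expect_equal(unname(lc$sd["vdw"]), sd(c(-50, -52, -54)))
  # constant table: zero spread
  const <- c(txt[1], "1,-50,-10,20,-0.5,-19", "2,-50,-10,20,-0.5,-19")
  expect_equal(unname(load_component_table(const, text = TRUE)$sd["vdw"]), 0)
  expect_error(load_component_table(c("frame,vdw", "1,2"), text = TRUE),
               "schema")
  expect_error(load_component_table(c(txt[1], "1,a,b,c,d,e"), text = TRUE),
               "parse error")
})
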