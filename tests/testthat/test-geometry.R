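test_that("Kabsch superposition agrees with a quaternion oracle and is proper", {
  set.seed(21)
  for (rep in 1:5) {
    x <- matrix(rnorm(12 * 3, sd = 3), ncol = 3)
    y <- x %*% random_rotation() + matrix(rnorm(36, sd = 0.3), ncol = 3)
    k <- kabsch_superpose(y, x)
    expect_lt(abs(k$rmsd - oracle_quaternion_rmsd(y, x)), 1e-9)
    expect_lt(abs(det(k$rotation) - 1), 1e-9)
    expect_lt(max(abs(crossprod(k$rotation) - diag(3))), 1e-9)
  }
})

test_that("superposition removes rigid motion and flags degenerate input", {
  x <- frame_coords(make_helix(8))
  k0 <- kabsch_superpose(x, x)
  expect_equal(k0$rmsd, 0, tolerance = 1e-10)
  expect_equal(k0$rotation, diag(3), tolerance = 1e-9)
  th <- 37 * pi / 180
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  moved <- sweep(x %*% R, 2, c(5, -3, 2), `+`)
  expect_lt(kabsch_superpose(moved, x)$rmsd, 1e-6)
  # RMSD decomposition invariant: value^2 * n = sum of squared deviations
  pert <- x + matrix(rnorm(length(x), sd = 0.5), ncol = 3)
  k <- kabsch_superpose(pert, x)
  expect_equal(k$rmsd^2 * k$n_atoms, sum(k$per_atom_deviation^2),
               tolerance = 1e-9)
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line + 0.1), "degenerate")
  expect_error(kabsch_superpose(x[1:2, ], x[1:2, ]), "at least 3")
})

test_that("superposed RMSD agrees with the bio3d reference implementation", {
  skip_if_not_installed("bio3d")
  set.seed(55)
  x <- matrix(rnorm(60, sd = 3), ncol = 3)
  y <- x %*% random_rotation() + matrix(rnorm(60, sd = 0.4), ncol = 3)
  mine <- kabsch_superpose(y, x)$rmsd
  ref <- bio3d::rmsd(as.vector(t(x)), as.vector(t(y)), fit = TRUE)
  expect_equal(mine, ref, tolerance = 5e-4)  # bio3d reports 3 decimals
})

test_that("superposed RMSD never exceeds unsuperposed RMSD and is symmetric", {
  set.seed(8)
  ts <- make_two_state_ensemble(c(0.6, 0.4), 12, 4, 0.5, seed = 15)
  for (pair in list(c(1, 5), c(2, 9), c(3, 12))) {
    a <- frame_coords(ts$traj, pair[1])
    b <- frame_coords(ts$traj, pair[2])
    fit_ab <- kabsch_superpose(a, b)$rmsd
    fit_ba <- kabsch_superpose(b, a)$rmsd
    raw <- sqrt(mean(rowSums((a - b)^2)))
    expect_lte(fit_ab, raw + 1e-12)
    expect_lt(abs(fit_ab - fit_ba), 1e-9)
  }
})

test_that("rmsd_series separates the two states of the bimodal fixture", {
  ts <- make_two_state_ensemble(c(0.7, 0.3), 400, displacement = 6,
                                noise_sigma = 0.05, seed = 33)
  sel <- select_atoms(ts$traj, "calpha")
  ref <- frame_coords(ts$traj, which(ts$states == 1L)[1])
  rs <- rmsd_series(ts$traj, reference = ref, sel = sel, discard_frac = 0)
  # closed form before fitting: d*sqrt(k/N); the optimal fit compensates
  # with a rigid shift of d*k/N plus a rotation, so the superposed value
  # sits between d*sqrt(k/N (1 - k/N)) shrunk by the rotation and the
  # unfitted bound
  k <- sum(ts$traj$topology$resid[sel] > 24)
  upper <- 6 * sqrt(k / length(sel))
  hi <- rs$rmsd[ts$states == 2L]
  lo <- rs$rmsd[ts$states == 1L]
  expect_true(all(lo < 0.5))
  expect_true(all(hi > upper / 2))
  expect_true(all(hi <= upper + 1e-9))
  expect_equal(rs$mean, mean(rs$rmsd), tolerance = 1e-12)
  expect_error(rmsd_series(ts$traj, sel = integer(0)), "empty selection")
})

test_that("rmsf recovers the injected isotropic noise amplitude", {
  n <- 2000
  sigma <- 0.4
  static <- make_two_state_ensemble(c(1, 0), n, displacement = 1,
                                    noise_sigma = sigma, seed = 77)
  r <- rmsf(static$traj)
  expected <- sigma * sqrt(3) * sqrt((n - 1) / n)
  expect_true(all(abs(r - expected) / expected < 0.05))
  # rigid motion only: zero fluctuation
  h <- frame_coords(make_helix(6))
  coords <- array(0, dim = c(nrow(h), 3, 4))
  for (f in 1:4) {
    th <- f * 0.3
    R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
    coords[, , f] <- sweep(h %*% R, 2, c(f, 0, -f), `+`)
  }
  rigid <- trajectory(make_helix(6)$topology, coords)
  expect_true(all(rmsf(rigid) < 1e-6))
  expect_error(rmsf(trajectory(make_helix(6)$topology, h)), "insufficient")
  # displaced segment fluctuates well above the static core (the mean-fit
  # compensation spreads some apparent motion onto static atoms, so the
  # comparison is on group means)
  ts <- make_two_state_ensemble(c(0.5, 0.5), 200, 5, 0.1, seed = 2)
  rr <- rmsf(ts$traj)
  expect_gt(mean(rr[ts$moving_atoms]), mean(rr[-ts$moving_atoms]))
  expect_gt(mean(rr[ts$moving_atoms]), 1)  # ideal 5*sqrt(0.25) = 2.5 A
})

test_that("B-factor conversion follows B = 8 pi^2 rmsf^2 / 3", {
  expect_equal(bfactor_from_rmsf(0), 0)
  expect_equal(bfactor_from_rmsf(1), 8 * pi^2 / 3, tolerance = 1e-12)
  expect_equal(bfactor_from_rmsf(2), 4 * bfactor_from_rmsf(1))
  expect_error(bfactor_from_rmsf(-0.1), "domain")
})

test_that("radius of gyration matches closed forms and is translation-invariant", {
  two <- rbind(c(0, 0, 0), c(4, 0, 0))
  expect_equal(radius_of_gyration(two), 2)
  ang <- 2 * pi * (0:359) / 360
  ring <- cbind(7 * cos(ang), 7 * sin(ang), 0)
  expect_equal(radius_of_gyration(ring), 7, tolerance = 0.01)
  expect_equal(radius_of_gyration(sweep(ring, 2, c(10, -3, 2), `+`)),
               radius_of_gyration(ring), tolerance = 1e-9)
  expect_error(radius_of_gyration(two, masses = c(0, 0)), "domain")
})

test_that("distance and angle series follow Euclidean geometry", {
  topo <- data.frame(serial = 1:3, name = c("A1", "A2", "A3"),
                     element = "C", resname = "GLY", resid = 1:3,
                     chain = "A", occupancy = 1, bfactor = 0,
                     is_heavy = TRUE, stringsAsFactors = FALSE)
  xyz <- rbind(c(0, 0, 0), c(3, 4, 0), c(6, 8, 0))
  tr <- trajectory(topo, xyz)
  expect_equal(distance_series(tr, 1, 2), 5)
  expect_equal(angle_series(tr, 1, 2, 3), 180)
  xyz2 <- rbind(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0))
  expect_equal(angle_series(trajectory(topo, xyz2), 1, 2, 3), 90)
  expect_error(distance_series(tr, 2, 2), "distinct")
  expect_error(angle_series(tr, 1, 2, 2), "distinct")
})

test_that("pearson correlation validates input and matches the direct formula", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_correlation(x, 2 * x + 1), 1)
  expect_equal(pearson_correlation(x, -x), -1)
  y <- c(2.3, 1.1, 4.7, 3.3, 0.9)
  direct <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_correlation(x, y), direct, tolerance = 1e-12)
  expect_error(pearson_correlation(x, rep(1, 5)), "zero variance")
  expect_error(pearson_correlation(1:2, 1:2), "at least 3")
})
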