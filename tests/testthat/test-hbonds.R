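water_dimer <- function() {
  # donor water (O1 H1 H2) hydrogen-bonded to acceptor water (O2 H3 H4)
  topo <- data.frame(serial = 1:6,
                     name = c("O", "H1", "H2", "O", "H1", "H2"),
                     element = c("O", "H", "H", "O", "H", "H"),
                     resname = "HOH", resid = c(1, 1, 1, 2, 2, 2),
                     chain = "A", occupancy = 1, bfactor = 0,
                     is_heavy = c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE),
                     stringsAsFactors = FALSE)
  xyz <- rbind(c(0, 0, 0),        # O1
               c(0.96, 0, 0),     # H1 donates toward O2
               c(-0.3, 0.9, 0),   # H2
               c(2.8, 0, 0),      # O2 (H1...O2 = 1.84 A)
               c(3.2, 0.85, 0),   # H3
               c(3.2, -0.85, 0))  # H4
  trajectory(topo, xyz)
}

test_that("candidate enumeration matches exhaustive donor/acceptor search", {
  w <- water_dimer()
  cand <- find_hbond_candidates(w, prefilter = 5)
  # oracle: every H within 1.2 A of an N/O/S donor x every N/O acceptor
  xyz <- frame_coords(w)
  topo <- w$topology
  expected <- 0L
  for (h in which(topo$element == "H")) {
    don <- which(topo$element %in% c("N", "O", "S"))
    dh <- sqrt(rowSums(sweep(xyz[don, , drop = FALSE], 2, xyz[h, ])^2))
    if (!any(dh <= 1.2)) next
    d <- don[which.min(dh)]
    for (a in which(topo$element %in% c("N", "O"))) {
      if (a == d) next
      if (sqrt(sum((xyz[a, ] - xyz[h, ])^2)) <= 5) expected <- expected + 1L
    }
  }
  expect_equal(nrow(cand), expected)
  expect_true(all(cand$donor != cand$acceptor))
  expect_true(all(w$topology$element[cand$hydrogen] == "H"))
  # apolar structure: no hydrogens attached to N/O/S, hence no donors
  ch <- data.frame(serial = 1:2, name = c("C1", "H1"),
                   element = c("C", "H"), resname = "LIG", resid = 1,
                   chain = "A", occupancy = 1, bfactor = 0,
                   is_heavy = c(TRUE, FALSE), stringsAsFactors = FALSE)
  apolar <- trajectory(ch, rbind(c(0, 0, 0), c(1.1, 0, 0)))
  expect_equal(nrow(find_hbond_candidates(apolar)), 0L)
  noh <- trajectory(ch[1, , drop = FALSE], matrix(0, 1, 3))
  expect_error(find_hbond_candidates(noh), "no hydrogens")
})

test_that("the geometric criterion accepts published geometry and is monotone", {
  expect_true(hbond_check(2.82, 155.44))
  expect_false(hbond_check(3.6, 170))
  expect_false(hbond_check(2.0, 135.0))  # strict angle bound
  expect_false(hbond_check(3.5, 150))    # strict distance bound
  # monotone: shrinking distance or growing angle never flips true->false
  set.seed(12)
  for (i in 1:50) {
    d <- runif(1, 1.5, 5)
    a <- runif(1, 90, 180)
    if (hbond_check(d, a)) {
      expect_true(hbond_check(d * runif(1, 0.5, 1), a))
      expect_true(hbond_check(d, a + (180 - a) * runif(1)))
    }
  }
})

test_that("occupancy recovers Bernoulli rates and equals the boolean-series mean", {
  for (p in c(0, 0.36, 0.58, 1)) {
    hb <- make_hbond_trajectory(p, 5000, seed = 100 + round(100 * p))
    st <- hbond_occupancy(hb$traj, hb$triple)
    tol <- 3 * sqrt(max(p * (1 - p), 1e-12) / 5000)
    expect_lte(abs(st$frequency - p), max(tol, 1e-12))
    expect_equal(st$frequency, mean(st$series$bonded))
    expect_gte(st$frequency, 0)
    expect_lte(st$frequency, 1)
  }
})

test_that("side-chain state classification splits folded and stretched frames", {
  cls <- classify_sidechain_state(angle = c(170, 80), distance = c(8, 3),
                                  angle_split = 120, distance_split = 5)
  expect_equal(as.character(cls$state), c("stretched", "folded"))
  alt <- classify_sidechain_state(angle = rep(c(170, 80), 50),
                                  distance = rep(c(8, 3), 50),
                                  angle_split = 120, distance_split = 5)
  expect_equal(alt$freq_folded, 0.5)
  expect_equal(alt$freq_stretched, 0.5)
  expect_error(classify_sidechain_state(1, 1), "must be supplied")
})

test_that("RDF of a periodic uniform gas is flat and integrates to the pair count", {
  g <- make_uniform_gas(1000, 50, seed = 17)
  r <- rdf(g, 1:1000, 1:1000, bin_width = 0.5, r_max = 12.5, box = 50)
  mid <- r$r >= 5 & r$r <= 12.5
  # 3x Poisson band around the ideal-gas expectation
  expected_counts <- 1000 * 999 / 2 * 4 * pi * r$r[mid]^2 * 0.5 / 50^3
  expect_true(all(abs(r$count[mid] - expected_counts) <=
                  3 * sqrt(expected_counts)))
  # histogram mass equals the pairs actually inside r_max
  xyz <- frame_coords(g)
  prs <- t(combn(1000, 2))
  dv <- xyz[prs[, 1], ] - xyz[prs[, 2], ]
  dv <- dv - 50 * round(dv / 50)
  n_in <- sum(sqrt(rowSums(dv^2)) < 12.5)
  expect_equal(sum(r$count), n_in)
})

test_that("RDF localizes a fixed pair and validates groups", {
  topo <- data.frame(serial = 1:2, name = c("A1", "A2"), element = "C",
                     resname = "LIG", resid = 1:2, chain = "A",
                     occupancy = 1, bfactor = 0, is_heavy = TRUE,
                     stringsAsFactors = FALSE)
  coords <- array(0, dim = c(2, 3, 5))
  coords[2, 1, ] <- 1.9
  tr <- trajectory(topo, coords)
  r <- rdf(tr, 1L, 2L, bin_width = 0.2, r_max = 4, volume = 1000)
  expect_equal(sum(r$count > 0), 1L)
  expect_equal(r$r[r$count > 0], 1.9, tolerance = 0.1)
  expect_error(rdf(tr, integer(0), 2L, 0.2, 4, volume = 1), "empty group")
  expect_error(rdf(tr, 1L, c(1L, 2L), 0.2, 4, volume = 1), "disjoint")
  expect_error(rdf(tr, 1L, 2L, 0.2, 4), "volume")
})
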