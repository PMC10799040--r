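three_atom_top <- function() {
  topology(tibble::tibble(
    element = c("O", "H", "Cl"), name = c("OD", "HD", "CLA"),
    charge = c(-0.5, 0.3, -1), lj_epsilon = 0.1, lj_sigma = c(3, 0.4, 4),
    molecule_id = c(1, 1, 2), species = c("ACE", "ACE", "CHL"),
    role = c("HBD", "HBD", "HBA")))
}

test_that("criteria presets carry the documented windows and validate", {
  th <- hbond_criteria("thymol")
  expect_equal(c(th$d_min, th$d_max, th$angle_min, th$angle_max),
               c(0, 3.5, 135, 150))
  cl <- hbond_criteria("chloride")
  expect_equal(c(cl$d_min, cl$d_max, cl$angle_min, cl$angle_max),
               c(2, 3, 130, 180))
  expect_error(hbond_criteria(d_min = 3, d_max = 2, angle_min = 0,
                              angle_max = 90), "d_min")
  expect_error(hbond_criteria(d_min = 0, d_max = 2, angle_min = 120,
                              angle_max = 190), "angle")
  expect_error(hbond_criteria("unknown-preset"), "preset")
})

test_that("detection accepts a linear in-window triple and rejects a bent one", {
  top <- three_atom_top()
  cell <- simulation_cell(c(20, 20, 20))
  dmap <- tibble::tibble(donor = 1L, hydrogen = 2L)
  crit <- hbond_criteria("chloride")
  pos <- rbind(c(0, 0, 0), c(1, 0, 0), c(2.8, 0, 0))
  ev <- detect_hbonds(pos, dmap, 3L, crit, cell, top)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$angle, 180)
  expect_equal(ev$distance, 2.8)
  # same distance, 90-degree angle at the hydrogen: rejected
  pos2 <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1.8, 0))
  expect_equal(nrow(detect_hbonds(pos2, dmap, 3L, crit, cell, top)), 0)
  # hydrogen-acceptor distance definition
  crit_ha <- hbond_criteria(d_min = 0, d_max = 2, angle_min = 130,
                            angle_max = 180,
                            distance_definition = "hydrogen_acceptor")
  ev2 <- detect_hbonds(pos, dmap, 3L, crit_ha, cell, top)
  expect_equal(ev2$distance, 1.8)
})

test_that("detector matches the triple-loop oracle on a random frame", {
  set.seed(41)
  cell <- simulation_cell(c(15, 15, 15))
  n_mol <- 30
  atoms <- dplyr::bind_rows(lapply(seq_len(n_mol), function(m) {
    tibble::tibble(element = c("O", "H"), name = c("OD", "HD"),
                   charge = 0, lj_epsilon = 0.1, lj_sigma = c(3, 0.4),
                   molecule_id = m, species = "DON", role = "HBD")
  }))
  top <- topology(atoms)
  pos <- matrix(0, 2 * n_mol, 3)
  pos[seq(1, 2 * n_mol, 2), ] <- matrix(runif(n_mol * 3, 0, 15), ncol = 3)
  dir <- matrix(rnorm(n_mol * 3), ncol = 3)
  dir <- dir / sqrt(rowSums(dir^2))
  pos[seq(2, 2 * n_mol, 2), ] <- pos[seq(1, 2 * n_mol, 2), ] + dir
  dmap <- donor_hydrogen_map(top, seq(1, 2 * n_mol, 2), seq(2, 2 * n_mol, 2))
  # donor oxygens double as acceptors (inter-molecular only)
  crit <- hbond_criteria(d_min = 0, d_max = 3.5, angle_min = 100,
                         angle_max = 180)
  got <- detect_hbonds(pos, dmap, seq(1, 2 * n_mol, 2), crit, cell, top)
  exp <- oracle_hbonds(pos, dmap, seq(1, 2 * n_mol, 2), crit, cell,
                       top$atoms$molecule_id)
  key <- function(d) d[order(d$donor, d$acceptor), ]
  expect_equal(key(got)$donor, key(exp)$donor)
  expect_equal(key(got)$acceptor, key(exp)$acceptor)
  expect_equal(key(got)$distance, key(exp)$distance, tolerance = 1e-9)
  expect_equal(key(got)$angle, key(exp)$angle, tolerance = 1e-6)
})

test_that("detection is invariant under lattice translation", {
  set.seed(42)
  cell <- simulation_cell(c(12, 12, 12))
  top <- three_atom_top()
  dmap <- tibble::tibble(donor = 1L, hydrogen = 2L)
  crit <- hbond_criteria("chloride")
  pos <- rbind(c(11.5, 0, 0), c(0.3, 0, 0), c(2.4, 0, 0))
  ev1 <- detect_hbonds(pos, dmap, 3L, crit, cell, top)
  ev2 <- detect_hbonds(sweep(pos, 2, c(12, -24, 36), "+"), dmap, 3L, crit,
                       cell, top)
  expect_equal(ev1, ev2, tolerance = 1e-9)
  expect_equal(nrow(ev1), 1)
})

test_that("tightening criteria never increases the event count", {
  sched <- matrix(runif(50 * 4) < 0.5, 50, 4)
  crit <- hbond_criteria("chloride")
  tr <- gen_hbond_dimers(sched, crit, seed = 43)
  dmap <- donor_hydrogen_map(tr$topology,
                             select_atoms(tr$topology, name = "OD"),
                             select_atoms(tr$topology, name = "HD"))
  acc <- select_atoms(tr$topology, name = "OA")
  wide <- hbond_count_series(tr, dmap, acc, crit)
  for (tight in list(
    hbond_criteria(d_min = 2.2, d_max = 2.8, angle_min = 130, angle_max = 180),
    hbond_criteria(d_min = 2, d_max = 3, angle_min = 140, angle_max = 170))) {
    narrow <- hbond_count_series(tr, dmap, acc, tight)
    expect_true(all(narrow$n_bonds <= wide$n_bonds))
  }
})

test_that("count series reproduces a constructed schedule exactly", {
  k_t <- c(0, 1, 2, 3, 2, 1, 0, 3, 3, 0)
  sched <- matrix(FALSE, 10, 3)
  for (f in 1:10) if (k_t[f] > 0) sched[f, seq_len(k_t[f])] <- TRUE
  crit <- hbond_criteria("chloride")
  tr <- gen_hbond_dimers(sched, crit, seed = 44)
  dmap <- donor_hydrogen_map(tr$topology,
                             select_atoms(tr$topology, name = "OD"),
                             select_atoms(tr$topology, name = "HD"))
  s <- hbond_count_series(tr, dmap, select_atoms(tr$topology, name = "OA"),
                          crit)
  expect_equal(s$n_bonds, k_t)
  # per-pair event-frames sum equals the series sum (single-route fixtures)
  occ <- hbond_occupancy(tr, dmap, select_atoms(tr$topology, name = "OA"),
                         crit)
  expect_equal(sum(occ$n_frames_bonded), sum(s$n_bonds))
})

test_that("occupancy collapses hydrogen identity to the donor-acceptor pair", {
  # one donor oxygen with two hydrogens, both able to reach one acceptor
  atoms <- tibble::tibble(
    element = c("O", "H", "H", "Cl"), name = c("OD", "H1", "H2", "CLA"),
    charge = 0, lj_epsilon = 0.1, lj_sigma = c(3, 0.4, 0.4, 4),
    molecule_id = c(1, 1, 1, 2), species = c("W", "W", "W", "CHL"),
    role = c("HBD", "HBD", "HBD", "HBA"))
  top <- topology(atoms)
  cell <- simulation_cell(c(20, 20, 20))
  # both hydrogens point roughly at the acceptor: two simultaneous routes
  pos <- rbind(c(0, 0, 0), c(0.95, 0.2, 0), c(0.95, -0.2, 0), c(2.6, 0, 0))
  tr <- static_traj(pos, cell, n_frames = 4, top = top)
  dmap <- tibble::tibble(donor = c(1L, 1L), hydrogen = c(2L, 3L))
  crit <- hbond_criteria(d_min = 2, d_max = 3, angle_min = 120,
                         angle_max = 180)
  ev <- detect_hbonds(pos, dmap, 4L, crit, cell, top)
  expect_equal(nrow(ev), 2)            # two routes detected
  occ <- hbond_occupancy(tr, dmap, 4L, crit)
  expect_equal(nrow(occ), 1)           # one donor-acceptor pair
  expect_equal(occ$occupancy, 100)
  expect_equal(occ$n_frames_bonded, 4L)
})

test_that("Gaussian fit recovers known parameters from sampled counts", {
  set.seed(45)
  x <- rnorm(1e4, mean = 100, sd = 5)
  fit <- fit_gaussian_histogram(x, n_bins = 40)
  expect_true(fit$converged)
  expect_gt(fit$mean, 99.5); expect_lt(fit$mean, 100.5)
  expect_gt(fit$sigma, 4.7); expect_lt(fit$sigma, 5.3)
  expect_true(is.finite(fit$se_mean))
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "mean"], fit$mean)
})

test_that("Gaussian fit is exact on a noiseless Gaussian curve", {
  xg <- seq(80, 120, by = 0.5)
  yg <- 40 / (5 * sqrt(2 * pi)) * exp(-(xg - 100)^2 / (2 * 25))
  fit <- fit_gaussian(xg, yg)
  expect_equal(fit$mean, 100, tolerance = 1e-6)
  expect_equal(fit$sigma, 5, tolerance = 1e-6)
  expect_equal(fit$a, 40, tolerance = 1e-6)
  expect_error(fit_gaussian_histogram(rep(7, 100)), "degenerate")
  expect_error(fit_gaussian_histogram(c(1, 2)), "length")
})
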