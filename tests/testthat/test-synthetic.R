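cell30 <- simulation_cell(c(30, 30, 30))

test_that("generators are deterministic in their seed and reject bad specs", {
  expect_error(gen_ideal_gas(0, 10, cell30, seed = 1), "spec error")
  expect_error(gen_brownian(5, 10, cell30, D = -1, dt = 0.1, seed = 1),
               "spec error")
  expect_error(gen_langevin(5, 10, cell30, gamma = 0, temperature = 300,
                            mass = 18, seed = 1), "spec error")
  expect_error(gen_rotor(5, 10, cell30, D_r = -0.1, seed = 1), "spec error")
  expect_error(gen_ou_stress(100, 0.1, C0 = 1, tau_c = 0, seed = 1),
               "spec error")
  expect_identical(gen_ideal_gas(20, 5, cell30, seed = 1),
                   gen_ideal_gas(20, 5, cell30, seed = 1))
  expect_identical(gen_brownian(10, 20, cell30, D = 0.5, dt = 0.1, seed = 3),
                   gen_brownian(10, 20, cell30, D = 0.5, dt = 0.1, seed = 3))
  expect_identical(gen_ou_stress(50, 0.1, 1, 2, seed = 9),
                   gen_ou_stress(50, 0.1, 1, 2, seed = 9))
  expect_false(identical(gen_ideal_gas(20, 5, cell30, seed = 1)$coords,
                         gen_ideal_gas(20, 5, cell30, seed = 2)$coords))
})

test_that("Brownian generator: D = 0 freezes particles; slope recovers D", {
  frozen <- gen_brownian(5, 10, cell30, D = 0, dt = 0.1, seed = 2)
  expect_equal(frozen$coords[, , 1], frozen$coords[, , 10])
  tr <- gen_brownian(200, 1000, cell30, D = 1, dt = 0.01, seed = 4)
  msd <- compute_msd(tr)
  # slope/6 over the well-averaged early-lag region (many time origins)
  early <- msd$lag > 0 & msd$lag <= 0.2 * max(msd$lag)
  slope <- coef(lm(value ~ lag, data = msd[early, ]))["lag"]
  expect_equal(unname(slope) / 6, 1, tolerance = 0.05)
})

test_that("Langevin generator satisfies equipartition and decorrelates", {
  tr <- gen_langevin(1000, 2000, cell30, gamma = 2, temperature = 300,
                     mass = 18, dt = 0.01, seed = 6)
  u <- des_units()
  var_expect <- u$k_B * 300 / 18 * u$kcal_per_g_to_A2ps2
  vx <- as.vector(tr$velocities[, 1, ])
  # correlated stream: n_eff = n_particles * T_total / (2 / gamma)
  n_eff <- 1000 * (2000 * 0.01) / (2 / 2)
  se <- var_expect * sqrt(2 / n_eff)
  expect_lt(abs(var(vx) - var_expect), 3 * se)
  # large gamma: consecutive velocities decorrelated
  tr2 <- gen_langevin(500, 200, cell30, gamma = 500, temperature = 300,
                      mass = 18, dt = 0.1, seed = 7)
  v1 <- as.vector(tr2$velocities[, 1, -200])
  v2 <- as.vector(tr2$velocities[, 1, -1])
  expect_lt(abs(cor(v1, v2)), 3 / sqrt(length(v1)))
})

test_that("rotor generator is rigid and frozen when D_r = 0", {
  tr0 <- gen_rotor(20, 30, cell30, D_r = 0, dt = 0.01, seed = 8)
  vrd0 <- compute_vrd(tr0, seq(1, 40, 2), seq(2, 40, 2))
  expect_equal(vrd0$value, rep(1, nrow(vrd0)), tolerance = 1e-12)
  tr <- gen_rotor(50, 100, cell30, D_r = 0.2, bond_length = 1.5, dt = 0.01,
                  seed = 9)
  d <- tr$coords[seq(2, 100, 2), , ] - tr$coords[seq(1, 100, 2), , ]
  lens <- sqrt(d[, 1, ]^2 + d[, 2, ]^2 + d[, 3, ]^2)
  expect_true(all(abs(lens - 1.5) < 1e-9))
})

test_that("dimer generator realizes its occupancy schedule exactly", {
  sched <- matrix(FALSE, 100, 2)
  sched[1:60, 1] <- TRUE
  crit <- hbond_criteria("chloride")
  tr <- gen_hbond_dimers(sched, crit, seed = 10)
  dmap <- donor_hydrogen_map(tr$topology,
                             select_atoms(tr$topology, name = "OD"),
                             select_atoms(tr$topology, name = "HD"))
  occ <- hbond_occupancy(tr, dmap, select_atoms(tr$topology, name = "OA"),
                         crit)
  expect_equal(nrow(occ), 1)        # pair 2 never bonds -> absent
  expect_equal(occ$occupancy, 60.0)
  # all-off schedule: nothing detected
  tr0 <- gen_hbond_dimers(matrix(FALSE, 20, 2), crit, seed = 11)
  dmap0 <- donor_hydrogen_map(tr0$topology,
                              select_atoms(tr0$topology, name = "OD"),
                              select_atoms(tr0$topology, name = "HD"))
  s0 <- hbond_count_series(tr0, dmap0,
                           select_atoms(tr0$topology, name = "OA"), crit)
  expect_true(all(s0$n_bonds == 0))
})

test_that("dimer in-bond distances follow the requested distribution", {
  sched <- matrix(TRUE, 400, 3)
  crit <- hbond_criteria("thymol")
  tr <- gen_hbond_dimers(sched, crit, d_mean = 2.0, d_sd = 0.05, seed = 12)
  dmap <- donor_hydrogen_map(tr$topology,
                             select_atoms(tr$topology, name = "OD"),
                             select_atoms(tr$topology, name = "HD"))
  ev <- dplyr::bind_rows(deswater:::hbond_events_by_frame(
    tr, dmap, select_atoms(tr$topology, name = "OA"), crit))
  expect_equal(nrow(ev), 1200)
  expect_lt(abs(mean(ev$distance) - 2.0), 3 * 0.05 / sqrt(1200))
})

test_that("toy mixture honours composition, exclusion and neutrality", {
  tr <- gen_toy_mixture(c(anion = 10, cation = 10, donor = 20, water = 50),
                        simulation_cell(c(40, 40, 40)), exclusion = 2,
                        seed = 13)
  top <- tr$topology
  expect_length(unique(top$atoms$molecule_id[top$groups$ANION]), 10)
  expect_length(unique(top$atoms$molecule_id[top$groups$CATION]), 10)
  expect_length(unique(top$atoms$molecule_id[top$groups$DONOR]), 20)
  expect_length(unique(top$atoms$molecule_id[top$groups$WATER]), 50)
  centers <- tr$metadata$generator$centers
  pr <- neighbor_pairs(centers, 1:90, 1:90, 1.999, simulation_cell(c(40, 40, 40)))
  expect_equal(nrow(pr), 0)
  expect_equal(sum(top$atoms$charge), 0, tolerance = 1e-9)
  expect_error(gen_toy_mixture(c(water = 500), simulation_cell(c(8, 8, 8)),
                               exclusion = 3, seed = 1, max_tries = 50),
               "packing")
})

test_that("biphasic slab stacks two boxes with separated phases", {
  sub <- simulation_cell(c(20, 20, 20))
  tr <- gen_biphasic_slab(c(anion = 10, cation = 10, donor = 10),
                          c(water = 40), sub, seed = 14)
  expect_equal(unclass(tr$cell), c(a = 20, b = 20, c = 40))
  z_w <- mean(tr$coords[tr$topology$groups$water, 3, 1])
  z_d <- mean(tr$coords[setdiff(seq_len(nrow(tr$topology$atoms)),
                                tr$topology$groups$water), 3, 1])
  expect_gte(abs(z_w - z_d), 10)   # quarter of the 40 A z edge
  # density profile shows two plateaus: water fraction low-z vs high-z
  lowz <- tr$coords[, 3, 1] < 20
  w <- seq_len(nrow(tr$topology$atoms)) %in% tr$topology$groups$water
  expect_gt(mean(w[!lowz]), 0.9)
  expect_lt(mean(w[lowz]), 0.1)
  # zero water molecules: single phase, no error
  tr0 <- gen_biphasic_slab(c(donor = 5), c(), sub, seed = 15)
  expect_equal(unclass(tr0$cell)[["c"]], 40)
})

test_that("OU stress components have the stated moments and independence", {
  s <- gen_ou_stress(100000, 0.05, C0 = 2, tau_c = 1, seed = 16)
  n_eff <- 100000 * 0.05 / (2 * 1)
  expect_lt(abs(var(s$pxy) - 2), 3 * 2 * sqrt(2 / n_eff))
  expect_lt(abs(cor(s$pxy, s$pxz)), 3 / sqrt(n_eff))
  expect_lt(abs(cor(s$pxy, s$pyz)), 3 / sqrt(n_eff))
  # autocorrelation decays with the stated time constant
  a <- acf(s$pxy, lag.max = 40, plot = FALSE)$acf[, 1, 1]
  expect_equal(a[21], exp(-20 * 0.05 / 1), tolerance = 0.1)
})
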