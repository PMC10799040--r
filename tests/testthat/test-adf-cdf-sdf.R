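test_that("ADF puts collinear triplets in the last bin and matches the oracle", {
  cell <- simulation_cell(c(20, 20, 20))
  # three collinear atoms, vertex in the middle
  pos <- rbind(c(5, 5, 5), c(6, 5, 5), c(7, 5, 5))
  top <- deswater:::point_topology(3)
  tr <- static_traj(pos, cell, top = top)
  adf <- compute_adf(tr, group_a = 1, group_vertex = 2, group_c = 3,
                     cutoff = 2, bin_width = 5)
  expect_equal(which(attr(adf, "counts") > 0), 36L)   # [175, 180)->last bin
  expect_equal(sum(adf$density) * 5, 1)               # unit area
  # random frame vs direct-loop oracle
  set.seed(31)
  pos2 <- matrix(runif(15 * 3, 8, 12), ncol = 3)
  tr2 <- static_traj(pos2, cell, top = deswater:::point_topology(15))
  adf2 <- compute_adf(tr2, 1:5, 6:10, 11:15, cutoff = 6, bin_width = 10)
  counts <- numeric(18)
  for (v in 6:10) for (a in 1:5) for (c_ in 11:15) {
    if (oracle_min_image_distance(pos2[v, ], pos2[a, ], cell) > 6) next
    if (oracle_min_image_distance(pos2[v, ], pos2[c_, ], cell) > 6) next
    ang <- oracle_angle(pos2[a, ], pos2[v, ], pos2[c_, ], cell)
    k <- min(18, floor(ang / 10) + 1)
    counts[k] <- counts[k] + 1
  }
  expect_equal(attr(adf2, "counts"), 2 * counts)      # two frames
  expect_error(compute_adf(tr2, 1:5, 6:10, 11:15, cutoff = 0.1),
               "empty selection")
})

test_that("distance-angle CDF concentrates a rigid dimer in one cell", {
  cell <- simulation_cell(c(30, 30, 30))
  # vertex atom b at the origin, its partner on +x; the probe atom a sits at
  # distance 2 with an a-b-partner angle of 150 degrees
  th <- 150 * pi / 180
  pos <- rbind(c(0, 0, 0), c(1, 0, 0), 2 * c(cos(th), sin(th), 0)) +
    matrix(10, 3, 3)
  top <- deswater:::point_topology(3)
  tr <- static_traj(pos, cell, top = top)
  cdf <- compute_cdf_dist_angle(tr, group_a = 3, group_b = 1,
                                partner_of_b = c("1" = 2L),
                                r_max = 4, n_dist = 40, n_angle = 36)
  expect_equal(sum(cdf$counts > 0), 1)
  pk <- cdf_argmax(cdf)
  expect_lt(abs(pk$x - 2), 0.1)
  expect_lt(abs(pk$y - 150), 5.1)
})

test_that("distance-angle CDF of independent draws separates into marginals", {
  set.seed(32)
  cell <- simulation_cell(c(200, 200, 200))
  n_ev <- 600
  d <- runif(n_ev, 1, 3)
  th <- runif(n_ev, 60, 120) * pi / 180
  # n_ev isolated triples: b at origin, partner on +x, a at (distance, angle)
  pos <- matrix(0, 3 * n_ev, 3)
  for (k in seq_len(n_ev)) {
    O <- c(5 + 12 * ((k - 1) %% 16), 5 + 12 * (((k - 1) %/% 16) %% 16),
           5 + 12 * ((k - 1) %/% 256))
    pos[3 * k - 2, ] <- O
    pos[3 * k - 1, ] <- O + c(1, 0, 0)
    pos[3 * k, ] <- O + d[k] * c(cos(th[k]), sin(th[k]), 0)
  }
  tr <- static_traj(pos, cell, top = deswater:::point_topology(3 * n_ev))
  bidx <- seq(1, 3 * n_ev, 3)
  cdf <- compute_cdf_dist_angle(
    tr, group_a = seq(3, 3 * n_ev, 3), group_b = bidx,
    partner_of_b = stats::setNames(as.integer(bidx + 1), bidx),
    r_max = 4, n_dist = 4, n_angle = 4)
  expect_equal(sum(cdf$counts), 2 * n_ev)
  # chi-squared independence test on the 2-way table not rejected at 0.01
  tab <- cdf$counts[rowSums(cdf$counts) > 0, colSums(cdf$counts) > 0]
  p <- suppressWarnings(chisq.test(tab)$p.value)
  expect_gt(p, 0.01)
})

test_that("distance-distance CDF is transposed under spec swap", {
  cell <- simulation_cell(c(30, 30, 30))
  # central atom 1; atom 2 at distance 2; atom 3 at distance 3
  pos <- rbind(c(10, 10, 10), c(12, 10, 10), c(10, 13, 10))
  tr <- static_traj(pos, cell, top = deswater:::point_topology(3))
  cdf <- compute_cdf_dist_dist(tr, 1, 2, 3, r_max_1 = 5, r_max_2 = 5,
                               n_bins_1 = 10, n_bins_2 = 10)
  expect_equal(sum(cdf$counts > 0), 1)
  pk <- cdf_argmax(cdf)
  expect_equal(c(pk$x, pk$y), c(2.25, 3.25))
  swapped <- compute_cdf_dist_dist(tr, 1, 3, 2, r_max_1 = 5, r_max_2 = 5,
                                   n_bins_1 = 10, n_bins_2 = 10)
  expect_equal(swapped$counts, t(cdf$counts))
  # oracle equivalence on a random cluster
  set.seed(33)
  pos2 <- matrix(runif(12 * 3, 10, 14), ncol = 3)
  tr2 <- static_traj(pos2, cell, top = deswater:::point_topology(12))
  got <- compute_cdf_dist_dist(tr2, 1:4, 5:8, 9:12, 6, 6,
                               n_bins_1 = 6, n_bins_2 = 6)
  counts <- matrix(0, 6, 6)
  for (a in 1:4) for (b in 5:8) for (c_ in 9:12) {
    d1 <- oracle_min_image_distance(pos2[a, ], pos2[b, ], cell)
    d2 <- oracle_min_image_distance(pos2[a, ], pos2[c_, ], cell)
    if (d1 > 6 || d2 > 6) next
    counts[min(6, floor(d1) + 1), min(6, floor(d2) + 1)] <-
      counts[min(6, floor(d1) + 1), min(6, floor(d2) + 1)] + 1
  }
  expect_equal(got$counts, 2 * counts)
})

test_that("SDF: a fixed target maps to a single voxel at the right value", {
  cell <- simulation_cell(c(20, 20, 20))
  # reference triad along the axes at the box center; target at local (3,0,0)
  pos <- rbind(c(10, 10, 10), c(11, 10, 10), c(10, 10, 11), c(13, 10, 10))
  tr <- static_traj(pos, cell, top = deswater:::point_topology(4))
  sdf <- compute_sdf(tr, ref_triad = c(1, 2, 3), target_group = 4,
                     radius = 4, voxel = 0.5)
  nz <- which(sdf$density > 0, arr.ind = TRUE)
  expect_equal(nrow(nz), 1)
  expect_equal(sdf$axis[nz[1, 1]], 3.25, tolerance = 0.26)
  expect_lt(abs(sdf$axis[nz[1, 2]]), 0.26)
  expect_lt(abs(sdf$axis[nz[1, 3]]), 0.26)
  # value = 1 / (n_frames*n_refs*voxel_vol*bulk); bulk = 1/8000
  expect_equal(max(sdf$density), 1 / (2 * 1 * 0.125 * (1 / 8000)) * 2)
})

test_that("SDF of isotropic targets is radially uniform and matches oracle", {
  set.seed(34)
  cell <- simulation_cell(c(20, 20, 20))
  n_t <- 4000
  tpos <- matrix(runif(n_t * 3, 0, 20), ncol = 3)
  pos <- rbind(c(10, 10, 10), c(11, 10, 10), c(10, 10, 11), tpos)
  tr <- static_traj(pos, cell, top = deswater:::point_topology(n_t + 3))
  sdf <- compute_sdf(tr, c(1, 2, 3), 4:(n_t + 3), radius = 5, voxel = 1)
  # mean normalized density over the inscribed sphere ~ 1
  ax <- sdf$axis
  inside <- array(FALSE, dim = dim(sdf$density))
  for (i in 1:10) for (j in 1:10) for (k in 1:10) {
    inside[i, j, k] <- sqrt(ax[i]^2 + ax[j]^2 + ax[k]^2) < 4
  }
  m <- mean(sdf$density[inside])
  expect_equal(m, 1, tolerance = 0.1)
  # direct rebase oracle on a small case
  small <- compute_sdf(tr, c(1, 2, 3), 4:40, radius = 5, voxel = 1)
  basis <- deswater:::local_frame(pos[1, ], pos[2, ], pos[3, ], cell)
  counts <- array(0, dim = c(10, 10, 10))
  for (t in 4:40) {
    d <- pos[t, ] - pos[1, ]
    d <- d - 20 * round(d / 20)
    loc <- as.vector(basis %*% d)
    if (all(abs(loc) < 5)) {
      ijk <- pmin(10, floor((loc + 5) / 1) + 1)
      counts[ijk[1], ijk[2], ijk[3]] <- counts[ijk[1], ijk[2], ijk[3]] + 1
    }
  }
  norm <- 2 * 1 * 1 * (37 / 8000)
  expect_equal(small$density, 2 * counts / norm)
  expect_error(compute_sdf(tr, c(1, 2, 2), 4:10, 5, 1), "degenera")
})

test_that("cube files round trip through an independent reader", {
  cell <- simulation_cell(c(20, 20, 20))
  set.seed(35)
  pos <- rbind(c(10, 10, 10), c(11, 10, 10), c(10, 10, 11),
               matrix(runif(90, 5, 15), ncol = 3))
  tr <- static_traj(pos, cell, top = deswater:::point_topology(33))
  sdf <- compute_sdf(tr, c(1, 2, 3), 4:33, radius = 4, voxel = 1)
  f <- tempfile(fileext = ".cube")
  ref <- data.frame(element = c("O", "H"), x = c(0, 1), y = 0, z = 0)
  write_cube(sdf, ref, f)
  arr <- oracle_read_cube(f)
  expect_equal(arr, unclass(sdf$density), tolerance = 1e-5)
  hdr <- strsplit(trimws(readLines(f)[3]), "[[:space:]]+")[[1]]
  expect_equal(as.integer(hdr[1]), 2)
  # empty grid -> all-zero cube
  sdf0 <- sdf
  sdf0$density[] <- 0
  write_cube(sdf0, NULL, f)
  expect_true(all(oracle_read_cube(f) == 0))
})
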