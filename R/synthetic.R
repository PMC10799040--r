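# Synthetic trajectory generators. Each one is a pure function of its
# arguments (seed included) and records its ground truth in
# trajectory$metadata$generator, so every downstream estimator can be tested
# against a known answer without any MD engine.

point_topology <- function(n, element = "X", species = "GAS", role = "other",
                           charge = 0, eps = 0, sigma = 1) {
  el <- rep(element, n)
  topology(tibble::tibble(
    element = el, name = el,
    charge = rep(charge, n), lj_epsilon = rep(eps, n),
    lj_sigma = rep(sigma, n), molecule_id = seq_len(n),
    species = rep(species, n), role = rep(role, n)))
}

#' Ideal-gas trajectory (uniform, uncorrelated positions)
#'
#' Positions are i.i.d. uniform in the cell, independently each frame; the
#' exact reference for the flat radial distribution function g(r) = 1.
#'
#' @param n Number of atoms (> 0).
#' @param n_frames Number of frames (>= 2).
#' @param cell A [simulation_cell()].
#' @param dt Frame spacing, ps.
#' @param seed Integer RNG seed (mandatory).
#' @return A [trajectory()].
#' @export
gen_ideal_gas <- function(n, n_frames, cell, dt = 1, seed) {
  if (n <= 0) stop("spec error: n must be positive")
  set.seed(seed)
  L <- unclass(cell)
  coords <- array(stats::runif(n * 3 * n_frames), dim = c(n, 3, n_frames))
  for (k in 1:3) coords[, k, ] <- coords[, k, ] * L[k]
  trajectory(point_topology(n), cell, dt * (seq_len(n_frames) - 1), coords,
             metadata = list(unwrapped = FALSE,
                             generator = list(kind = "ideal_gas", n = n,
                                              seed = seed)))
}

#' Brownian (random-walk) trajectory with known diffusion coefficient
#'
#' Each coordinate increments by Normal(0, 2 D dt) per step, giving
#' MSD(tau) = 6 D tau exactly in expectation. Positions are stored unwrapped
#' (`metadata$unwrapped = TRUE`) unless `wrapped = TRUE`, so the MSD
#' estimator needs no unwrapping.
#'
#' @param n Number of particles.
#' @param n_frames Number of frames.
#' @param cell A [simulation_cell()] (used for the box; walk is free).
#' @param D Diffusion coefficient, A^2/ps (> 0; 0 allowed and yields frozen
#'   particles).
#' @param dt Frame spacing, ps.
#' @param seed Integer RNG seed.
#' @param wrapped If TRUE, store coordinates wrapped into the cell.
#' @return A [trajectory()].
#' @export
gen_brownian <- function(n, n_frames, cell, D, dt = 0.01, seed,
                         wrapped = FALSE) {
  if (D < 0) stop("spec error: D must be >= 0")
  set.seed(seed)
  L <- unclass(cell)
  start <- matrix(stats::runif(n * 3), ncol = 3)
  start <- sweep(start, 2, L, "*")
  coords <- array(0, dim = c(n, 3, n_frames))
  coords[, , 1] <- start
  sd_step <- sqrt(2 * D * dt)
  for (f in seq_len(n_frames)[-1]) {
    coords[, , f] <- coords[, , f - 1] +
      matrix(stats::rnorm(n * 3, sd = sd_step), ncol = 3)
  }
  if (wrapped) {
    for (k in 1:3) coords[, k, ] <- coords[, k, ] -
        L[k] * floor(coords[, k, ] / L[k])
  }
  trajectory(point_topology(n), cell, dt * (seq_len(n_frames) - 1), coords,
             metadata = list(unwrapped = !wrapped,
                             generator = list(kind = "brownian", D = D,
                                              dt = dt, seed = seed)))
}

#' Langevin (Ornstein-Uhlenbeck velocity) trajectory
#'
#' Velocities follow the exact OU update
#' `v(t+dt) = v(t) exp(-gamma dt) + xi` with stationary variance
#' k_B T / m per component (in A^2/ps^2), so the normalized velocity
#' autocorrelation is exp(-gamma tau). Positions are obtained by trapezoidal
#' integration of the velocities and stored unwrapped.
#'
#' @param n Number of particles.
#' @param n_frames Number of frames.
#' @param cell A [simulation_cell()].
#' @param gamma Friction, 1/ps (> 0).
#' @param temperature Temperature, K.
#' @param mass Particle mass, g/mol.
#' @param dt Frame spacing, ps.
#' @param seed Integer RNG seed.
#' @return A [trajectory()] with velocities.
#' @export
gen_langevin <- function(n, n_frames, cell, gamma, temperature, mass,
                         dt = 0.01, seed) {
  if (gamma <= 0) stop("spec error: gamma must be positive")
  set.seed(seed)
  u <- des_units()
  var_v <- u$k_B * temperature / mass * u$kcal_per_g_to_A2ps2  # A^2/ps^2
  decay <- exp(-gamma * dt)
  noise_sd <- sqrt(var_v * (1 - decay^2))
  L <- unclass(cell)
  vel <- array(0, dim = c(n, 3, n_frames))
  vel[, , 1] <- matrix(stats::rnorm(n * 3, sd = sqrt(var_v)), ncol = 3)
  for (f in 2:n_frames) {
    vel[, , f] <- vel[, , f - 1] * decay +
      matrix(stats::rnorm(n * 3, sd = noise_sd), ncol = 3)
  }
  coords <- array(0, dim = c(n, 3, n_frames))
  start <- sweep(matrix(stats::runif(n * 3), ncol = 3), 2, L, "*")
  coords[, , 1] <- start
  for (f in 2:n_frames) {
    coords[, , f] <- coords[, , f - 1] + 0.5 * dt * (vel[, , f - 1] + vel[, , f])
  }
  trajectory(point_topology(n), cell, dt * (seq_len(n_frames) - 1), coords,
             velocities = vel,
             metadata = list(unwrapped = TRUE,
                             generator = list(kind = "langevin", gamma = gamma,
                                              temperature = temperature,
                                              mass = mass, var_v = var_v,
                                              seed = seed)))
}

#' Rigid two-site rotor trajectory (isotropic rotational diffusion)
#'
#' Each molecule is a rigid dimer whose axis performs isotropic rotational
#' diffusion: per step the unit axis receives a Gaussian tangential kick of
#' variance 2 D_r dt per component and is renormalized. The first-rank
#' orientational autocorrelation of this process is exp(-2 D_r tau).
#'
#' @param n Number of molecules.
#' @param n_frames Number of frames.
#' @param cell A [simulation_cell()].
#' @param D_r Rotational diffusion coefficient, 1/ps (>= 0).
#' @param bond_length Site separation, A.
#' @param dt Frame spacing, ps (should satisfy `dt <= 0.0025 / D_r` to keep
#'   discretization bias negligible; the default pairing of D_r = 0.1 and
#'   dt = 0.01 does).
#' @param seed Integer RNG seed.
#' @return A [trajectory()]; sites named `A1` (center) and `A2` (tip).
#' @export
gen_rotor <- function(n, n_frames, cell, D_r, bond_length = 1, dt = 0.01,
                      seed) {
  if (D_r < 0) stop("spec error: D_r must be >= 0")
  set.seed(seed)
  L <- unclass(cell)
  centers <- sweep(matrix(stats::runif(n * 3), ncol = 3), 2, L, "*")
  # random initial axes, uniform on the sphere
  ax <- matrix(stats::rnorm(n * 3), ncol = 3)
  ax <- ax / sqrt(rowSums(ax^2))
  coords <- array(0, dim = c(2 * n, 3, n_frames))
  sd_kick <- sqrt(2 * D_r * dt)
  for (f in seq_len(n_frames)) {
    if (f > 1 && D_r > 0) {
      kick <- matrix(stats::rnorm(n * 3, sd = sd_kick), ncol = 3)
      kick <- kick - ax * rowSums(kick * ax)   # project to tangent plane
      ax <- ax + kick
      ax <- ax / sqrt(rowSums(ax^2))
    }
    coords[seq(1, 2 * n, 2), , f] <- centers
    coords[seq(2, 2 * n, 2), , f] <- centers + bond_length * ax
  }
  atoms <- tibble::tibble(
    element = rep("X", 2 * n),
    name = rep(c("A1", "A2"), n),
    charge = 0, lj_epsilon = 0, lj_sigma = 1,
    molecule_id = rep(seq_len(n), each = 2),
    species = "ROT", role = "other")
  trajectory(topology(atoms), cell, dt * (seq_len(n_frames) - 1), coords,
             metadata = list(unwrapped = TRUE,
                             generator = list(kind = "rotor", D_r = D_r,
                                              bond_length = bond_length,
                                              seed = seed)))
}

#' Hydrogen-bonded dimer trajectory with an exact occupancy schedule
#'
#' Builds `n_pairs` donor(-H)/acceptor dimers on a sparse lattice. A logical
#' schedule matrix (frames x pairs) states when each pair is hydrogen
#' bonded: scheduled-on frames satisfy the given criteria by construction
#' (donor-acceptor distance drawn from a truncated normal inside the
#' distance window, D-H...A angle uniform inside the angle window);
#' scheduled-off frames place the acceptor at twice the maximum distance.
#' Downstream detection therefore recovers the schedule, counts and percent
#' occupancies exactly.
#'
#' @param schedule Logical matrix, `n_frames x n_pairs`.
#' @param criteria An [hbond_criteria()]; geometry is generated inside it.
#' @param d_mean,d_sd Mean/SD of the donor-acceptor distance draw, A
#'   (truncated to the criteria window).
#' @param dt Frame spacing, ps.
#' @param seed Integer RNG seed.
#' @return A [trajectory()]; metadata records the schedule.
#' @export
gen_hbond_dimers <- function(schedule, criteria = hbond_criteria("chloride"),
                             d_mean = NULL, d_sd = 0.05, dt = 1, seed) {
  if (!is.matrix(schedule)) schedule <- matrix(schedule, ncol = 1)
  set.seed(seed)
  nf <- nrow(schedule); np <- ncol(schedule)
  d_lo <- max(criteria$d_min, 1.2)   # keep acceptor off the hydrogen
  d_hi <- criteria$d_max
  if (is.null(d_mean)) d_mean <- (d_lo + d_hi) / 2
  spacing <- 4 * d_hi
  side <- ceiling(np^(1 / 3))
  cellL <- simulation_cell(rep(spacing * (side + 1), 3))
  grid <- as.matrix(expand.grid(seq_len(side), seq_len(side),
                                seq_len(side)))[seq_len(np), , drop = FALSE]
  origins <- grid * spacing
  coords <- array(0, dim = c(3 * np, 3, nf))
  for (p in seq_len(np)) {
    iD <- 3 * (p - 1) + 1; iH <- iD + 1; iA <- iD + 2
    for (f in seq_len(nf)) {
      O <- origins[p, ]
      coords[iD, , f] <- O
      coords[iH, , f] <- O + c(1, 0, 0)
      if (schedule[f, p]) {
        d <- rtruncnorm1(d_mean, d_sd, d_lo, d_hi)
        th <- stats::runif(1, criteria$angle_min, criteria$angle_max) * pi / 180
        # vertex at H: angle between H->D = (-1,0,0) and H->A
        rho <- cos(th) + sqrt(cos(th)^2 - 1 + d^2)
        coords[iA, , f] <- O + c(1, 0, 0) + rho * c(-cos(th), sin(th), 0)
      } else {
        coords[iA, , f] <- O + c(2 * d_hi + 1, 0, 0)
      }
    }
  }
  atoms <- tibble::tibble(
    element = rep(c("O", "H", "O"), np),
    name = rep(c("OD", "HD", "OA"), np),
    charge = 0, lj_epsilon = 0, lj_sigma = 1,
    molecule_id = c(t(cbind(2 * seq_len(np) - 1, 2 * seq_len(np) - 1,
                            2 * seq_len(np)))),
    species = rep(c("DON", "DON", "ACC"), np),
    role = rep(c("HBD", "HBD", "HBA"), np))
  trajectory(topology(atoms), cellL, dt * (seq_len(nf) - 1), coords,
             metadata = list(unwrapped = TRUE,
                             generator = list(kind = "hbond_dimers",
                                              schedule = schedule,
                                              criteria = criteria,
                                              d_mean = d_mean, d_sd = d_sd,
                                              seed = seed)))
}

rtruncnorm1 <- function(mean, sd, lo, hi) {
  repeat {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lo && x <= hi) return(x)
  }
}

# built-in rigid site templates for the toy mixture (offsets in A)
.species_templates <- list(
  cation = list(role = "HBA", sites = tibble::tibble(
    element = "N", name = "N1", charge = 1, lj_epsilon = 0.17, lj_sigma = 3.25,
    dx = 0, dy = 0, dz = 0)),
  anion = list(role = "HBA", sites = tibble::tibble(
    element = "Cl", name = "CLA", charge = -1, lj_epsilon = 0.15,
    lj_sigma = 4.04, dx = 0, dy = 0, dz = 0)),
  donor = list(role = "HBD", sites = tibble::tibble(
    element = c("C", "O", "H"), name = c("C1", "O1", "HA"),
    charge = c(0.3, -0.55, 0.25), lj_epsilon = c(0.07, 0.21, 0.046),
    lj_sigma = c(3.55, 2.96, 0.4),
    dx = c(0, 1.2, 2.1), dy = 0, dz = 0)),
  water = list(role = "water", sites = tibble::tibble(
    element = c("O", "H", "H"), name = c("OW", "HW1", "HW2"),
    charge = c(-0.834, 0.417, 0.417), lj_epsilon = c(0.1521, 0.046, 0.046),
    lj_sigma = c(3.1507, 0.4, 0.4),
    dx = c(0, 0.9572, -0.24), dy = c(0, 0, 0.9266), dz = 0))
)

#' Toy DES/water mixture with hard-core exclusion
#'
#' Places rigid template molecules (single-site cation/anion, a three-site
#' carboxylic-donor caricature, three-site water) uniformly in the cell by
#' rejection sampling so that no two molecular centers come closer than
#' `exclusion`. Species labels, roles, charges and Lennard-Jones parameters
#' are filled from the templates; composition is exactly as requested and
#' the net charge is the sum of species charges.
#'
#' @param counts Named integer vector over templates
#'   `c(cation=, anion=, donor=, water=)` (any subset).
#' @param cell A [simulation_cell()].
#' @param n_frames Number of frames (identical molecular positions each
#'   frame unless `jitter > 0`).
#' @param exclusion Minimum center-center distance, A.
#' @param jitter Per-frame Gaussian positional jitter SD, A (default 0).
#' @param dt Frame spacing, ps.
#' @param seed Integer RNG seed.
#' @param max_tries Rejection budget per molecule before a packing error.
#' @return A [trajectory()] (its `$topology` carries groups per species and
#'   role).
#' @export
gen_toy_mixture <- function(counts, cell, n_frames = 2, exclusion = 2,
                            jitter = 0, dt = 1, seed, max_tries = 2000) {
  bad <- setdiff(names(counts), names(.species_templates))
  if (length(bad)) stop("unknown species template(s): ",
                        paste(bad, collapse = ", "))
  set.seed(seed)
  L <- unclass(cell)
  nmol <- sum(counts)
  centers <- matrix(0, nmol, 3)
  placed <- 0L
  for (m in seq_len(nmol)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      cand <- stats::runif(3) * L
      if (placed == 0L) { ok <- TRUE; break }
      d <- min_image_displacement(centers[seq_len(placed), , drop = FALSE],
                                  matrix(cand, placed, 3, byrow = TRUE),
                                  cell)$distance
      if (min(d) >= exclusion) { ok <- TRUE; break }
    }
    if (!ok) stop("packing error: rejection budget exhausted at molecule ", m)
    placed <- placed + 1L
    centers[m, ] <- cand
  }
  species_of_mol <- rep(names(counts), counts)
  atoms_list <- list(); pos_list <- list()
  for (m in seq_len(nmol)) {
    tpl <- .species_templates[[species_of_mol[m]]]
    s <- tpl$sites
    atoms_list[[m]] <- tibble::tibble(
      element = s$element, name = s$name, charge = s$charge,
      lj_epsilon = s$lj_epsilon, lj_sigma = s$lj_sigma,
      molecule_id = m, species = toupper(species_of_mol[m]), role = tpl$role)
    pos_list[[m]] <- cbind(s$dx, s$dy, s$dz) +
      matrix(centers[m, ], nrow(s), 3, byrow = TRUE)
  }
  atoms <- dplyr::bind_rows(atoms_list)
  base <- do.call(rbind, pos_list)
  n <- nrow(base)
  coords <- array(0, dim = c(n, 3, n_frames))
  for (f in seq_len(n_frames)) {
    coords[, , f] <- base +
      if (jitter > 0) matrix(stats::rnorm(n * 3, sd = jitter), ncol = 3) else 0
  }
  trajectory(topology(atoms), cell, dt * (seq_len(n_frames) - 1), coords,
             metadata = list(unwrapped = TRUE,
                             generator = list(kind = "toy_mixture",
                                              counts = counts,
                                              exclusion = exclusion,
                                              centers = centers,
                                              seed = seed)))
}

#' Biphasic slab: a DES box and a water box joined along z
#'
#' Emulates an interface setup: two sub-boxes with identical x,y edges are
#' stacked along z (DES phase at low z, water phase at high z), giving a
#' rectangular cell whose z edge is the sum of the sub-box z edges. At frame
#' 0 the species centroids of the two phases are separated by at least a
#' quarter of the z edge by construction.
#'
#' @param des_counts,water_counts Named count vectors as in
#'   [gen_toy_mixture()] for the two phases (water phase may be empty).
#' @param sub_cell A [simulation_cell()] for each sub-box (both identical).
#' @param n_frames,exclusion,jitter,dt,seed As in [gen_toy_mixture()].
#' @return A [trajectory()] with cell `(Lx, Ly, 2 Lz)`.
#' @export
gen_biphasic_slab <- function(des_counts, water_counts, sub_cell,
                              n_frames = 2, exclusion = 2, jitter = 0,
                              dt = 1, seed) {
  L <- unclass(sub_cell)
  full <- simulation_cell(c(L[1], L[2], 2 * L[3]))
  des <- gen_toy_mixture(des_counts, sub_cell, n_frames, exclusion, jitter,
                         dt, seed = seed)
  have_water <- sum(water_counts) > 0
  if (have_water) {
    wat <- gen_toy_mixture(water_counts, sub_cell, n_frames, exclusion,
                           jitter, dt, seed = seed + 1)
    wc <- wat$coords
    wc[, 3, ] <- wc[, 3, ] + L[3]
    wat_atoms <- wat$topology$atoms
    wat_atoms$molecule_id <- wat_atoms$molecule_id +
      max(des$topology$atoms$molecule_id)
    atoms <- dplyr::bind_rows(des$topology$atoms, wat_atoms)
    coords <- array(0, dim = c(nrow(atoms), 3, n_frames))
    coords[seq_len(dim(des$coords)[1]), , ] <- des$coords
    coords[-seq_len(dim(des$coords)[1]), , ] <- wc
  } else {
    atoms <- des$topology$atoms
    coords <- des$coords
  }
  trajectory(topology(atoms), full, dt * (seq_len(n_frames) - 1), coords,
             metadata = list(unwrapped = TRUE,
                             generator = list(kind = "biphasic_slab",
                                              des_counts = des_counts,
                                              water_counts = water_counts,
                                              seed = seed)))
}

#' Ornstein-Uhlenbeck stress-tensor series with known autocorrelation
#'
#' Three independent stationary OU components (pxy, pxz, pyz) whose
#' autocovariance is `C0 * exp(-t / tau_c)`; the exact Green-Kubo integral
#' is therefore `V * C0 * tau_c / (k_B T)`.
#'
#' @param n_steps Series length.
#' @param dt Sampling interval, ps.
#' @param C0 Stationary variance (internal stress units squared).
#' @param tau_c Correlation time, ps (> 0).
#' @param seed Integer RNG seed.
#' @return Tibble `time, pxy, pxz, pyz` with attributes `units` and
#'   `generator` (the ground truth).
#' @export
gen_ou_stress <- function(n_steps, dt, C0, tau_c, seed) {
  if (tau_c <= 0) stop("spec error: tau_c must be positive")
  set.seed(seed)
  decay <- exp(-dt / tau_c)
  noise_sd <- sqrt(C0 * (1 - decay^2))
  comp <- function() {
    x <- numeric(n_steps)
    x[1] <- stats::rnorm(1, sd = sqrt(C0))
    innov <- stats::rnorm(n_steps - 1, sd = noise_sd)
    for (i in 2:n_steps) x[i] <- x[i - 1] * decay + innov[i - 1]
    x
  }
  out <- tibble::tibble(time = dt * (seq_len(n_steps) - 1),
                        pxy = comp(), pxz = comp(), pyz = comp())
  attr(out, "units") <- "internal"
  attr(out, "generator") <- list(kind = "ou_stress", C0 = C0, tau_c = tau_c,
                                 dt = dt, seed = seed)
  out
}
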