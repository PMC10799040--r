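cell50 <- simulation_cell(c(50, 50, 50))

ballistic_traj <- function(v = c(1, 0, 0), n_frames = 50, dt = 0.1) {
  coords <- array(0, dim = c(1, 3, n_frames))
  for (f in seq_len(n_frames)) coords[1, , f] <- c(25, 25, 25) + (f - 1) * dt * v
  trajectory(deswater:::point_topology(1), cell50,
             dt * (seq_len(n_frames) - 1), coords,
             metadata = list(unwrapped = TRUE))
}

test_that("MSD is exact for ballistic and static motion", {
  tr <- ballistic_traj()
  msd <- compute_msd(tr)
  expect_equal(msd$value, msd$lag^2, tolerance = 1e-10)
  expect_equal(msd$value[1], 0)
  static <- static_traj(matrix(25, 3, 3), cell50, n_frames = 20)
  expect_lt(max(abs(compute_msd(static)$value)), 1e-9)
})

test_that("FFT MSD equals the O(T^2) double-loop oracle", {
  set.seed(51)
  tr <- gen_brownian(5, 50, cell50, D = 0.5, dt = 0.1, seed = 52)
  msd <- compute_msd(tr, max_lag_fraction = 0.5)
  ora <- matrix(0, 26, 5)
  for (m in 1:5) {
    ora[, m] <- oracle_msd(t(tr$coords[m, , ]), 25)
  }
  expect_equal(msd$value[-1], rowMeans(ora)[-1], tolerance = 1e-9)
  expect_equal(msd$n_origins, 50 - 0:25)
})

test_that("MSD refuses wrapped positions unless unwrapping is requested", {
  tr <- gen_brownian(5, 50, cell50, D = 0.5, dt = 0.1, seed = 53,
                     wrapped = TRUE)
  expect_error(compute_msd(tr), "wrapped")
  ref <- gen_brownian(5, 50, cell50, D = 0.5, dt = 0.1, seed = 53)
  msd_w <- compute_msd(tr, unwrap = TRUE)
  msd_u <- compute_msd(ref)
  expect_equal(msd_w$value, msd_u$value, tolerance = 1e-9)
})

test_that("beta identifies ballistic, diffusive and crossover regimes", {
  lag <- seq(0, 100, by = 0.05)
  mk_msd <- function(value) {
    out <- tibble::tibble(lag = lag, value = value, n_origins = 1)
    class(out) <- c("correlation_result", class(out))
    attr(out, "kind") <- "msd"
    out
  }
  b2 <- compute_beta(mk_msd(lag^2))
  expect_true(all(abs(b2$value - 2) < 1e-8))
  b1 <- compute_beta(mk_msd(6 * 1 * lag))
  expect_true(all(abs(b1$value - 1) < 1e-8))
  # crossover MSD = tau^2/(1+tau): beta = 2 - tau/(1+tau)
  bc <- compute_beta(mk_msd(lag^2 / (1 + lag)))
  expect_lt(max(abs(bc$value - (2 - bc$lag / (1 + bc$lag)))), 0.02)
  expect_error(compute_beta(mk_msd(lag - 50)), "domain|positive")
})

test_that("diffusion fit is exact on MSD = 6 tau and errors on ballistic", {
  lag <- seq(0, 50, by = 0.1)
  msd <- tibble::tibble(lag = lag, value = 6 * lag, n_origins = 1)
  class(msd) <- c("correlation_result", class(msd))
  fit <- fit_diffusion(msd)
  expect_equal(fit$D_A2_per_ps, 1, tolerance = 1e-9)
  expect_equal(fit$D_s, 1000, tolerance = 1e-6)
  expect_false(fit$fallback)
  bal <- tibble::tibble(lag = lag, value = lag^2 + 1e-12, n_origins = 1)
  class(bal) <- c("correlation_result", class(bal))
  expect_error(fit_diffusion(bal, allow_fallback = FALSE), "regime")
  fb <- fit_diffusion(bal, allow_fallback = TRUE)
  expect_true(fb$fallback)
})

test_that("diffusion fit recovers the Brownian generator's D within 5%", {
  tr <- gen_brownian(500, 2000, cell50, D = 1, dt = 0.01, seed = 54)
  msd <- compute_msd(tr)
  fit <- fit_diffusion(msd)
  expect_equal(fit$D_s, 1000, tolerance = 0.05)
  expect_false(fit$fallback)
  expect_equal(fit$beta_window, 1, tolerance = 0.1)
})

test_that("VACF is 1 for constant velocities and matches the direct sum", {
  coords <- array(0, dim = c(2, 3, 30))
  vel <- array(0, dim = c(2, 3, 30))
  vel[1, 1, ] <- 1; vel[2, 2, ] <- -2
  for (f in 2:30) coords[, , f] <- coords[, , f - 1] + 0.1 * vel[, , f]
  tr <- trajectory(deswater:::point_topology(2), cell50, 0.1 * (0:29),
                   coords, vel, metadata = list(unwrapped = TRUE))
  v <- compute_vacf(tr)
  expect_equal(v$value, rep(1, nrow(v)), tolerance = 1e-12)
  # FFT path vs direct sum on a Langevin fixture
  tl <- gen_langevin(3, 100, cell50, gamma = 1, temperature = 300, mass = 18,
                     dt = 0.01, seed = 55)
  got <- compute_vacf(tl)
  S <- numeric(51)
  for (m in 1:3) S <- S + oracle_corr(t(tl$velocities[m, , ]), 50)
  exp_c <- (S / (100 - 0:50)) / (S[1] / 100)
  expect_equal(got$value, exp_c, tolerance = 1e-10)
  expect_error(compute_vacf(ballistic_traj()), "velocities")
})

test_that("Langevin VACF decays as exp(-gamma tau)", {
  tr <- gen_langevin(800, 1500, cell50, gamma = 2, temperature = 353,
                     mass = 18, dt = 0.01, seed = 56)
  v <- compute_vacf(tr)
  sel <- v$lag <= 2
  expect_lt(max(abs(v$value[sel] - exp(-2 * v$lag[sel]))), 0.05)
})

test_that("VACF zero crossings are located by interpolation", {
  lag <- seq(0, 6, by = 0.01)
  vacf <- tibble::tibble(lag = lag, value = cos(lag), n_origins = 1)
  z <- vacf_zero_times(vacf)
  expect_equal(z$mean_collision_time, pi / 2, tolerance = 0.01)
  expect_equal(z$velocity_randomization_time, 3 * pi / 2, tolerance = 0.01)
  expect_true(all(z$found))
  mono <- tibble::tibble(lag = lag, value = exp(-lag), n_origins = 1)
  zm <- vacf_zero_times(mono)
  expect_false(zm$found["first"][[1]])
  expect_true(is.na(zm$mean_collision_time))
  # damped oscillator: first zero where cos(2t) = 0
  osc <- tibble::tibble(lag = lag, value = exp(-lag) * cos(2 * lag),
                        n_origins = 1)
  expect_equal(vacf_zero_times(osc)$mean_collision_time, pi / 4,
               tolerance = 0.01)
})

test_that("VRD is 1 for a frozen rotor and matches the double loop", {
  tr <- gen_rotor(4, 40, cell50, D_r = 0.3, dt = 0.01, seed = 57)
  got <- compute_vrd(tr, seq(1, 8, 2), seq(2, 8, 2))
  S <- numeric(40)
  for (m in 1:4) {
    u <- t(tr$coords[2 * m, , ] - tr$coords[2 * m - 1, , ])
    u <- u / sqrt(rowSums(u^2))
    S <- S + oracle_corr(u, 39)
  }
  exp_v <- S[1:21] / (4 * (40 - 0:20))
  expect_equal(got$value[-1], exp_v[-1], tolerance = 1e-10)
  expect_equal(got$value[1], 1)
})

test_that("rotor VRD decay rate recovers 2 D_r within 10%", {
  tr <- gen_rotor(400, 800, cell50, D_r = 0.1, dt = 0.01, seed = 58)
  v <- compute_vrd(tr, seq(1, 800, 2), seq(2, 800, 2))
  sel <- v$value > 0.2 & v$lag > 0
  rate <- -coef(lm(log(v$value[sel]) ~ v$lag[sel]))[[2]]
  expect_equal(rate, 0.2, tolerance = 0.1)
})
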