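# Time-correlation estimators: MSD / anomalous exponent / self-diffusion,
# velocity autocorrelation with zero-crossing times, and bond-vector
# reorientation. All multi-origin sums use FFT correlation; the direct
# double-loop equivalents exist in the test suite as oracles.

# per-column multi-origin correlation sums S(tau) = sum_t x(t) x(t+tau)
corr_sums_fft <- function(X) {
  X <- as.matrix(X)
  T_ <- nrow(X)
  n2 <- stats::nextn(2 * T_, 2)
  pad <- rbind(X, matrix(0, n2 - T_, ncol(X)))
  F <- stats::mvfft(pad)
  S <- Re(stats::mvfft(F * Conj(F), inverse = TRUE)) / n2
  S[seq_len(T_), , drop = FALSE]
}

# resolve a molecule selection: species/role/group name or atom indices ->
# list of atom-index vectors, one per molecule
molecule_members <- function(top, group) {
  idx <- resolve_group(top, group %||% seq_len(n_atoms(top)))
  mols <- unique(top$atoms$molecule_id[idx])
  lapply(mols, function(m) which(top$atoms$molecule_id == m))
}

# unwrapped per-molecule COM coordinates, T x 3 per molecule
com_series <- function(traj, group, unwrap = FALSE) {
  unwrapped <- isTRUE(traj$metadata$unwrapped)
  coords <- traj$coords
  if (!unwrapped) {
    if (!unwrap) {
      stop("state error: positions are wrapped; call with unwrap = TRUE")
    }
    coords <- unwrap_coords(coords, traj$cell)
  }
  members <- molecule_members(traj$topology, group)
  mass <- element_mass(traj$topology$atoms$element)
  nf <- dim(coords)[3]
  L <- unclass(traj$cell)
  lapply(members, function(idx) {
    if (length(idx) > 1) {
      # make intramolecular geometry minimum-image consistent at frame 1 and
      # carry the same image shift through the whole (unwrapped) series
      ref <- coords[idx[1], , 1]
      raw <- coords[idx, , 1, drop = TRUE] -
        matrix(ref, length(idx), 3, byrow = TRUE)
      shift <- sweep_min_image(raw, L) - raw
    } else {
      shift <- matrix(0, 1, 3)
    }
    m <- mass[idx]
    out <- matrix(0, nf, 3)
    for (f in seq_len(nf)) {
      p <- coords[idx, , f, drop = FALSE]
      dim(p) <- c(length(idx), 3)
      out[f, ] <- colSums((p + shift) * m) / sum(m)
    }
    out
  })
}

# frame-to-frame minimum-image unwrapping of an n x 3 x T array
unwrap_coords <- function(coords, cell) {
  L <- unclass(cell)
  nf <- dim(coords)[3]
  out <- coords
  half <- min(L) / 2
  for (f in 2:nf) {
    d <- out[, , f, drop = TRUE] - out[, , f - 1, drop = TRUE]
    dim(d) <- c(dim(coords)[1], 3)
    d <- sweep_min_image(d, L)
    if (max(abs(d)) >= half) {
      stop("unwrapping failed: per-step displacement exceeds half the box")
    }
    out[, , f] <- out[, , f - 1, drop = TRUE] + d
  }
  out
}

#' Mean squared displacement of molecular centers of mass
#'
#' MSD(tau) averaged over all molecules of the selection and all time
#' origins (FFT algorithm). Positions must be unwrapped
#' (`metadata$unwrapped`); otherwise set `unwrap = TRUE` to apply
#' frame-to-frame minimum-image unwrapping.
#'
#' @param traj A [trajectory()].
#' @param group Molecule selection: a topology group/species name, atom
#'   indices, or NULL for all molecules.
#' @param max_lag_fraction Largest lag as a fraction of the trajectory
#'   length (default 0.5).
#' @param unwrap Unwrap wrapped coordinates first (default FALSE).
#' @return Tibble of class `correlation_result`: `lag` (ps), `value`
#'   (MSD, A^2), `n_origins`; attribute `kind = "msd"`.
#' @export
compute_msd <- function(traj, group = NULL, max_lag_fraction = 0.5,
                        unwrap = FALSE) {
  coms <- com_series(traj, group, unwrap)
  nf <- nrow(coms[[1]])
  max_lag <- max(2L, as.integer(floor(max_lag_fraction * nf)))
  msd <- numeric(max_lag + 1)
  for (r in coms) {
    S <- corr_sums_fft(r)                       # T x 3
    D <- rowSums(r * r)
    # S1 recursion: sum_t (D(t) + D(t+tau)) for t = 1..T-tau
    S1 <- numeric(nf)
    S1[1] <- 2 * sum(D)
    for (tau in seq_len(nf - 1)) {
      S1[tau + 1] <- S1[tau] - D[tau] - D[nf - tau + 1]
    }
    msd_r <- (S1 - 2 * rowSums(S)) / (nf - (seq_len(nf) - 1))
    msd <- msd + msd_r[seq_len(max_lag + 1)]
  }
  msd <- msd / length(coms)
  msd[1] <- 0   # exact by definition
  dt <- frame_dt(traj)
  out <- tibble::tibble(lag = dt * (0:max_lag), value = msd,
                        n_origins = nf - (0:max_lag))
  class(out) <- c("correlation_result", class(out))
  attr(out, "kind") <- "msd"
  attr(out, "units") <- "A^2"
  out
}

#' Anomalous-diffusion exponent beta(tau) from an MSD curve
#'
#' beta = d log10 MSD / d log10 tau, evaluated by centered finite
#' differences on a log-spaced resampling of the curve (linear
#' interpolation in log-log space) with moving-average smoothing. beta = 2
#' marks the inertial (ballistic) regime, beta = 1 the diffusive regime,
#' beta < 1 sub-diffusion.
#'
#' @param msd A `correlation_result` from [compute_msd()].
#' @param points_per_decade Resampling density (default 25).
#' @param smooth_window Moving-average window on beta, points (default 5).
#' @return Tibble of class `correlation_result` (`kind = "beta"`): `lag`
#'   (ps), `value` (beta).
#' @export
compute_beta <- function(msd, points_per_decade = 25, smooth_window = 5) {
  keep <- msd$lag > 0
  lag <- msd$lag[keep]; val <- msd$value[keep]
  if (any(val <= 0)) stop("domain error: MSD must be positive beyond lag 0")
  lx <- log10(lag); ly <- log10(val)
  n_pts <- max(5, ceiling((max(lx) - min(lx)) * points_per_decade))
  gx <- seq(min(lx), max(lx), length.out = n_pts)
  gy <- stats::approx(lx, ly, xout = gx)$y
  beta <- numeric(n_pts)
  beta[2:(n_pts - 1)] <- (gy[3:n_pts] - gy[1:(n_pts - 2)]) /
    (gx[3:n_pts] - gx[1:(n_pts - 2)])
  beta[1] <- (gy[2] - gy[1]) / (gx[2] - gx[1])
  beta[n_pts] <- (gy[n_pts] - gy[n_pts - 1]) / (gx[n_pts] - gx[n_pts - 1])
  if (smooth_window > 1) {
    sm <- stats::filter(beta, rep(1 / smooth_window, smooth_window),
                        sides = 2)
    beta <- ifelse(is.na(sm), beta, as.numeric(sm))
  }
  out <- tibble::tibble(lag = 10^gx, value = beta)
  class(out) <- c("correlation_result", class(out))
  attr(out, "kind") <- "beta"
  out
}

#' Einstein self-diffusion coefficient from the diffusive MSD window
#'
#' Finds the longest contiguous run of lags with |beta - 1| <=
#' `beta_tolerance`, fits MSD = 6 D tau + b over that window by weighted
#' least squares (weights `n_origins / lag^2`, the approximate inverse
#' variance of a multi-origin MSD estimate, so the well-averaged short-lag
#' end of the window dominates), and reports D_s = slope / 6 in A^2/ns
#' (1 A^2/ps = 1000 A^2/ns).
#' If no window qualifies, the last 20 percent of lags is used and flagged
#' (`fallback = TRUE`), unless `allow_fallback = FALSE`, in which case a
#' regime error is raised.
#'
#' @param msd A `correlation_result` from [compute_msd()].
#' @param beta_tolerance Width of the diffusive-regime test (default 0.1).
#' @param allow_fallback Permit the last-20-percent fallback window.
#' @return Object of class `diffusion_fit`: `D_s` (A^2/ns), `D_A2_per_ps`,
#'   `window` (ps), `beta_window` (mean beta over the window), `se_D`
#'   (A^2/ns), `fallback`.
#' @export
fit_diffusion <- function(msd, beta_tolerance = 0.1, allow_fallback = TRUE) {
  beta <- compute_beta(msd)
  ok <- abs(beta$value - 1) <= beta_tolerance
  runs <- rle(ok)
  fallback <- FALSE
  if (any(runs$values)) {
    best <- which.max(ifelse(runs$values, runs$lengths, 0))
    ends <- cumsum(runs$lengths)
    i2 <- ends[best]; i1 <- ends[best] - runs$lengths[best] + 1
    lo <- beta$lag[i1]; hi <- beta$lag[i2]
  } else if (allow_fallback) {
    fallback <- TRUE
    lo <- stats::quantile(msd$lag[msd$lag > 0], 0.8)
    hi <- max(msd$lag)
  } else {
    stop("regime error: no window with |beta - 1| <= ", beta_tolerance)
  }
  win <- msd$lag >= lo - 1e-12 & msd$lag <= hi + 1e-12 & msd$lag > 0
  wdat <- msd[win, ]
  w <- if ("n_origins" %in% names(wdat)) {
    wdat$n_origins / wdat$lag^2
  } else {
    1 / wdat$lag^2
  }
  fit <- stats::lm(value ~ lag, data = wdat, weights = w / mean(w))
  slope <- unname(stats::coef(fit)["lag"])
  se <- tryCatch(
    suppressWarnings(summary(fit)$coefficients["lag", "Std. Error"]),
    error = function(e) NA_real_)
  bw <- beta$value[beta$lag >= lo - 1e-12 & beta$lag <= hi + 1e-12]
  structure(list(D_s = 1000 * slope / 6, D_A2_per_ps = slope / 6,
                 window = c(lo, hi), beta_window = mean(bw),
                 se_D = 1000 * se / 6, fallback = fallback),
            class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf(
    "<diffusion_fit> D_s = %.4g A^2/ns (window %.3g-%.3g ps, beta ~ %.3f%s)\n",
    x$D_s, x$window[1], x$window[2], x$beta_window,
    if (x$fallback) ", fallback window" else ""))
  invisible(x)
}

#' @export
tidy.diffusion_fit <- function(x, ...) {
  tibble::tibble(term = "D_s", estimate = x$D_s, std.error = x$se_D,
                 units = "A^2/ns")
}

#' @export
glance.diffusion_fit <- function(x, ...) {
  tibble::tibble(window_lo = x$window[1], window_hi = x$window[2],
                 beta_window = x$beta_window, fallback = x$fallback)
}

#' Normalized velocity autocorrelation function
#'
#' C(tau) = <v_i(t) . v_i(t + tau)> / <v_i(t) . v_i(t)> over molecular
#' center-of-mass velocities, averaged over molecules and all time origins
#' (FFT). C(0) = 1 exactly.
#'
#' @param traj A [trajectory()] with velocities.
#' @param group Molecule selection as in [compute_msd()].
#' @param max_lag_fraction Largest lag as a fraction of the length.
#' @return Tibble of class `correlation_result` (`kind = "vacf"`).
#' @export
compute_vacf <- function(traj, group = NULL, max_lag_fraction = 0.5) {
  if (is.null(traj$velocities)) {
    stop("state error: trajectory has no velocities")
  }
  members <- molecule_members(traj$topology, group)
  mass <- element_mass(traj$topology$atoms$element)
  nf <- n_frames(traj)
  max_lag <- max(2L, as.integer(floor(max_lag_fraction * nf)))
  S_tot <- numeric(nf)
  for (idx in members) {
    m <- mass[idx]
    v <- matrix(0, nf, 3)
    for (f in seq_len(nf)) {
      vv <- traj$velocities[idx, , f, drop = FALSE]
      dim(vv) <- c(length(idx), 3)
      v[f, ] <- colSums(vv * m) / sum(m)
    }
    S_tot <- S_tot + rowSums(corr_sums_fft(v))
  }
  n_org <- nf - (0:max_lag)
  C <- (S_tot[seq_len(max_lag + 1)] / n_org) / (S_tot[1] / nf)
  out <- tibble::tibble(lag = frame_dt(traj) * (0:max_lag), value = C,
                        n_origins = n_org)
  class(out) <- c("correlation_result", class(out))
  attr(out, "kind") <- "vacf"
  out
}

#' Zero-crossing times of a VACF
#'
#' The first zero of the normalized VACF estimates the mean collision time;
#' the second estimates the velocity-randomization time. Crossings are
#' located by linear interpolation between bracketing lags. A missing
#' crossing is reported as `NA` with `found = FALSE`, not an error.
#'
#' @param vacf A `correlation_result` from [compute_vacf()] (or any tibble
#'   with `lag`, `value`).
#' @return List: `mean_collision_time`, `velocity_randomization_time` (ps,
#'   or NA), `found` (logical 2-vector).
#' @export
vacf_zero_times <- function(vacf) {
  lag <- vacf$lag; v <- vacf$value
  sgn <- sign(v)
  cross <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  interp <- function(i) {
    lag[i] + (lag[i + 1] - lag[i]) * v[i] / (v[i] - v[i + 1])
  }
  t1 <- if (length(cross) >= 1) interp(cross[1]) else NA_real_
  t2 <- if (length(cross) >= 2) interp(cross[2]) else NA_real_
  list(mean_collision_time = t1, velocity_randomization_time = t2,
       found = c(first = !is.na(t1), second = !is.na(t2)))
}

#' Vector reorientation dynamics (first-rank bond-vector autocorrelation)
#'
#' For each molecule the unit vector from `site_a` to `site_b`
#' (minimum-imaged) is tracked and VRD(tau) = <u(t) . u(t + tau)> is
#' averaged over molecules and time origins, normalized so VRD(0) = 1. For
#' isotropic rotational diffusion with coefficient D_r this decays as
#' exp(-2 D_r tau).
#'
#' @param traj A [trajectory()].
#' @param site_a,site_b Equal-length atom-index vectors (one per molecule):
#'   tail and tip of the intramolecular vector (e.g. O and H of a hydroxyl).
#' @param max_lag_fraction Largest lag as a fraction of the length.
#' @return Tibble of class `correlation_result` (`kind = "vrd"`).
#' @export
compute_vrd <- function(traj, site_a, site_b, max_lag_fraction = 0.5) {
  stopifnot(length(site_a) == length(site_b))
  nf <- n_frames(traj)
  max_lag <- max(2L, as.integer(floor(max_lag_fraction * nf)))
  L <- unclass(traj$cell)
  S_tot <- numeric(nf)
  for (m in seq_along(site_a)) {
    u <- matrix(0, nf, 3)
    for (f in seq_len(nf)) {
      d <- sweep_min_image(rbind(traj$coords[site_b[m], , f] -
                                   traj$coords[site_a[m], , f]), L)
      nd <- sqrt(sum(d^2))
      if (nd < 1e-12) stop("geometry error: zero-length bond vector")
      u[f, ] <- d / nd
    }
    S_tot <- S_tot + rowSums(corr_sums_fft(u))
  }
  n_org <- nf - (0:max_lag)
  vrd <- S_tot[seq_len(max_lag + 1)] / (length(site_a) * n_org)
  vrd[1] <- 1   # unit vectors: exact
  out <- tibble::tibble(lag = frame_dt(traj) * (0:max_lag), value = vrd,
                        n_origins = n_org)
  class(out) <- c("correlation_result", class(out))
  attr(out, "kind") <- "vrd"
  out
}
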