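# Independent brute-force oracles used across the suite. Each one is a
# deliberately naive implementation kept independent of the package's
# vectorised/FFT code paths.

# minimum distance over all 27 periodic image translations
oracle_min_image_distance <- function(a, b, cell) {
  L <- unclass(cell)
  best <- Inf
  for (ix in -1:1) for (iy in -1:1) for (iz in -1:1) {
    d <- (b + c(ix, iy, iz) * L) - a
    best <- min(best, sqrt(sum(d^2)))
  }
  best
}

# O(n^2) neighbour pair list
oracle_pairs <- function(positions, group_a, group_b, cutoff, cell) {
  same <- identical(sort(group_a), sort(group_b))
  out <- NULL
  for (i in group_a) for (j in group_b) {
    if (i == j) next
    if (same && i >= j) next
    d <- oracle_min_image_distance(positions[i, ], positions[j, ], cell)
    if (d <= cutoff) out <- rbind(out, c(i, j, d))
  }
  if (is.null(out)) {
    return(tibble::tibble(i = integer(0), j = integer(0),
                          distance = numeric(0)))
  }
  tibble::tibble(i = as.integer(out[, 1]), j = as.integer(out[, 2]),
                 distance = out[, 3])
}

# direct double-loop RDF histogram (ordered pairs), same binning rule
oracle_rdf_counts <- function(positions, group_a, group_b, cell, r_max, dr,
                              mol_id = NULL, exclude_same_molecule = FALSE) {
  nbin <- round(r_max / dr)
  counts <- numeric(nbin)
  for (i in group_a) for (j in group_b) {
    if (i == j) next
    if (exclude_same_molecule && mol_id[i] == mol_id[j]) next
    d <- oracle_min_image_distance(positions[i, ], positions[j, ], cell)
    if (d < r_max) {
      k <- floor(d / dr) + 1
      counts[k] <- counts[k] + 1
    }
  }
  counts
}

# naive angle with explicit image search for each arm
oracle_angle <- function(a, v, c_, cell) {
  L <- unclass(cell)
  best_arm <- function(p) {
    best <- NULL; bd <- Inf
    for (ix in -1:1) for (iy in -1:1) for (iz in -1:1) {
      d <- (p + c(ix, iy, iz) * L) - v
      n <- sqrt(sum(d^2))
      if (n < bd) { bd <- n; best <- d }
    }
    best
  }
  u <- best_arm(a); w <- best_arm(c_)
  acos(max(-1, min(1, sum(u * w) / sqrt(sum(u^2) * sum(w^2))))) * 180 / pi
}

# triple-loop hydrogen-bond detector
oracle_hbonds <- function(positions, donor_map, acceptors, criteria, cell,
                          mol_id) {
  out <- NULL
  for (r in seq_len(nrow(donor_map))) {
    D <- donor_map$donor[r]; H <- donor_map$hydrogen[r]
    for (A in acceptors) {
      if (A == D || A == H) next
      if (mol_id[A] == mol_id[D]) next
      ref <- if (criteria$distance_definition == "donor_acceptor") D else H
      d <- oracle_min_image_distance(positions[ref, ], positions[A, ], cell)
      if (d < criteria$d_min || d > criteria$d_max) next
      ang <- oracle_angle(positions[D, ], positions[H, ], positions[A, ], cell)
      if (ang < criteria$angle_min || ang > criteria$angle_max) next
      out <- rbind(out, c(D, H, A, d, ang))
    }
  }
  if (is.null(out)) return(deswater:::empty_hbond_events())
  tibble::tibble(donor = as.integer(out[, 1]), hydrogen = as.integer(out[, 2]),
                 acceptor = as.integer(out[, 3]), distance = out[, 4],
                 angle = out[, 5])
}

# O(T^2) multi-origin MSD of one T x 3 coordinate matrix
oracle_msd <- function(r, max_lag) {
  T_ <- nrow(r)
  vapply(0:max_lag, function(tau) {
    s <- 0
    for (t in seq_len(T_ - tau)) {
      d <- r[t + tau, ] - r[t, ]
      s <- s + sum(d^2)
    }
    s / (T_ - tau)
  }, numeric(1))
}

# direct-sum correlation of a T x k matrix: sum over columns and origins
oracle_corr <- function(x, max_lag) {
  T_ <- nrow(x)
  vapply(0:max_lag, function(tau) {
    s <- 0
    for (t in seq_len(T_ - tau)) s <- s + sum(x[t, ] * x[t + tau, ])
    s
  }, numeric(1))
}

# minimal Gaussian cube reader (independent of write_cube)
oracle_read_cube <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[3]), "[[:space:]]+")[[1]]
  natoms <- as.integer(hdr[1])
  n <- as.integer(strsplit(trimws(lines[4]), "[[:space:]]+")[[1]][1])
  vals <- as.numeric(unlist(strsplit(trimws(
    lines[(7 + natoms):length(lines)]), "[[:space:]]+")))
  arr <- array(0, dim = c(n, n, n))
  k <- 1
  for (i in seq_len(n)) for (j in seq_len(n)) {
    arr[i, j, ] <- vals[k:(k + n - 1)]
    k <- k + n
  }
  arr
}

# small two-frame trajectory from explicit positions
static_traj <- function(positions, cell, n_frames = 2, top = NULL, dt = 1) {
  n <- nrow(positions)
  if (is.null(top)) top <- deswater:::point_topology(n)
  coords <- array(rep(positions, n_frames), dim = c(n, 3, n_frames))
  trajectory(top, cell, dt * (seq_len(n_frames) - 1), coords,
             metadata = list(unwrapped = TRUE))
}
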