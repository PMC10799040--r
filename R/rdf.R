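# Radial distribution functions and coordination numbers.
#
# g(r) per bin is the frame-averaged ordered pair count divided by
# N_a * 4 pi r^2 dr * rho_b with rho_b = N_b / V, so a homogeneous system
# tends to 1 at large r. Binning is half-open [left, right); distances at or
# beyond r_max are dropped.

# ordered-pair minimum-image distance histogram for one frame
frame_pair_hist <- function(pos, group_a, group_b, cell, r_max, dr,
                            mol_id = NULL, exclude_same_molecule = FALSE) {
  L <- unclass(cell)
  pa <- pos[group_a, , drop = FALSE]
  pb <- pos[group_b, , drop = FALSE]
  d2 <- matrix(0, nrow(pa), nrow(pb))
  for (k in 1:3) {
    dk <- outer(pa[, k], pb[, k], "-")
    dk <- dk - L[k] * round(dk / L[k])
    d2 <- d2 + dk * dk
  }
  # drop self pairs
  self <- outer(group_a, group_b, "==")
  d2[self] <- Inf
  if (exclude_same_molecule && !is.null(mol_id)) {
    same_mol <- outer(mol_id[group_a], mol_id[group_b], "==")
    d2[same_mol] <- Inf
  }
  d <- sqrt(d2[d2 < r_max^2])
  nbin <- as.integer(round(r_max / dr))
  tabulate(pmin(nbin, floor(d / dr) + 1L), nbins = nbin)
}

#' Radial distribution function between two atom groups
#'
#' @param traj A [trajectory()].
#' @param group_a,group_b Atom-index vectors, or names of topology groups
#'   (e.g. a species or role label).
#' @param r_max Histogram range, A; must be at most half the smallest cell
#'   edge. Default `min(12, half smallest edge)`.
#' @param dr Bin width, A (default 0.05).
#' @param exclude_same_molecule Drop pairs within one molecule (default
#'   TRUE; self pairs are always dropped).
#' @return A tibble of class `rdf_result` with columns `r` (bin centers, A)
#'   and `g`; attributes `density_b` (A^-3), `dr`, `n_frames`, `counts`
#'   (frame-summed raw pair counts), `n_a`, `n_b`, `groups`.
#' @export
compute_rdf <- function(traj, group_a, group_b,
                        r_max = NULL, dr = 0.05,
                        exclude_same_molecule = TRUE) {
  ga <- resolve_group(traj$topology, group_a)
  gb <- resolve_group(traj$topology, group_b)
  if (!length(ga) || !length(gb)) stop("selection error: empty atom group")
  if (is.null(r_max)) r_max <- min(12, cell_half_min(traj$cell))
  check_cutoff(r_max, traj$cell)
  if (dr <= 0) stop("dr must be positive")
  nf <- n_frames(traj)
  nbin <- as.integer(round(r_max / dr))
  counts <- numeric(nbin)
  mol <- traj$topology$atoms$molecule_id
  for (f in seq_len(nf)) {
    counts <- counts + frame_pair_hist(
      traj$coords[, , f, drop = TRUE], ga, gb, traj$cell, r_max, dr,
      mol, exclude_same_molecule)
  }
  centers <- (seq_len(nbin) - 0.5) * dr
  rho_b <- length(gb) / cell_volume(traj$cell)
  shell <- 4 * pi * centers^2 * dr
  g <- counts / (nf * length(ga) * shell * rho_b)
  out <- tibble::tibble(r = centers, g = g)
  class(out) <- c("rdf_result", class(out))
  attr(out, "density_b") <- rho_b
  attr(out, "dr") <- dr
  attr(out, "n_frames") <- nf
  attr(out, "counts") <- counts
  attr(out, "n_a") <- length(ga)
  attr(out, "n_b") <- length(gb)
  attr(out, "groups") <- c(label_of(group_a), label_of(group_b))
  out
}

resolve_group <- function(top, g) {
  if (is.character(g) && length(g) == 1) {
    if (!g %in% names(top$groups)) stop("no such group: ", g)
    top$groups[[g]]
  } else {
    as.integer(g)
  }
}

label_of <- function(g) {
  if (is.character(g) && length(g) == 1) g else sprintf("%d atoms", length(g))
}

#' First maximum and first minimum of an RDF
#'
#' Locates, on a moving-average-smoothed copy of the curve, the first local
#' maximum significantly above the bulk level g = 1 and the first
#' subsequent local minimum. The first minimum is the conventional
#' integration limit for coordination numbers.
#'
#' A candidate maximum must exceed 1 by at least `prominence`, and — when
#' the RDF carries raw pair counts (every RDF computed by this package
#' does) — by at least three estimated standard errors of the smoothed
#' curve. This keeps sparsely populated small-r bins, whose g estimate is
#' extremely noisy, from masquerading as structure.
#'
#' @param rdf An `rdf_result`.
#' @param window Moving-average window in bins (odd; default 5).
#' @param prominence Minimum excess over the bulk level (default 0.02).
#' @return List with `r_first_max`, `r_first_min` (bin centers, A);
#'   `r_first_min` may be `NA` when the curve never turns back up in range.
#' @export
find_first_extrema <- function(rdf, window = 5, prominence = 0.02) {
  if (nrow(rdf) < 10) stop("RDF must have at least 10 bins")
  g <- rdf$g
  n <- length(g)
  smooth_vec <- function(x) {
    if (window <= 1) return(x)
    sm <- stats::filter(x, rep(1 / window, window), sides = 2)
    half <- (window - 1) / 2
    sm[seq_len(half)] <- x[seq_len(half)]
    sm[(n - half + 1):n] <- x[(n - half + 1):n]
    as.numeric(sm)
  }
  g <- smooth_vec(rdf$g)
  # per-bin SE of smoothed g from Poisson pair counts, when available
  counts <- attr(rdf, "counts")
  se <- rep(0, n)
  if (!is.null(counts) && any(rdf$g > 0)) {
    norm <- ifelse(rdf$g > 0, counts / rdf$g, NA)
    if (anyNA(norm)) {
      ok <- !is.na(norm)
      norm[!ok] <- stats::approx(seq_len(n)[ok], norm[ok],
                                 xout = seq_len(n)[!ok], rule = 2)$y
    }
    var_bin <- 2 * (counts + 1) / norm^2
    se <- sqrt(smooth_vec(var_bin) / window)
  }
  i_max <- NA_integer_
  for (i in 2:(n - 1)) {
    if (g[i] >= 1 + max(prominence, 3 * se[i]) &&
        g[i] >= g[i - 1] && g[i] > g[i + 1]) { i_max <- i; break }
  }
  if (is.na(i_max)) {
    stop("featureless RDF: no significant local maximum above g = 1")
  }
  # first minimum: running minimum after the peak, accepted once the curve
  # has risen back above it by the significance threshold (a genuine
  # turning point, not a noise wiggle)
  i_min <- NA_integer_
  if (i_max < n) {
    run_i <- i_max + 1
    for (i in (i_max + 1):n) {
      if (g[i] < g[run_i]) run_i <- i
      if (g[i] >= g[run_i] + max(prominence, 3 * se[i])) {
        i_min <- run_i
        break
      }
    }
  }
  list(r_first_max = rdf$r[i_max],
       r_first_min = if (is.na(i_min)) NA_real_ else rdf$r[i_min])
}

#' Coordination number by RDF integration
#'
#' CN = 4 pi rho_b * integral of g(r) r^2 dr from 0 to `r_limit`
#' (trapezoidal rule on bin centers): the average number of b-group
#' neighbors within `r_limit` of an a-group site. By convention `r_limit`
#' is the first RDF minimum.
#'
#' @param rdf An `rdf_result`.
#' @param r_limit Integration limit, A. Default: first minimum from
#'   [find_first_extrema()].
#' @return Coordination number (dimensionless).
#' @export
coordination_number <- function(rdf, r_limit = NULL) {
  if (is.null(r_limit)) {
    r_limit <- find_first_extrema(rdf)$r_first_min
    if (is.na(r_limit)) stop("no first minimum found; supply r_limit")
  }
  if (r_limit > max(rdf$r) + attr(rdf, "dr") / 2 + 1e-9) {
    stop("range error: r_limit beyond RDF range")
  }
  keep <- rdf$r <= r_limit
  r <- rdf$r[keep]
  g <- rdf$g[keep]
  # close the quadrature at both ends: g r^2 -> 0 at r = 0, and the curve
  # is extended to r_limit by linear interpolation (constant beyond the
  # last center)
  if (r_limit > max(r)) {
    g_end <- if (sum(keep) < nrow(rdf)) {
      stats::approx(rdf$r, rdf$g, xout = r_limit, rule = 2)$y
    } else {
      g[length(g)]
    }
    r <- c(r, r_limit); g <- c(g, g_end)
  }
  r <- c(0, r); g <- c(0, g)
  rho_b <- attr(rdf, "density_b")
  4 * pi * rho_b * trapz(r, g * r^2)
}

trapz <- function(x, y) {
  if (length(x) < 2) return(0)
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Center-of-mass radial distribution function between species
#'
#' As [compute_rdf()] but between per-molecule centers of mass. The COM of
#' each molecule is assembled minimum-image-consistently: every atom is
#' unwrapped relative to the molecule's first atom before mass weighting,
#' then the COM is wrapped back into the cell. A molecule whose unwrapped
#' extent exceeds half the box is a geometry error.
#'
#' @param traj A [trajectory()].
#' @param species_a,species_b Species labels (topology groups).
#' @param r_max,dr As in [compute_rdf()].
#' @return An `rdf_result` over molecule COMs (same-molecule exclusion does
#'   not apply; distinct molecules only).
#' @export
compute_com_rdf <- function(traj, species_a, species_b,
                            r_max = NULL, dr = 0.05) {
  top <- traj$topology
  ga <- resolve_group(top, species_a)
  gb <- resolve_group(top, species_b)
  if (!length(ga) || !length(gb)) stop("selection error: empty species group")
  if (is.null(r_max)) r_max <- min(12, cell_half_min(traj$cell))
  check_cutoff(r_max, traj$cell)
  nf <- n_frames(traj)
  mol_a <- unique(top$atoms$molecule_id[ga])
  mol_b <- unique(top$atoms$molecule_id[gb])
  nbin <- as.integer(round(r_max / dr))
  counts <- numeric(nbin)
  for (f in seq_len(nf)) {
    pos <- traj$coords[, , f, drop = TRUE]
    coms <- molecule_coms(pos, top, traj$cell, union(mol_a, mol_b))
    ia <- match(mol_a, coms$mol)
    ib <- match(mol_b, coms$mol)
    counts <- counts + frame_pair_hist(
      coms$xyz, ia, ib, traj$cell, r_max, dr,
      mol_id = coms$mol, exclude_same_molecule = TRUE)
  }
  centers <- (seq_len(nbin) - 0.5) * dr
  rho_b <- length(mol_b) / cell_volume(traj$cell)
  g <- counts / (nf * length(mol_a) * 4 * pi * centers^2 * dr * rho_b)
  out <- tibble::tibble(r = centers, g = g)
  class(out) <- c("rdf_result", class(out))
  attr(out, "density_b") <- rho_b
  attr(out, "dr") <- dr
  attr(out, "n_frames") <- nf
  attr(out, "counts") <- counts
  attr(out, "n_a") <- length(mol_a)
  attr(out, "n_b") <- length(mol_b)
  attr(out, "groups") <- c(label_of(species_a), label_of(species_b))
  out
}

# minimum-image-consistent molecular centers of mass for one frame
molecule_coms <- function(pos, top, cell, mols = NULL) {
  mol_id <- top$atoms$molecule_id
  if (is.null(mols)) mols <- unique(mol_id)
  mass <- element_mass(top$atoms$element)
  L <- unclass(cell)
  xyz <- matrix(0, length(mols), 3)
  half <- cell_half_min(cell)
  for (i in seq_along(mols)) {
    idx <- which(mol_id == mols[i])
    ref <- pos[idx[1], ]
    d <- pos[idx, , drop = FALSE] -
      matrix(ref, length(idx), 3, byrow = TRUE)
    d <- sweep_min_image(d, L)
    if (length(idx) > 1 && max(sqrt(rowSums(d^2))) > half) {
      stop("geometry error: molecule ", mols[i],
           " spans more than half the box")
    }
    m <- mass[idx]
    com <- ref + colSums(d * m) / sum(m)
    xyz[i, ] <- com - L * floor(com / L)
  }
  list(mol = mols, xyz = xyz)
}
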