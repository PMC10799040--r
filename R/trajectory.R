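#' Construct a trajectory
#'
#' A trajectory bundles a [topology()], a [simulation_cell()] and a
#' time-ordered stack of frames. Coordinates (and optional velocities) are
#' stored as `n_atoms x 3 x n_frames` arrays. Frame times must be strictly
#' increasing with constant spacing (relative tolerance 1e-6), because all
#' correlation estimators assume a uniform time grid.
#'
#' @param top A [topology()].
#' @param cell A [simulation_cell()].
#' @param times Numeric vector of frame times, ps.
#' @param coords `n_atoms x 3 x n_frames` array of positions, A.
#' @param velocities Optional array of the same shape, A/ps.
#' @param metadata Named list; generators record their ground truth here.
#'   The logical entry `unwrapped` marks coordinates safe for direct MSD use.
#' @return Object of class `trajectory`.
#' @export
trajectory <- function(top, cell, times, coords, velocities = NULL,
                       metadata = list()) {
  stopifnot(inherits(top, "topology"), inherits(cell, "simulation_cell"))
  n <- n_atoms(top)
  if (length(dim(coords)) != 3 || dim(coords)[1] != n || dim(coords)[2] != 3) {
    stop("coords must be an n_atoms x 3 x n_frames array")
  }
  nf <- dim(coords)[3]
  if (nf < 2) stop("a trajectory needs at least 2 frames")
  if (length(times) != nf) stop("times length must equal number of frames")
  dt <- diff(times)
  if (any(dt <= 0)) stop("frame times must be strictly increasing")
  if (nf > 2 && (max(dt) - min(dt)) > 1e-6 * max(abs(dt))) {
    stop("frame spacing must be constant (relative tolerance 1e-6)")
  }
  if (!is.null(velocities) && !all(dim(velocities) == dim(coords))) {
    stop("velocities must have the same shape as coords")
  }
  structure(list(topology = top, cell = cell, times = as.numeric(times),
                 coords = coords, velocities = velocities,
                 metadata = metadata),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "<trajectory> %d atoms, %d frames, dt = %.6g ps, cell %.6g x %.6g x %.6g A%s\n",
    n_atoms(x$topology), n_frames(x), frame_dt(x),
    x$cell[1], x$cell[2], x$cell[3],
    if (is.null(x$velocities)) "" else ", with velocities"))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A [trajectory()].
#' @return Integer frame count.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

frame_dt <- function(traj) traj$times[2] - traj$times[1]

#' Extract one frame
#' @param traj A [trajectory()].
#' @param i Frame index (1-based).
#' @return List with `time`, `positions` (n x 3), `velocities` (n x 3 or NULL).
#' @export
get_frame <- function(traj, i) {
  list(time = traj$times[i],
       positions = traj$coords[, , i, drop = TRUE],
       velocities = if (is.null(traj$velocities)) NULL
                    else traj$velocities[, , i, drop = TRUE])
}

# ---- extended XYZ ----------------------------------------------------------

#' Read an extended-XYZ trajectory
#'
#' Multi-frame XYZ with a comment line carrying
#' `Lattice="ax 0 0 0 by 0 0 0 cz"` and `Time=<ps>` per frame; columns are
#' `element x y z` with optional `vx vy vz`. The lattice is taken from the
#' first frame and must stay constant; non-orthorhombic lattices are
#' rejected.
#'
#' @param path Path to the file.
#' @param top The [topology()] describing the atoms (count must match).
#' @return A [trajectory()].
#' @export
read_extended_xyz <- function(path, top) {
  lines <- readLines(path)
  n <- n_atoms(top)
  pos <- 1L
  frames_xyz <- list(); frames_vel <- list(); times <- numeric(0)
  cell <- NULL
  fidx <- 0L
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos]))) { pos <- pos + 1L; next }
    fidx <- fidx + 1L
    natoms <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(natoms)) {
      stop(sprintf("format error in frame %d: bad atom-count line", fidx))
    }
    if (natoms != n) {
      stop(sprintf(
        "format error in frame %d: %d atoms in file, topology has %d",
        fidx, natoms, n))
    }
    comment <- lines[pos + 1L]
    this_cell <- parse_lattice(comment, fidx)
    if (is.null(cell)) cell <- this_cell
    else if (max(abs(unclass(this_cell) - unclass(cell))) > 1e-8) {
      stop(sprintf("cell changes at frame %d; constant cell required", fidx))
    }
    tm <- parse_time(comment)
    times <- c(times, if (is.na(tm)) fidx - 1 else tm)
    block <- lines[(pos + 2L):(pos + 1L + natoms)]
    m <- do.call(rbind, strsplit(trimws(block), "[[:space:]]+"))
    ncol_dat <- ncol(m) - 1L
    if (!ncol_dat %in% c(3L, 6L)) {
      stop(sprintf("format error in frame %d: expected 3 or 6 coordinate columns",
                   fidx))
    }
    xyz <- matrix(as.numeric(m[, 2:4]), ncol = 3)
    frames_xyz[[fidx]] <- xyz
    if (ncol_dat == 6L) frames_vel[[fidx]] <- matrix(as.numeric(m[, 5:7]), ncol = 3)
    pos <- pos + 2L + natoms
  }
  if (fidx < 2) stop("trajectory file has fewer than 2 frames: ", path)
  has_vel <- length(frames_vel) > 0
  if (has_vel && length(frames_vel) != fidx) {
    stop("velocities present for some frames but not all")
  }
  coords <- array(unlist(frames_xyz), dim = c(n, 3, fidx))
  vel <- if (has_vel) array(unlist(frames_vel), dim = c(n, 3, fidx)) else NULL
  trajectory(top, cell, times, coords, vel)
}

parse_lattice <- function(comment, fidx) {
  m <- regmatches(comment, regexpr('Lattice="[^"]*"', comment))
  if (!length(m)) {
    stop(sprintf("cell error in frame %d: missing Lattice entry", fidx))
  }
  vals <- as.numeric(strsplit(trimws(sub('Lattice="([^"]*)"', "\\1", m)),
                              "[[:space:]]+")[[1]])
  if (length(vals) != 9 || anyNA(vals)) {
    stop(sprintf("cell error in frame %d: Lattice needs 9 numbers", fidx))
  }
  off <- vals[c(2, 3, 4, 6, 7, 8)]
  if (any(abs(off) > 1e-8)) {
    stop(sprintf("unsupported cell in frame %d: lattice is not orthorhombic",
                 fidx))
  }
  simulation_cell(vals[c(1, 5, 9)])
}

parse_time <- function(comment) {
  m <- regmatches(comment, regexpr("Time=[-0-9.eE+]+", comment))
  if (!length(m)) return(NA_real_)
  as.numeric(sub("Time=", "", m))
}

#' Write an extended-XYZ trajectory
#'
#' Inverse of [read_extended_xyz()]; positions (and velocities, if present)
#' are written with 6 decimals and round-trip to that precision.
#'
#' @param traj A [trajectory()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_extended_xyz <- function(traj, path) {
  n <- n_atoms(traj$topology)
  L <- unclass(traj$cell)
  elements <- traj$topology$atoms$element
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(traj))) {
    writeLines(as.character(n), con)
    props <- if (is.null(traj$velocities)) {
      "Properties=species:S:1:pos:R:3"
    } else {
      "Properties=species:S:1:pos:R:3:vel:R:3"
    }
    writeLines(sprintf(
      'Lattice="%.8g 0 0 0 %.8g 0 0 0 %.8g" %s Time=%.8g',
      L[1], L[2], L[3], props, traj$times[f]), con)
    xyz <- traj$coords[, , f, drop = TRUE]
    if (is.null(traj$velocities)) {
      writeLines(sprintf("%s %.6f %.6f %.6f", elements,
                         xyz[, 1], xyz[, 2], xyz[, 3]), con)
    } else {
      v <- traj$velocities[, , f, drop = TRUE]
      writeLines(sprintf("%s %.6f %.6f %.6f %.6f %.6f %.6f", elements,
                         xyz[, 1], xyz[, 2], xyz[, 3],
                         v[, 1], v[, 2], v[, 3]), con)
    }
  }
  invisible(path)
}

# ---- PDB (read-only) -------------------------------------------------------

#' Read a (multi-model) PDB trajectory
#'
#' MODEL/ENDMDL blocks become frames; the cell is taken from the CRYST1
#' record, which must be orthorhombic (all angles 90 degrees). Atom parsing
#' is delegated to `bio3d::read.pdb`. PDB files carry no time axis, so frame
#' times are `0, dt, 2 dt, ...`.
#'
#' @param path Path to the PDB file.
#' @param top The [topology()] describing the atoms.
#' @param dt Frame spacing to assign, ps (default 1).
#' @return A [trajectory()].
#' @export
read_pdb_trajectory <- function(path, top, dt = 1) {
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    stop("PDB reading requires the bio3d package")
  }
  cryst <- grep("^CRYST1", readLines(path), value = TRUE)
  if (!length(cryst)) stop("PDB file has no CRYST1 record: ", path)
  fields <- as.numeric(c(substr(cryst[1], 7, 15), substr(cryst[1], 16, 24),
                         substr(cryst[1], 25, 33), substr(cryst[1], 34, 40),
                         substr(cryst[1], 41, 47), substr(cryst[1], 48, 54)))
  if (any(abs(fields[4:6] - 90) > 1e-3)) {
    stop("unsupported cell: PDB CRYST1 is not orthorhombic")
  }
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz                      # n_frames x 3n matrix
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n <- ncol(xyz) / 3
  if (n != n_atoms(top)) {
    stop(sprintf("format error: PDB has %d atoms, topology has %d",
                 n, n_atoms(top)))
  }
  nf <- nrow(xyz)
  coords <- array(0, dim = c(n, 3, nf))
  for (f in seq_len(nf)) {
    coords[, , f] <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
  }
  trajectory(top, simulation_cell(fields[1:3]),
             times = dt * (seq_len(nf) - 1), coords = coords)
}

# ---- stress time series ----------------------------------------------------

#' Read an off-diagonal stress-tensor time series
#'
#' CSV with header `time,pxy,pxz,pyz` (time in ps) and optionally a leading
#' comment line `# units: <tag>`. Row spacing must be constant (relative
#' tolerance 1e-6).
#'
#' @param path Path to the CSV file.
#' @return Tibble with columns `time`, `pxy`, `pxz`, `pyz`; attribute
#'   `units` carries the unit tag (`"internal"` if absent).
#' @export
read_stress_series <- function(path) {
  lines <- readLines(path, n = 1)
  units <- "internal"
  skip <- 0
  if (grepl("^#", lines[1])) {
    m <- regmatches(lines[1], regexpr("units:\\s*\\S+", lines[1]))
    if (length(m)) units <- sub("units:\\s*", "", m)
    skip <- 1
  }
  df <- utils::read.csv(path, skip = skip)
  req <- c("time", "pxy", "pxz", "pyz")
  if (!all(req %in% names(df))) {
    stop("stress CSV must have header time,pxy,pxz,pyz: ", path)
  }
  tm <- df$time
  if (length(tm) >= 3) {
    dt <- diff(tm)
    if (any(dt <= 0) || (max(dt) - min(dt)) > 1e-6 * max(abs(dt))) {
      stop("sampling error: stress series times not uniformly increasing")
    }
  } else if (length(tm) == 2 && diff(tm) <= 0) {
    stop("sampling error: stress series times not uniformly increasing")
  }
  out <- tibble::as_tibble(df[req])
  attr(out, "units") <- units
  out
}

#' Write a stress series CSV
#' @param stress Tibble as returned by [read_stress_series()] or
#'   [gen_ou_stress()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_stress_series <- function(stress, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# units: %s", attr(stress, "units") %||% "internal"), con)
  utils::write.csv(as.data.frame(stress)[c("time", "pxy", "pxz", "pyz")],
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
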