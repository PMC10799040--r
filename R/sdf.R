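# Spatial distribution functions: time-averaged 3-D density of a target
# species in the body-fixed frame of a reference molecule, normalized by the
# target's bulk density so that unstructured regions tend to 1.

#' Spatial distribution function on a voxel grid
#'
#' Each reference molecule defines a local orthonormal frame from three of
#' its atoms: the origin sits on atom 1, the x-axis points toward atom 2,
#' and atom 3 fixes the xz half-plane (positive z). Target atom positions
#' are rebased into every reference frame each trajectory frame
#' (minimum-image displacements from the origin atom) and accumulated on a
#' cubic voxel grid spanning \[-radius, radius\]^3. Voxel values are counts
#' divided by `n_frames * n_refs * voxel_volume * bulk_density(target)`.
#'
#' @param traj A [trajectory()].
#' @param ref_triad 3-column integer matrix (one row per reference molecule)
#'   of atom indices (origin, x-axis atom, plane atom).
#' @param target_group Atom-index vector or group name of the target
#'   species.
#' @param radius Half-extent of the grid, A.
#' @param voxel Voxel edge length, A.
#' @return Object of class `sdf_grid`: list with `density` (3-D array),
#'   `axis` (voxel-center coordinates along each axis), `voxel`, `radius`,
#'   `n_refs`, `n_frames`, `bulk_density`.
#' @export
compute_sdf <- function(traj, ref_triad, target_group, radius, voxel) {
  if (is.null(dim(ref_triad))) ref_triad <- matrix(ref_triad, nrow = 1)
  stopifnot(ncol(ref_triad) == 3)
  tg <- resolve_group(traj$topology, target_group)
  if (!length(tg)) stop("selection error: empty target group")
  nside <- as.integer(ceiling(2 * radius / voxel))
  dens <- array(0, dim = c(nside, nside, nside))
  L <- unclass(traj$cell)
  nrefs <- nrow(ref_triad)
  for (f in seq_len(n_frames(traj))) {
    pos <- traj$coords[, , f, drop = TRUE]
    for (r in seq_len(nrefs)) {
      basis <- local_frame(pos[ref_triad[r, 1], ], pos[ref_triad[r, 2], ],
                           pos[ref_triad[r, 3], ], traj$cell)
      d <- sweep_min_image(
        pos[tg, , drop = FALSE] -
          matrix(pos[ref_triad[r, 1], ], length(tg), 3, byrow = TRUE), L)
      loc <- d %*% t(basis)     # rows: (x, y, z) in the local frame
      inside <- rowSums(abs(loc) < radius) == 3
      if (!any(inside)) next
      ijk <- floor((loc[inside, , drop = FALSE] + radius) / voxel) + 1L
      ijk[ijk > nside] <- nside
      for (k in seq_len(nrow(ijk))) {
        dens[ijk[k, 1], ijk[k, 2], ijk[k, 3]] <-
          dens[ijk[k, 1], ijk[k, 2], ijk[k, 3]] + 1
      }
    }
  }
  bulk <- length(tg) / cell_volume(traj$cell)
  dens <- dens / (n_frames(traj) * nrefs * voxel^3 * bulk)
  axis <- -radius + (seq_len(nside) - 0.5) * voxel
  structure(list(density = dens, axis = axis, voxel = voxel, radius = radius,
                 n_refs = nrefs, n_frames = n_frames(traj),
                 bulk_density = bulk),
            class = "sdf_grid")
}

# orthonormal local frame rows (ex, ey, ez): origin at p1, x toward p2,
# p3 in the xz half-plane with positive z
local_frame <- function(p1, p2, p3, cell) {
  ex <- min_image_displacement(p1, p2, cell)
  w <- min_image_displacement(p1, p3, cell)
  if (ex$distance < 1e-10 || w$distance < 1e-10) {
    stop("frame degeneracy: coincident triad atoms")
  }
  ex <- ex$vector / ex$distance
  wz <- w$vector - sum(w$vector * ex) * ex
  nz <- sqrt(sum(wz^2))
  if (nz < 1e-10) stop("frame degeneracy: collinear reference triad")
  ez <- wz / nz
  ey <- c(ez[2] * ex[3] - ez[3] * ex[2],
          ez[3] * ex[1] - ez[1] * ex[3],
          ez[1] * ex[2] - ez[2] * ex[1])
  rbind(ex, ey, ez)
}

#' @export
print.sdf_grid <- function(x, ...) {
  cat(sprintf("<sdf_grid> %d^3 voxels, voxel %.3f A, radius %.2f A, %d refs x %d frames\n",
              dim(x$density)[1], x$voxel, x$radius, x$n_refs, x$n_frames))
  invisible(x)
}

#' Write an SDF grid as a Gaussian cube file
#'
#' Axes are converted to Bohr and voxels are written z-fastest per the cube
#' convention. The reference structure provides the atom block (element
#' symbols are mapped to atomic numbers where known, else 0).
#'
#' @param sdf An `sdf_grid`.
#' @param reference Data frame with columns `element`, `x`, `y`, `z`
#'   (Angstrom) for the header atom block; may have zero rows.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cube <- function(sdf, reference, path) {
  b <- des_units()$bohr_per_angstrom
  n <- dim(sdf$density)[1]
  origin <- (-sdf$radius + sdf$voxel / 2) * b
  znum <- c(H = 1, C = 6, N = 7, O = 8, F = 9, P = 15, S = 16, Cl = 17)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("deswater spatial distribution function",
               "normalized target density in the reference local frame"), con)
  natoms <- if (is.null(reference)) 0L else nrow(reference)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", natoms,
                     origin, origin, origin), con)
  for (ax in 1:3) {
    step <- c(0, 0, 0); step[ax] <- sdf$voxel * b
    writeLines(sprintf("%5d %11.6f %11.6f %11.6f", n,
                       step[1], step[2], step[3]), con)
  }
  if (natoms > 0) {
    zz <- znum[reference$element]
    zz[is.na(zz)] <- 0
    writeLines(sprintf("%5d %11.6f %11.6f %11.6f %11.6f", as.integer(zz), 0,
                       reference$x * b, reference$y * b, reference$z * b), con)
  }
  vals <- numeric(n^3)
  k <- 1L
  for (i in seq_len(n)) for (j in seq_len(n)) {
    vals[k:(k + n - 1L)] <- sdf$density[i, j, ]
    k <- k + n
  }
  lines <- vapply(split(vals, ceiling(seq_along(vals) / 6)),
                  function(v) paste(sprintf("%13.5e", v), collapse = " "),
                  character(1))
  writeLines(lines, con)
  invisible(path)
}
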