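#' Minimum-image displacement between two positions
#'
#' Returns the displacement vector from `pos_a` to `pos_b` under the
#' minimum-image convention of an orthorhombic periodic cell, together with
#' its length. Each component of the returned vector has magnitude at most
#' half the corresponding cell edge.
#'
#' @param pos_a,pos_b Numeric 3-vectors (or n x 3 matrices for vectorised
#'   use), Angstrom.
#' @param cell A [simulation_cell()].
#' @return For vector input, a list with `vector` (3-vector, A) and
#'   `distance` (A). For matrix input, a list with an n x 3 `vector` matrix
#'   and a length-n `distance` vector.
#' @export
#' @examples
#' cell <- simulation_cell(c(10, 10, 10))
#' min_image_displacement(c(0, 0, 0), c(9, 0, 0), cell)$distance  # 1
min_image_displacement <- function(pos_a, pos_b, cell) {
  single <- is.null(dim(pos_a)) && is.null(dim(pos_b))
  a <- rbind(pos_a)
  b <- rbind(pos_b)
  if (!all(is.finite(a)) || !all(is.finite(b))) {
    stop("positions must be finite")
  }
  d <- b - a
  L <- unclass(cell)
  d <- sweep_min_image(d, L)
  dist <- unname(sqrt(rowSums(d * d)))
  if (single) list(vector = unname(d[1, ]), distance = dist[1])
  else list(vector = d, distance = dist)
}

# apply minimum image to an n x 3 displacement matrix
sweep_min_image <- function(d, L) {
  for (k in 1:3) d[, k] <- d[, k] - L[k] * round(d[, k] / L[k])
  d
}

#' Angle at a vertex under periodic boundary conditions
#'
#' Computes the A-V-C angle in degrees at vertex `pos_vertex`, with both arm
#' vectors taken as minimum-image displacements. This is the convention used
#' for the donor-hydrogen-acceptor angle (vertex at the hydrogen, 180 deg =
#' linear).
#'
#' @param pos_a,pos_vertex,pos_c Numeric 3-vectors, Angstrom.
#' @inheritParams min_image_displacement
#' @return Angle in degrees, in \[0, 180\].
#' @export
angle_at_vertex <- function(pos_a, pos_vertex, pos_c, cell) {
  u <- min_image_displacement(pos_vertex, pos_a, cell)
  w <- min_image_displacement(pos_vertex, pos_c, cell)
  if (u$distance < 1e-12 || w$distance < 1e-12) {
    stop("degenerate geometry: zero-length arm at angle vertex")
  }
  cosang <- sum(u$vector * w$vector) / (u$distance * w$distance)
  cosang <- pmin(1, pmax(-1, cosang))
  acos(cosang) * 180 / pi
}

# vectorised form: arms as n x 3 matrices already minimum-imaged
angles_from_arms <- function(u, w) {
  nu <- sqrt(rowSums(u * u))
  nw <- sqrt(rowSums(w * w))
  if (any(nu < 1e-12) || any(nw < 1e-12)) {
    stop("degenerate geometry: zero-length arm at angle vertex")
  }
  cosang <- rowSums(u * w) / (nu * nw)
  cosang <- pmin(1, pmax(-1, cosang))
  acos(cosang) * 180 / pi
}

#' Find all atom pairs within a cutoff
#'
#' Enumerates pairs (i in `group_a`, j in `group_b`) whose minimum-image
#' distance is at most `cutoff`. Self pairs are excluded. When the two
#' groups are identical each unordered pair is reported once (i < j). A
#' cell-list search is used for large systems, with a direct double loop
#' below 200 atoms; both paths give identical pair sets.
#'
#' @param positions n x 3 matrix of positions, Angstrom.
#' @param group_a,group_b Integer vectors of atom indices (1-based).
#' @param cutoff Distance cutoff in Angstrom; must be at most half the
#'   smallest cell edge.
#' @inheritParams min_image_displacement
#' @return A tibble with columns `i`, `j`, `distance`.
#' @export
neighbor_pairs <- function(positions, group_a, group_b, cutoff, cell) {
  check_cutoff(cutoff, cell)
  same <- identical(sort(group_a), sort(group_b))
  n_involved <- length(unique(c(group_a, group_b)))
  if (n_involved < 200) {
    res <- pairs_bruteforce(positions, group_a, group_b, cutoff, cell, same)
  } else {
    res <- pairs_celllist(positions, group_a, group_b, cutoff, cell, same)
  }
  tibble::tibble(i = res$i, j = res$j, distance = res$d)
}

# direct double loop via a full distance matrix (vectorised)
pairs_bruteforce <- function(positions, group_a, group_b, cutoff, cell, same) {
  pa <- positions[group_a, , drop = FALSE]
  pb <- positions[group_b, , drop = FALSE]
  L <- unclass(cell)
  d2 <- matrix(0, nrow(pa), nrow(pb))
  for (k in 1:3) {
    dk <- outer(pa[, k], pb[, k], "-")
    dk <- dk - L[k] * round(dk / L[k])
    d2 <- d2 + dk * dk
  }
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  ia <- group_a[hit[, 1]]
  jb <- group_b[hit[, 2]]
  keep <- ia != jb
  if (same) keep <- keep & ia < jb
  list(i = ia[keep], j = jb[keep],
       d = sqrt(d2[hit])[keep])
}

# cell-list (linked-cell) neighbour search
pairs_celllist <- function(positions, group_a, group_b, cutoff, cell, same) {
  L <- unclass(cell)
  idx <- sort(unique(c(group_a, group_b)))
  pos <- positions[idx, , drop = FALSE]
  # wrap into [0, L)
  for (k in 1:3) pos[, k] <- pos[, k] - L[k] * floor(pos[, k] / L[k])
  ncell <- pmax(1L, as.integer(floor(L / cutoff)))
  csize <- L / ncell
  cidx <- matrix(0L, nrow(pos), 3)
  for (k in 1:3) {
    cidx[, k] <- pmin(ncell[k] - 1L, as.integer(floor(pos[, k] / csize[k])))
  }
  lin <- cidx[, 1] + ncell[1] * (cidx[, 2] + ncell[2] * cidx[, 3])
  buckets <- split(seq_len(nrow(pos)), lin)
  in_a <- idx %in% group_a
  in_b <- idx %in% group_b
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  out_i <- integer(0); out_j <- integer(0); out_d <- numeric(0)
  key_of <- function(cv) cv[, 1] + ncell[1] * (cv[, 2] + ncell[2] * cv[, 3])
  for (key in names(buckets)) {
    members <- buckets[[key]]
    k0 <- as.integer(key)
    c0 <- c(k0 %% ncell[1],
            (k0 %/% ncell[1]) %% ncell[2],
            k0 %/% (ncell[1] * ncell[2]))
    neigh <- sweep(offs, 2, c0, "+")
    for (k in 1:3) neigh[, k] <- neigh[, k] %% ncell[k]
    nkeys <- unique(key_of(neigh))
    cand <- unlist(buckets[as.character(nkeys)], use.names = FALSE)
    ai <- members[in_a[members]]
    bj <- cand[in_b[cand]]
    if (!length(ai) || !length(bj)) next
    pa <- pos[ai, , drop = FALSE]
    pb <- pos[bj, , drop = FALSE]
    d2 <- matrix(0, length(ai), length(bj))
    for (k in 1:3) {
      dk <- outer(pa[, k], pb[, k], "-")
      dk <- dk - L[k] * round(dk / L[k])
      d2 <- d2 + dk * dk
    }
    hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
    if (!nrow(hit)) next
    gi <- idx[ai[hit[, 1]]]
    gj <- idx[bj[hit[, 2]]]
    keep <- gi != gj
    out_i <- c(out_i, gi[keep]); out_j <- c(out_j, gj[keep])
    out_d <- c(out_d, sqrt(d2[hit])[keep])
  }
  # cell loop emits each a-b ordered pair once per a-cell; dedupe ordered
  # duplicates arising from a==b overlap, then apply unordered rule
  if (same) {
    keep <- out_i < out_j
    out_i <- out_i[keep]; out_j <- out_j[keep]; out_d <- out_d[keep]
  }
  dup <- duplicated(cbind(out_i, out_j))
  list(i = out_i[!dup], j = out_j[!dup], d = out_d[!dup])
}
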