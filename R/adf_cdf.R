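# Angular distribution functions and 2-D combined distribution functions
# (distance x angle, distance x distance). CDFs are the standard tool for
# deriving geometric hydrogen-bond criteria: the populated region of the
# (donor-acceptor distance, D-H...A angle) plane fixes the cutoff windows.

#' Angular distribution function over site triplets
#'
#' For every vertex atom in `group_vertex`, every pair of flanking atoms
#' (one from `group_a`, one from `group_c`, both within `cutoff` of the
#' vertex, all three atoms distinct) contributes the a-vertex-c angle. The
#' histogram over \[0, 180\] degrees is normalized to unit area.
#'
#' @param traj A [trajectory()].
#' @param group_a,group_vertex,group_c Atom-index vectors or group names.
#' @param cutoff Association cutoff vertex-flank, A.
#' @param bin_width Bin width, degrees (default 2).
#' @return Tibble of class `adf_result` with columns `angle` (bin centers,
#'   degrees) and `density` (1/degree); attribute `counts`.
#' @export
compute_adf <- function(traj, group_a, group_vertex, group_c, cutoff,
                        bin_width = 2) {
  top <- traj$topology
  ga <- resolve_group(top, group_a)
  gv <- resolve_group(top, group_vertex)
  gc_ <- resolve_group(top, group_c)
  nbin <- as.integer(ceiling(180 / bin_width))
  counts <- numeric(nbin)
  L <- unclass(traj$cell)
  total <- 0
  for (f in seq_len(n_frames(traj))) {
    pos <- traj$coords[, , f, drop = TRUE]
    pav <- neighbor_pairs(pos, gv, ga, cutoff, traj$cell)
    pcv <- neighbor_pairs(pos, gv, gc_, cutoff, traj$cell)
    if (!nrow(pav) || !nrow(pcv)) next
    by_v_a <- split(pav$j, pav$i)
    by_v_c <- split(pcv$j, pcv$i)
    for (v in intersect(names(by_v_a), names(by_v_c))) {
      vi <- as.integer(v)
      combos <- expand.grid(a = by_v_a[[v]], c = by_v_c[[v]])
      combos <- combos[combos$a != combos$c, , drop = FALSE]
      if (!nrow(combos)) next
      u <- sweep_min_image(pos[combos$a, , drop = FALSE] -
                             matrix(pos[vi, ], nrow(combos), 3, byrow = TRUE), L)
      w <- sweep_min_image(pos[combos$c, , drop = FALSE] -
                             matrix(pos[vi, ], nrow(combos), 3, byrow = TRUE), L)
      ang <- angles_from_arms(u, w)
      counts <- counts + tabulate(pmin(nbin, floor(ang / bin_width) + 1L),
                                  nbins = nbin)
      total <- total + nrow(combos)
    }
  }
  if (total == 0) stop("empty selection: no angle triplets found")
  centers <- (seq_len(nbin) - 0.5) * bin_width
  out <- tibble::tibble(angle = centers,
                        density = counts / (total * bin_width))
  class(out) <- c("adf_result", class(out))
  attr(out, "counts") <- counts
  out
}

new_cdf2d <- function(counts, x_centers, y_centers, x_lab, y_lab, mode) {
  structure(list(counts = counts, x = x_centers, y = y_centers,
                 x_lab = x_lab, y_lab = y_lab, mode = mode),
            class = "cdf2d")
}

#' @export
print.cdf2d <- function(x, ...) {
  cat(sprintf("<cdf2d> %d x %d bins (%s x %s), %d events\n",
              length(x$x), length(x$y), x$x_lab, x$y_lab, sum(x$counts)))
  invisible(x)
}

#' Peak cell of a 2-D combined distribution
#' @param cdf A `cdf2d`.
#' @return List with `x`, `y` (bin centers of the maximum cell) and `count`.
#' @export
cdf_argmax <- function(cdf) {
  ij <- which(cdf$counts == max(cdf$counts), arr.ind = TRUE)[1, ]
  list(x = cdf$x[ij[1]], y = cdf$y[ij[2]], count = max(cdf$counts))
}

#' Tidy a 2-D combined distribution into a long tibble
#' @param x A `cdf2d`.
#' @param ... Unused.
#' @return Tibble with the two axis coordinates and `count`.
#' @export
tidy.cdf2d <- function(x, ...) {
  out <- tibble::tibble(x = rep(x$x, times = length(x$y)),
                        y = rep(x$y, each = length(x$x)),
                        count = as.vector(x$counts))
  names(out)[1:2] <- c(x$x_lab, x$y_lab)
  out
}

# shared event walk: for each (a, b) pair within r_max yield distance and,
# via partner_of_b, the angle a-b-partner at vertex b
cdf_dist_angle_events <- function(traj, ga, gb, partner_of_b, r_max) {
  L <- unclass(traj$cell)
  d_all <- numeric(0); ang_all <- numeric(0)
  for (f in seq_len(n_frames(traj))) {
    pos <- traj$coords[, , f, drop = TRUE]
    pr <- neighbor_pairs(pos, ga, gb, r_max, traj$cell)
    if (!nrow(pr)) next
    pt <- partner_of_b[as.character(pr$j)]
    u <- sweep_min_image(pos[pr$i, , drop = FALSE] -
                           pos[pr$j, , drop = FALSE], L)
    w <- sweep_min_image(pos[pt, , drop = FALSE] -
                           pos[pr$j, , drop = FALSE], L)
    d_all <- c(d_all, pr$distance)
    ang_all <- c(ang_all, angles_from_arms(u, w))
  }
  list(d = d_all, angle = ang_all)
}

#' Combined distance-angle distribution function
#'
#' One event per (a, b) pair per frame with minimum-image distance at most
#' `r_max`: the pair distance on the x-axis and the a-b-partner angle
#' (vertex at b, partner atom in b's molecule named by `partner_of_b`) on
#' the y-axis. Counts are raw occurrences (the figure-style normalization);
#' use [cdf_argmax()] to locate the populated region.
#'
#' @param traj A [trajectory()].
#' @param group_a,group_b Atom-index vectors or group names.
#' @param partner_of_b Named integer vector mapping each atom index of
#'   `group_b` (as character name) to its partner atom index.
#' @param r_max Distance limit, A.
#' @param n_dist,n_angle Number of bins for each axis.
#' @return A `cdf2d` (distance bins x angle bins).
#' @export
compute_cdf_dist_angle <- function(traj, group_a, group_b, partner_of_b,
                                   r_max, n_dist = 60, n_angle = 60) {
  top <- traj$topology
  ga <- resolve_group(top, group_a)
  gb <- resolve_group(top, group_b)
  if (is.null(names(partner_of_b))) {
    stop("spec error: partner_of_b must be a named vector keyed by atom index")
  }
  if (!all(as.character(gb) %in% names(partner_of_b))) {
    stop("spec error: partner_of_b must cover every atom of group_b")
  }
  ev <- cdf_dist_angle_events(traj, ga, gb, partner_of_b, r_max)
  dx <- r_max / n_dist
  da <- 180 / n_angle
  counts <- matrix(0, n_dist, n_angle)
  if (length(ev$d)) {
    bi <- pmin(n_dist, floor(ev$d / dx) + 1L)
    bj <- pmin(n_angle, floor(ev$angle / da) + 1L)
    for (k in seq_along(bi)) counts[bi[k], bj[k]] <- counts[bi[k], bj[k]] + 1
  }
  new_cdf2d(counts, (seq_len(n_dist) - 0.5) * dx,
            (seq_len(n_angle) - 0.5) * da,
            "distance", "angle", "counts")
}

#' Combined distance-distance distribution function
#'
#' One event per (a, b, c) triple per frame where b (from `group_b`) is
#' within `r_max_1` of a and c (from `group_c`) is within `r_max_2` of a:
#' d(a, b) on the x-axis against d(a, c) on the y-axis. Swapping the two
#' flank groups (with their ranges) transposes the count matrix.
#'
#' @param traj A [trajectory()].
#' @param group_a Central atoms; each of its neighbours in the two flank
#'   groups is combined.
#' @param group_b,group_c Flank groups (index vectors or group names).
#' @param r_max_1,r_max_2 Distance limits for the two axes, A.
#' @param n_bins_1,n_bins_2 Bin counts.
#' @return A `cdf2d`.
#' @export
compute_cdf_dist_dist <- function(traj, group_a, group_b, group_c,
                                  r_max_1, r_max_2,
                                  n_bins_1 = 60, n_bins_2 = 60) {
  top <- traj$topology
  ga <- resolve_group(top, group_a)
  gb <- resolve_group(top, group_b)
  gc_ <- resolve_group(top, group_c)
  d1x <- r_max_1 / n_bins_1
  d2x <- r_max_2 / n_bins_2
  counts <- matrix(0, n_bins_1, n_bins_2)
  for (f in seq_len(n_frames(traj))) {
    pos <- traj$coords[, , f, drop = TRUE]
    p1 <- neighbor_pairs(pos, ga, gb, r_max_1, traj$cell)
    p2 <- neighbor_pairs(pos, ga, gc_, r_max_2, traj$cell)
    if (!nrow(p1) || !nrow(p2)) next
    b1 <- split(seq_len(nrow(p1)), p1$i)
    b2 <- split(seq_len(nrow(p2)), p2$i)
    for (a in intersect(names(b1), names(b2))) {
      combos <- expand.grid(k1 = b1[[a]], k2 = b2[[a]])
      keep <- p1$j[combos$k1] != p2$j[combos$k2]
      combos <- combos[keep, , drop = FALSE]
      if (!nrow(combos)) next
      bi <- pmin(n_bins_1, floor(p1$distance[combos$k1] / d1x) + 1L)
      bj <- pmin(n_bins_2, floor(p2$distance[combos$k2] / d2x) + 1L)
      for (k in seq_along(bi)) counts[bi[k], bj[k]] <- counts[bi[k], bj[k]] + 1
    }
  }
  new_cdf2d(counts, (seq_len(n_bins_1) - 0.5) * d1x,
            (seq_len(n_bins_2) - 0.5) * d2x,
            "distance_1", "distance_2", "counts")
}
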