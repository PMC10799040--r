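# Geometric hydrogen-bond analysis: detection under distance/angle windows,
# per-frame count series, Gaussian fits of the count histogram, and per-pair
# percent occupancy.

#' Hydrogen-bond geometric criteria
#'
#' A hydrogen bond D-H...A is counted when the chosen distance (donor to
#' acceptor by default, hydrogen to acceptor optionally) lies in
#' \[d_min, d_max\] and the D-H...A angle (vertex at the hydrogen, 180 deg =
#' linear) lies in \[angle_min, angle_max\]. Two named presets reflect the
#' criteria windows appropriate for the two DES families studied with this
#' package:
#'
#' * `"thymol"` — angle 135-150 deg, donor-acceptor distance < 3.5 A
#'   (neutral-donor DES such as thymol/fatty-acid mixtures).
#' * `"chloride"` — angle 130-180 deg, donor-acceptor distance 2-3 A
#'   (chloride-acceptor DES such as choline chloride/fatty-acid mixtures).
#'
#' @param preset `"thymol"`, `"chloride"`, or `NULL` for fully manual
#'   windows.
#' @param d_min,d_max Distance window, A.
#' @param angle_min,angle_max Angle window, degrees.
#' @param distance_definition `"donor_acceptor"` or `"hydrogen_acceptor"`.
#' @return Object of class `hbond_criteria`.
#' @export
#' @examples
#' hbond_criteria("chloride")
hbond_criteria <- function(preset = NULL, d_min = NULL, d_max = NULL,
                           angle_min = NULL, angle_max = NULL,
                           distance_definition = "donor_acceptor") {
  base <- switch(
    preset %||% "manual",
    thymol   = list(d_min = 0, d_max = 3.5, angle_min = 135, angle_max = 150),
    chloride = list(d_min = 2, d_max = 3, angle_min = 130, angle_max = 180),
    manual   = list(d_min = d_min, d_max = d_max,
                    angle_min = angle_min, angle_max = angle_max),
    stop("unknown preset: ", preset)
  )
  if (!is.null(d_min)) base$d_min <- d_min
  if (!is.null(d_max)) base$d_max <- d_max
  if (!is.null(angle_min)) base$angle_min <- angle_min
  if (!is.null(angle_max)) base$angle_max <- angle_max
  if (is.null(base$d_min) || is.null(base$d_max) ||
      is.null(base$angle_min) || is.null(base$angle_max)) {
    stop("criteria need d_min, d_max, angle_min, angle_max (or a preset)")
  }
  if (!(base$d_min >= 0 && base$d_min < base$d_max)) {
    stop("criteria require 0 <= d_min < d_max")
  }
  if (!(base$angle_min >= 0 && base$angle_min < base$angle_max &&
        base$angle_max <= 180)) {
    stop("criteria require 0 <= angle_min < angle_max <= 180")
  }
  if (!distance_definition %in% c("donor_acceptor", "hydrogen_acceptor")) {
    stop("distance_definition must be donor_acceptor or hydrogen_acceptor")
  }
  structure(c(base, list(distance_definition = distance_definition,
                         preset = preset %||% "manual")),
            class = "hbond_criteria")
}

#' @export
print.hbond_criteria <- function(x, ...) {
  cat(sprintf(
    "<hbond_criteria> preset '%s': distance (%s) in [%.2f, %.2f] A, angle in [%.0f, %.0f] deg\n",
    x$preset, x$distance_definition, x$d_min, x$d_max,
    x$angle_min, x$angle_max))
  invisible(x)
}

#' Detect hydrogen bonds in one frame
#'
#' Enumerates all (donor, hydrogen, acceptor) triples satisfying the
#' criteria. The covalent donor-hydrogen pairing comes from `donor_map`
#' (see [donor_hydrogen_map()]); acceptors in the donor's own molecule are
#' skipped unless `allow_intramolecular`.
#'
#' @param positions n x 3 position matrix (one frame), A.
#' @param donor_map Tibble with columns `donor`, `hydrogen` (atom indices).
#' @param acceptors Integer vector of acceptor atom indices.
#' @param criteria An [hbond_criteria()].
#' @param cell A [simulation_cell()].
#' @param top The [topology()] (for molecule ids).
#' @param allow_intramolecular Count acceptors within the donor's molecule
#'   (default FALSE).
#' @return Tibble of class `hbond_events`: `donor`, `hydrogen`, `acceptor`,
#'   `distance` (per the criteria's definition, A), `angle` (degrees).
#' @export
detect_hbonds <- function(positions, donor_map, acceptors, criteria, cell,
                          top, allow_intramolecular = FALSE) {
  stopifnot(inherits(criteria, "hbond_criteria"))
  mol <- top$atoms$molecule_id
  if (any(mol[donor_map$donor] != mol[donor_map$hydrogen])) {
    stop("topology error: donor and hydrogen must share a molecule")
  }
  L <- unclass(cell)
  dist_atom <- if (criteria$distance_definition == "donor_acceptor") {
    donor_map$donor
  } else {
    donor_map$hydrogen
  }
  # candidate (DH-row, acceptor) pairs by distance window
  pr <- neighbor_pairs(positions, unique(dist_atom), acceptors,
                       criteria$d_max, cell)
  if (!nrow(pr)) return(empty_hbond_events())
  rows_of <- split(seq_len(nrow(donor_map)), dist_atom)
  out <- list()
  for (k in seq_len(nrow(pr))) {
    for (row in rows_of[[as.character(pr$i[k])]]) {
      D <- donor_map$donor[row]; H <- donor_map$hydrogen[row]
      A <- pr$j[k]
      if (A == D || A == H) next
      if (!allow_intramolecular && mol[A] == mol[D]) next
      d <- pr$distance[k]
      if (d < criteria$d_min) next
      u <- sweep_min_image(rbind(positions[D, ] - positions[H, ]), L)
      w <- sweep_min_image(rbind(positions[A, ] - positions[H, ]), L)
      ang <- angles_from_arms(u, w)
      if (ang < criteria$angle_min || ang > criteria$angle_max) next
      out[[length(out) + 1]] <- c(D, H, A, d, ang)
    }
  }
  if (!length(out)) return(empty_hbond_events())
  m <- do.call(rbind, out)
  tibble::tibble(donor = as.integer(m[, 1]), hydrogen = as.integer(m[, 2]),
                 acceptor = as.integer(m[, 3]), distance = m[, 4],
                 angle = m[, 5])
}

empty_hbond_events <- function() {
  tibble::tibble(donor = integer(0), hydrogen = integer(0),
                 acceptor = integer(0), distance = numeric(0),
                 angle = numeric(0))
}

# run detection over all frames; returns list of event tibbles
hbond_events_by_frame <- function(traj, donor_map, acceptors, criteria,
                                  allow_intramolecular = FALSE) {
  lapply(seq_len(n_frames(traj)), function(f) {
    detect_hbonds(traj$coords[, , f, drop = TRUE], donor_map, acceptors,
                  criteria, traj$cell, traj$topology, allow_intramolecular)
  })
}

#' Per-frame hydrogen-bond count series
#'
#' @param traj A [trajectory()].
#' @param donor_map Tibble `donor`, `hydrogen` (see [donor_hydrogen_map()]).
#' @param acceptors Acceptor atom indices or a group name.
#' @param criteria An [hbond_criteria()].
#' @param allow_intramolecular Passed to [detect_hbonds()].
#' @return Tibble of class `hbond_series`: `time` (ps), `n_bonds`;
#'   attribute `criteria`.
#' @export
hbond_count_series <- function(traj, donor_map, acceptors, criteria,
                               allow_intramolecular = FALSE) {
  acceptors <- resolve_group(traj$topology, acceptors)
  ev <- hbond_events_by_frame(traj, donor_map, acceptors, criteria,
                              allow_intramolecular)
  out <- tibble::tibble(time = traj$times,
                        n_bonds = vapply(ev, nrow, integer(1)))
  class(out) <- c("hbond_series", class(out))
  attr(out, "criteria") <- criteria
  out
}

#' Percent occupancy of unique donor-acceptor pairs
#'
#' For every donor-atom/acceptor-atom pair observed bonded at least once,
#' the percentage of frames in which the pair has at least one
#' criteria-satisfying hydrogen route. Hydrogen identity is collapsed: two
#' hydrogens of one donor bonding the same acceptor in a frame count once.
#'
#' @inheritParams hbond_count_series
#' @return Tibble sorted by descending occupancy: `donor`, `acceptor`,
#'   `n_frames_bonded`, `occupancy` (percent).
#' @export
hbond_occupancy <- function(traj, donor_map, acceptors, criteria,
                            allow_intramolecular = FALSE) {
  acceptors <- resolve_group(traj$topology, acceptors)
  ev <- hbond_events_by_frame(traj, donor_map, acceptors, criteria,
                              allow_intramolecular)
  nf <- n_frames(traj)
  pairs <- dplyr::bind_rows(lapply(seq_len(nf), function(f) {
    e <- ev[[f]]
    if (!nrow(e)) return(NULL)
    dplyr::distinct(tibble::tibble(frame = f, donor = e$donor,
                                   acceptor = e$acceptor))
  }))
  if (is.null(pairs) || !nrow(pairs)) {
    return(tibble::tibble(donor = integer(0), acceptor = integer(0),
                          n_frames_bonded = integer(0),
                          occupancy = numeric(0)))
  }
  pairs |>
    dplyr::count(.data$donor, .data$acceptor, name = "n_frames_bonded") |>
    dplyr::mutate(occupancy = 100 * .data$n_frames_bonded / nf) |>
    dplyr::arrange(dplyr::desc(.data$occupancy), .data$donor, .data$acceptor)
}

#' Fit a Gaussian to a histogram of hydrogen-bond counts
#'
#' Bins the per-frame count series and fits
#' `F(X) = a / (sigma * sqrt(2 pi)) * exp(-(X - mean)^2 / (2 sigma^2))`
#' to the bin counts by Levenberg-Marquardt least squares, started from the
#' sample moments. The amplitude `a` absorbs the series length and bin
#' width. The fitted mean is reported with its fit standard error.
#'
#' @param series An `hbond_series`, or any numeric vector of counts.
#' @param n_bins Number of histogram bins (default 30).
#' @return A `gaussian_fit` object; see [fit_gaussian()].
#' @export
fit_gaussian_histogram <- function(series, n_bins = 30) {
  x <- if (is.data.frame(series)) series$n_bonds else as.numeric(series)
  if (length(x) < 10) stop("count series must have length >= 10")
  if (stats::sd(x) == 0) {
    stop("degenerate distribution: count series has zero variance")
  }
  h <- graphics::hist(x, breaks = n_bins, plot = FALSE)
  fit_gaussian(h$mids, h$counts,
               init = list(mean = mean(x), sigma = stats::sd(x),
                           a = length(x) * diff(h$breaks[1:2])))
}

#' Least-squares Gaussian fit to (x, y) curve data
#'
#' @param x,y Curve abscissae and values (e.g. histogram bin centers and
#'   counts).
#' @param init Optional list with starting `mean`, `sigma`, `a`.
#' @return Object of class `gaussian_fit`: `a`, `mean`, `sigma`, `se_mean`,
#'   `converged`, `residual_norm`. On non-convergence the moment estimates
#'   are returned with `converged = FALSE`.
#' @export
fit_gaussian <- function(x, y, init = NULL) {
  if (is.null(init)) {
    w <- pmax(y, 0)
    mu0 <- sum(x * w) / sum(w)
    s0 <- sqrt(sum(w * (x - mu0)^2) / sum(w))
    init <- list(mean = mu0, sigma = max(s0, 1e-6), a = sum(w) *
                   mean(diff(x)))
  }
  df <- data.frame(x = x, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ a / (sigma * sqrt(2 * pi)) * exp(-(x - mean)^2 / (2 * sigma^2)),
      data = df,
      start = list(a = init$a, mean = init$mean, sigma = init$sigma),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(a = init$a, mean = init$mean, sigma = init$sigma,
                          se_mean = NA_real_, converged = FALSE,
                          residual_norm = NA_real_),
                     class = "gaussian_fit"))
  }
  co <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients["mean", "Std. Error"],
                 error = function(e) NA_real_)
  structure(list(a = unname(co["a"]), mean = unname(co["mean"]),
                 sigma = abs(unname(co["sigma"])), se_mean = se,
                 converged = TRUE,
                 residual_norm = sqrt(sum(stats::residuals(fit)^2))),
            class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf("<gaussian_fit> mean = %.4f +/- %.4f, sigma = %.4f%s\n",
              x$mean, x$se_mean, x$sigma,
              if (x$converged) "" else " (did not converge; moment estimates)"))
  invisible(x)
}

#' @export
tidy.gaussian_fit <- function(x, ...) {
  tibble::tibble(term = c("a", "mean", "sigma"),
                 estimate = c(x$a, x$mean, x$sigma),
                 std.error = c(NA, x$se_mean, NA))
}

#' @export
glance.gaussian_fit <- function(x, ...) {
  tibble::tibble(converged = x$converged, residual_norm = x$residual_norm)
}
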