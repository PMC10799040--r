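# Pairwise nonbonded energy decomposition between role groups (HBA, HBD,
# water) and the relative water-stability factor S derived from it.
#
# S = |E(HBA-HBD)| / (|E(HBA-water)| + |E(HBD-water)|): the strength of the
# cohesive acceptor-donor interaction relative to how strongly either
# component binds water. Large S means the eutectic pair holds together in
# an aqueous environment; S at or below the conventional threshold 3.30
# classifies the solvent as water-miscible.

#' Lennard-Jones pair energy (Lorentz-Berthelot, truncated and shifted)
#'
#' 12-6 potential with epsilon = sqrt(eps_i eps_j) and
#' sigma = (sigma_i + sigma_j)/2, shifted so the energy is exactly zero at
#' the cutoff and beyond.
#'
#' @param r Distance(s), A (> 0).
#' @param epsilon_i,epsilon_j Well depths, kcal/mol.
#' @param sigma_i,sigma_j LJ diameters, A.
#' @param cutoff Truncation distance, A (default 12).
#' @return Energy, kcal/mol (vectorized over `r`).
#' @export
pair_energy_lj <- function(r, epsilon_i, sigma_i, epsilon_j, sigma_j,
                           cutoff = 12) {
  if (any(r <= 0)) stop("domain error: r must be positive")
  eps <- sqrt(epsilon_i * epsilon_j)
  sig <- (sigma_i + sigma_j) / 2
  lj <- function(x) {
    sr6 <- (sig / x)^6
    4 * eps * (sr6^2 - sr6)
  }
  ifelse(r < cutoff, lj(r) - lj(cutoff), 0)
}

#' Coulomb pair energy (truncated and shifted)
#'
#' `k_C q_i q_j (1/r - 1/cutoff)` for r < cutoff, zero beyond: continuous
#' at the cutoff. With `cutoff = Inf` this is the bare Coulomb energy
#' (332.0636 kcal/mol for unit charges at 1 A).
#'
#' @param r Distance(s), A (> 0).
#' @param q_i,q_j Partial charges, e.
#' @param cutoff Truncation distance, A (default 12; `Inf` for bare).
#' @return Energy, kcal/mol (vectorized over `r`).
#' @export
pair_energy_coulomb <- function(r, q_i, q_j, cutoff = 12) {
  if (any(r <= 0)) stop("domain error: r must be positive")
  kC <- des_units()$k_C
  inv_rc <- if (is.finite(cutoff)) 1 / cutoff else 0
  ifelse(r < cutoff, kC * q_i * q_j * (1 / r - inv_rc), 0)
}

#' Frame-averaged nonbonded interaction energy between two groups
#'
#' Sums [pair_energy_lj()] + [pair_energy_coulomb()] over every
#' intermolecular a-b pair within the cutoff (minimum image), averaged over
#' frames. The two groups must not share any molecule. Per-frame values are
#' retrievable from the `per_frame` attribute.
#'
#' @param traj A [trajectory()].
#' @param group_a,group_b Atom-index vectors or group names (e.g. roles
#'   `"HBA"`, `"HBD"`, `"water"`).
#' @param cutoff Interaction cutoff, A (default 12; capped at half the
#'   smallest cell edge check).
#' @param label Pair label for the output row (default from group names).
#' @return Tibble of class `energy_decomposition` with one row: `pair`,
#'   `e_elec`, `e_vdw`, `e_total` (kcal/mol), `n_frames`.
#' @export
group_interaction_energy <- function(traj, group_a, group_b, cutoff = 12,
                                     label = NULL) {
  top <- traj$topology
  ga <- resolve_group(top, group_a)
  gb <- resolve_group(top, group_b)
  check_cutoff(cutoff, traj$cell)
  mol <- top$atoms$molecule_id
  if (length(intersect(mol[ga], mol[gb]))) {
    stop("selection error: groups share molecule(s); ",
         "the decomposition is intermolecular")
  }
  lbl <- label %||% paste(label_of(group_a), label_of(group_b), sep = "-")
  nf <- n_frames(traj)
  a <- top$atoms
  ee <- numeric(nf); ev <- numeric(nf)
  for (f in seq_len(nf)) {
    pr <- neighbor_pairs(traj$coords[, , f, drop = TRUE], ga, gb, cutoff,
                         traj$cell)
    if (!nrow(pr)) next
    ev[f] <- sum(pair_energy_lj(pr$distance,
                                a$lj_epsilon[pr$i], a$lj_sigma[pr$i],
                                a$lj_epsilon[pr$j], a$lj_sigma[pr$j],
                                cutoff))
    ee[f] <- sum(pair_energy_coulomb(pr$distance,
                                     a$charge[pr$i], a$charge[pr$j],
                                     cutoff))
  }
  out <- tibble::tibble(pair = lbl,
                        e_elec = mean(ee), e_vdw = mean(ev),
                        e_total = mean(ee) + mean(ev),
                        n_frames = nf)
  class(out) <- c("energy_decomposition", class(out))
  attr(out, "per_frame") <- tibble::tibble(frame = seq_len(nf),
                                           e_elec = ee, e_vdw = ev,
                                           e_total = ee + ev)
  out
}

#' Relative water-stability factor S
#'
#' `S = |E(HBA-HBD)| / (|E(HBA-water)| + |E(HBD-water)|)` from the three
#' pairwise total interaction energies. Magnitudes are used: the energies
#' are attractive (negative) and S is reported positive. S is a ratio, so
#' it is invariant under any common rescaling of the energy unit.
#'
#' @param e_ab_total HBA-HBD total interaction energy, kcal/mol.
#' @param e_aw_total HBA-water total interaction energy, kcal/mol.
#' @param e_bw_total HBD-water total interaction energy, kcal/mol.
#' @return S (dimensionless); vectorized.
#' @export
#' @examples
#' stability_factor(-27.319, -2.7159, -4.011)  # ~ 4.06
stability_factor <- function(e_ab_total, e_aw_total, e_bw_total) {
  den <- abs(e_aw_total) + abs(e_bw_total)
  if (any(den == 0)) stop("undefined S: both water interaction energies zero")
  abs(e_ab_total) / den
}

#' Stability report over multiple systems
#'
#' Computes S per system from a long table of pair energies, ranks systems
#' by descending S, and classifies each against the miscibility threshold
#' (S <= threshold: water-miscible; S > threshold: water-stable).
#'
#' @param energies Tibble with columns `system`, `pair`, `e_total`, where
#'   `pair` takes the values `"hba-hbd"`, `"hba-water"`, `"hbd-water"` for
#'   every system.
#' @param threshold Classification threshold (default 3.30).
#' @return Tibble of class `stability_report`: `system`, `S`, `rank`,
#'   `classification`, sorted by descending S; attribute `threshold`.
#' @export
stability_report <- function(energies, threshold = 3.30) {
  req_pairs <- c("hba-hbd", "hba-water", "hbd-water")
  wide <- energies |>
    dplyr::select("system", "pair", "e_total") |>
    tidyr::pivot_wider(names_from = "pair", values_from = "e_total")
  miss <- setdiff(req_pairs, names(wide))
  incomplete <- length(miss) > 0 ||
    anyNA(wide[req_pairs[req_pairs %in% names(wide)]])
  if (incomplete) {
    stop("incomplete system: every system needs the three pair energies ",
         paste(req_pairs, collapse = ", "))
  }
  out <- wide |>
    dplyr::mutate(S = stability_factor(.data[["hba-hbd"]],
                                       .data[["hba-water"]],
                                       .data[["hbd-water"]])) |>
    dplyr::arrange(dplyr::desc(.data$S)) |>
    dplyr::mutate(rank = dplyr::row_number(),
                  classification = ifelse(.data$S > threshold,
                                          "water-stable", "water-miscible")) |>
    dplyr::select("system", "S", "rank", "classification")
  class(out) <- c("stability_report", class(out))
  attr(out, "threshold") <- threshold
  out
}

#' Decomposition tibble helper for stability input
#'
#' Binds single-row [group_interaction_energy()] results into the long
#' format [stability_report()] expects.
#'
#' @param system System label.
#' @param hba_hbd,hba_water,hbd_water `energy_decomposition` rows.
#' @return Long tibble with `system`, `pair`, `e_elec`, `e_vdw`, `e_total`.
#' @export
bind_decompositions <- function(system, hba_hbd, hba_water, hbd_water) {
  d <- dplyr::bind_rows(hba_hbd, hba_water, hbd_water)
  tibble::tibble(system = system,
                 pair = c("hba-hbd", "hba-water", "hbd-water"),
                 e_elec = d$e_elec, e_vdw = d$e_vdw, e_total = d$e_total)
}
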