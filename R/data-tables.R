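#' Published-scale nonbonded interaction energies for DES/water systems
#'
#' A bundled reference table of frame-averaged nonbonded interaction
#' energies (kcal/mol, 353 K) between the component pairs of eleven binary
#' deep-eutectic-solvent systems in contact with water: six choline
#' chloride/fatty-acid mixtures (CAC acetic, CBU butyric, CCA caprylic,
#' CDC decanoic, CLA lauric, CMA myristic) and five thymol/fatty-acid
#' mixtures (TAC acetic, TBA butyric, TCA caprylic, TDA decanoic, TMA
#' myristic). For each system the three pairs are the HBA-HBD interaction
#' and the interactions of either component with water (TIP3).
#'
#' This table is the worked-example input for [stability_report()]: the
#' relative stability factor recomputes from the `e_total` column. Two rows
#' carry known quirks, preserved as printed in the source material: the TBA
#' system's reported S (21.371) is inconsistent with its own pair energies
#' (which give 1.371), and the CMA HBA-water electrostatic term is large
#' and positive where every other row is negative. `s_reported` is carried
#' for reference only; nothing in the package reads it.
#'
#' @param include_tba Keep the TBA row (default TRUE).
#' @return Tibble: `system`, `pair` (`hba-hbd`, `hba-water`, `hbd-water`),
#'   `e_elec`, `e_vdw`, `e_total` (kcal/mol), `s_reported` (on the hba-hbd
#'   row of each system, NA elsewhere).
#' @export
#' @examples
#' des_energy_table() |> stability_report()
des_energy_table <- function(include_tba = TRUE) {
  rows <- list(
    #        system  e_elec    e_vdw     e_total   s_reported
    CAC = list(c(-0.193, -10.5039, -10.697), c(0.3709, -85.704, -85.333),
               c(-0.5363, -14.7486, -15.285), 0.1063),
    CBU = list(c(-0.2005, -10.529, -10.729), c(0.3726, -85.886, -85.5131),
               c(-0.5753, -14.361, -14.936), 0.1068),
    CCA = list(c(-0.2444, -11.452, -11.696), c(0.3723, -85.612, -85.2402),
               c(-0.3351, -15.525, -15.86), 0.1157),
    CDC = list(c(-0.5962, -12.387, -12.984), c(0.5438, -83.977, -83.433),
               c(-1.236, -17.871, -19.115), 0.1266),
    CLA = list(c(-0.4837, -16.206, -16.689), c(0.532, -86.477, -85.945),
               c(-0.7201, -32.384, -33.104), 0.1402),
    CMA = list(c(-0.7004, -11.588, -12.289), c(64.492, -84.023, -19.531),
               c(-1.799, -17.732, -19.531), 0.3146),
    TAC = list(c(-1.023, -10.589, -11.612), c(-0.923, -2.771, -3.694),
               c(-1.0111, -8.591, -9.6021), 0.8734),
    TBA = list(c(-2.9986, -11.178, -14.176), c(-0.807, -2.504, -3.311),
               c(-0.766, -6.2641, -7.0301), 21.371),
    TCA = list(c(-5.058, -21.571, -26.629), c(-0.6349, -2.088, -2.723),
               c(-0.3605, -4.111, -4.472), 3.7013),
    TDA = list(c(-5.7264, -21.592, -27.319), c(-0.6434, -2.0724, -2.7159),
               c(-0.412, -3.599, -4.011), 4.0612),
    TMA = list(c(-6.1074, -29.491, -35.598), c(-0.551, -1.7479, -2.298),
               c(-0.3624, -5.082, -5.4443), 4.597)
  )
  out <- dplyr::bind_rows(lapply(names(rows), function(sys) {
    r <- rows[[sys]]
    m <- do.call(rbind, r[1:3])
    tibble::tibble(system = sys,
                   pair = c("hba-hbd", "hba-water", "hbd-water"),
                   e_elec = m[, 1], e_vdw = m[, 2], e_total = m[, 3],
                   s_reported = c(r[[4]], NA, NA))
  }))
  if (!include_tba) out <- dplyr::filter(out, .data$system != "TBA")
  out
}

#' System family of the bundled energy table
#'
#' @param systems Character vector of system codes.
#' @return `"choline-chloride"` for C-prefixed codes, `"thymol"` for
#'   T-prefixed.
#' @export
des_system_family <- function(systems) {
  ifelse(substr(systems, 1, 1) == "C", "choline-chloride", "thymol")
}
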