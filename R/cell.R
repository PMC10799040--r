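#' Orthorhombic simulation cell
#'
#' Constructs the periodic simulation cell used by all distance and energy
#' kernels. Only orthorhombic (rectangular) cells are supported; any analysis
#' cutoff must not exceed half the smallest edge so that the minimum-image
#' convention is unambiguous.
#'
#' @param lengths Numeric vector of three box edge lengths in Angstrom.
#' @return An object of class `simulation_cell` (named numeric length 3).
#' @export
#' @examples
#' simulation_cell(c(30, 30, 60))
simulation_cell <- function(lengths) {
  lengths <- as.numeric(lengths)
  if (length(lengths) != 3 || anyNA(lengths) || any(!is.finite(lengths))) {
    stop("cell lengths must be three finite numbers")
  }
  if (any(lengths <= 0)) stop("cell lengths must all be positive")
  structure(c(a = lengths[1], b = lengths[2], c = lengths[3]),
            class = "simulation_cell")
}

#' @export
print.simulation_cell <- function(x, ...) {
  cat(sprintf("<simulation_cell> %.4f x %.4f x %.4f A (orthorhombic)\n",
              x[1], x[2], x[3]))
  invisible(x)
}

cell_volume <- function(cell) prod(unclass(cell))

# smallest half-edge: upper bound for any minimum-image cutoff
cell_half_min <- function(cell) min(unclass(cell)) / 2

check_cutoff <- function(cutoff, cell) {
  if (cutoff > cell_half_min(cell) + 1e-9) {
    stop(sprintf(
      "cutoff %.3f A exceeds half the smallest cell edge (%.3f A)",
      cutoff, cell_half_min(cell)))
  }
  invisible(cutoff)
}
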