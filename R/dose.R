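#' Injected dCas13/gRNA molecules per embryo
#'
#' Converts an injected dose (molar concentration times injected volume)
#' into a molecule count via Avogadro's number, reported to two
#' significant figures. A typical zygotic injection of a 5.6 uM complex
#' in a ~1 nL bolus delivers ~3.4e9 molecules.
#'
#' @param concentration_M complex concentration, mol/L.
#' @param volume_L injected volume, L.
#' @return molecule count (2 significant figures).
#' @examples
#' molecules_per_embryo(5.6e-6, 1e-9)  # 3.4e9
#' @export
molecules_per_embryo <- function(concentration_M, volume_L) {
  stop_if_not_scalar_num(concentration_M, "concentration_M", min = 0)
  stop_if_not_scalar_num(volume_L, "volume_L", min = 0)
  signif(concentration_M * volume_L * 6.02214076e23, 2)
}

#' Molecules remaining per cell after synchronous divisions
#'
#' The injected pool is assumed to partition evenly over \eqn{2^n} cells
#' after \eqn{n} synchronous division cycles; reported to one significant
#' figure. After 15 cycles (32,768 cells, more than the ~30,000 cells of
#' a gastrula-stage embryo) a 3.4e9-molecule bolus still leaves ~1e5
#' molecules per cell.
#'
#' @param total total molecules injected.
#' @param n_cycles number of division cycles (>= 0).
#' @return molecules per cell (1 significant figure).
#' @examples
#' molecules_per_cell(3.4e9, 15)  # 1e5
#' @export
molecules_per_cell <- function(total, n_cycles) {
  stop_if_not_scalar_num(total, "total", min = 0)
  stop_if_not_scalar_num(n_cycles, "n_cycles", min = 0)
  signif(total / 2^n_cycles, 1)
}

#' Molar ratio of gRNA to dCas13 protein
#'
#' @param c_gRNA gRNA concentration (any unit).
#' @param c_protein protein concentration (same unit, > 0).
#' @return dimensionless ratio.
#' @examples
#' molar_ratio(8.4, 5.6)  # 1.5
#' @export
molar_ratio <- function(c_gRNA, c_protein) {
  stop_if_not_scalar_num(c_gRNA, "c_gRNA", min = 0)
  if (!is.numeric(c_protein) || c_protein <= 0)
    stop("'c_protein' must be > 0", call. = FALSE)
  c_gRNA / c_protein
}
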