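# BDE assembly from species enthalpies and the statistical quality-control
# screens applied to externally supplied computation records. No electronic
# structure is computed here: these functions consume enthalpy tables,
# conformer ensembles and geometries produced elsewhere.

#' @name constants
#' @title Unit constants
#' @description `R_KCAL` is the gas constant in kcal/(mol K);
#'   `HARTREE_TO_KCAL` converts Hartree to kcal/mol.
#' @export
R_KCAL <- 1.987204e-3

#' @rdname constants
#' @export
HARTREE_TO_KCAL <- 627.509

#' Covalent radii (Angstrom)
#'
#' Single-bond covalent radii for the supported elements (Cordero et al.
#' 2008, Dalton Trans., 2832; sp3 value for carbon), used by the geometry
#' connectivity check.
#' @export
COVALENT_RADII <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66)

#' BDE from species enthalpies
#'
#' The enthalpy change of the gas-phase homolysis A-B -> A. + B. at 298 K:
#' `h(radical1) + h(radical2) - h(parent)`, all in kcal/mol.
#'
#' @param h_parent,h_r1,h_r2 enthalpies in kcal/mol (vectorized).
#' @return BDE in kcal/mol.
#' @examples
#' bde_from_enthalpies(20, 52.1, 52.1)  # 84.2
#' @export
bde_from_enthalpies <- function(h_parent, h_r1, h_r2) {
  stopifnot(is.finite(h_parent), is.finite(h_r1), is.finite(h_r2))
  h_r1 + h_r2 - h_parent
}

#' Boltzmann-weighted ensemble enthalpy
#'
#' Boltzmann average of per-conformer enthalpies at temperature `T_K`,
#' together with the gap between the ensemble average and the first
#' conformer (the one derived from the force-field minimum). Energies are
#' shifted by their minimum before exponentiation for numerical stability.
#'
#' @param conformer_h numeric vector of conformer enthalpies (kcal/mol);
#'   element 1 is the first conformer.
#' @param T_K temperature in kelvin (default 298.15).
#' @return list with `h_mean` (the Boltzmann average), `first_conformer_gap`
#'   (`h_mean - conformer_h[1]`) and `weights`.
#' @examples
#' boltzmann_enthalpy(c(0, 0.5926))$h_mean
#' @export
boltzmann_enthalpy <- function(conformer_h, T_K = 298.15) {
  if (!length(conformer_h)) stop("empty conformer ensemble", call. = FALSE)
  stopifnot(T_K > 0, all(is.finite(conformer_h)))
  shifted <- conformer_h - min(conformer_h)
  w <- exp(-shifted / (R_KCAL * T_K))
  w <- w / sum(w)
  h <- sum(w * conformer_h)
  list(h_mean = h, first_conformer_gap = h - conformer_h[1], weights = w)
}

#' Geometry connectivity check
#'
#' Verifies that an optimized structure kept its Lewis-structure bonds: every
#' expected bond must be shorter than the sum of the two covalent radii plus
#' 0.4 Angstrom, otherwise the species decomposed or rearranged.
#'
#' @param symbols character vector of atom element symbols.
#' @param coords numeric matrix (atoms x 3) of coordinates in Angstrom.
#' @param expected_bonds two-column integer matrix (or data.frame) of atom
#'   index pairs from the Lewis structure.
#' @param radii named covalent-radius table (Angstrom).
#' @param slack additive tolerance in Angstrom (default 0.4).
#' @return list with `ok` (logical) and `report` (per-bond data.frame with
#'   `a1`, `a2`, `length`, `threshold`, `intact`).
#' @export
check_connectivity <- function(symbols, coords, expected_bonds,
                               radii = COVALENT_RADII, slack = 0.4) {
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == length(symbols), ncol(coords) == 3L)
  eb <- as.matrix(expected_bonds)
  if (!nrow(eb))
    return(list(ok = TRUE,
                report = data.frame(a1 = integer(0), a2 = integer(0),
                                    length = numeric(0), threshold = numeric(0),
                                    intact = logical(0))))
  miss <- setdiff(unique(symbols[c(eb)]), names(radii))
  if (length(miss))
    stop("no covalent radius for element(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  len <- sqrt(rowSums((coords[eb[, 1], , drop = FALSE] -
                       coords[eb[, 2], , drop = FALSE])^2))
  thr <- radii[symbols[eb[, 1]]] + radii[symbols[eb[, 2]]] + slack
  report <- data.frame(a1 = eb[, 1], a2 = eb[, 2], length = len,
                       threshold = unname(thr), intact = len < thr)
  list(ok = all(report$intact), report = report)
}

#' Read an XYZ geometry file
#'
#' @param path path to a plain XYZ file (count line, comment line, then
#'   `symbol x y z` rows).
#' @return list with `symbols` and `coords` (matrix, Angstrom).
#' @export
read_xyz <- function(path) {
  ln <- readLines(path)
  n <- as.integer(trimws(ln[1]))
  rows <- strsplit(trimws(ln[2L + seq_len(n)]), "[[:space:]]+")
  list(symbols = vapply(rows, `[[`, "", 1),
       coords = matrix(as.numeric(unlist(lapply(rows, `[`, 2:4))), n, 3L,
                       byrow = TRUE))
}

#' Per-formula enthalpy outlier screen
#'
#' Fits one least-squares regression of enthalpy on elemental composition
#' (counts of C, H, N, O, with intercept) over all records and flags records
#' whose absolute residual exceeds `3 x IQR` of the residuals. This screens
#' out species whose computed enthalpy is abnormal for their formula
#' (unreasonable geometries, wrong electronic states).
#'
#' @param records data.frame with columns `smiles` and `h_kcal_mol`, or with
#'   precomputed count columns `nC`, `nH`, `nN`, `nO`.
#' @param iqr_mult residual threshold in IQR units (default 3).
#' @return the input data.frame with added columns `residual` and `flagged`.
#' @export
formula_outlier_screen <- function(records, iqr_mult = 3) {
  if (nrow(records) < 5L)
    stop("need at least 5 records for the outlier screen", call. = FALSE)
  if (!all(c("nC", "nH", "nN", "nO") %in% names(records))) {
    mols <- parse_mol(records$smiles)
    if (inherits(mols, "bde_mol")) mols <- list(mols)
    cnt <- function(m, e) sum(m$atoms$element == e)
    records$nC <- vapply(mols, cnt, 0L, "C")
    records$nH <- vapply(mols, cnt, 0L, "H")
    records$nN <- vapply(mols, cnt, 0L, "N")
    records$nO <- vapply(mols, cnt, 0L, "O")
  }
  X <- as.matrix(records[, c("nC", "nH", "nN", "nO")])
  if (qr(cbind(1, X))$rank < 2L)
    stop("degenerate design: all records share the same composition",
         call. = FALSE)
  fit <- stats::lm.fit(cbind(1, X), records$h_kcal_mol)
  r <- as.numeric(fit$residuals)
  iqr <- stats::IQR(r, type = 7)  # linear-interpolation quantiles
  records$residual <- r
  records$flagged <- abs(r) > iqr_mult * iqr
  records
}

#' Convergence-flag filter for one computation record
#'
#' A record passes only when all four checks recorded by the upstream
#' computation are present: proper termination, no imaginary frequencies,
#' intact connectivity, and a stable wavefunction.
#'
#' @param qc_flags character vector of flags present on the record.
#' @return list with `pass` (logical) and `reasons` (character vector of
#'   failure descriptions, empty when passing).
#' @examples
#' qc_filter(c("ok_termination", "no_imaginary_freq",
#'             "connectivity_ok", "stable_wavefunction"))$pass
#' @export
qc_filter <- function(qc_flags) {
  required <- c(ok_termination = "failed termination",
                no_imaginary_freq = "imaginary frequency",
                connectivity_ok = "decomposed",
                stable_wavefunction = "unstable wavefunction")
  missing <- setdiff(names(required), qc_flags)
  list(pass = length(missing) == 0L, reasons = unname(required[missing]))
}
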