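#' Define a magnetic nucleus
#'
#' @param label Text label (e.g. `"H3"`).
#' @param position_A Cartesian position in angstrom, molecule-fixed frame.
#' @param A_iso_MHz Isotropic hyperfine coupling constant in MHz.
#' @param isotope Isotope string used to look up the gyromagnetic ratio
#'   (see [nucleus_gamma()]); ignored if `gamma_si` is given.
#' @param gamma_si Gyromagnetic ratio in rad s^-1 T^-1 (overrides
#'   `isotope`). Must be nonzero.
#' @return Object of class `nucleus` with the position and couplings stored
#'   both in input units and atomic units.
#' @export
nucleus <- function(label, position_A, A_iso_MHz = 0, isotope = "1H",
                    gamma_si = NULL) {
  if (length(position_A) != 3 || !all(is.finite(position_A))) {
    stop("position must be a finite 3-vector (angstrom)")
  }
  if (is.null(gamma_si)) gamma_si <- nucleus_gamma(isotope)
  if (!is.finite(gamma_si) || gamma_si == 0) {
    stop("gyromagnetic ratio must be finite and nonzero")
  }
  obj <- list(label = as.character(label),
              position_A = as.numeric(position_A),
              position_au = au_from_angstrom(as.numeric(position_A)),
              A_iso_MHz = A_iso_MHz,
              A_iso_au = au_from_MHz(A_iso_MHz),
              gamma_si = gamma_si,
              gamma_au = au_from_gamma_si(gamma_si))
  class(obj) <- "nucleus"
  obj
}

#' @export
print.nucleus <- function(x, ...) {
  cat(sprintf("<nucleus> %s  r = (%.3f, %.3f, %.3f) A  A_iso = %g MHz\n",
              x$label, x$position_A[1], x$position_A[2], x$position_A[3],
              x$A_iso_MHz))
  invisible(x)
}

new_coupling_operator <- function(ops, kind, label) {
  ops <- lapply(ops, function(M) (M + Conj(t(M))) / 2)
  structure(list(ops = ops, kind = kind, label = label),
            class = "coupling_operator")
}

#' @export
print.coupling_operator <- function(x, ...) {
  cat("<coupling_operator>", x$kind, "for", x$label, "\n")
  invisible(x)
}

#' Fermi-contact coupling operator
#'
#' The derivative of the hyperfine Hamiltonian with respect to the nuclear
#' magnetic moment for a purely isotropic coupling:
#' dH/dM_i = (A_iso / gamma) S_i (atomic units).
#'
#' @param system A [spin_system()].
#' @param nuc A [nucleus()].
#' @return A `coupling_operator` of kind `"FC"` (three Hermitian matrices).
#' @export
fc_operator <- function(system, nuc) {
  stopifnot(inherits(system, "spin_system"), inherits(nuc, "nucleus"))
  pref <- nuc$A_iso_au / nuc$gamma_au
  sp <- system$spin
  new_coupling_operator(list(pref * sp$Sx, pref * sp$Sy, pref * sp$Sz),
                        "FC", nuc$label)
}

#' Electronic magnetic moment operator
#'
#' M_el = -dH/dB0 = -(1/2) g S in the spin-Hamiltonian approximation
#' (atomic units, Bohr magneton = 1/2). Component i is
#' -(1/2) sum_j g_ij S_j, consistent with the field derivative of
#' [build_hamiltonian()].
#'
#' @param system A [spin_system()].
#' @return List of three Hermitian matrices.
#' @export
electronic_moment_operator <- function(system) {
  lapply(field_derivative_operators(system), function(M) -M)
}

#' Point-dipole pseudocontact coupling operator
#'
#' Treats the electronic magnetic moment as a point dipole at the
#' paramagnetic center: dH/dM = -(3 alpha^2 / r^3) (rhat x rhat)_aniso M_el
#' with (rhat x rhat)_aniso,ij = rhat_i rhat_j - delta_ij / 3, r the
#' center-to-nucleus distance. The pseudocontact shift is computed here in
#' the spin-Hamiltonian approximation, i.e. with M_el = -(1/2) g S.
#'
#' @param system A [spin_system()].
#' @param nuc A [nucleus()].
#' @param center_A Paramagnetic center in angstrom (default: origin).
#' @param r_min_A Guard distance; below it the point-dipole approximation
#'   is considered broken and an error is raised.
#' @return A `coupling_operator` of kind `"PC"`.
#' @export
pc_operator <- function(system, nuc, center_A = c(0, 0, 0), r_min_A = 0.5) {
  stopifnot(inherits(system, "spin_system"), inherits(nuc, "nucleus"))
  rvec <- nuc$position_au - au_from_angstrom(as.numeric(center_A))
  r <- sqrt(sum(rvec^2))
  if (r < au_from_angstrom(r_min_A)) {
    stop("nucleus '", nuc$label, "' is closer than ", r_min_A,
         " A to the paramagnetic center; point-dipole approximation invalid")
  }
  rhat <- rvec / r
  K <- outer(rhat, rhat) - diag(3) / 3
  Mel <- electronic_moment_operator(system)
  pref <- -3 * .pnmr_const$alpha^2 / r^3
  ops <- lapply(1:3, function(i) {
    M <- matrix(0i, system$dim, system$dim)
    for (j in 1:3) M <- M + pref * K[i, j] * Mel[[j]]
    M
  })
  new_coupling_operator(ops, "PC", nuc$label)
}

# operator triple for a requested contribution; "both" sums FC and PC
coupling_for <- function(system, nuc, contribution = c("FC", "PC", "both"),
                         center_A = c(0, 0, 0)) {
  contribution <- match.arg(contribution)
  if (contribution == "FC") return(fc_operator(system, nuc))
  if (contribution == "PC") return(pc_operator(system, nuc, center_A))
  fc <- fc_operator(system, nuc)
  pc <- pc_operator(system, nuc, center_A)
  new_coupling_operator(Map(`+`, fc$ops, pc$ops), "FC+PC", nuc$label)
}
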