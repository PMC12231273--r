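#' Thermal (Boltzmann) state of a spin Hamiltonian
#'
#' Exact diagonalization thermodynamics: eigenvalues, populations, the
#' partition function and the Helmholtz free energy F = -(1/beta) ln Z.
#' All Boltzmann factors are computed relative to the ground state so that
#' the result is overflow-safe at arbitrarily low temperature or strong
#' field.
#'
#' @param H Complex Hermitian matrix (hartree).
#' @param T_K Temperature in kelvin, > 0.
#' @return Object of class `thermal_state`: `values` (ascending, hartree),
#'   `vectors` (columns = eigenstates), `populations`, `logZ`, `Z`,
#'   `F` (hartree), `T_K`, `beta` (1/hartree).
#' @export
thermal_state <- function(H, T_K) {
  if (!is.numeric(T_K) || length(T_K) != 1 || !is.finite(T_K) || T_K <= 0) {
    stop("temperature must be a single positive number (kelvin)")
  }
  e <- eigen(H, symmetric = TRUE)
  ord <- order(e$values)
  E <- e$values[ord]
  V <- e$vectors[, ord, drop = FALSE]
  beta <- 1 / (.pnmr_const$kB_au * T_K)
  w <- exp(-beta * (E - E[1]))       # ground state factored out
  Zs <- sum(w)
  st <- list(values = E, vectors = V, populations = w / Zs,
             logZ = -beta * E[1] + log(Zs), Z = exp(-beta * E[1] + log(Zs)),
             F = E[1] - log(Zs) / beta, T_K = T_K, beta = beta)
  class(st) <- "thermal_state"
  st
}

#' @export
print.thermal_state <- function(x, ...) {
  cat("<thermal_state>  T =", x$T_K, "K,  F =", format(x$F, digits = 10),
      "Eh\n")
  cat("levels (cm^-1 above ground):",
      paste(format(cm1_from_au(x$values - x$values[1]), digits = 6),
            collapse = ", "), "\n")
  cat("populations:", paste(format(x$populations, digits = 6),
                            collapse = ", "), "\n")
  invisible(x)
}

#' Thermal expectation value of a Hermitian operator
#'
#' (1/Z) sum_i <i|O|i> exp(-beta E_i), evaluated in the eigenbasis of the
#' thermal state.
#'
#' @param state A [thermal_state()].
#' @param O Hermitian matrix of matching dimension.
#' @return Real scalar.
#' @export
thermal_expectation <- function(state, O) {
  stopifnot(inherits(state, "thermal_state"))
  d <- length(state$values)
  if (!all(dim(O) == c(d, d))) {
    stop("operator dimension (", paste(dim(O), collapse = "x"),
         ") does not match state dimension (", d, ")")
  }
  diagO <- Re(colSums(Conj(state$vectors) * (O %*% state$vectors)))
  sum(state$populations * diagO)
}

#' Electronically averaged induced field in the molecule-fixed frame
#'
#' <B_ind>_i = -<dH/dM_i> where dH/dM is a hyperfine coupling operator
#' triple (Fermi-contact or point-dipole) and the thermal average is taken
#' over the eigenstates of the Zeeman+ZFS Hamiltonian at field `B_mol_T`.
#'
#' @param system A [spin_system()].
#' @param dHdM A [coupling_operator()] (or bare list of three Hermitian
#'   matrices, atomic units).
#' @param B_mol_T Field 3-vector, tesla, molecule-fixed frame.
#' @param T_K Temperature, kelvin.
#' @return Induced-field 3-vector in tesla (molecule-fixed frame).
#' @export
induced_field_mol <- function(system, dHdM, B_mol_T, T_K) {
  st <- thermal_state(build_hamiltonian(system, B_mol_T), T_K)
  ops <- coupling_ops(dHdM)
  tesla_from_au(-vapply(ops, function(O) thermal_expectation(st, O),
                        numeric(1)))
}

# accept either a coupling_operator object or a raw list of three matrices
coupling_ops <- function(dHdM) {
  if (inherits(dHdM, "coupling_operator")) return(dHdM$ops)
  if (is.list(dHdM) && length(dHdM) == 3) return(dHdM)
  stop("dHdM must be a coupling_operator or a list of three matrices")
}
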