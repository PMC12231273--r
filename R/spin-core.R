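#' Spin angular momentum matrices
#'
#' Standard matrices of Sx, Sy, Sz in the |S, mS> basis ordered
#' mS = S, S-1, ..., -S. They are Hermitian, satisfy the angular-momentum
#' commutation relations and Sx^2+Sy^2+Sz^2 = S(S+1) I.
#'
#' @param S Spin quantum number; non-negative half-integer.
#' @return List with complex matrices `Sx`, `Sy`, `Sz` of dimension
#'   (2S+1) x (2S+1).
#' @examples
#' sm <- spin_matrices(1/2)   # one half of the Pauli matrices
#' @export
spin_matrices <- function(S) {
  check_half_integer_spin(S)
  d <- as.integer(round(2 * S + 1))
  m <- S - seq_len(d) + 1                      # mS = S ... -S
  Sz <- diag(m, d, d) + 0i
  Sp <- matrix(0i, d, d)
  if (d > 1) {
    # S+ |S, m> = sqrt(S(S+1) - m(m+1)) |S, m+1>; raising moves up one row
    for (k in 2:d) {
      mk <- m[k]
      Sp[k - 1, k] <- sqrt(S * (S + 1) - mk * (mk + 1)) + 0i
    }
  }
  Sm <- Conj(t(Sp))
  list(Sx = (Sp + Sm) / 2, Sy = (Sp - Sm) / (2i), Sz = Sz)
}

check_half_integer_spin <- function(S) {
  if (!is.numeric(S) || length(S) != 1 || !is.finite(S) || S < 0 ||
      abs(2 * S - round(2 * S)) > 1e-12) {
    stop("S must be a non-negative half-integer (0, 1/2, 1, 3/2, ...)")
  }
  invisible(S)
}

#' Construct a spin system
#'
#' An effective electronic model defined by the spin quantum number S, the
#' 3x3 g matrix and the zero-field-splitting (ZFS) tensor D. D must be
#' symmetric; any residual trace is projected out on input (the isotropic
#' part of D only shifts all levels and carries no observable effect).
#'
#' @param S Spin quantum number (half-integer, >= 0).
#' @param g 3x3 g matrix (dimensionless), or a scalar for isotropic g.
#'   Non-symmetric matrices are accepted verbatim; no symmetrization.
#' @param D_cm1 3x3 symmetric ZFS tensor in cm^-1, or `NULL`/0 for none.
#'   Alternatively use `D_axial_cm1`/`E_rhombic_cm1` for the conventional
#'   axial/rhombic parametrization (principal axes = coordinate axes).
#' @param D_axial_cm1,E_rhombic_cm1 Axial parameter D and rhombic parameter
#'   E in cm^-1; used only when `D_cm1` is `NULL`. The principal values are
#'   (-D/3 + E, -D/3 - E, 2D/3).
#' @return Object of class `spin_system` with elements `S`, `g`, `D_au`
#'   (traceless symmetric, hartree), and the spin matrices.
#' @examples
#' sys <- spin_system(S = 1, g = 2.2, D_axial_cm1 = 5, E_rhombic_cm1 = 0.5)
#' @export
spin_system <- function(S, g = 2.0, D_cm1 = NULL,
                        D_axial_cm1 = 0, E_rhombic_cm1 = 0) {
  check_half_integer_spin(S)
  if (length(g) == 1) g <- diag(3) * g
  g <- as.matrix(g)
  if (!all(dim(g) == c(3, 3)) || !all(is.finite(g))) {
    stop("g must be a finite 3x3 matrix or a scalar")
  }
  if (is.null(D_cm1)) {
    D_cm1 <- diag(c(-D_axial_cm1 / 3 + E_rhombic_cm1,
                    -D_axial_cm1 / 3 - E_rhombic_cm1,
                    2 * D_axial_cm1 / 3))
  }
  if (length(D_cm1) == 1) D_cm1 <- diag(3) * D_cm1
  D_cm1 <- as.matrix(D_cm1)
  if (!all(dim(D_cm1) == c(3, 3)) || !all(is.finite(D_cm1))) {
    stop("D must be a finite 3x3 matrix")
  }
  if (max(abs(D_cm1 - t(D_cm1))) > 1e-10 * max(1, max(abs(D_cm1)))) {
    stop("D must be symmetric")
  }
  D_cm1 <- (D_cm1 + t(D_cm1)) / 2
  D_cm1 <- D_cm1 - diag(3) * sum(diag(D_cm1)) / 3   # project out trace
  obj <- list(S = S, g = g, D_au = au_from_cm1(D_cm1),
              spin = spin_matrices(S), dim = as.integer(round(2 * S + 1)))
  class(obj) <- "spin_system"
  obj
}

#' @export
print.spin_system <- function(x, ...) {
  cat("<spin_system>  S =", format(x$S), " (", x$dim, "states )\n")
  cat("g matrix:\n"); print(round(x$g, 6))
  cat("D tensor (cm^-1):\n"); print(round(cm1_from_au(x$D_au), 6))
  invisible(x)
}

#' Zeeman + zero-field-splitting spin Hamiltonian
#'
#' H = S^T D S + (1/2) B^T g S in Hartree atomic units, where the factor
#' 1/2 is the Bohr magneton in atomic units and B is the external field
#' expressed in the molecule-fixed frame. Hyperfine terms are deliberately
#' not part of the diagonalized Hamiltonian; they enter only through the
#' coupling operators (Hellmann-Feynman).
#'
#' @param system A [spin_system()].
#' @param B_mol_T Field 3-vector in tesla, molecule-fixed frame.
#' @return Complex Hermitian matrix, hartree.
#' @export
build_hamiltonian <- function(system, B_mol_T = c(0, 0, 0)) {
  stopifnot(inherits(system, "spin_system"))
  if (length(B_mol_T) != 3 || !all(is.finite(B_mol_T))) {
    stop("B_mol_T must be a finite 3-vector (tesla)")
  }
  B <- au_from_tesla(as.numeric(B_mol_T))
  sp <- system$spin
  Sv <- list(sp$Sx, sp$Sy, sp$Sz)
  d <- system$dim
  H <- matrix(0i, d, d)
  Dm <- system$D_au
  for (i in 1:3) for (j in 1:3) {
    if (Dm[i, j] != 0) H <- H + Dm[i, j] * (Sv[[i]] %*% Sv[[j]])
  }
  gB <- as.numeric(B %*% system$g)   # (B^T g)_j
  for (j in 1:3) {
    if (gB[j] != 0) H <- H + 0.5 * gB[j] * Sv[[j]]
  }
  (H + Conj(t(H))) / 2               # enforce exact Hermiticity
}

# Derivative of the spin Hamiltonian w.r.t. the molecule-fixed field
# components, in atomic units per atomic unit of field:
# dH/dB_i = (1/2) sum_j g_ij S_j
field_derivative_operators <- function(system) {
  sp <- system$spin
  Sv <- list(sp$Sx, sp$Sy, sp$Sz)
  lapply(1:3, function(i) {
    M <- matrix(0i, system$dim, system$dim)
    for (j in 1:3) M <- M + 0.5 * system$g[i, j] * Sv[[j]]
    M
  })
}
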