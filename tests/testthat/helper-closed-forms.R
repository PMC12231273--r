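# Independent closed-form oracles, written directly in SI units so that
# they share nothing with the package's atomic-unit internals beyond the
# CODATA constants themselves.

si <- list(
  muB = 9.2740100783e-24,   # J/T
  kB  = 1.380649e-23,       # J/K
  gamma_1H_MHz_T = 42.577478518
)

# two-level Zeeman populations for S = 1/2, isotropic g
two_level_lower_population <- function(g, B0_T, T_K) {
  x <- g * si$muB * B0_T / (si$kB * T_K)
  1 / (1 + exp(-x))
}

# <Sz> for S = 1/2, isotropic g (Boltzmann average of +-1/2)
two_level_sz <- function(g, B0_T, T_K) {
  -0.5 * tanh(g * si$muB * B0_T / (2 * si$kB * T_K))
}

# Curie law: isotropic molecular susceptibility in atomic units,
# chi = mu0 muB^2 g^2 S(S+1) / (3 kB T), with mu0 = 4 pi alpha^2 and
# muB = 1/2 in atomic units
curie_chi_au <- function(g, S, T_K) {
  cst <- pnmr_constants()
  cst$mu0_au * 0.25 * g^2 * S * (S + 1) / (3 * cst$kB_au * T_K)
}

# classic axial pseudocontact shift (ppm): chi in m^3 per molecule,
# r in metres, theta the polar angle from the chi principal axis
pcs_axial_ppm <- function(dchi_ax_m3, r_m, theta) {
  1e6 * dchi_ax_m3 * (3 * cos(theta)^2 - 1) / (12 * pi * r_m^3)
}

# real spherical harmonics (unnormalized polynomial forms suffice for
# "integrates to zero" checks); degree from 1 to 6
sph_polynomials <- list(
  l1 = function(u) u[3],
  l2 = function(u) 3 * u[3]^2 - 1,
  l3 = function(u) u[1] * (5 * u[3]^2 - 1),
  l4 = function(u) 35 * u[3]^4 - 30 * u[3]^2 + 3,
  l5 = function(u) u[2] * (63 * u[3]^4 - 70 * u[3]^2 + 15) / 8,
  l6 = function(u) 231 * u[3]^6 - 315 * u[3]^4 + 105 * u[3]^2 - 5
)

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

# rotate an entire model (g, D, nuclear positions) by R
rotate_model <- function(system, nuclei, R) {
  sysR <- spin_system(system$S,
                      g = R %*% system$g %*% t(R),
                      D_cm1 = R %*% cm1_from_au(system$D_au) %*% t(R))
  nucR <- lapply(nuclei, function(nu)
    nucleus(nu$label, as.numeric(R %*% nu$position_A), nu$A_iso_MHz,
            gamma_si = nu$gamma_si))
  list(system = sysR, nuclei = nucR)
}

rel_dev <- function(a, b) max(abs(a - b)) / max(abs(b))
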