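#' Physical constants and unit conversions (CODATA 2018)
#'
#' All internal computations in paranmr use Hartree atomic units
#' (hbar = e = m_e = 1, Bohr magneton = 1/2). This function returns the
#' pinned constant set used for every conversion between practical input
#' units (cm^-1, MHz, angstrom, tesla, kelvin) and atomic units.
#'
#' @return Named list of constants. Energies in joule or hartree as named;
#'   `field_au_T` is the atomic unit of magnetic flux density in tesla;
#'   `gamma_1H` is the proton gyromagnetic ratio in rad s^-1 T^-1.
#' @examples
#' cst <- pnmr_constants()
#' cst$field_au_T   # one atomic unit of B in tesla
#' @export
pnmr_constants <- function() .pnmr_const

.pnmr_const <- local({
  alpha     <- 7.2973525693e-3        # fine-structure constant
  hartree_J <- 4.3597447222071e-18    # Eh in joule
  kB_J      <- 1.380649e-23           # exact SI
  bohr_m    <- 0.529177210903e-10     # a0 in metre
  time_au_s <- 2.4188843265857e-17    # atomic unit of time
  field_au  <- 2.35051756758e5        # hbar/(e a0^2) in tesla
  list(
    alpha        = alpha,
    mu0_au       = 4 * pi * alpha^2,        # vacuum permeability, atomic units
    muB_au       = 0.5,                     # Bohr magneton, atomic units
    muB_J_T      = 9.2740100783e-24,        # Bohr magneton, J/T
    kB_J         = kB_J,
    kB_au        = kB_J / hartree_J,        # hartree per kelvin
    hartree_J    = hartree_J,
    bohr_m       = bohr_m,
    time_au_s    = time_au_s,
    field_au_T   = field_au,
    hartree_cm1  = 219474.6313632,          # Eh in cm^-1
    hartree_Hz   = 6.579683920502e15,       # Eh in Hz
    gamma_1H     = 2.6752218744e8,          # rad s^-1 T^-1
    gamma_1H_MHz_T = 42.577478518,          # gamma_1H / 2pi, MHz per tesla
    avogadro     = 6.02214076e23
  )
})

# gyromagnetic ratios for common nuclei, rad s^-1 T^-1 (CODATA 2018 where
# listed, IAEA/INDC recommended values otherwise)
.pnmr_gammas <- c(
  "1H"  =  2.6752218744e8,
  "13C" =  6.728284e7,
  "15N" = -2.7126180e7,
  "19F" =  2.518148e8,
  "31P" =  1.08394e8
)

#' Gyromagnetic ratio of a common nucleus
#'
#' @param isotope One of `"1H"`, `"13C"`, `"15N"`, `"19F"`, `"31P"`.
#' @return Gyromagnetic ratio in rad s^-1 T^-1.
#' @export
nucleus_gamma <- function(isotope) {
  if (!isotope %in% names(.pnmr_gammas)) {
    stop("unknown isotope '", isotope, "'; built-in values exist for: ",
         paste(names(.pnmr_gammas), collapse = ", "),
         " (pass gamma explicitly for other nuclei)")
  }
  unname(.pnmr_gammas[[isotope]])
}

#' Conversions between practical units and Hartree atomic units
#'
#' Energy (cm^-1, MHz), magnetic flux density (tesla) and length
#' (angstrom) converters used at the package's unit boundary. All
#' round-trip to better than 1e-12 relative.
#'
#' @param x Numeric vector.
#' @return Converted numeric vector.
#' @name unit_conversions
NULL

#' @rdname unit_conversions
#' @export
au_from_cm1 <- function(x) x / .pnmr_const$hartree_cm1
#' @rdname unit_conversions
#' @export
cm1_from_au <- function(x) x * .pnmr_const$hartree_cm1

#' @rdname unit_conversions
#' @export
au_from_MHz <- function(x) x * 1e6 / .pnmr_const$hartree_Hz
#' @rdname unit_conversions
#' @export
MHz_from_au <- function(x) x * .pnmr_const$hartree_Hz / 1e6

#' @rdname unit_conversions
#' @export
au_from_tesla <- function(x) x / .pnmr_const$field_au_T
#' @rdname unit_conversions
#' @export
tesla_from_au <- function(x) x * .pnmr_const$field_au_T

au_from_angstrom <- function(x) x * 1e-10 / .pnmr_const$bohr_m
angstrom_from_au <- function(x) x * .pnmr_const$bohr_m / 1e-10

# gamma: rad s^-1 T^-1  ->  atomic units (rad / (a.u. time * a.u. field))
au_from_gamma_si <- function(x) x * .pnmr_const$field_au_T * .pnmr_const$time_au_s
gamma_si_from_au <- function(x) x / (.pnmr_const$field_au_T * .pnmr_const$time_au_s)

# molecular susceptibility: atomic units (bohr^3) -> SI m^3 (per molecule)
m3_from_au_chi <- function(x) x * .pnmr_const$bohr_m^3

#' Convert a proton Larmor frequency to magnetic flux density
#'
#' A "400 MHz spectrometer" labels the magnet by the Larmor frequency of a
#' bare proton; the conversion always uses the proton gyromagnetic ratio,
#' regardless of which nucleus is observed.
#'
#' @param nu_MHz Proton Larmor frequency in MHz (scalar or vector, >= 0).
#' @return Magnetic flux density in tesla.
#' @examples
#' larmor_to_field(1200)  # ~28.2 T
#' @export
larmor_to_field <- function(nu_MHz) {
  if (any(!is.finite(nu_MHz)) || any(nu_MHz < 0)) {
    stop("Larmor frequency must be finite and non-negative")
  }
  nu_MHz / .pnmr_const$gamma_1H_MHz_T
}

#' Convert a magnetic flux density to the proton Larmor frequency
#' @param B0_T Field in tesla.
#' @return Proton Larmor frequency in MHz.
#' @export
field_to_larmor <- function(B0_T) B0_T * .pnmr_const$gamma_1H_MHz_T
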