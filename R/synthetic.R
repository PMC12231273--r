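#' Seeded synthetic spin system generator
#'
#' Draws a random but fully reproducible paramagnetic model in the regime
#' of a high-spin pentacoordinate Ni(II) complex: S = 1, axial ZFS of a
#' few cm^-1 with rhombicity E/D in [0, 1/3] and randomly oriented
#' principal axes, a slightly anisotropic g tensor around 2.2, and protons
#' at 2-6 angstrom from the paramagnetic center with isotropic hyperfine
#' couplings up to about 1 MHz. These defaults are the study conditions of
#' the package's synthetic tests; the RNG state of the caller is left
#' untouched.
#'
#' @param seed Integer seed; the same seed reproduces the system
#'   bit-for-bit.
#' @param S Spin quantum number (default 1).
#' @param n_nuclei Number of protons (default 5).
#' @param D_range Axial ZFS magnitude range in cm^-1 (default 2-8).
#' @param g_range Range for the g principal values (default 2.1-2.3).
#' @param r_range Center-to-nucleus distance range in angstrom
#'   (default 2-6).
#' @param A_range Magnitude range for A_iso in MHz (default 0.1-1);
#'   signs are random.
#' @return List with `system` (a [spin_system()]), `nuclei` (list of
#'   [nucleus()]), and `seed`.
#' @examples
#' synth <- synthetic_system(1)
#' synth$system
#' @export
synthetic_system <- function(seed, S = 1, n_nuclei = 5,
                             D_range = c(2, 8), g_range = c(2.1, 2.3),
                             r_range = c(2, 6), A_range = c(0.1, 1)) {
  if (missing(seed)) stop("a seed is required for reproducibility")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)

  rand_rotation <- function() {
    # uniform random rotation from a normalized quaternion
    q <- stats::rnorm(4)
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
             2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
             2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
           3, 3)
  }

  Dax <- stats::runif(1, D_range[1], D_range[2]) * sample(c(-1, 1), 1)
  EoD <- stats::runif(1, 0, 1 / 3)
  Erh <- abs(Dax) * EoD
  Dprin <- diag(c(-Dax / 3 + Erh, -Dax / 3 - Erh, 2 * Dax / 3))
  RD <- rand_rotation()
  D_cm1 <- RD %*% Dprin %*% t(RD)

  gprin <- diag(stats::runif(3, g_range[1], g_range[2]))
  Rg <- rand_rotation()
  g <- Rg %*% gprin %*% t(Rg)

  system <- spin_system(S, g = g, D_cm1 = D_cm1)

  nucs <- lapply(seq_len(n_nuclei), function(i) {
    u <- stats::rnorm(3)
    u <- u / sqrt(sum(u^2))
    r <- stats::runif(1, r_range[1], r_range[2])
    A <- stats::runif(1, A_range[1], A_range[2]) * sample(c(-1, 1), 1)
    nucleus(label = paste0("H", i), position_A = r * u, A_iso_MHz = A)
  })
  list(system = system, nuclei = nucs, seed = seed)
}
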