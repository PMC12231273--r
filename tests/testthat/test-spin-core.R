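test_that("spin matrices reproduce the defining angular-momentum algebra", {
  # S = 1/2: half the Pauli matrices
  sm <- spin_matrices(1/2)
  expect_equal(sm$Sx, matrix(c(0, 0.5, 0.5, 0), 2, 2) + 0i)
  expect_equal(sm$Sy, matrix(c(0, 0.5i, -0.5i, 0), 2, 2))
  expect_equal(sm$Sz, diag(c(0.5, -0.5)) + 0i)

  for (S in c(1/2, 1, 3/2, 2, 5/2)) {
    sm <- spin_matrices(S)
    d <- 2 * S + 1
    # Hermitian
    for (M in sm) expect_lt(max(abs(M - Conj(t(M)))), 1e-14)
    # commutator [Sx, Sy] = i Sz (cyclically)
    comm <- function(A, B) A %*% B - B %*% A
    expect_lt(max(abs(comm(sm$Sx, sm$Sy) - 1i * sm$Sz)), 1e-13)
    expect_lt(max(abs(comm(sm$Sy, sm$Sz) - 1i * sm$Sx)), 1e-13)
    # Casimir Sx^2 + Sy^2 + Sz^2 = S(S+1) I
    cas <- sm$Sx %*% sm$Sx + sm$Sy %*% sm$Sy + sm$Sz %*% sm$Sz
    expect_lt(max(abs(cas - S * (S + 1) * diag(d))), 1e-12)
  }
  expect_error(spin_matrices(0.3), "half-integer")
  expect_error(spin_matrices(-1), "half-integer")
})

test_that("spin_system validates and projects the ZFS tensor", {
  sys <- spin_system(1, g = 2.1, D_cm1 = diag(c(1, 1, 1)) + 0.5)
  # trace projected out
  expect_lt(abs(sum(diag(sys$D_au))), 1e-14 * max(abs(sys$D_au), 1))
  expect_error(spin_system(1, g = 2, D_cm1 = matrix(1:9, 3, 3)), "symmetric")
  # D/E parametrization puts the gap structure where expected
  sys2 <- spin_system(1, g = 2, D_axial_cm1 = 4, E_rhombic_cm1 = 0)
  E <- sort(Re(eigen(build_hamiltonian(sys2), symmetric = TRUE)$values))
  expect_equal(cm1_from_au(E[3] - E[1]), 4, tolerance = 1e-10)
})

test_that("Hamiltonian is Hermitian and reproduces the Zeeman splitting", {
  # trivial cases
  sys <- spin_system(1, g = 2, D_cm1 = NULL)
  expect_equal(max(abs(build_hamiltonian(sys, c(0, 0, 0)))), 0)

  # axial D, B = 0: gap between mS = 0 and mS = +-1 equals D
  sysD <- spin_system(1, g = 2, D_axial_cm1 = 7)
  E <- sort(Re(eigen(build_hamiltonian(sysD), symmetric = TRUE)$values))
  expect_equal(cm1_from_au(E[2] - E[1]), 7, tolerance = 1e-10)
  expect_equal(E[3], E[2], tolerance = 1e-18)

  # S = 1/2 Zeeman splitting equals g muB B0 (converted back to SI)
  g <- 2.31; B0 <- 17.6
  sys12 <- spin_system(1/2, g = g)
  E <- sort(Re(eigen(build_hamiltonian(sys12, c(0, 0, B0)),
                     symmetric = TRUE)$values))
  gap_J <- (E[2] - E[1]) * pnmr_constants()$hartree_J
  expect_equal(gap_J, g * si$muB * B0, tolerance = 1e-10)

  # Hermiticity and joint-rotation invariance of the spectrum
  set.seed(42)
  for (k in 1:5) {
    S <- sample(c(1/2, 1, 3/2, 2), 1)
    g <- matrix(rnorm(9, sd = 0.3), 3, 3) + diag(3) * 2
    Dm <- matrix(rnorm(9), 3, 3); Dm <- (Dm + t(Dm))
    sys <- spin_system(S, g = g, D_cm1 = Dm)
    B <- rnorm(3, sd = 10)
    H <- build_hamiltonian(sys, B)
    expect_lt(max(abs(H - Conj(t(H)))), 1e-14 * max(1, max(abs(H))))
    R <- random_rotation()
    sysR <- spin_system(S, g = R %*% g %*% t(R),
                        D_cm1 = R %*% (Dm - diag(3) * sum(diag(Dm)) / 3) %*% t(R))
    HR <- build_hamiltonian(sysR, as.numeric(R %*% B))
    expect_equal(sort(Re(eigen(HR, symmetric = TRUE)$values)),
                 sort(Re(eigen(H, symmetric = TRUE)$values)),
                 tolerance = 1e-10)
  }
})

test_that("an isotropic energy offset leaves populations and shifts alone", {
  sys <- spin_system(1, g = 2.2, D_axial_cm1 = 5, E_rhombic_cm1 = 1)
  nuc <- nucleus("H1", c(2.5, 1, -0.5), A_iso_MHz = 0.7)
  H <- build_hamiltonian(sys, c(0, 0, 10))
  c0 <- 3.7e-3  # hartree
  st1 <- thermal_state(H, 298)
  st2 <- thermal_state(H + c0 * diag(3), 298)
  expect_equal(st2$values, st1$values + c0, tolerance = 1e-12)
  expect_equal(st2$populations, st1$populations, tolerance = 1e-12)
  op <- fc_operator(sys, nuc)
  expect_equal(thermal_expectation(st2, op$ops[[3]]),
               thermal_expectation(st1, op$ops[[3]]), tolerance = 1e-12)
})

test_that("unit conversions round-trip to 1e-12 relative", {
  vals <- c(1e-6, 0.17, 3.5, 1234)
  expect_equal(cm1_from_au(au_from_cm1(vals)), vals, tolerance = 1e-12)
  expect_equal(MHz_from_au(au_from_MHz(vals)), vals, tolerance = 1e-12)
  expect_equal(tesla_from_au(au_from_tesla(vals)), vals, tolerance = 1e-12)
  expect_equal(angstrom_from_au(au_from_angstrom(vals)), vals,
               tolerance = 1e-12)
  expect_equal(gamma_si_from_au(au_from_gamma_si(vals)), vals,
               tolerance = 1e-12)
})
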