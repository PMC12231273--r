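test_that("Curie law: isotropic chi from both derivative routes", {
  for (S in c(1/2, 1, 5/2)) {
    g <- 2.04
    sys <- spin_system(S, g = g)
    chi_cf <- curie_chi_au(g, S, 298)
    so <- sos_free_energy_derivatives(sys, NULL, 298, order = 2)
    expect_equal(-pnmr_constants()$mu0_au * so$F_BB, chi_cf * diag(3),
                 tolerance = 1e-10)
    nu <- numeric_free_energy_derivatives(sys, NULL, 298, order = 2)
    expect_equal(-pnmr_constants()$mu0_au * nu$F_BB, chi_cf * diag(3),
                 tolerance = 1e-8)
  }
})

test_that("S = 0 analog: one-dimensional space gives vanishing tensors", {
  sys <- spin_system(0, g = 2)
  nuc <- nucleus("H", c(3, 0, 0), A_iso_MHz = 1)
  resp <- assemble_response(sys, nuc, 298, "FC")
  expect_equal(max(abs(resp$sigma)), 0)
  expect_equal(max(abs(resp$chi_au)), 0)
  expect_equal(max(abs(resp$tau4)), 0)
  nu2 <- numeric_free_energy_derivatives(sys, fc_operator(sys, nuc), 298,
                                         order = 4)
  expect_equal(max(abs(nu2$F_MB)), 0, tolerance = 1e-20)
  expect_equal(max(abs(nu2$F_MBBB)), 0, tolerance = 1e-20)
})

test_that("sum-over-states matches the numerical-derivative oracle on a seeded suite", {
  # randomized systems spanning all spins, rhombic D, anisotropic g;
  # quasi-degenerate Kramers doublets included by construction
  spins <- rep(c(1/2, 1, 3/2, 2, 5/2), 2)
  for (k in seq_along(spins)) {
    synth <- synthetic_system(100 + k, S = spins[k], n_nuclei = 1)
    sys <- synth$system
    nuc <- synth$nuclei[[1]]
    for (kind in c("FC", "PC")) {
      op <- if (kind == "FC") fc_operator(sys, nuc) else pc_operator(sys, nuc)
      so <- sos_free_energy_derivatives(sys, op, 298, order = 4)
      nu <- numeric_free_energy_derivatives(sys, op, 298, order = 4)
      expect_lt(rel_dev(so$F_MB, nu$F_MB), 1e-6)
      expect_lt(rel_dev(so$F_BB, nu$F_BB), 1e-6)
      expect_lt(rel_dev(so$F_MBBB, nu$F_MBBB), 1e-6)
    }
  }
})

test_that("Van Vleck structure: S = 1 susceptibility across temperatures", {
  # Curie term + temperature-independent term; SOS must track the numeric
  # oracle over the whole range, including kT comparable to the ZFS
  sys <- spin_system(1, g = diag(c(2.1, 2.15, 2.3)), D_axial_cm1 = 8,
                     E_rhombic_cm1 = 2)
  for (T_K in c(50, 100, 200, 400)) {
    so <- sos_free_energy_derivatives(sys, NULL, T_K, order = 2)
    nu <- numeric_free_energy_derivatives(sys, NULL, T_K, order = 2)
    expect_lt(rel_dev(so$F_BB, nu$F_BB), 1e-6)
  }
})

test_that("high-temperature scaling: chi ~ 1/T and tau4 ~ 1/T^3", {
  synth <- synthetic_system(31)
  sys <- synth$system
  op <- fc_operator(sys, synth$nuclei[[1]])
  Ts <- c(500, 1000, 2000, 5000)
  chi_n <- vapply(Ts, function(Tk)
    max(abs(sos_free_energy_derivatives(sys, NULL, Tk)$F_BB)), numeric(1))
  tau_n <- vapply(Ts, function(Tk)
    max(abs(sos_free_energy_derivatives(sys, op, Tk, order = 4)$F_MBBB)),
    numeric(1))
  fit <- function(y) stats::coef(stats::lm(log(y) ~ log(Ts)))[2]
  expect_equal(as.numeric(fit(chi_n)), -1, tolerance = 0.01)
  expect_equal(as.numeric(fit(tau_n)), -3, tolerance = 0.01)
})

test_that("spin dyadic and tetradic: closed form, supersymmetry, contraction routes", {
  cst <- pnmr_constants()
  # D = 0: dyadic = -beta S(S+1)/3 delta_ij
  for (S in c(1/2, 3/2)) {
    mo <- spin_moments(spin_system(S, g = 2), 298)
    beta <- 1 / (cst$kB_au * 298)
    expect_equal(mo$dyadic, -beta * S * (S + 1) / 3 * diag(3),
                 tolerance = 1e-12)
  }
  synth <- synthetic_system(41)
  sys <- synth$system
  mo <- spin_moments(sys, 298)
  expect_equal(mo$dyadic, t(mo$dyadic), tolerance = 1e-12)
  # tetradic invariant under all 24 index permutations
  perms <- list(c(2, 1, 3, 4), c(1, 3, 2, 4), c(1, 2, 4, 3),
                c(4, 3, 2, 1), c(3, 4, 1, 2), c(2, 3, 4, 1))
  for (p in perms) {
    expect_lt(max(abs(aperm(mo$tetradic, p) - mo$tetradic)),
              1e-10 * max(abs(mo$tetradic)))
  }
  # contracting the moments with the operator coefficient matrices must
  # reproduce the generic sum-over-states tensors
  nuc <- synth$nuclei[[1]]
  cB <- sys$g / 2                        # dH/dB_i = sum_j (g_ij/2) S_j
  cM <- diag(3) * nuc$A_iso_au / nuc$gamma_au
  F_BB_mo <- cB %*% mo$dyadic %*% t(cB)
  F_MB_mo <- cM %*% mo$dyadic %*% t(cB)
  so <- sos_free_energy_derivatives(sys, fc_operator(sys, nuc), 298,
                                    order = 4)
  expect_lt(rel_dev(F_BB_mo, so$F_BB), 1e-8)
  expect_lt(rel_dev(F_MB_mo, so$F_MB), 1e-8)
  F_MBBB_mo <- array(0, c(3, 3, 3, 3))
  for (i in 1:3) for (j in 1:3) for (k in 1:3) for (l in 1:3) {
    acc <- 0
    for (p in 1:3) for (q in 1:3) for (r in 1:3) for (s in 1:3) {
      acc <- acc + cM[i, p] * cB[j, q] * cB[k, r] * cB[l, s] *
        mo$tetradic[p, q, r, s]
    }
    F_MBBB_mo[i, j, k, l] <- acc
  }
  expect_lt(rel_dev(F_MBBB_mo, so$F_MBBB), 1e-8)
})

test_that("assembled tensors: symmetries, tau closed form, index pairing", {
  cst <- pnmr_constants()
  # S=1/2 isotropic FC: tau from the (4:2)/5 contraction equals the
  # closed form from the x^3 coefficient of tanh
  g <- 2.0
  sys <- spin_system(1/2, g = g)
  nuc <- nucleus("H1", c(3, 0, 0), A_iso_MHz = 0.5)
  resp <- assemble_response(sys, nuc, 298, "FC")
  beta <- 1 / (cst$kB_au * 298)
  tau_cf <- (nuc$A_iso_au / (2 * nuc$gamma_au)) * (1 / 3) * (beta * g / 4)^3
  expect_equal(resp$tau_au, tau_cf, tolerance = 1e-12)
  sigma_cf <- -(nuc$A_iso_au * beta * g) / (8 * nuc$gamma_au)
  expect_equal(resp$sigma, sigma_cf * diag(3), tolerance = 1e-12)

  synth <- synthetic_system(51)
  respA <- assemble_response(synth$system, synth$nuclei[[1]], 298, "PC")
  # chi symmetric; tau4 symmetric in its three field indices
  expect_equal(respA$chi_au, t(respA$chi_au),
               tolerance = 1e-10 * max(abs(respA$chi_au)))
  for (p in list(c(1, 3, 2, 4), c(1, 2, 4, 3), c(1, 4, 3, 2))) {
    expect_lt(max(abs(aperm(respA$tau4, p) - respA$tau4)),
              1e-10 * max(abs(respA$tau4)))
  }
  # pairing the moment index with any one field index in the (4:2)
  # contraction is equivalent (asserted, not assumed)
  c1 <- sum(vapply(1:3, function(i) sum(vapply(1:3, function(j)
    respA$tau4[i, i, j, j], numeric(1))), numeric(1)))
  c2 <- sum(vapply(1:3, function(i) sum(vapply(1:3, function(j)
    respA$tau4[i, j, i, j], numeric(1))), numeric(1)))
  c3 <- sum(vapply(1:3, function(i) sum(vapply(1:3, function(j)
    respA$tau4[i, j, j, i], numeric(1))), numeric(1)))
  expect_equal(c1, c2, tolerance = 1e-10 * abs(c1))
  expect_equal(c1, c3, tolerance = 1e-10 * abs(c1))

  # trace of sigma_PC vanishes for an isotropic electronic response
  sys_iso <- spin_system(1, g = 2.2)
  resp_iso <- assemble_response(sys_iso, nucleus("H", c(1.8, 2.2, -1)),
                                298, "PC")
  expect_lt(abs(sum(diag(resp_iso$sigma))), 1e-10 * max(abs(resp_iso$sigma)))
})

test_that("response tensors transform covariantly under rotations", {
  synth <- synthetic_system(61)
  resp <- assemble_response(synth$system, synth$nuclei[[1]], 298, "PC")
  set.seed(62)
  for (k in 1:5) {
    R <- random_rotation()
    rot <- rotate_model(synth$system, synth$nuclei[1], R)
    respR <- assemble_response(rot$system, rot$nuclei[[1]], 298, "PC")
    expect_lt(rel_dev(R %*% resp$sigma %*% t(R), respR$sigma), 1e-8)
    expect_lt(rel_dev(R %*% resp$chi_au %*% t(R), respR$chi_au), 1e-8)
    t4 <- array(0, c(3, 3, 3, 3))
    for (i in 1:3) for (j in 1:3) for (kk in 1:3) for (l in 1:3) {
      t4[i, j, kk, l] <- sum(outer(outer(R[i, ], R[j, ]),
                                   outer(R[kk, ], R[l, ])) * resp$tau4)
    }
    expect_lt(rel_dev(t4, respR$tau4), 1e-8)
  }
})

test_that("a non-convergent Richardson sequence is flagged, not silent", {
  sys <- spin_system(1, g = 2.2, D_axial_cm1 = 5)
  nuc <- nucleus("H", c(2.5, 0, 1), A_iso_MHz = 0.4)
  # a grotesquely large base step cannot converge
  expect_warning(
    numeric_free_energy_derivatives(sys, fc_operator(sys, nuc), 298,
                                    order = 2, h0 = 50, levels = 2),
    "tolerance")
})
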