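test_that("finite-field induced field: zero operators, closed form, weak-field limit", {
  sys <- spin_system(1/2, g = 2.0)
  nuc <- nucleus("H1", c(3, 0, 0), A_iso_MHz = 0.8)
  grid <- lebedev_grid(26)
  zero_ops <- lapply(1:3, function(i) matrix(0i, 2, 2))
  expect_identical(
    as.numeric(finite_field_induced_field(sys, zero_ops, 20, 298, grid)), 0)

  # isotropic system: orientational average is trivial, tanh closed form
  op <- fc_operator(sys, nuc)
  pref_au <- nuc$A_iso_au / nuc$gamma_au
  for (B0 in c(9.4, 28.2, 200)) {
    b <- finite_field_induced_field(sys, op, B0, 298, grid)
    expect_equal(b, tesla_from_au(-pref_au * two_level_sz(2.0, B0, 298)),
                 tolerance = 1e-10)
  }

  # B0 -> 0: delta converges to -tr(sigma)/3 from the response route
  sysA <- spin_system(1, g = diag(c(2.1, 2.2, 2.3)), D_axial_cm1 = 5,
                      E_rhombic_cm1 = 1)
  nucA <- nucleus("H", c(2.4, 1.1, -0.8), A_iso_MHz = 0.6)
  resp <- assemble_response(sysA, nucA, 298, "FC")
  delta0 <- -sum(diag(resp$sigma)) / 3
  B0 <- 1e-3
  b <- finite_field_induced_field(sysA, fc_operator(sysA, nucA), B0, 298,
                                  lebedev_grid(50))
  expect_equal(b / B0, delta0, tolerance = 1e-8)
})

test_that("finite-field shifts: errors, isotropic PC null, decomposition", {
  sys <- spin_system(1/2, g = 2.0)   # isotropic, no ZFS
  nuc <- nucleus("H1", c(3, 1, 0), A_iso_MHz = 0.5)
  grid <- lebedev_grid(26)
  expect_error(finite_field_shift(sys, list(nuc), 0, 298, grid),
               "second-order")

  # far-away nucleus without hyperfine: both contributions vanish
  nfar <- nucleus("far", c(4e3, 0, 0), A_iso_MHz = 0)
  tab <- finite_field_shift(sys, list(nfar), 28.2, 298, grid)
  expect_lt(abs(tab$delta_FC_ppm), 1e-14)
  expect_lt(abs(tab$delta_PC_ppm), 1e-12)

  # isotropic electronic response: orientationally averaged PC shift is
  # zero at any field strength
  for (B0 in c(9.4, 28.2, 100)) {
    tab <- finite_field_shift(sys, list(nuc), B0, 298, grid,
                              contributions = "PC")
    expect_lt(abs(tab$delta_PC_ppm), 1e-9)
  }

  # delta_total = delta_FC + delta_PC exactly
  synth <- synthetic_system(21)
  tab <- finite_field_shift(synth$system, synth$nuclei, 28.2, 298, grid)
  expect_equal(tab$delta_ppm, tab$delta_FC_ppm + tab$delta_PC_ppm,
               tolerance = 1e-15)
})

test_that("induced field is odd in B0", {
  synth <- synthetic_system(5)
  op <- coupling_for(synth$system, synth$nuclei[[1]], "both")
  grid <- lebedev_grid(38)
  for (B0 in c(2, 28.2, 150)) {
    bp <- finite_field_induced_field(synth$system, op, B0, 298, grid)
    bm <- finite_field_induced_field(synth$system, op, -B0, 298, grid)
    expect_equal(bp, -bm, tolerance = 1e-12)
  }
})

test_that("shifts are invariant under a global rotation of the model", {
  synth <- synthetic_system(9, n_nuclei = 2)
  set.seed(13)
  R <- random_rotation()
  rot <- rotate_model(synth$system, synth$nuclei, R)
  grid <- lebedev_grid(110)
  t1 <- finite_field_shift(synth$system, synth$nuclei, 28.2, 298, grid)
  t2 <- finite_field_shift(rot$system, rot$nuclei, 28.2, 298, grid)
  expect_lt(rel_dev(t2$delta_ppm, t1$delta_ppm), 1e-10)
})

test_that("grid convergence: every rule from 26 points on agrees with the largest grid", {
  synth <- synthetic_system(11)
  B0 <- larmor_to_field(400)
  ref <- finite_field_shift(synth$system, synth$nuclei, B0, 298,
                            lebedev_grid(434))
  for (n in c(26, 38, 50, 110, 194)) {
    tab <- finite_field_shift(synth$system, synth$nuclei, B0, 298,
                              lebedev_grid(n))
    expect_lt(max(abs(tab$delta_ppm - ref$delta_ppm) / abs(ref$delta_ppm)),
              1e-8)
  }
})

test_that("dropping the Boltzmann orientation weights changes anisotropic shifts", {
  synth <- synthetic_system(11)
  op <- fc_operator(synth$system, synth$nuclei[[1]])
  grid <- lebedev_grid(50)
  b_w <- finite_field_induced_field(synth$system, op, 28.2, 298, grid)
  b_u <- finite_field_induced_field(synth$system, op, 28.2, 298, grid,
                                    weighting = "uniform")
  # the self-orientation effect is small but far above quadrature noise
  expect_gt(abs(b_w - b_u) / abs(b_w), 1e-8)
})
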