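# Free-energy derivative tensors at zero field.
#
# Analytic route: k-th derivatives of Z = tr exp(-beta H) with respect to
# parameters that enter H linearly are sums over chains of eigenstates of
# the field-free Hamiltonian, weighted by confluent divided differences of
# exp(-beta x) at the chain energies (imaginary-time Dyson expansion +
# Hermite-Genocchi). Divided differences with coincident or nearly
# coincident nodes are evaluated exactly through the Opitz identity
# (corner entry of the matrix exponential of a bidiagonal node matrix), so
# degenerate and quasi-degenerate levels need no special-casing and no
# grouping tolerance. Derivatives of F = -ln(Z)/beta follow from the
# log-cumulant (Faa di Bruno) formulas.

# divided difference of exp(-beta x) at the given nodes (length k+1)
dd_exp <- function(nodes, beta) {
  k <- length(nodes) - 1
  if (k == 0) return(exp(-beta * nodes))
  if (max(nodes) - min(nodes) == 0) {
    return((-beta)^k * exp(-beta * nodes[1]) / factorial(k))
  }
  ref <- min(nodes)
  J <- diag(-beta * (nodes - ref))
  for (i in seq_len(k)) J[i, i + 1] <- 1
  # f[x0..xk] of exp at -beta*(nodes-ref), scaled back; beta absorbed in J
  # via exp(-beta x) = exp(y) with y = -beta x, dd picks up (-beta)^0: the
  # node matrix already carries -beta, so expm(J)[1, k+1] is the divided
  # difference of exp(y) at y_i = -beta(x_i - ref) w.r.t. y; convert to
  # x-divided-difference by (-beta)^k.
  P <- as.matrix(Matrix::expm(J))
  exp(-beta * ref) * (-beta)^k * P[1, k + 1]
}

# chain-weight tables G_k[n1,...,nk] = dd_exp(E[n1],...,E[nk],E[n1]) with a
# cache keyed by the sorted node multiset (divided differences are
# symmetric in their nodes)
chain_weights <- function(E, beta, kmax) {
  d <- length(E)
  cache <- new.env(parent = emptyenv())
  dd <- function(idx) {
    key <- paste(sort.int(idx), collapse = ",")
    v <- cache[[key]]
    if (is.null(v)) {
      v <- dd_exp(E[idx], beta)
      cache[[key]] <- v
    }
    v
  }
  out <- list()
  out$G1 <- vapply(seq_len(d), function(n) dd(c(n, n)), numeric(1))
  if (kmax >= 2) {
    g <- expand.grid(n1 = seq_len(d), n2 = seq_len(d))
    out$G2 <- array(vapply(seq_len(nrow(g)), function(r)
      dd(c(g$n1[r], g$n2[r], g$n1[r])), numeric(1)), c(d, d))
  }
  if (kmax >= 3) {
    g <- expand.grid(n1 = seq_len(d), n2 = seq_len(d), n3 = seq_len(d))
    out$G3 <- array(vapply(seq_len(nrow(g)), function(r)
      dd(c(g$n1[r], g$n2[r], g$n3[r], g$n1[r])), numeric(1)), c(d, d, d))
  }
  if (kmax >= 4) {
    g <- expand.grid(n1 = seq_len(d), n2 = seq_len(d), n3 = seq_len(d),
                     n4 = seq_len(d))
    out$G4 <- array(vapply(seq_len(nrow(g)), function(r)
      dd(c(g$n1[r], g$n2[r], g$n3[r], g$n4[r], g$n1[r])), numeric(1)),
      c(d, d, d, d))
  }
  out
}

# Sum-over-states engine for one field-free Hamiltonian and a list of
# perturbing operators (all entering H linearly). Returns closures that
# evaluate derivatives of F w.r.t. the coefficients of the named operators.
sos_engine <- function(H0, ops, T_K, kmax = 4) {
  beta <- 1 / (.pnmr_const$kB_au * T_K)
  e <- eigen(H0, symmetric = TRUE)
  E <- e$values - min(e$values)          # common shift cancels in all ratios
  U <- e$vectors
  d <- length(E)
  W <- lapply(ops, function(V) Conj(t(U)) %*% V %*% U)
  G <- chain_weights(E, beta, kmax)
  Z <- sum(exp(-beta * E))

  # linear chain indices for the contraction sums
  li <- function(i, j) i + d * (j - 1L)
  g3 <- expand.grid(n1 = seq_len(d), n2 = seq_len(d), n3 = seq_len(d))
  I3 <- list(li(g3$n1, g3$n2), li(g3$n2, g3$n3), li(g3$n3, g3$n1))
  g4 <- expand.grid(n1 = seq_len(d), n2 = seq_len(d), n3 = seq_len(d),
                    n4 = seq_len(d))
  I4 <- list(li(g4$n1, g4$n2), li(g4$n2, g4$n3), li(g4$n3, g4$n4),
             li(g4$n4, g4$n1))

  zcache <- new.env(parent = emptyenv())
  zmemo <- function(idx, fun) {
    key <- paste(c(length(idx), sort.int(idx)), collapse = ",")
    v <- zcache[[key]]
    if (is.null(v)) { v <- fun(); zcache[[key]] <- v }
    v
  }
  z1 <- function(a) zmemo(a, function()
    sum(Re(diag(W[[a]])) * G$G1))
  z2 <- function(a, b) zmemo(c(a, b), function()
    sum(Re(W[[a]] * t(W[[b]]) + W[[b]] * t(W[[a]])) * G$G2))
  perms3 <- list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  z3 <- function(a, b, c) zmemo(c(a, b, c), function() {
    ab <- c(a, b, c)
    tot <- 0
    for (p in perms3) {
      P <- lapply(ab[p], function(q) as.vector(W[[q]]))
      tot <- tot + sum(Re(P[[1]][I3[[1]]] * P[[2]][I3[[2]]] *
                          P[[3]][I3[[3]]]) * G$G3)
    }
    tot
  })
  perms4 <- as.matrix(expand.grid(i = 1:4, j = 1:4, k = 1:4, l = 1:4))
  perms4 <- perms4[apply(perms4, 1, function(r) length(unique(r)) == 4), ,
                   drop = FALSE]
  z4 <- function(a, b, c, e4) zmemo(c(a, b, c, e4), function() {
    ab <- c(a, b, c, e4)
    tot <- 0
    for (r in seq_len(nrow(perms4))) {
      P <- lapply(ab[perms4[r, ]], function(q) as.vector(W[[q]]))
      tot <- tot + sum(Re(P[[1]][I4[[1]]] * P[[2]][I4[[2]]] *
                          P[[3]][I4[[3]]] * P[[4]][I4[[4]]]) * G$G4)
    }
    tot
  })

  # cumulant (log-derivative) assembly: F = -(1/beta) ln Z
  F1 <- function(a) -(1 / beta) * z1(a) / Z
  F2 <- function(a, b) -(1 / beta) *
    (z2(a, b) / Z - z1(a) * z1(b) / Z^2)
  F3 <- function(a, b, c) -(1 / beta) *
    (z3(a, b, c) / Z -
       (z2(a, b) * z1(c) + z2(a, c) * z1(b) + z2(b, c) * z1(a)) / Z^2 +
       2 * z1(a) * z1(b) * z1(c) / Z^3)
  F4 <- function(a, b, c, e4) {
    s31 <- z3(a, b, c) * z1(e4) + z3(a, b, e4) * z1(c) +
      z3(a, c, e4) * z1(b) + z3(b, c, e4) * z1(a)
    s22 <- z2(a, b) * z2(c, e4) + z2(a, c) * z2(b, e4) +
      z2(a, e4) * z2(b, c)
    s211 <- z2(a, b) * z1(c) * z1(e4) + z2(a, c) * z1(b) * z1(e4) +
      z2(a, e4) * z1(b) * z1(c) + z2(b, c) * z1(a) * z1(e4) +
      z2(b, e4) * z1(a) * z1(c) + z2(c, e4) * z1(a) * z1(b)
    s1111 <- z1(a) * z1(b) * z1(c) * z1(e4)
    -(1 / beta) * (z4(a, b, c, e4) / Z - (s31 + s22) / Z^2 +
                     2 * s211 / Z^3 - 6 * s1111 / Z^4)
  }
  list(F1 = F1, F2 = F2, F3 = F3, F4 = F4, beta = beta)
}

#' Analytic sum-over-states free-energy derivatives at zero field
#'
#' Second and fourth derivatives of the electronic Helmholtz free energy
#' with respect to the molecule-fixed field components (and one nuclear
#' magnetic moment component when a coupling operator is supplied),
#' evaluated analytically from the eigensystem of the field-free
#' Hamiltonian. Degenerate and quasi-degenerate levels are handled exactly
#' through confluent divided differences; no energy-gap division occurs.
#'
#' @param system A [spin_system()].
#' @param dHdM Optional [coupling_operator()]; required for the mixed
#'   moment-field derivatives (shielding, tau).
#' @param T_K Temperature in kelvin.
#' @param order 2 or 4.
#' @return List with `F_BB` (3x3, d2F/dB_i dB_j, atomic units); when
#'   `dHdM` is given additionally `F_MB` (3x3, `[i, j]` = F_{M_i B_j}) and,
#'   for `order = 4`, `F_MBBB` (3x3x3x3, `[i, j, k, l]` =
#'   F_{M_i B_j B_k B_l}).
#' @export
sos_free_energy_derivatives <- function(system, dHdM = NULL, T_K,
                                        order = 2) {
  if (!order %in% c(2, 4)) stop("order must be 2 or 4")
  H0 <- build_hamiltonian(system, c(0, 0, 0))
  VB <- field_derivative_operators(system)
  ops <- VB
  iM <- NULL
  if (!is.null(dHdM)) {
    VM <- coupling_ops(dHdM)
    ops <- c(ops, VM)
    iM <- 4:6
  }
  eng <- sos_engine(H0, ops, T_K, kmax = if (order >= 4) 4 else 2)
  out <- list(T_K = T_K)
  out$F_BB <- outer(1:3, 1:3, Vectorize(function(i, j) eng$F2(i, j)))
  if (!is.null(iM)) {
    out$F_MB <- outer(1:3, 1:3,
                      Vectorize(function(i, j) eng$F2(iM[i], j)))
    if (order >= 4) {
      A <- array(0, c(3, 3, 3, 3))
      for (i in 1:3) for (j in 1:3) for (k in j:3) for (l in k:3) {
        v <- eng$F4(iM[i], j, k, l)
        for (p in unique(list(c(j,k,l), c(j,l,k), c(k,j,l),
                              c(k,l,j), c(l,j,k), c(l,k,j)))) {
          A[i, p[1], p[2], p[3]] <- v
        }
      }
      out$F_MBBB <- A
    }
  }
  out
}

## -- numerical differentiation oracle ---------------------------------------

# Richardson extrapolation of a finite-difference estimator D(h) with
# leading error O(h^2). Returns extrapolated value and an error estimate.
richardson <- function(Dfun, h0, levels = 4) {
  Tt <- vector("list", levels)
  for (k in seq_len(levels)) {
    row <- vector("list", k)
    row[[1]] <- Dfun(h0 / 2^(k - 1))
    if (k > 1) {
      for (j in 2:k) {
        row[[j]] <- (4^(j - 1) * row[[j - 1]] - Tt[[k - 1]][[j - 1]]) /
          (4^(j - 1) - 1)
      }
    }
    Tt[[k]] <- row
  }
  best <- Tt[[levels]][[levels]]
  prev <- Tt[[levels]][[levels - 1]]
  list(value = best, error = max(abs(best - prev)))
}

#' Numerical free-energy derivatives (finite-difference oracle)
#'
#' Central differences with Richardson extrapolation for the zero-field
#' derivatives of the electronic Helmholtz free energy. Derivatives with
#' respect to a nuclear-moment component are never taken numerically: the
#' Hellmann-Feynman identity F_M(B) = <dH/dM> reduces them to thermal
#' expectation values, so only field derivatives are differenced.
#'
#' @param system A [spin_system()].
#' @param dHdM Optional [coupling_operator()] triple; required for mixed
#'   moment-field derivatives (orders carrying one M index).
#' @param T_K Temperature in kelvin.
#' @param order 2, 3 or 4.
#' @param h0 Base field step in atomic units; default
#'   0.05 * kT / (muB * max|g|), which keeps the stencil well inside the
#'   Boltzmann saturation scale at every temperature.
#' @param levels Richardson levels (>= 2).
#' @param tol Relative accuracy demanded of the extrapolation; a result
#'   whose error estimate exceeds it is flagged, not silently returned.
#' @return List with the same tensor layout as
#'   [sos_free_energy_derivatives()] (plus `F_BBB`/`F_MBB` at order 3),
#'   and for each tensor an `<name>_error` estimate; `converged` reports
#'   the flag per tensor.
#' @export
numeric_free_energy_derivatives <- function(system, dHdM = NULL, T_K,
                                            order = 2, h0 = NULL,
                                            levels = 4, tol = 1e-6) {
  if (!order %in% c(2, 3, 4)) stop("order must be 2, 3 or 4")
  if (is.null(h0)) {
    gmax <- max(abs(system$g), 1e-3)
    h0 <- 0.05 * .pnmr_const$kB_au * T_K / (0.5 * gmax)
  }
  Fscal <- function(B) thermal_state(
    build_hamiltonian(system, tesla_from_au(B)), T_K)$F
  Gvec <- NULL
  if (!is.null(dHdM)) {
    ops <- coupling_ops(dHdM)
    cache <- new.env(parent = emptyenv())
    Gvec <- function(B) {
      key <- paste(sprintf("%.17g", B), collapse = ",")
      v <- cache[[key]]
      if (is.null(v)) {
        st <- thermal_state(build_hamiltonian(system, tesla_from_au(B)), T_K)
        v <- vapply(ops, function(O) thermal_expectation(st, O), numeric(1))
        cache[[key]] <- v
      }
      v
    }
  }
  ei <- function(i) { v <- numeric(3); v[i] <- 1; v }
  out <- list(T_K = T_K, h0 = h0)
  conv <- c()

  # F_BB: second differences of the scalar free energy
  d2 <- function(i, j, h) {
    if (i == j) {
      (Fscal(h * ei(i)) - 2 * Fscal(c(0, 0, 0)) + Fscal(-h * ei(i))) / h^2
    } else {
      (Fscal(h * (ei(i) + ei(j))) - Fscal(h * (ei(i) - ei(j))) -
         Fscal(h * (ei(j) - ei(i))) + Fscal(-h * (ei(i) + ei(j)))) / (4 * h^2)
    }
  }
  r <- richardson(function(h) outer(1:3, 1:3,
                                    Vectorize(function(i, j) d2(i, j, h))),
                  h0, levels)
  out$F_BB <- r$value
  out$F_BB_error <- r$error
  conv["F_BB"] <- r$error <= tol * max(abs(r$value), .Machine$double.xmin)

  if (!is.null(Gvec)) {
    # F_MB: first differences of the Hellmann-Feynman vector
    d1 <- function(j, h) (Gvec(h * ei(j)) - Gvec(-h * ei(j))) / (2 * h)
    r <- richardson(function(h) t(vapply(1:3, function(j) d1(j, h),
                                         numeric(3))), h0, levels)
    # d1 returns d G_i / d B_j as [j, i]; transpose to [i, j]
    out$F_MB <- t(r$value)
    out$F_MB_error <- r$error
    conv["F_MB"] <- r$error <= tol * max(abs(r$value), .Machine$double.xmin)

    if (order >= 3) {
      d2v <- function(j, k, h) {
        if (j == k) {
          (Gvec(h * ei(j)) - 2 * Gvec(c(0, 0, 0)) + Gvec(-h * ei(j))) / h^2
        } else {
          (Gvec(h * (ei(j) + ei(k))) - Gvec(h * (ei(j) - ei(k))) -
             Gvec(h * (ei(k) - ei(j))) + Gvec(-h * (ei(j) + ei(k)))) /
            (4 * h^2)
        }
      }
      r <- richardson(function(h) {
        A <- array(0, c(3, 3, 3))
        for (j in 1:3) for (k in j:3) {
          v <- d2v(j, k, h)
          A[, j, k] <- v; A[, k, j] <- v
        }
        A
      }, h0, levels)
      out$F_MBB <- r$value
      out$F_MBB_error <- r$error
      # F_MBB vanishes identically at zero field (time reversal); judge
      # convergence against the generic scale max|F_MB|/h0, not against a
      # tensor that may be numerically zero
      conv["F_MBB"] <- r$error <= tol * max(abs(r$value),
                                            max(abs(out$F_MB)) / h0,
                                            .Machine$double.xmin)
    }
    if (order >= 4) {
      d3v <- function(j, k, l, h) {
        idx <- c(j, k, l)
        if (j == k && k == l) {
          (Gvec(2 * h * ei(j)) - 2 * Gvec(h * ei(j)) + 2 * Gvec(-h * ei(j)) -
             Gvec(-2 * h * ei(j))) / (2 * h^3)
        } else if (length(unique(idx)) == 2) {
          # two equal indices p, one distinct q: d^2/dp^2 d/dq
          p <- idx[duplicated(idx)][1]
          q <- setdiff(idx, p)
          (Gvec(h * (ei(p) + ei(q))) - 2 * Gvec(h * ei(q)) +
             Gvec(h * (ei(q) - ei(p))) -
             Gvec(h * (ei(p) - ei(q))) + 2 * Gvec(-h * ei(q)) -
             Gvec(-h * (ei(p) + ei(q)))) / (2 * h^3)
        } else {
          s <- expand.grid(s1 = c(1, -1), s2 = c(1, -1), s3 = c(1, -1))
          tot <- 0
          for (r2 in seq_len(nrow(s))) {
            sg <- as.numeric(s[r2, ])
            tot <- tot + prod(sg) *
              Gvec(h * (sg[1] * ei(j) + sg[2] * ei(k) + sg[3] * ei(l)))
          }
          tot / (8 * h^3)
        }
      }
      r <- richardson(function(h) {
        A <- array(0, c(3, 3, 3, 3))
        for (j in 1:3) for (k in j:3) for (l in k:3) {
          v <- d3v(j, k, l, h)
          for (p in unique(list(c(j,k,l), c(j,l,k), c(k,j,l),
                                c(k,l,j), c(l,j,k), c(l,k,j)))) {
            A[, p[1], p[2], p[3]] <- v
          }
        }
        A
      }, h0, levels)
      out$F_MBBB <- r$value
      out$F_MBBB_error <- r$error
      conv["F_MBBB"] <- r$error <= tol * max(abs(r$value),
                                             max(abs(out$F_MB)) / h0^2,
                                             .Machine$double.xmin)
    }
  } else if (order >= 3) {
    stop("orders 3 and 4 require a coupling operator (dHdM); ",
         "pass field_derivative_operators(system) wrapped as a coupling ",
         "operator for pure field derivatives")
  }
  out$converged <- conv
  if (!all(conv)) {
    warning("Richardson extrapolation above tolerance for: ",
            paste(names(conv)[!conv], collapse = ", "))
  }
  out
}

## -- spin moments and assembled response tensors ----------------------------

#' Thermal spin dyadic and tetradic response tensors
#'
#' Second and fourth free-energy responses to perturbations coupling
#' linearly to the bare spin components: dyadic_{ij} = <<S_i S_j>> and
#' tetradic_{ijkl} = <<S_i S_j S_k S_l>>, with the field-free Hamiltonian
#' S^T D S. The dyadic equals -beta <S_i S_j> when D = 0 (so that the
#' whole temperature dependence sits in these tensors); the tetradic is
#' supersymmetric (invariant under all 24 index permutations). Contracting
#' them with the linear coefficients of the coupling operators reproduces
#' the shielding, susceptibility and tau tensors.
#'
#' @param system A [spin_system()].
#' @param T_K Temperature in kelvin.
#' @return Object of class `spin_moments`: `dyadic` (3x3), `tetradic`
#'   (3x3x3x3), `T_K`.
#' @export
spin_moments <- function(system, T_K) {
  H0 <- build_hamiltonian(system, c(0, 0, 0))
  sp <- system$spin
  eng <- sos_engine(H0, list(sp$Sx, sp$Sy, sp$Sz), T_K, kmax = 4)
  dy <- outer(1:3, 1:3, Vectorize(function(i, j) eng$F2(i, j)))
  te <- array(0, c(3, 3, 3, 3))
  idx <- which(array(TRUE, c(3, 3, 3, 3)), arr.ind = TRUE)
  srt <- t(apply(idx, 1, sort))
  for (r in seq_len(nrow(idx))) {
    i <- srt[r, ]
    if (te[i[1], i[2], i[3], i[4]] == 0 &&
        all(idx[r, ] == i)) {
      te[i[1], i[2], i[3], i[4]] <- eng$F4(i[1], i[2], i[3], i[4])
    }
  }
  # fill all permutations from the sorted representatives
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, ]; s <- srt[r, ]
    te[i[1], i[2], i[3], i[4]] <- te[s[1], s[2], s[3], s[4]]
  }
  structure(list(dyadic = dy, tetradic = te, T_K = T_K),
            class = "spin_moments")
}

#' @export
print.spin_moments <- function(x, ...) {
  cat("<spin_moments> T =", x$T_K, "K\n")
  cat("dyadic <<S_i S_j>> (atomic units):\n")
  print(signif(x$dyadic, 6))
  invisible(x)
}

#' Assemble response tensors for one nucleus
#'
#' Shielding sigma, susceptibility chi and the fourth-order tau tensor
#' from the analytic sum-over-states derivatives (or, optionally, the
#' numerical-derivative oracle). Conventions: sigma[j, i] = F_{M_i B_j};
#' chi_ij = -mu0 F_{B_i B_j} reported in SI m^3 per molecule;
#' tau4[i, j, k, l] = F_{M_i B_j B_k B_l} / 3! with i the moment index;
#' tau = (1/5) sum_ij tau4[i, i, j, j].
#'
#' @param system A [spin_system()].
#' @param nuc A [nucleus()].
#' @param T_K Temperature in kelvin.
#' @param contribution `"FC"` or `"PC"` (one coupling kind per call; they
#'   are additive).
#' @param center_A Paramagnetic center for the point-dipole operator.
#' @param method `"sos"` (analytic, default) or `"numeric"` (oracle).
#' @return Object of class `response_tensors`: `sigma` (3x3,
#'   dimensionless), `chi_si_m3` (3x3), `chi_au`, `tau4` (3^4, atomic
#'   units), `tau_au`, raw `F_BB`, plus metadata.
#' @export
assemble_response <- function(system, nuc, T_K,
                              contribution = c("FC", "PC"),
                              center_A = c(0, 0, 0),
                              method = c("sos", "numeric")) {
  contribution <- match.arg(contribution)
  method <- match.arg(method)
  op <- if (contribution == "FC") fc_operator(system, nuc) else
    pc_operator(system, nuc, center_A)
  der <- if (method == "sos") {
    sos_free_energy_derivatives(system, op, T_K, order = 4)
  } else {
    numeric_free_energy_derivatives(system, op, T_K, order = 4)
  }
  sigma <- t(der$F_MB)                       # sigma[j, i] = F_{M_i B_j}
  F_BB <- (der$F_BB + t(der$F_BB)) / 2
  chi_au <- -.pnmr_const$mu0_au * F_BB
  tau4 <- der$F_MBBB / 6
  tau_au <- sum(vapply(1:3, function(i)
    sum(vapply(1:3, function(j) tau4[i, i, j, j], numeric(1))),
    numeric(1))) / 5
  structure(list(sigma = sigma, chi_au = chi_au,
                 chi_si_m3 = m3_from_au_chi(chi_au),
                 tau4 = tau4, tau_au = tau_au, F_BB = F_BB,
                 T_K = T_K, kind = contribution, label = nuc$label,
                 method = method),
            class = "response_tensors")
}

#' @export
print.response_tensors <- function(x, ...) {
  cat("<response_tensors>", x$kind, "for", x$label, "at", x$T_K, "K (",
      x$method, ")\n")
  cat("isotropic shift -tr(sigma)/3:",
      format(-sum(diag(x$sigma)) / 3 * 1e6, digits = 8), "ppm\n")
  cat("chi_iso:", format(sum(diag(x$chi_si_m3)) / 3, digits = 8),
      "m^3/molecule\n")
  cat("tau:", format(x$tau_au, digits = 8), "a.u.\n")
  invisible(x)
}

#' Molar isotropic susceptibility
#'
#' Convenience conversion of a per-molecule chi (m^3) to cm^3 mol^-1.
#' @param chi_m3 Susceptibility per molecule in m^3 (scalar or matrix).
#' @return Value in cm^3 per mole.
#' @export
chi_cm3_per_mol <- function(chi_m3) chi_m3 * 1e6 * .pnmr_const$avogadro
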