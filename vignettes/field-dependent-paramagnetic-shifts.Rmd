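---
title: "Field-dependent NMR shifts of paramagnetic molecules: models and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Field-dependent NMR shifts of paramagnetic molecules: models and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paranmr)
```

## The physical problem

A paramagnetic molecule in solution experiences an external field $B_0$
and responds with an induced field at each magnetic nucleus. The ratio
$\delta = B^\mathrm{ind}/B_0$ is the paramagnetic chemical shift. Because
the electronic magnetization saturates (Boltzmann populations of the spin
levels are not linear in $B_0$ forever) and because anisotropic molecules
partially self-orient in the field, $\delta$ is *not* field-independent:
at the strongest spectrometers available today (1.2 GHz proton Larmor
frequency, 28.2 T) the variation is of order one percent of the absolute
shift for strongly shifted protons — small, but resolvable.

`paranmr` computes these shifts from an effective electronic model
specified entirely by spin-Hamiltonian parameters:

$$ H = \mathbf{S}^{\mathsf T} \mathbf{D}\, \mathbf{S}
   + \tfrac{1}{2}\, \mathbf{B}_0^{\mathsf T} \mathbf{g}\, \mathbf{S}, $$

in Hartree atomic units, where $\mathbf{D}$ is the traceless symmetric
zero-field-splitting (ZFS) tensor, $\mathbf{g}$ the (possibly
non-symmetric) g matrix, and the factor $1/2$ is the Bohr magneton in
atomic units. Hyperfine coupling is deliberately left out of the
diagonalized Hamiltonian; it enters only through the coupling operators
below (consequently indirect nuclear spin–spin coupling is outside the
model). Diamagnetic (orbital-current) shielding is likewise not part of
this model.

Two coupling operators connect the electronic model to a nucleus with
magnetic moment $\mathbf{M}$:

* **Fermi contact (FC)**: $\partial H/\partial M_i = (A_\mathrm{iso}/\gamma)\, S_i$,
  from the isotropic hyperfine coupling constant $A_\mathrm{iso}$ and the
  nuclear gyromagnetic ratio $\gamma$.
* **Pseudocontact (PC)**, in the point-dipole approximation:
  $\partial H/\partial \mathbf{M} = -(3\alpha^2/r^3)\,
  (\hat{\mathbf r}\otimes\hat{\mathbf r})^\mathrm{aniso}\, \mathbf{M}^\mathrm{el}$,
  with $\hat{\mathbf r}$ the unit vector from the paramagnetic center to
  the nucleus and $\mathbf{M}^\mathrm{el} = -\tfrac12 \mathbf{g}\mathbf{S}$
  the electronic moment operator. The PC route here stays within the
  spin-Hamiltonian approximation throughout (no ligand-field treatment);
  this is stated in the output metadata. For axial susceptibility the
  resulting shift reduces to the classic
  $\Delta\chi_\mathrm{ax}(3\cos^2\Theta - 1)/(12\pi r^3)$ geometric law,
  which fixes the sign convention unambiguously — the package's tests
  assert exactly this.

## Two computational routes

**Finite-field route** (`finite_field_shift()`): exact to all orders in
$B_0$. For each unit direction $\mathbf{u}$ of the field in the
molecule-fixed frame, the Hamiltonian is diagonalized at $B_0\mathbf{u}$;
the electronic Boltzmann average gives the induced field
$\langle\mathbf{B}^\mathrm{ind}\rangle^\mathrm{mol}(\mathbf{u})$ and the
Helmholtz free energy $F(\mathbf{u})$. Only the laboratory-frame $z$
component survives orientational averaging (the $x$/$y$ components cancel
exactly in the analytic azimuthal integral), and it equals
$\mathbf{u}\cdot\langle\mathbf{B}^\mathrm{ind}\rangle^\mathrm{mol}$. The
average is the ratio

$$ B^\mathrm{ind} =
   \frac{\sum_k w_k\, e^{-\beta F(\mathbf{u}_k)}\,
         \mathbf{u}_k\cdot\langle\mathbf{B}^\mathrm{ind}\rangle^\mathrm{mol}(\mathbf{u}_k)}
        {\sum_k w_k\, e^{-\beta F(\mathbf{u}_k)}} $$

over a Lebedev quadrature grid. The $e^{-\beta F}$ weights carry the
self-orientation physics; dropping them changes the answer for any
anisotropic system (a property test guards this).

**Second-order route** (`second_order_shift()`): the expansion of the
same quantity through third order in $B_0$ (odd orders only; even-order
terms vanish by symmetry), with the orientational average done
analytically:

$$ \delta(B_0) \approx -\tfrac13\sigma^{(2:1)}
   + \left[\tfrac{1}{45}\tfrac{\beta}{\mu_0}\,\sigma^{(2:1)}\chi^{(2:1)}
   - \tfrac{1}{15}\tfrac{\beta}{\mu_0}\,(\sigma\chi)^{(2:1)}
   - \tau\right] B_0^2 . $$

The first bracketed pair is the **indirect** (residual shielding
anisotropy / self-orientation) term; it vanishes identically when either
$\sigma$ or $\chi$ is isotropic. The last term, $\tau =
\tau^{(4:2)}/5$, is the **direct** (saturation) term. Here
$\sigma_{ji} = F_{M_i B_j}(0)$, $\chi_{ij} = -\mu_0 F_{B_i B_j}(0)$ and
$\tau^i_{jkl} = F_{M_i B_j B_k B_l}(0)/3!$ are second and fourth
derivatives of the Helmholtz free energy at zero field. (Note the
$\beta/\mu_0$ prefactor: with $\chi = -\mu_0 F_{BB}$ the $\mu_0$ cancels
and the implementation works directly with the raw $F_{BB}$ derivative;
dimensional analysis and the classic residual-CSA literature both require
$1/\mu_0$ here.) The shift is reported with the paramagnetic reference
contribution taken as zero and $1-\sigma_\mathrm{ref}\approx 1$, so
positive $\delta$ means downfield.

The code computes the indirect term as
$(\beta/15)\,\mathrm{tr}(\sigma^\mathrm{aniso}\chi^\mathrm{aniso})$ using
explicitly detraced tensors — algebraically identical to the two-term
form, but the cancellation for isotropic inputs is then *exact in
floating point*, not merely to roundoff.

## Analytic free-energy derivatives without degeneracy bookkeeping

Sum-over-states expressions for thermal response tensors usually need
separate formulas for degenerate and nondegenerate levels and a grouping
tolerance to decide which is which. This package uses an equivalent
formulation that needs neither. Writing the $k$-th derivative of
$Z = \mathrm{tr}\, e^{-\beta H}$ with respect to parameters that enter
$H$ linearly as an imaginary-time Dyson expansion, each term is a cyclic
chain of operator matrix elements between eigenstates $n_1 \to n_2 \to
\dots \to n_k \to n_1$ of the field-free Hamiltonian, weighted by the
*confluent divided difference* of $e^{-\beta x}$ at the chain energies
(Hermite–Genocchi). Divided differences are smooth functions of their
nodes: coincident energies are the ordinary limit, not a special case, so
Kramers degeneracies and near-degeneracies never produce small-denominator
blowups. Numerically each divided difference is evaluated through the
Opitz identity — it is the corner entry of the matrix exponential of a
small bidiagonal matrix holding the (ground-state-shifted) energies — via
`Matrix::expm` on at most 5×5 matrices, with caching over the sorted node
multiset. Derivatives of $F = -\ln(Z)/\beta$ then follow from the
log-cumulant formulas through fourth order.

Because the FC and PC operators and the Zeeman derivative are all linear
in the spin components, the same machinery yields the spin dyadic
$\langle\langle S_i S_j\rangle\rangle$ and supersymmetric spin tetradic
$\langle\langle S_i S_j S_k S_l\rangle\rangle$ (`spin_moments()`), whose
contractions with the operator coefficient matrices reproduce $\sigma$,
$\chi$ and $\tau$ — a two-route consistency that is asserted in the test
suite rather than assumed.

**The numerical oracle.** `numeric_free_energy_derivatives()` provides an
independent check: central differences with Richardson extrapolation, with
nuclear-moment derivatives never differenced (the Hellmann–Feynman
identity $F_{M_i} = \langle\partial H/\partial M_i\rangle$ reduces them to
expectation values, so fourth derivatives need only third field
differences). The base step is $0.05\,k_BT/(\mu_B g_\mathrm{max})$ —
5% of the Boltzmann saturation field scale — with 4 Richardson levels.
A fixed cap in tesla is deliberately *not* applied: for third differences
a step far below the saturation scale amplifies roundoff
($\varepsilon/x^3$ at relative stencil variation $x$) past the $10^{-6}$
accuracy target, while the scale-proportional step keeps both truncation
($\sim x^8$ after extrapolation) and roundoff below $10^{-9}$ at any
temperature. Non-convergent extrapolations are flagged in the result and
warned about, never silently returned; third-derivative tensors, which
vanish identically at zero field by time reversal, are judged against the
generic scale $|F_{MB}|/h_0$ so that "numerically zero" is not
misreported as "not converged".

## Orientational quadrature

All 32 Lebedev–Laikov rules (6 to 5810 points, algebraic orders 3 to 131)
are embedded as plain-text orbit-parameter tables and expanded into
explicit points at load time (`lebedev_grid()`). Weights are normalized
to sum to one, absorbing the $1/4\pi$ of the continuous average. The 74-,
230- and 266-point rules contain a few small negative weights — a
documented property of those published rules, accepted by the validator.
Tests assert the second- and fourth-moment identities
$\langle u_i u_j\rangle = \delta_{ij}/3$ and
$\langle u_i u_j u_k u_l\rangle = (\delta_{ij}\delta_{kl} +
\delta_{ik}\delta_{jl} + \delta_{il}\delta_{jk})/15$ to $10^{-12}$ on
every rule, and that spherical harmonics up to each rule's design order
integrate to zero.

The default grid for the finite-field route is the 26-point rule: for
room-temperature systems at spectrometer fields the relative quadrature
error is already below $10^{-8}$ (the acceptance suite recomputes this
against the 5810-point rule). Weak anisotropy is the reason: the
integrand $e^{-\beta F(\mathbf u)}\, \mathbf{u}\cdot\mathbf{B}^\mathrm{ind}$
is a low-degree spherical polynomial to excellent approximation when
$\beta$ times the orientational free-energy spread is small.

## Tunable parameters

| Parameter | Units | Default | Meaning |
|---|---|---|---|
| `S` | — | — | electron spin quantum number (half-integer) |
| `g` | — | 2.0 | g matrix (scalar, principal values, or 3×3) |
| `D_cm1` / `D_axial_cm1`, `E_rhombic_cm1` | cm⁻¹ | 0 | ZFS tensor or its axial/rhombic parameters |
| `A_iso_MHz` | MHz | 0 | isotropic hyperfine coupling per nucleus |
| `position_A`, `center_A` | Å | — / origin | nuclear position and paramagnetic center |
| `T_K` | K | 298 | temperature |
| fields | tagged `"T"`/`"MHz"`/`"GHz"` | — | untagged numbers are rejected to prevent tesla/MHz confusion |
| `grid` | points | 26 | Lebedev rule size |
| `r_min_A` | Å | 0.5 | point-dipole breakdown guard |

Internally everything is converted once to Hartree atomic units
($\mu_B = 1/2$, $\mu_0 = 4\pi\alpha^2$, CODATA 2018 constants pinned in
`pnmr_constants()`); all public inputs and outputs use the practical
units above, with shifts in ppm. $\chi$ is reported in SI m³ per molecule
(`chi_cm3_per_mol()` converts to molar cgs-style units on request).
Proton-Larmor field tags always convert with the *proton* gyromagnetic
ratio — a "400 MHz" magnet is 9.4 T no matter which nucleus is observed.

## The synthetic generator: what it emulates and what it does not

`synthetic_system(seed)` draws the study conditions used throughout the
tests: $S = 1$ with axial ZFS of 2–8 cm⁻¹, rhombicity $E/D \in [0, 1/3]$,
randomly oriented principal axes, g principal values in 2.1–2.3, and five
protons at 2–6 Å with $|A_\mathrm{iso}|$ between 0.1 and 1 MHz — the
regime of a high-spin pentacoordinate Ni(II) complex at room temperature.
These ranges were chosen once, from what is typical for such complexes,
and are the generator's fixed defaults. The generator does *not* emulate:
ligand-field orbital contributions beyond the spin Hamiltonian (real
Ni(II) PC shifts inherit some), anisotropic hyperfine tensors beyond the
point dipole, chemical exchange, or solvent/dynamics effects. Passing
tests therefore demonstrate internal correctness of the models stated
above on realistic parameter magnitudes — not agreement with any
particular measured compound.

## Numerical choices and degenerate inputs

* Boltzmann factors are always formed relative to the ground state
  (orientation-wise in the thermal state, grid-wise in the $N/D$ ratio),
  so the finite-field route stays valid at arbitrarily low temperature
  and arbitrarily high field. The only irreducible limit is input
  rounding: adding an offset of $10^6\,k_BT$ to the Hamiltonian perturbs
  the stored matrix itself at $\beta\Delta \sim 10^{-10}$, which is where
  the corresponding property test places its tolerance.
* The ZFS tensor is symmetrized and its trace projected out on input
  (an isotropic part of `D` shifts all levels equally and is
  unobservable); `g` is accepted verbatim, without symmetrization, and
  $\mathbf{M}^\mathrm{el}_i = -\tfrac12\sum_j g_{ij} S_j$ uses the row
  convention that makes it exactly $-\partial H/\partial B_{0,i}$ (checked
  by finite differences in the tests; for symmetric g both conventions
  coincide).
* A one-dimensional electronic space ($S = 0$ analog) yields exactly zero
  for every response tensor and shift, with no special-casing.
* `spin_system(0.3)` and other non-half-integer spins, zero gyromagnetic
  ratios, nuclei inside the 0.5 Å point-dipole guard radius, empty field
  lists, and untagged field numbers are all rejected with specific
  errors; configuration validation aggregates all problems into one
  report.

## Problem sizes in the shipped tests

The test and acceptance suites run on one CPU in well under their
budgets using: the full 32-rule grid catalog for moment identities; the
5810-point rule (once) for the grid-convergence check; a 20-system seeded
suite spanning $S \in \{1/2, 1, 3/2, 2, 5/2\}$ for the
sum-over-states-vs-numerics oracle comparison; and five field strengths
from 100 MHz to 1 GHz for the $B_0^4$ error-scaling fit. These sizes were
chosen as the smallest that exercise every code path and spin dimension;
the quantities themselves are insensitive to making them larger.

## Known limitations

* PC shifts use the spin-Hamiltonian approximation with a point dipole;
  metal-centered orbital contributions and spin delocalization onto
  ligands are outside the model.
* The second-order route fails by construction when $\beta$ times the
  Zeeman energy is not small (very strong fields or cryogenic
  temperatures); the finite-field route remains valid there and is the
  built-in cross-check (`method = "both"`).
* Shifts are referenced by neglecting the paramagnetic contribution of
  the reference compound; diamagnetic shielding differences are not
  modeled.
* Solid-state (single-orientation) spectra are not a supported surface,
  although the machinery would permit them.

## A short session

```{r example, eval = FALSE}
synth <- synthetic_system(seed = 1)
cfg <- run_config(
  spin = list(S = 1, g = synth$system$g,
              D_cm1 = cm1_from_au(synth$system$D_au)),
  nuclei = lapply(synth$nuclei, function(nu)
    list(label = nu$label, position_A = nu$position_A,
         A_iso_MHz = nu$A_iso_MHz)),
  fields = list("400 MHz", "1.2 GHz"),
  method = "both", grid = 26, seed = 1)
tab <- run_shifts(cfg)
tab[, c("label", "field", "delta_ppm_ff", "delta_ppm_so", "ff_so_diff_ppm")]
```

The command-line wrapper `inst/cli/paranmr` exposes the same pipeline as
`paranmr run --config run.yaml`, plus `paranmr synth --seed N` and
`paranmr convert --larmor 1200`.
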