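---
title: "Modelling heme magnetism with a multi-orbital Anderson model and Hirsch-Fye QMC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling heme magnetism with a multi-orbital Anderson model and Hirsch-Fye QMC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemeqmc)
```

## The model

A heme group is treated as a multi-orbital Anderson impurity problem: the
five Fe(3d) orbitals ($\nu = xy, xz, yz, z^2, x^2\!-\!y^2$) are the
correlated impurity, and the remaining molecular orbitals of the
porphyrin/ligand cluster are a noninteracting host. Per spin the one-body
Hamiltonian is

$$ H_0 = \sum_m (\epsilon_m - \mu)\, c^\dagger_m c_m
       + \sum_\nu (\epsilon_{d\nu} - \mu)\, d^\dagger_\nu d_\nu
       + \sum_{m\nu} V_{m\nu} (c^\dagger_m d_\nu + d^\dagger_\nu c_m), $$

and the interaction on the impurity keeps every density-density channel:
intra-orbital $U\, n_{\nu\uparrow} n_{\nu\downarrow}$, opposite-spin
inter-orbital $U' = U - 2J$, and parallel-spin inter-orbital
$U'' = U' - J$, with $J$ the Hund coupling. Spin-flip and pair-hopping
terms are excluded; the discrete-time determinantal solver cannot treat
them, and the omission makes total $S_z$ (in fact every
$n_{\nu\sigma}$-diagonal symmetry) conserved. Two consequences matter
throughout:

* the static susceptibility can be measured as
  $\chi_t = \beta \langle M_{z,t}^2 \rangle$ (at zero field
  $\langle M_z\rangle = 0$ by symmetry), and the imaginary-time-displaced
  correlator $\langle M_{z,t}(\tau) M_{z,t}(0)\rangle$ must be flat — the
  solver measures both and their agreement is asserted in the tests;
* "free spin" limits are Ising-like: a decoupled high-spin shell
  maximizes $|M_z|$ instead of forming an isotropic multiplet. Moment
  *conventions* (below) therefore refer to the isotropic free spin, while
  the solver's raw $\langle M_z^2\rangle$ is what enters estimators.

Units: energies in eV, temperatures in K ($k_B = 8.617\times10^{-5}$
eV/K), inverse temperature $\beta$ in eV$^{-1}$, moments in Bohr
magnetons with $g = 2$, so one orbital contributes
$m_z = n_\uparrow - n_\downarrow$ in $\mu_B$.

Host states enter as already-diagonal levels (molecular-orbital
eigenstates), so the one-body matrix is an arrowhead. Hybridizations are
real.

## The solver

`run_qmc()` implements the discrete-time Hirsch-Fye scheme. Each of the
$n_\mathrm{pairs} = n_\mathrm{orb} + 2 n_\mathrm{orb}(n_\mathrm{orb}-1)$
density-density pairs (45 for five orbitals) is decoupled on each of the
$L$ time slices by an Ising field with
$\cosh\lambda = e^{\Delta\tau W/2}$; the interaction is first brought to
the particle-hole symmetric form $W (n_a - \tfrac12)(n_b - \tfrac12)$,
which shifts each impurity level by half the sum of its couplings
(`hartree_model()`). The bath Green's function $g_0$ is evaluated
*exactly* from the eigen-decomposition of the full one-body problem —
every host level is kept — and only the impurity block, of size
$n_\mathrm{orb} L$, enters the QMC matrices. In the stored convention
$g = -\langle T c(\tau) c^\dagger(0)\rangle$ the clean-update Dyson
equation reads $G = [1 + (1 + g_0)(e^{V(s)} - 1)]^{-1} g_0$, single-field
flips are accepted on scalar or $2\times2$ determinant ratios and applied
as rank-1 updates, and the configuration weight sign is tracked and
reweighted (single-orbital models are sign-problem free; the average sign
is always reported and results with $|\langle s\rangle| < 0.05$ are
flagged).

Host observables are never simulated directly. For fixed fields the
action is Gaussian, so the full-cluster equal-time Green's function
follows from the impurity one through the exact embedding relation
$G = g + g_{:,\mathrm{imp}}\, g_\mathrm{imp}^{-1} (G_\mathrm{imp} -
g_\mathrm{imp})\, g_\mathrm{imp}^{-1} g_{\mathrm{imp},:}$, and Wick's
theorem per configuration gives site-resolved moments, the total-moment
fluctuation, and Fe-host correlations at $O((n_\mathrm{orb}L)^3)$ cost
independent of the host size. This is what makes "keep all host states"
affordable: a 65-site cluster runs with $300^2$ matrices.

Two solver details are worth recording:

* **Spin-exchange move.** The orientation of a formed local moment decays
  extremely slowly under single-field flips. An exact global move —
  negate the intra-orbital fields, exchange the fields of spin-mirrored
  pairs, swap the two spin blocks of $G$ — maps the configuration to its
  time-reversed partner with identical weight. Interleaving it between
  measurements (default) symmetrizes the spin-resolved estimators
  exactly. The headline occupation estimator is additionally the
  spin-symmetrized $(n_\uparrow + n_\downarrow)/2$, which carries none of
  the orientation noise.
* **Error bars.** All estimators are sign-reweighted bin averages with
  jackknife errors over at least 16 bins; the Green's function is rebuilt
  from scratch every 50 sweeps and the fast-update drift is checked
  against a $10^{-6}$ tolerance.

### Trotter errors and extrapolation

The only systematic error is the time discretization. `extrapolate_dtau()`
fits $O(\Delta\tau) = O_0 + c\,\Delta\tau^2 + d\,\Delta\tau^4$; the
quartic term is kept by default because at $\Delta\tau\,U$ of order one
(where $\lambda \approx 1$) it dominates the residual, and a pure
quadratic fit through $\Delta\tau = 0.5$ data visibly overshoots. With
steps $\{0.5, 0.25, 0.125\}$ the extrapolated occupations, double
occupancies and susceptibilities of ED-checkable clusters land within
about half a percent of the exact values (the acceptance suite asserts
1% and three jackknife sigma).

The host-observable reconstruction mixes the exact continuous bath
propagator with the Trotterized impurity Green's function; the resulting
bias scales like $(V\Delta\tau)^2$ and, unlike the impurity estimators,
can be the dominant error for *small* host correlations — at
$\Delta\tau \approx 0.3$ it can even flip the sign of a weak Fe-host
correlation. Correlation measurements in the validation suites therefore
use $\Delta\tau \le 0.18$, where the bias is subdominant (verified
against ED on reduced clusters).

## The exact-diagonalization oracle

`ed_spectrum()` diagonalizes clusters of up to 6 sites (12 spin-orbitals)
in the occupation basis with fermionic signs, blocked by the conserved
$(N_\uparrow, N_\downarrow)$; an independent unblocked construction over
the full $4^{n}$ Fock space is kept for cross-validation. Every QMC
estimator is validated against it: exhaustively (summing the
Hubbard-Stratonovich weights over all $2^{n_\mathrm{pairs} L}$
configurations reproduces ED to 0.1% at $\Delta\tau \le 0.1$) and
stochastically (sampled runs with Trotter extrapolation).

## Derived observables

* `effective_moment()`: $M_\mathrm{eff} = \sqrt{3 k_B T \chi}$, the
  Curie-law convention under which an isotropic free spin gives
  $g\sqrt{S(S+1)}$ — 4.9 $\mu_B$ for $S = 2$, $\sqrt 3$ for $S = 1/2$.
  The instantaneous alternative $\sqrt{3\langle M_z^2\rangle}$ is exposed
  as `instantaneous_moment()` since moment maps can be defined either
  way.
* `curie_fit()`: weighted least squares of $\chi = C/T$, with an optional
  piecewise two-regime fit that scans every split point and flags a
  crossover when the two-branch fit is decisively (4x) better — the
  oxy-heme phenomenology of two Curie regimes separated by a crossover
  temperature.
* `tune_mu()`: bisection on the monotone $\langle N\rangle(\mu)$, with
  noninteracting, ED, or QMC evaluation. Bisection rather than a
  derivative method because the QMC-evaluated count is noisy. For
  interacting clusters the fast seed is the noninteracting density of
  the Hartree-shifted model.
* `project_moment_density()`: the per-atom signed moment map,
  $M_A = \sum_\mathrm{states} w_{A,\mathrm{state}}\,
  \langle M_{z,\mathrm{state}} M_{z,t}\rangle / \sqrt{\langle
  M_{z,t}^2\rangle}$. Correlating against the *total* moment keeps the
  map well-defined when the Fe moment collapses (the oxy case); sites
  antiferromagnetically correlated with the dominant moment come out
  negative, and the atomic moments sum to the instantaneous total moment
  as an exact bookkeeping identity.
* `fe_host_correlation()`: equal-time
  $\langle M_{z,\mathrm{Fe}} M_{z,m}\rangle$ per host state; negative
  values are the antiferromagnetic Fe-porphyrin correlations.
* `pair_correlation_from_moments()`: the four-heme algebra
  $\langle M_1 M_2\rangle = (M_\mathrm{ind}^2 - M_\mathrm{single}^2) /
  (n-1)$, the reconstruction that reproduces both published inter-heme
  correlation values (about 1.9 $\mu_B^2$ against the free-ion 4.9
  $\mu_B$, about 4.3 $\mu_B^2$ against the screened 4.1 $\mu_B$) from
  the measured independent-heme moment 5.46 $\mu_B$.

## The MCD band model

`mcd_band_model()` implements the orbital-selective two-band picture of
the UV magnetic circular dichroism of deoxy-heme: a bonding $\pi$ level
3 eV below the Fermi level, a nearly half-filled $\pi_1^*$ band and a
nearly empty $\pi_2^*$ band 0.3 eV higher, both 0.3 eV wide.
Left-circularly polarized light drives $\pi \to \pi_1^*$ and
right-circularly polarized light $\pi \to \pi_2^*$; because the
$\pi_1^*$ spin polarization is locked antiparallel to Fe by the
antiferromagnetic coupling, the bands acquire opposite circular
polarizations with a common thermal carrier
$p = \tanh(g\,\mu_B B / 2 k_B T)$ — linear in $B/T$, the 1/T law of the
temperature-dependent MCD. The spectrum is

$$ \Delta\epsilon(E) = A\,p\,[(1 - f_1)\,G(E; E_\pi + E_1, w_1)
                       - (1 - f_2)\,G(E; E_\pi + E_2, w_2)] $$

with unit-area Gaussian (or Lorentzian) line shapes, and the absorption
$\epsilon(E)$ is the same combination with a plus sign —
temperature-independent, as observed. The positive peak precedes the
negative dip (`classify_lineshape()` returns `"anomalous"`; flipping the
coupling sign restores the conventional dip-then-peak shape), and
$\int \Delta\epsilon\, dE = A p (f_2 - f_1)$ is nonzero precisely
because the fillings differ. One honest limitation: with equal widths
and unit-area shapes the *depth* of the dip exceeds the peak height (the
empty band has more final states), so the "shallow dip" of the measured
spectra is not reproduced by this stand-in; only the ordering, the null
and normal cases, and the 1/T amplitude scaling are claimed and tested.
Spin-orbit coupling is not modelled explicitly; it enters only through
the selection-rule sign conventions.

## The synthetic generators

The DFT-derived model parameters of real heme clusters are not publicly
available, so `make_heme_like()` generates parameter sets with the
qualitative structure the analysis assumes: 60 host states on a jittered
grid over $[-25, 10]$ eV; a bonding $\pi$ state at $-3$ eV; a $\pi_1^*$
manifold (3 states, 0.3 eV wide) and a $\pi_2^*$ manifold 0.3 eV above
it; background hybridizations Gaussian with scale 0.2 eV decaying away
from the Fermi level. Design choices that were genuinely open, and why
they were settled as they are:

* **$\pi$-symmetry selection rule.** The $\pi/\pi^*$ states (C $2p_z$
  character) couple only to the $xz/yz$ orbitals. This is not cosmetic:
  coupling the half-filled $\pi_1^*$ manifold equally to all five
  orbitals produces Hund-assisted *ferromagnetic* Fe-host correlations
  (double exchange through the high-spin shell), while the
  orbital-selective coupling gives the antiferromagnetic superexchange
  the analysis is about. Verified both ways against ED on reduced
  clusters.
* **Coupling scales.** $\pi_1^*$ couples at `v_special` = 0.7 eV, strong
  enough that the Fe-$\pi_1^*$ screening is already developed at the
  simulation temperatures (so $\chi_t(T)$ is near-Curie over the scanned
  range) yet weak enough that the Fe moment survives; $\pi_2^*$ (empty)
  couples at 0.35 of that scale.
* **Frontier window.** Background states are kept out of
  $(-0.6, 0.6)$ eV: the near-Fermi physics is carried entirely by the
  designed $\pi^*$/acceptor structure, not by accidental background
  draws.
* **Variants.** The deoxy variant places all five impurity levels near
  half filling after the Hartree shift (high-spin $S = 2$-like Fe) with
  $\pi_1^*$ straddling the Fermi level. The oxy variant is the
  spin-gapped molecule: $t_{2g}$-like levels filled, $e_g$-like empty
  (low-spin Fe), the $\pi_1^*$ manifold pushed just below and $\pi_2^*$
  just above the Fermi level, and an O$_2$-derived acceptor *at* the
  Fermi level, strongly (1.7 `v_special`) and axially (mainly $z^2$)
  coupled to Fe, which hybridization-splits it out of the frontier
  window. That construction yields simultaneously the reduced $\chi_t$
  and the suppression of the total moment when $\mu$ sits at $\mu_F$ —
  moving $\mu$ by $\pm 0.3$ eV reaches the $\pi^*$ manifolds and the
  moment recovers, which is the dip structure the scan
  (`moment_vs_mu_scan()`) resolves.
* **$U = 4$ eV, $J = 0.9$ eV** are the interaction constants used for
  all heme-like fixtures.

Everything is a pure function of the seed; special-state couplings are
fixed (not drawn) so the screening physics is stable across seeds.

### What the scaled-down runs do and do not show

Production-grade simulations of the real clusters run at 100-1000 K with
fine time steps; a desk-scale validation cannot. The packaged analyses
run at 800-1600 K with $\Delta\tau$ between 0.18 and 0.29 — chosen so
the full suite completes in minutes on one CPU — and the generator's
coupling scales place the interesting crossovers inside that window.
Consequently all heme-level checks are *direction-only*: the deoxy
fixture shows a near-Curie $\chi_t(T)$, a negative Fe-$\pi_1^*$
correlation and a carbon-site moment map anticorrelated with Fe; the oxy
fixture shows a many-fold smaller $\chi_t$ and a Fermi-level moment dip.
The published absolute numbers (Fe moment 4.6 $\mu_B$, total 4.1
$\mu_B$, oxy crossover near 300 K, $\chi_t \approx 150\ \mu_B^2$/eV)
require the unpublished DFT parameters and low-temperature runs, and are
deliberately not targeted; the inter-heme algebra and moment conventions,
which are temperature-independent arithmetic, are reproduced exactly.

Real-data features the generator does not emulate: orbital-resolved
hybridization anisotropies beyond the $\pi$ selection rule, the
temperature dependence of the molecular coordinates, charge-transfer
energetics of the O$_2$ bond beyond one acceptor level, and any
quantitative match to the true DFT spectrum.

## Numerical choices and degenerate inputs

* $\langle n\rangle(\mu)$ bisection tolerance: 0.01 electrons (tighter
  tolerances do not pin $\mu$ better once the count is flat).
* HS constants require $W \ge 0$: models with $U < 3J$ (attractive
  parallel-spin channel) are refused at the pair table with a warning at
  construction.
* $\Delta\tau\,\max(U, U', U'')> 0.5$ triggers a Trotter warning at grid
  construction.
* Degenerate special cases covered by tests: decoupled levels ($V = 0$),
  $U = 0$ (sampler accepts every move and returns $g_0$), empty/filled
  occupation limits, zero-field MCD ($\Delta\epsilon \equiv 0$),
  equal-band MCD cancellation, independent hemes (zero pair
  correlation).

## Problem sizes used by the validation suites

Chosen so the whole test suite runs in well under half an hour on a
single CPU: ED oracles at 2-4 sites; exhaustive enumeration at
$2^{10}$-$2^{12}$ configurations; QMC-vs-ED runs of $10^5$ sweeps at
$L \le 24$; heme-scale runs of 400 sweeps at $L \le 41$ with 65 sites.

## Known limitations

* Longitudinal-only Hund coupling: no spin-flip or pair-hopping terms,
  hence Ising-like atomic multiplets and no transverse susceptibility.
* No real-frequency information: estimators are static or imaginary-time
  quantities; no analytic continuation is attempted.
* The MCD stand-in reproduces the anomalous ordering and 1/T scaling,
  not the measured relative depth of peak and dip.
* Host observables inherit an $O((V\Delta\tau)^2)$ reconstruction bias;
  weak correlations need $\Delta\tau \lesssim 0.2$ at heme-like
  couplings.
* The sign problem is mild in all packaged fixtures but is only
  monitored, not solved; low-temperature multi-orbital runs with strong
  same-spin couplings would degrade.
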