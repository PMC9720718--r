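---
title: "Nuclear-ensemble absorption spectra from conformer ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nuclear-ensemble absorption spectra from conformer ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specens)
library(dplyr)
```

## The problem

Flexible fluorophores — here, probes built around a xanthene chromophore
carrying rotatable substituents — absorb differently depending on their
instantaneous conformation. A single quantum-chemistry calculation on the
optimised ground-state geometry (the *static* or *opt* approach) misses
this: at room temperature the molecule populates conformations away from
its energy minimum, and the torsions that control the conjugation of the
peripheral groups with the chromophore shift the bright transition.
The *nuclear-ensemble* approach instead samples many geometries from a
molecular-dynamics trajectory, computes vertical excitations on each, and
averages broadened lineshapes over the ensemble (the *conf* approach).

`specens` implements the post-processing half of that workflow: everything
between "I have trajectory frames and per-conformer excited-state
energies" and "here is the absorption spectrum, its maximum, and the
static-versus-ensemble and gas-versus-solution shifts". Running MD or
TD-DFT is out of scope; a seeded synthetic generator stands in for both so
every stage is testable.

## The spectrum model

For an ensemble of $N_p$ sampled geometries $\mathbf{R}_k$, each carrying
$N_s(k)$ vertical transitions with energies $\Delta E_{IL}(\mathbf{R}_k)$
and oscillator strengths $f_{IL}(\mathbf{R}_k)$, the absorption profile is

$$
A[E] \;=\; \frac{1}{N_p}\sum_{k=1}^{N_p}\;\sum_{L=1}^{N_s(k)}
  f_{IL}(\mathbf{R}_k)\; g\!\left(E;\, \Delta E_{IL}(\mathbf{R}_k),\, \delta\right),
$$

where $g$ is a unit-area Gaussian of full width at half maximum $\delta$,
i.e. $\sigma = \delta / (2\sqrt{2\ln 2})$. Assumptions worth stating:

* **Empirical broadening.** The Gaussian width is phenomenological; no
  vibronic (Franck–Condon) structure, lifetime/Lorentzian broadening, or
  molar-absorptivity conversion is attempted.
* **Averaging prefactor.** The $1/N_p$ average makes a one-conformer
  "ensemble" directly comparable with the optimised-structure spectrum,
  and makes the spectrum invariant under duplicating the ensemble. Only
  absolute intensity depends on this choice; peak positions and all
  reported ratios do not.
* **Energy-domain convolution.** Spectra are built and convolved on an
  energy grid; the wavelength view is the pointwise map
  $\lambda = hc/E$ with **no** Jacobian reweighting, and
  $\lambda_{\max} = hc/E_{\text{peak}}$. The constant is pinned at
  $hc = 1239.841984$ eV·nm so conversions are bit-stable.

### Parameters that matter

| Parameter | Units | Default | Why |
|---|---|---|---|
| `fwhm_eV` | eV | 0.2 | standard empirical width for room-temperature ensembles of this kind |
| grid | eV | 1.0–5.0, step 0.001 | covers the visible band at a resolution ≪ FWHM; the step is validated to be ≤ FWHM/10 |
| `save_interval_ps` | ps | 4 | the reference sampling protocol: a 5 ns production run saved every 4 ps gives 1250 post-initial frames |
| `stride` | – | 10 | decimation of saved frames before quantum chemistry: 1251 frames (t = 0 plus 1250 saves) → 126 conformers |
| histogram `bin_width` | deg | 1 | torsional maxima are conventionally quoted to ±1°; centers sit on integers so quoted values are representable |

### Numerical choices

* **Peak location.** `lambda_max()` refines the grid argmax by three-point
  parabolic interpolation; exact ties break toward lower energy (longer
  wavelength). On a 0.001 eV grid the refinement is far below the 1 nm
  precision at which maxima are quoted.
* **Half-maximum width.** The acceptance script measures FWHM by linear
  interpolation of the two half-maximum crossings, an independent check
  that the reconstruction reproduces its nominal broadening.
* **Area conservation.** Because each lineshape has unit area, the
  trapezoidal $\int A\,dE$ must equal the conformer-mean total oscillator
  strength; `integrated_strength()` exposes both sides of that identity,
  and warns (returning `NA`) when clipping or normalisation voids it.
* **Clipping.** Transitions outside the grid extended by $5\sigma$ raise a
  warning rather than an error: partial reconstructions are sometimes
  wanted, but their areas are no longer meaningful.
* **Degenerate inputs.** All-zero spectra cannot be normalised; flat
  spectra have no defined maximum; both raise typed errors rather than
  returning artifacts of floating-point ties.

## Torsional geometry and circular statistics

Dihedrals use the signed two-plane `atan2` formulation. The positive sense
is fixed by construction: placing A = (0,1,0), B = (0,0,0), C = (1,0,0)
and rotating D about the B→C axis by $+\varphi$ (right-hand rule) yields a
torsion of $+\varphi$. Cis is 0°, trans is +180°, and values live in
(−180°, +180°] with −180° mapped to +180°. The value is invariant under
rigid motions and under reversing the quadruple — both are tested
properties, the former to 10⁻⁹ degrees.

Angle distributions are circular histograms normalised to unit circular
integral. The −180/+180 seam is one bin, so nearby angles on either side
of it never end up 359° apart.

**Mode detection.** `find_modes()` smooths the binned density with a
symmetric triangular kernel (default half-width 5°, circular convolution)
before locating local maxima. The smoothing is the package's estimator
choice: raw 1°-bin argmaxes on realistic sample sizes (10⁴ draws) jitter
by several degrees and occasionally split one mode into two, while the
symmetric kernel leaves an isolated spike on its own bin and a uniform
density flat. Candidate maxima below 10% of the global maximum are
dropped (configurable — the threshold is a convention, not physics), and
candidates closer than 20° are merged keeping the denser one. Mode
positions are reported with a ±half-bin-width uncertainty: the histogram's
resolution, not a statistical confidence interval.

## What the synthetic generator emulates — and what it does not

The generator produces data with the statistical structure the analysis
assumes, so the whole pipeline can be exercised and property-tested
without MD or TD-DFT engines:

* **Torsional populations** are von Mises mixtures (sampled with the
  Best–Fisher rejection algorithm). Default: modes at −113° and −76°,
  equal weights — a bimodal structure typical of a hindered aryl torsion.
* **Frames are i.i.d. draws**, not autocorrelated dynamics: the sampling
  schedules this package models save frames far apart relative to the
  torsional correlation time, so decimated frames are treated as
  uncorrelated anyway. Passing tests therefore say nothing about
  equilibration or autocorrelation handling in real trajectories.
* **Excitation coupling.** The bright-state energy follows
  $E_k = E_{\text{ref}} - a\,(1 - \cos(\delta_k - \delta_0))$ plus
  Gaussian noise: the simplest periodic map anchored at a reference
  dihedral $\delta_0$, with energy decreasing away from it. That is the
  mechanism by which populating non-minimum conformations red-shifts the
  ensemble band; it is not a model of any real chromophore's
  potential-energy surface. Sign and amplitude are configurable.
* **Weak states** ride along at fixed offsets (+0.4 eV, f = 0.05;
  +0.7 eV, f = 0.02) so bright-state selection and multi-state
  reconstruction are exercised.

### Default scenario parameters, and why

The defaults are the package's reference study conditions, chosen once:

* Schedule 5 ns / 4 ps / stride 10 (1251 → 126 conformers), the sampling
  protocol the counts above are calibrated to.
* Bright state 2.65 eV, f = 0.8012 — a visible-band π–π* transition.
* $\delta_0 = -66°$, near the denser mode: the optimised-structure-like
  torsion. Coupling amplitude a = 1.2 eV, noise 0.02 eV.
* Gas κ = 12, solution κ = 60: narrowing the torsional distribution
  emulates the reduced conformational mobility of the solvated probe, and
  is what makes the solution-phase static-versus-ensemble shift smaller.
* Solution reference energy 2.25 eV (vs 2.65 gas): a fixed 0.4 eV
  solvatochromic offset of the bright state, so the gas/solution pair
  yields a positive solvent red-shift (~80 nm on the optimised structure)
  with the conf shift slightly smaller than the opt shift.

A design limitation found while fixing these defaults: with cosine
coupling, $dE/d\delta = 0$ at $\delta_0$, so any torsional density near
$\delta_0$ piles up spectral density at $E_{\text{ref}}$ and pins the
broadened band maximum near it. The static-versus-ensemble shift of the
default scenarios therefore saturates around 0.06 eV (gas) and 0.03 eV
(solution) — a clear, correctly ordered ~2:1 ratio, but smaller in
absolute terms than the ~0.2/0.1 eV shifts seen in real hybrid-functional
studies of such probes. Tests assert the sign, ordering, seed-robustness
and amplitude-monotonicity of the shift, not its absolute magnitude.

Under the default seed the shipped pipeline prints:

```
[gas] N_p = 126, lambda_max conf 479.2 nm, opt 467.9 nm, dE = 0.0629 eV
[solution] N_p = 126, lambda_max conf 558.0 nm, opt 551.0 nm, dE = 0.0279 eV
solvent shift (conf) 78.7 nm, (opt) 83.2 nm
```

(Reproduce with `run_pipeline(default_run_config())`; every number above
is recomputed by the test suite's pipeline tests at a reduced problem
size, and the full-size run takes a few seconds.)

## Conventions that reconcile the protocol counts

A 5 ns run saved every 4 ps yields 1250 saved configurations; extracting
"one in every ten" of them must nevertheless give 126. The only simple
convention consistent with both counts is to model the trajectory as 1251
frames — t = 0 plus 1250 saves — and decimate zero-based indices
0, 10, …, 1250. `saved_frame_times()` and `decimation_indices()` implement
exactly this, and the convention is pinned by tests.

## Known limitations

* No trajectory alignment, periodic-boundary unwrapping or solvent atoms:
  frames are assumed whole-molecule, solute-only.
* No statistical uncertainty on $\lambda_{\max}$ from finite $N_p$; none
  is conventionally reported for this estimator.
* The Gaussian-log parser reads only the excited-state summary lines
  (`Excited State N: … eV … nm f=…`); orbitals, transition dipoles and
  solvation metadata are ignored. Re-printed state blocks supersede
  earlier ones, which matches how stateful jobs append to logs.
* Mixed levels of theory in one ensemble are rejected; heterogeneous
  state counts per conformer (five for most, ten for a few) only warn,
  mirroring mixed real-world protocols.
* Problem sizes in the test suite are scaled to the structure of each
  property (e.g. oracle equivalence on $N_p \le 20$, mode recovery on
  10⁴ draws × 20 seeds, pipeline round-trips on ~100-frame schedules);
  the defaults always reproduce the full 1251/126 protocol.
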