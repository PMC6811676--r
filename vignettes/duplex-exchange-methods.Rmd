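---
title: "Models and methods: exchange kinetics, sugar geometry and NOE restraints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: exchange kinetics, sugar geometry and NOE restraints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duplexdyn)
```

`duplexdyn` quantifies slow two-state conformational exchange in nucleic-acid
duplexes — the regime in which two conformers give separate resonances and
interconvert at a few events per second, as in duplexes carrying
metal-mediated base pairs.  This vignette documents the models, their
assumptions, the numerical choices, and what the synthetic-data tests do and
do not establish.

## The kinetic model

All magnetization transfer is expressed through a first-order generator
matrix acting on pool magnetizations, $d\mathbf{M}/dt = G\,\mathbf{M}$, with
non-negative off-diagonal transfer rates and losses (including longitudinal
relaxation $R_1$) on the diagonal.  `propagate_rate_matrix()` solves this by
eigendecomposition of $G$, falling back to scaling-and-squaring
(`Matrix::expm`) when the eigenbasis is ill-conditioned (condition estimate
above $10^{10}$).  The closed forms are convenience layers over this model
and are tested to agree with the matrix exponential to $10^{-10}$ and with
adaptive ODE integration (`deSolve::lsoda`) to $10^{-8}$.

**Two-site exchange.**  A major conformer A converts to a minor conformer
with rate $k_1$ and back with $k_{-1}$ (`k_rev` in code); both share $R_1$.
Equilibrium populations follow from detailed balance,
$p_A = k_{-1}/k_{ex}$, $p_B = k_1/k_{ex}$, $k_{ex} = k_1 + k_{-1}$.
For magnetization starting on A:

$$V_{AA}(t) = V_0\,(p_A + p_B e^{-k_{ex} t})\,e^{-R_1 t}, \qquad
  V_{aA}(t) = V_0\,p_B\,(1 - e^{-k_{ex} t})\,e^{-R_1 t}.$$

Peak labels are detected-site then origin-site, so `aA` is the exchange
cross peak detected on the minor resonance from major-site origin.

**The amide/amine z-z scheme.**  The reporter in the z-z exchange
experiment is a cytosine amine (NH$_2$, major form) that becomes an imino-type
NH in the minor form.  The reverse branch conserves pool magnetization — the
NH proton is converted equally to both NH$_2$ protons — while the forward
branch carries only a fraction of the NH$_2$-pool magnetization into NH,
because one of the two amine protons is lost on deprotonation.  That
fraction is the `retention_factor`, default $1/2$; it is exposed as a
parameter because the forward branch is a modelling choice, not something
the experiment pins down.  With `retention_factor = 1` the scheme reduces
exactly to symmetric two-site exchange, a reduction the tests assert.
All pools share one $R_1$, mirroring how the experiment is analysed.

**Four-pool exchange + NOE.**  For exchange-mediated NOESY cross peaks, two
protons X and Y are tracked in both conformers (pools `A`, `a`, `B`, `b`).
Exchange connects the same proton across conformers ($k_1$, $k_{-1}$);
dipolar cross-relaxation $\sigma$ connects X and Y within a conformer.  The
rate-matrix off-diagonals use $|\sigma|$; the sign convention (negative for
slowly tumbling macromolecules) is documented but only the magnitude enters
the kinetics, and transverse effects, spin diffusion through third protons,
and $\geq 3$-state exchange are out of scope.  Origin amplitudes default to
the equilibrium populations, as in a NOESY experiment whose longitudinal
magnetization starts at thermal equilibrium.

## Fitting procedures

All fits use bounded Levenberg–Marquardt (`minpack.lm::nls.lm`) with a
three-point multi-start ladder over $k_{ex} \in \{1, 10, 50\}$ s$^{-1}$ to
avoid local minima; rates are constrained non-negative.  Standard errors
come from the Gauss–Newton approximation (scaled inverse of $J^\top J$ at
the optimum).  When volume uncertainties are supplied the residuals are
inverse-variance weighted; otherwise unweighted, since the weighting used in
the original analyses is not stated.  Fitted rate constants are invariant to
per-curve amplitude scaling, so normalization conventions (for display,
curves are often normalized to a fixed mixing time) do not affect them —
each fit carries free amplitude parameters instead.

* `fit_global_zz()` fits all four NH2/NH curves jointly with one shared
  $(k_1, k_{-1}, R_1)$ and one amplitude per origin — five parameters over
  64 points on the default grid.
* `fit_buildup_sum()` fits a single exchange cross peak to
  $C\,(1-e^{-k_{ex}t})\,e^{-R_1 t}$; the maximum of that curve sits at
  $t^* = \ln(1 + k_{ex}/R_1)/k_{ex}$, which the tests verify against a
  dense grid.  Data with no visible decay leave $R_1$ unconstrained and are
  flagged, not silently fitted.
* `fit_normalized_rates()` fits the relaxation-free ratio
  $aA/(AA + aA) = p\,(1 - e^{-k_{ex}t})$, whose plateau is the destination
  population; $k_1 = p\,k_{ex}$ (origin-dependent) and
  $k_{-1} = k_{ex} - k_1$.  Delta-method errors are propagated to the
  derived rates.
* `fit_mediated_noe()` fits $Ab/(AB + Ab)$ to the exact four-pool model.
  Two analytic facts shape this fit: a uniform $R_1$ factors out of every
  curve, so the ratio is relaxation-free; and when both conformers share
  one cross-relaxation rate the ratio is *invariant to its magnitude*
  (the NOE step scales mediated and direct transfer identically).  The
  shared $\sigma$ is therefore held fixed rather than estimated — a
  deliberate design choice; data with no mediated signal, or generated
  with $\sigma = 0$, are flagged unidentifiable.
* `aggregate_sites()` reports the unweighted mean and sample standard
  deviation over converged per-site fits, the convention used when several
  reporter sites are summarized as mean ± sd.

One identification caveat is intentional: the fitted minor population is
not constrained to any nominal species ratio.  A reported 3:1 ratio and a
rate ratio $k_{-1}/k_1 \approx 2.2$ need not coincide exactly, and the
package does not force them to.

## Karplus conversion

`karplus_forward()` evaluates
$J(\phi) = A\cos^2\phi + B\cos\phi + C$, optionally extended with
Haasnoot-type substituent corrections
$\sum_i \lambda_i\,(P_4 + P_5 \cos^2(\xi_i\phi + P_6|\lambda_i|))$.
The bundled default, `karplus_params_h1h2()`, is the generalized
parameterization for the H1'-C1'-C2'-H2' coupling of a 2'-deoxyribose
nucleotide: $P_{1..3} = (13.70, -0.73, 0)$,
$P_{4..6} = (0.56, -2.47, 16.9^\circ)$, with beta-corrected group
electronegativities for the three non-hydrogen substituents (O4'
$\lambda = 1.207$, $\xi = +1$; glycosidic N $\lambda = 0.724$, $\xi = -1$;
C3' $\lambda = 0.209$, $\xi = +1$).  This curve gives the characteristic
$\sim$1 Hz (N-type) to $\sim$10 Hz (S-type) sugar couplings and places a
6.5 Hz coupling at $\phi = 142^\circ$ on the 90–180° branch.  The
coefficients are overridable through `karplus_params()` for other coupling
pathways.

`karplus_invert()` brackets roots on a 1° grid and refines them to
$10^{-6}$ degrees with `uniroot`.  Two numerical subtleties are handled
explicitly: the attainable range is computed from the *continuous* curve
(a grid extremum can undershoot the true one by $\sim 10^{-3}$ Hz), and
couplings lying between a grid extremum and the true local extremum — which
produce no sign change on the grid — are recovered by refining the
extremum and bracketing both sides.  Couplings outside the attainable range
raise an error that reports the range.

## Pseudorotation and pucker classes

Ring torsions follow the standard pseudorotation description
$\nu_j = \nu_{max}\cos(P + 144^\circ (j-2))$, so $\nu_2 = \nu_{max}\cos P$.
The analyzer inverts this with
$\tan P = ((\nu_4+\nu_1)-(\nu_3+\nu_0)) / (2\nu_2(\sin 36^\circ + \sin 72^\circ))$,
quadrant-corrected via `atan2`, and recovers the amplitude from
$\nu_{max} = \sqrt{\nu_2^2 + ((\nu_4+\nu_1-\nu_3-\nu_0)/s)^2}$, which stays
positive through both $\cos P = 0$ points.  A ring planar to within
$10^{-6\,\circ}$ is reported as `planar/undefined` rather than dividing by
zero.  Real (non-ideal) rings carry an `rms_residual` diagnostic — the rms
misfit of the ideal cosine wave to the measured torsions.

The pucker wheel has twenty 18° sectors, half-open on the right, with
envelope forms centred at odd multiples of 18° (C3'-endo at 18°, O4'-endo
at 90°, C2'-endo at 162°) and twist forms at even multiples named by their
two displacements (the P = 0° sector is `C3'-endo/C2'-exo`).  The class
depends only on the phase, so it is invariant to amplitude scaling.

Dihedrals use the sign convention shared by gemmi, biopython and bio3d
(verified against `bio3d::torsion.xyz` in the tests): for the staircase
arrangement (0,0,0)→(1,0,0)→(1,1,0)→(1,1,1) the angle is $+90^\circ$.
Ensemble summaries use circular statistics (resultant-vector mean and
$\sqrt{-2\ln \bar R}$ sd) so that values near ±180° never average to ~0°.
Ensemble r.m.s.d. superposes each model on the reference by the Kabsch
algorithm over the heavy atoms in common, cross-checked against
`bio3d::rmsd(fit = TRUE)`.

## NOE calibration and restraint bookkeeping

Volumes map to distances by the isolated spin-pair approximation against a
reference pair of fixed separation, $r_i = r_{ref}(V_{ref}/V_i)^{1/6}$; the
default reference is the covalently fixed pyrimidine H5–H6 pair at 2.45 Å,
overridable.  Calibration is scale-invariant and monotone, both asserted as
properties.

How distances map to the four restraint categories is not prescribed by the
calibration itself; the package assigns by calibrated distance with
thresholds at 3.0, 4.5 and 6.0 Å, half-open on the right.  The rationale:
the thresholds coincide with the printed upper bounds of the strong, medium
and weak categories, so a distance is always inside its category's bounds
(strong 1.8–3.0, medium 1.8–4.5, weak 3.0–6.0, very weak 4.0–7.0 Å).
Pseudo-atom corrections (+1.0 Å on the upper bound for methyl/amine
protons) exist behind a flag but default off.  The per-residue figure
divides the total count by the duplex length (all residues) and is reported
to two decimals, the convention of published restraint tables.  The XPLOR
writer emits `assign (resid i and name A) (resid j and name B) d dminus
dplus` with `d` the bounds midpoint — a bit-exact template asserted in the
tests.

## The synthetic-data generators

The generators define the study conditions under which every stage is
tested: a two-conformer system with forward/reverse rates 3.5/7.7 s$^{-1}$
(local amide/amine scheme) or 4.3/8.8 s$^{-1}$ (global NOESY scheme),
shared $R_1 = 2$ s$^{-1}$, 16 log-spaced mixing times from 0.01 to 0.5 s,
and 5% multiplicative Gaussian volume noise.  The log-spaced grid covers
both the exchange build-up (time scale $1/k_{ex} \approx 80$ ms) and the
relaxation decay; the exact experimental grids are not published, so these
are realistic stand-ins, overridable in `scenario_config()`.
Multiplicative noise was chosen over additive because peak-volume errors
scale with intensity in practice; volumes are floored at $10^{-6}$ of the
clean signal so noise never flips a peak's sign.  Every generator requires
a seed and emits a ground-truth sidecar, giving each fit a one-command
recovery test.

What passing these tests shows: the estimators are consistent and
well-calibrated *under the assumed model* — correct kinetic scheme, shared
$R_1$, multiplicative noise, ideal integration.  What they do not show:
robustness to peak overlap, baseline distortions, spin diffusion,
differential relaxation between conformers, or integration errors in real
spectra.  Parameter-recovery results on synthetic data are a floor, not a
ceiling, for real-data uncertainty.

## Problem sizes and numerical defaults

The shipped tests use 16-point mixing grids, 25–100 noisy replicates for
recovery studies, 100 random systems for the triple closed-form/expm/ODE
agreement checks, and 250-draw round-trip loops for the Karplus and
pseudorotation inversions — sizes chosen so the whole suite settles in
well under a minute while keeping Monte-Carlo checks stable.  Oracle
tolerances: $10^{-10}$ closed-form vs. eigendecomposition, $10^{-8}$ vs.
ODE integration, $10^{-6}$ Hz and $10^{-9}$ degrees for the geometry round
trips.  Multi-start seeds and all scenario seeds are fixed and documented
in the test files.

## Known limitations

* The exchange models are longitudinal-only: no transverse relaxation,
  chemical-shift evolution, lineshape or relaxation-dispersion analysis.
* The four-pool NOE model tracks one proton pair per conformer; spin
  diffusion through additional protons is not modelled.
* The shared-$\sigma$ mediated-ratio fit cannot estimate $\sigma$ itself
  (invariance, above); per-conformer $\sigma$ values are representable in
  the forward model but not separately identifiable from a single ratio.
* Analyses of deposited coordinate ensembles require the user to supply
  the PDB files; the package does not download them.
* Helicoidal parameters (twist, rise, grooves), axis bend and
  solvent-accessible surface areas are out of scope — established tools
  (Curves+, 3DNA) cover them.
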