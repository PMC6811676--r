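# duplexdyn

Exchange kinetics, sugar geometry and NOE restraint analysis for dynamic
DNA duplexes studied by solution NMR.

## The problem

Duplexes carrying metal-mediated base pairs (such as C–Hg(II)–T) can exist
as two well-resolved conformers in slow dynamic equilibrium — a major and a
minor species interconverting at a few events per second.  Standard NMR
experiments quantify this exchange: z-z exchange (EXSY) spectra and NOESY
mixing-time series show exchange cross peaks whose build-up encodes the
forward and reverse rate constants, while scalar couplings, sugar-ring
torsions and NOE volumes encode the local geometry of each conformer.
`duplexdyn` implements the full quantitative chain for such systems:

* **Forward models** of longitudinal magnetization exchange: the two-pool
  closed form `V_AA(t) = V0 (p_A + p_B e^{-k_ex t}) e^{-R1 t}`,
  `V_aA(t) = V0 p_B (1 - e^{-k_ex t}) e^{-R1 t}`; general rate-matrix
  propagation `dM/dt = G M` by matrix exponential; an amide/amine (NH2/NH)
  z-z exchange scheme in which one of two amine protons is lost on
  conversion; and a four-pool exchange + cross-relaxation network for
  exchange-mediated NOEs.
* **Inference**: a global least-squares fit of the four NH2/NH curves with
  shared `(k1, k-1, R1)`; the build-up fit
  `V(t) = C (1 - e^{-k_ex t}) e^{-R1 t}` for the total rate; the
  normalized-ratio fit `aA/(AA + aA) = p (1 - e^{-k_ex t})` that separates
  `k1` and `k-1`; and the exchange-mediated ratio fit `Ab/(AB + Ab)`
  against the exact four-pool model.
* **Geometry**: Karplus-equation conversion between three-bond couplings
  and dihedrals, `J(phi) = A cos^2 phi + B cos phi + C` with optional
  electronegativity corrections; sugar pseudorotation analysis
  (`P`, `nu_max`, pucker class) from torsions or multi-model PDB
  ensembles; circular ensemble statistics and superposition r.m.s.d.
* **Restraints**: NOE volume-to-distance calibration by the isolated
  spin-pair approximation `r_i = r_ref (V_ref / V_i)^{1/6}`, four-category
  binning with the standard bounds (strong 1.8–3.0 Å, medium 1.8–4.5 Å,
  weak 3.0–6.0 Å, very weak 4.0–7.0 Å), per-residue bookkeeping and
  XPLOR-dialect restraint output.
* **Synthetic data**: seeded generators for every input, so each fitting
  stage ships with a parameter-recovery test.

## Worked example

Simulate one reporter site of a z-z exchange experiment at the study
conditions (k1 = 3.5 s⁻¹, k⁻¹ = 7.7 s⁻¹, R1 = 2 s⁻¹, 16 log-spaced mixing
times from 10 to 500 ms, 5% multiplicative noise) and fit it globally:

```r
library(duplexdyn)
cfg <- scenario_config(k1 = 3.5, k_rev = 7.7, R1 = 2.0,
                       noise_sd = 0.05, seed = 42)
fit <- fit_global_zz(generate_zz_dataset(cfg)$sites$site1)
fit
#> Exchange-kinetics fit
#>   k1            3.458  +/- 0.423
#>   k_rev         7.521  +/- 0.372
#>   R1            1.901  +/- 0.225
#>   k_ex = 10.98 s^-1;  rss = 0.04385 over 64 points;  converged
```

The fitted forward and reverse rates (3.46 and 7.52 s⁻¹) recover the
generating values within their standard errors; `k_ex` is their sum.

Convert an observed sugar H1'-H2' coupling to a dihedral, and classify a
sugar pucker:

```r
karplus_invert(6.5, branch = c(90, 180))
#> [1] 142.0623
pseudorotation_from_torsions(torsions_from_pseudorotation(88, 34))
#> Pucker: P = 88.00 deg, nu_max = 34.00 deg  [O4'-endo]
```

A 6.5 Hz coupling on the 90–180° branch corresponds to a 142° H1'-C1'-C2'-H2'
dihedral; a ring with pseudorotation phase 88° is an O4'-endo pucker.

A command-line wrapper with the same functionality is installed at
`inst/cli/duplexdyn` (subcommands `simulate-zz`, `fit-zz`, `karplus`,
`pucker`, `noe-calibrate`, `recover`, ...).

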