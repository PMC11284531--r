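# radscav

Radical-scavenging kinetics from quantum thermochemistry: the
post-electronic-structure half of an antioxidant activity assessment,
following the QM-ORSA protocol (quantum-mechanics-based test for overall
radical scavenging activity).

## Who this is for

Computational chemists who have per-species enthalpies and Gibbs energies
(and transition-state barriers) from a quantum-chemistry code and want the
downstream analysis done reproducibly: which mechanism operates at which
bond, how the acid–base speciation partitions the reactive population at a
given pH, and what the observable overall rate constant against a probe
radical such as HOO• is. The package ships the published tables for the
coumarinolignans cleomiscosin A/B/C as a bundled regression dataset.

## What it computes

**Thermodynamic descriptors** per phenolic/benzylic site, in kcal/mol:

    PA  = H(CM–O⁻)   + H(H⁺) − H(CM–OH)     (SPLET first step)
    IE  = H(CM–OH⁺•) + H(e⁻) − H(CM–OH)     (SETPT first step)
    BDE = H(CM–O•)   + H(H•) − H(CM–OH)     (FHT)

plus products-minus-reactants reaction free energies of each mechanism's
first step against HOO•, and ΔG°-threshold screening of (site, mechanism)
channels.

**Speciation**: pKa from a supplied linear free-energy model and
Henderson–Hasselbalch (or general sequential-ladder) mole fractions.

**Channel kinetics**: conventional TST on a 1 M standard state,
`k = σ κ (k_B T/h) exp(−ΔG‡/RT)`, with per-channel tunneling resolution
(explicit κ → asymmetric-Eckart quadrature → Wigner → 1), Marcus-theory
SET barriers `(λ + ΔG°)²/4λ`, and Collins–Kimball combination with the
Smoluchowski/Stokes–Einstein diffusion limit in condensed media.

**Assembly**: population-weighted channel rates `k_f = f·k_app`, overall
rate constants `k_overall = Σ k_f` under a medium-dependent
channel-admission rule, branching ratios `Γ = 100·k_f/k_overall`, scenario
comparisons and fold-differences against reference antioxidants.

## Worked example

Gas-phase FHT channels of cleomiscosin A from its printed barriers and
tunneling coefficients:

```r
library(radscav)

branches <- data.frame(compound = "CMA", site = c("O14-H", "C18-H"),
                       mechanism = "FHT", protonation_state = "HA",
                       k_app = tst_rate(c(16.7, 18.6),
                                        kappa = c(195.2, 153.0)))
overall_rate(branches, medium("gas"))
#> <overall_result> CMA in gas (default): k_overall = 718 M-1 s-1
#>   FHT  HA  O14-H  f=1  k_app=696   k_f=696   Gamma= 96.9%
#>   FHT  HA  C18-H  f=1  k_app=22.1  k_f=22.1  Gamma=  3.1%
```

The O14–H phenolic site carries 96.9% of the flux; the recomputed
`k_overall` of 7.2×10² M⁻¹ s⁻¹ agrees with the published 7.52×10² within
the ~10% implied by barriers printed to 0.1 kcal/mol. In water the picture
inverts — the sub-percent phenoxide population dominates through
diffusion-limited electron transfer:

```r
mole_fractions(9.43, 7.4)
#>     neutral       anion
#> 0.990753748 0.009246252
weighted_rate(0.009, 7.80e9)   # f * k_app  ->  7.02e7 M-1 s-1
```

The full replay of the bundled dataset — TST recomputation, weighted
rates, overall sums, branching ratios, speciation percentages, scenario
ratios — runs with:

```r
chk <- run_reproduce()
attr(chk, "pass")   # TRUE; 100 checks
```

Stage drivers (`run_thermo`, `run_speciation`, `run_kinetics`,
`run_overall`, `run_simulate`, `run_reproduce`) accept data.frames or CSV
paths and write stage tables plus a run manifest; a thin CLI wrapper lives
at `inst/scripts/radscav.R`. The synthetic-data generator
(`generator_config()`, `run_simulate()`) builds internally consistent
species/barrier tables whose composed descriptors recover the sampled
targets exactly. See `vignette("radical-scavenging-kinetics")` for the
model details, numerical choices and limitations.

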