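# hkadyn

Analysis toolkit for molecular-dynamics ensembles of the gastric
H⁺,K⁺-ATPase cation-binding pocket in its luminal-open, phosphorylated
(E₂P) conformation — the state in which the pump releases protons into the
stomach lumen and takes up K⁺.

The pocket carries five titratable carboxylates (E343, E795, E820, D824,
D942). A classical MD simulation fixes which of them are protonated, so the
biology question "how do protons and K⁺ ions share this pocket as luminal pH
changes?" becomes an ensemble question over protonation microstates. The
package implements the full downstream analysis of such an ensemble:

- **Protonation states** — enumerate and canonically label the pocket
  microstates (the standard ensemble is the 20 states with two or three
  protons, three replicates each = 60 trajectories), and serialize the
  ensemble design as a JSON manifest.
- **pKa series** — ingest per-frame pKa tables produced by an external
  empirical predictor on trajectory snapshots (CSV, one row per frame at
  1 ns spacing), or estimate them with a simple built-in geometry-only
  stand-in so synthetic structures are analyzable end to end.
- **Dynamic pKa correlation** — per trajectory, the pairwise Pearson
  coefficient over the trailing window (default the last 100 ns,
  n = 100 samples),

  r = Σₜ (xₜ − x̄)(yₜ − ȳ) / √(Σₜ (xₜ − x̄)² · Σₜ (yₜ − ȳ)²),

  with Fisher-z confidence intervals for the strongest pairs.
- **Proton-transfer network** — strong anti-correlation (r < −0.5) between
  a pair of which exactly one member is protonated marks a candidate
  proton transfer from the protonated donor to the deprotonated acceptor;
  candidates can be filtered by carboxylate O–O proximity, and are
  aggregated over the ensemble into a directed network whose edge weights
  count contributing trajectories (exported as CSV / JSON / Graphviz DOT).
- **K⁺ binding occupancy** — coordination-based detection of bound ions
  (≥ 2 pocket oxygens within 0.35 nm), classification into site I/II
  versus the deeper aspartate-coordinated site III, per-trajectory binding
  traces, and end-of-trajectory occupancy statistics per state and per
  proton-count group.
- **Umbrella sampling / WHAM** — window planning (47 windows over
  0.20–2.50 nm at 0.05 nm spacing, k = 5000 kJ·mol⁻¹·nm⁻², 310 K),
  the self-consistent weighted-histogram estimate of the 1-D potential of
  mean force G(z) = −k_BT ln P(z), moving-block bootstrap errors,
  bulk-zero alignment and binding free energies.
- **Synthetic data** — generators for correlated AR(1) pKa series (with
  planted anti-correlation motifs and change points), stochastic ion
  binding over a toy pocket geometry, and Boltzmann-sampled umbrella
  windows from a known potential. They define the ground truth against
  which every analysis stage is tested.

## Worked example

Generate a synthetic 60-trajectory ensemble with a transfer motif
(E795⁺ → E820 at ρ = −0.923) planted in the nine trajectories of three
states, then recover it:

```r
library(hkadyn)

spec <- synth_spec(seed = 7,
  motifs = list(list(pair = c("E795", "E820"), rho = -0.923,
                     states = c("E343+E795+", "E795+D824+", "E795+D942+"))))

series <- gen_pka_ensemble(spec)              # 60 pka_series
mats   <- lapply(series, correlation_matrix, window_ns = 100)
mats[[34]]                                    # the E795+D824+ replicate 1
#> correlation_matrix (state E795+D824+, replicate 1): n = 100, window 151-250 ns
#>        E343   E795   E820   D824   D942
#> E343  1.000  0.108 -0.146  0.143  0.094
#> E795  0.108  1.000 -0.938 -0.063 -0.129
#> E820 -0.146 -0.938  1.000  0.122  0.198
#> D824  0.143 -0.063  0.122  1.000  0.349
#> D942  0.094 -0.129  0.198  0.349  1.000

pairs <- do.call(rbind, lapply(mats, candidate_pairs, threshold = -0.5))
aggregate_network(pairs)
#> transfer_network: 5 residues, 2 directed edges
#>            edge instances
#> 1 E795+ -> E820         9
#> 2 D824+ -> E795         1
```

The planted donor→acceptor edge is recovered with its nine contributing
trajectories (the sample r in the matrix above, −0.938, estimates the
planted −0.923); the single-count D824⁺ → E795 edge is a null false
positive at the −0.5 threshold, the kind the instance ranking is designed
to discount.

The umbrella/WHAM round trip on the same spec (windows Boltzmann-sampled
from the built-in well-plus-barrier test potential):

```r
wins <- gen_umbrella_samples(spec)            # 47 windows, 40k samples each
prof <- align_pmf(wham(wins, n_bins = 200), bulk_region = c(2.0, 2.5))
prof
#> pmf_profile: 200 bins over [ 0.12 , 2.587 ] nm @ 310 K
#>   G range: 17.58 kJ/mol ( 6.82 kT ); zeroed over [2, 2.5] nm
binding_free_energy(prof)
#> $dG_kJmol
#> [1] -11.55088
#> $dG_kT
#> [1] -4.481457
#> $z_min
#> [1] 0.4545288
```

The recovered well depth (−11.55 kJ/mol at z = 0.45 nm) matches the
generator potential's −12 kJ/mol well within the profile's bootstrap
error.

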