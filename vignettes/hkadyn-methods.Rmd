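---
title: "Methods: dynamic pKa correlation, transfer networks, occupancy and WHAM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dynamic pKa correlation, transfer networks, occupancy and WHAM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hkadyn)
```

# The scientific setting

The gastric proton pump (H⁺,K⁺-ATPase) exchanges cytoplasmic H⁺ for
luminal K⁺ across the parietal-cell membrane. In the luminal-open E₂P
conformation its transmembrane cation pocket — five carboxylates E343,
E795, E820, D824, D942, plus the lysine K791 — must release protons and
accept K⁺ against a million-fold proton gradient. Classical MD cannot move
protons during a run, so the ensemble strategy is to simulate every
plausible fixed protonation microstate of the pocket and infer proton
mobility *indirectly*, from how the residues' environment-dependent pKa
values co-fluctuate along each trajectory. `hkadyn` implements that
inference chain, plus the companion analyses (spontaneous K⁺-binding
occupancy and umbrella-sampling free-energy profiles), and a synthetic-data
layer that makes the whole chain testable without any trajectory data.

A note on residue naming: one early mention of the fifth pocket residue as
"D842" appears in the source literature, while all structural and methods
contexts use D942; `hkadyn` uses D942 throughout.

# Protonation microstates

A state is a subset of the pocket carrying protons; its canonical label is
the `'+'`-suffixed concatenation in fixed pocket order (`"E343+E795+"`).
Labels are the join keys across all modules, so the pocket order
(E343, E795, E820, D824, D942) is fixed regardless of how a state was
constructed, and enumeration returns states in lexicographic label order so
any two runs list the ensemble identically.

The default ensemble is the 20 states with exactly two or three protons
(`choose(5,2) + choose(5,3)`). Single-proton states leave too much net
negative charge in the pocket for stable conformations, and four- or
five-proton states essentially abolish K⁺ binding; both remain enumerable
through the API (`enumerate_states()`) but are excluded from
`default_ensemble_states()`. With the conventional three replicates per
state the ensemble is 60 trajectories of 250 ns each — 750 ns of sampling
per state, recorded per state in the JSON ensemble manifest together with
deterministic per-replicate seeds.

# pKa series and the stand-in estimator

Production input is the output of an external empirical pKa predictor run
on trajectory snapshots every 1 ns: a CSV per trajectory with header
`time_ns,E343,E795,E820,D824,D942`. Ingestion sorts rows by time, rejects
duplicate times and non-numeric cells with the offending row index, and
tolerates missing cells (predictor failures) up to 10% per residue —
beyond that the series is refused rather than silently imputed, because
imputation would bias the correlation estimates. Missing pairs are dropped
pairwise downstream, with the dropped count reported on the coefficient.

For end-to-end runs on synthetic structures the package includes a
deliberately minimal stand-in estimator. It is *not* a reimplementation of
any published predictor; it is the simplest geometry-only model with the
dependence structure the downstream analysis needs:

\[
\mathrm{p}K_a = \mathrm{p}K_a^{model}(\text{class})
  + \underbrace{\mathrm{clamp}\!\big(w_b\,(N_{heavy}(r_b) - N_{ref}),\,0,\,b_{max}\big)}_{\text{burial}}
  + \sum_{j}\underbrace{(-q_j)\,w_c / d_j}_{\text{charge shifts},\ d_j \le r_c}
\]

with model pKa 3.80 (Asp) / 4.50 (Glu), burial shell radius
$r_b = 0.9$ nm, charge cutoff $r_c = 1.2$ nm, $w_c = 2.4$ pKa·nm,
$w_b = 0.02$ pKa per atom. $N_{ref} = 20$ and $b_{max} = 2.0$ pKa units
are the package's own calibration of the burial term (a typical
solvent-exposed carboxylate in the toy geometries sees ~20 heavy
neighbours; the clamp keeps pathological geometries from dominating).
Positive neighbours (K⁺, amine nitrogens) lower the pKa, negative ones
(deprotonated carboxylates) raise it; distances are measured from the
residue's carboxylate-oxygen centroid, only heavy atoms are used (hydrogen
positions never enter), and the burial count includes every non-self heavy
atom in the frame. Because only interatomic distances enter, the estimator
is exactly invariant under rigid motions — a tested property.

# Windowed Pearson correlation

Per trajectory and residue pair the package computes the standard Pearson
coefficient

\[
r=\frac{\sum_{t}(x_t-\bar x)(y_t-\bar y)}
       {\sqrt{\sum_t (x_t-\bar x)^2}\sqrt{\sum_t (y_t-\bar y)^2}}
\]

restricted to the trailing window of the series, by default the last
100 ns (n = 100 samples at 1 ns). Both the sums and the means use only the
windowed samples: mixing full-trajectory sums with windowed means would
not be a correlation coefficient, so the windowed reading is adopted
throughout and the window is recorded in the result. When the window is
not a multiple of the sampling interval the sample count is floored, with
a message. The trailing window is used because early trajectory segments
reflect relaxation from the starting structure (including K⁺ arrival),
while the transfer inference is about the settled pocket.

Confidence intervals use the Fisher z-transform,
$\tanh(\operatorname{atanh} r \pm z_{crit}/\sqrt{n-3})$, two-sided at a
configurable level (default 99%, the level used when annotating the three
strongest pairs of a matrix). The transform is the standard choice at
moderate n; its empirical coverage on independent null data is itself an
acceptance-tested property. Note that the pKa series are autocorrelated
(the generator's default AR time constant of 5 ns leaves only ~20
effective samples in a 100-sample window), which widens the *true*
sampling distribution relative to the nominal interval; the coverage test
therefore uses independent samples, and intervals on strongly
autocorrelated series should be read as optimistic.

# The transfer network

Four physical criteria turn correlation matrices into directed
proton-transfer hypotheses:

1. **Exactly one protonated member.** A transfer needs a donor proton and
   an acceptor vacancy, so pairs with both or neither member protonated
   are excluded however strong their anti-correlation. The protonated
   member is the donor.
2. **Strong anti-correlation**, strictly $r < -0.5$ by default: when one
   residue's pKa runs high while its partner's runs low, the pocket
   electrostatics are consistent with the proton preferring the other
   site.
3. **Proximity.** Transfer over several water shells is implausible; the
   optional filter keeps pairs whose time-averaged minimum carboxylate
   O–O distance is ≤ 0.6 nm (a typical hydrogen-bond/water-bridge reach;
   no quantitative rule is published, so the cutoff is configurable and
   the distance is recorded on every pair).
4. **Depth from the luminal access pathway** bears on release to bulk; no
   quantitative rule exists for it either, so it is reported as a
   per-residue annotation (`rank_transfer_likelihood()`), never applied
   as an automatic filter.

The donor is defined operationally by protonation. The complementary
reading — transfer runs from the low-pKa residue to the high-pKa one — is
recorded per pair as a `low_to_high` consistency flag (windowed-mean
comparison); inconsistent pairs are flagged, not dropped.

Aggregation counts **one instance per trajectory** (state × replicate),
not per frame: an edge's weight is the number of distinct trajectories in
which the pair passed the filters, which is what makes counts comparable
across an ensemble of equal-length trajectories. Duplicate tuples are
deduplicated with a warning, conservation (edge counts sum to accepted
tuples) is a tested invariant, and edges are ranked by count with
canonical-order tie-breaks so reports are stable.

# K⁺ binding and occupancy

No explicit binding criterion is published for this system, and sites I
and II cannot be distinguished in the trajectories, so `hkadyn` uses a
coordination criterion rather than site centroids: an ion is bound when at
least `min_coord = 2` pocket carboxylate oxygens lie within
`cutoff_nm = 0.35` (the typical K⁺–O coordination distance); both
parameters are exposed. A bound ion is classified **site III** when a
strict majority of its coordinating oxygens come from the aspartates
D824/D942 (the deeper locus), otherwise **site I/II**; exact ties go to
site I/II with a flag. Classification is a pure function of the
coordination multiset, and detection is monotone in the cutoff and
invariant to atom ordering — all tested properties.

Occupancy statistics are computed from the **end-of-trajectory** bound
counts (mean ± standard error over replicates, n−1 denominator), matching
how per-state bar summaries are conventionally built; time-averaged
occupancy is reported alongside as a diagnostic. Group means over the
two- and three-proton states summarize the stoichiometry picture, and
`stoichiometry_correlation()` quantifies the occupancy trend against the
number of protonated glutamates (with the aspartate analogue as a null
comparison): protonated glutamates mimic a lower luminal pH, so a negative
trend supports the 2H⁺/2K⁺ → 1H⁺/1K⁺ stoichiometry-variation hypothesis.
An ion bound since equilibration has first-binding time 0 by convention.

# Umbrella sampling and WHAM

The reaction coordinate is the distance along the membrane normal between
the bound K⁺ and a reference atom. The standard layout is 47 windows over
0.20–2.50 nm at 0.05 nm spacing with force constant 5000 kJ·mol⁻¹·nm⁻²
at 310 K. `generate_windows()` builds layouts with a floating-point-safe
count and refuses non-commensurate spans; `select_initial_frames()` picks
per-window starting frames from a pull trace (argmin with earliest-frame
tie-break).

`wham()` is the standard 1-D self-consistent scheme on `n_bins = 200`
equal-width bins: iterate the window constants $f_i$ and unbiased bin
probabilities until $\max_i |\Delta f_i| < 10^{-7}\,k_BT$ (cap 10⁵
iterations, with the residual reported on failure), then
$G(z) = -k_BT\ln P(z)$. Adjacent windows must share occupied bins —
a missing overlap is an error naming the gap, and the shared histogram
fraction is reported per neighbour pair. In the degenerate single-unbiased-
window limit the scheme reduces exactly to Boltzmann inversion of the
histogram, which is one of the tested oracle equivalences; the other is an
independently written *unbinned* MBAR-style estimator kept in the test
suite. Bin-center bias evaluation means very narrow bins relative to the
window width are unnecessary; 200 bins over the standard span puts several
bins under each window.

Errors come from a **moving-block bootstrap** (default block 50 samples)
because window series are autocorrelated and i.i.d. resampling would
understate the error; each replicate is recomputed with WHAM (warm-started
from the full-data constants), shifted onto the full profile (a PMF is
defined only up to a constant), and the per-bin standard deviation is
returned. Bootstrap runs are seed-deterministic.

`align_pmf()` subtracts the mean over a bulk region so the unbound plateau
defines zero, and `binding_free_energy()` reports the minimum over the
binding region in kJ/mol and in $k_BT$ ($k_B = 0.0083144621$
kJ·mol⁻¹·K⁻¹; one published description equates the ~0.8 kcal/mol profile
precision with $k_BT$, although $k_BT$ at 310 K is ≈0.62 kcal/mol — the
package always uses the physical value). The lateral flat-bottom
cylindrical restraint used in real sampling simulations only shapes the
sample generation; a 1-D estimator never sees it, and the synthetic
generator mimics its effect simply by sampling the 1-D coordinate.

# The synthetic-data layer

The generators produce inputs with exactly the statistical structure the
analysis assumes — no more:

- **pKa series**: stationary Gaussian AR(1) vectors whose stationary
  cross-residue correlation equals a target matrix (identity plus planted
  motif entries), built via the Cholesky factor of the target; non-PSD
  targets are refused. Defaults: 250 frames at 1 ns, per-residue means at
  the class model pKa, sd 1, autocorrelation time 5 ns — so a 100-sample
  window holds only ~20 effective samples, which stresses the interval
  machinery the way real series would. A change-point mode swaps a pair's
  means mid-trajectory to mimic observed regime switches.
- **Ion trajectories**: discrete-time jump dynamics of ions between bulk
  and two binding slots over a fixed toy pocket geometry (E795/E820
  proximal by construction; a site-III locus between the aspartates that
  becomes available when both aspartates are deprotonated). Per-slot
  on/off rates are set so the stationary occupancy matches the group
  endpoint targets — 1.87 bound K⁺ for two-proton states and 1.10 for
  three-proton states, the calibration values of the study design — in
  expectation; the acceptance check compares ensemble means against these
  targets within Monte-Carlo error.
- **Umbrella windows**: inverse-CDF sampling of
  $p_i(z)\propto e^{-\beta[U(z)+k(z-z_i)^2/2]}$ on a 10⁴-point grid that
  auto-expands until the density is negligible at its edges, followed by a
  Gaussian-copula AR(1) rank reshuffle that imposes a chosen
  autocorrelation time while leaving the marginal exact. The default test
  potential is a 12 kJ/mol well at 0.45 nm plus a 6 kJ/mol barrier at
  1.0 nm, flat in bulk.

What the generators deliberately do **not** model: force-field energetics,
coupled protein conformational dynamics, correlated binding/unbinding of
multiple ions, predictor-specific pKa error structure, or lateral ion
motion. Passing tests therefore demonstrate that the *estimators* are
correct and calibrated on data with the assumed structure — not that the
biological conclusions transfer to any particular MD data set. The
published ensemble-scale numbers (occupancy means, specific correlation
values, instance counts, ~5 $k_BT$ PMF orderings) derive from
micro-second MD on undeposited trajectories; here they serve as
calibration parameters and consistency fixtures, not as reproduction
targets.

# Numerical choices and problem sizes

- WHAM tolerance $10^{-7}\,k_BT$, 10⁵ iteration cap, 200 bins; window-order
  invariance holds to the self-consistency tolerance.
- Pearson guards: series shorter than 3 complete pairs, or with zero
  variance, raise errors rather than returning NaN; |r| is clipped to 1
  only against rounding.
- Tie-breaks everywhere are canonical pocket order, making every ranking
  byte-stable across runs.
- Test and acceptance problem sizes are chosen for desk-scale runs: the
  WHAM round trip uses the full 47-window layout at 40 000 samples per
  window (where the recovered profile matches the generator potential to
  < 0.5 $k_BT$, typically ~0.15–0.3); interval coverage uses 2000 null
  simulations; bootstrap scaling uses 40 replicates at two sample sizes;
  ensemble recovery uses the full 60-trajectory design at 250 frames.
  The complete suite runs in about two minutes on one CPU.

# Known limitations

- The stand-in pKa estimator is a three-term toy; it shares no code or
  coefficients with empirical predictors and should never be used to make
  pKa claims about real structures.
- Fisher intervals assume independent samples; on autocorrelated series
  they are optimistic (documented above, by design).
- WHAM is 1-D only; no MBAR production path (an unbinned MBAR variant
  exists only as a test oracle), no 2-D reaction coordinates.
- The binding criterion is geometric; transient mouth-of-pocket ions near
  the cutoff will flicker, which end-of-trajectory counting mitigates but
  does not remove.
- No explicit proton-transfer simulation: the network is a hypothesis
  generator over classical trajectories, exactly as intended.
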