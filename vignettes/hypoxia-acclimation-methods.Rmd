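---
title: "Methods: respirometry, hemoglobin-oxygen equilibria, qPCR expression and gill morphometrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: respirometry, hemoglobin-oxygen equilibria, qPCR expression and gill morphometrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypoxphys)
```

`hypoxphys` implements the quantitative pipeline of a fish
hypoxia-acclimation experiment: whole-animal intermittent-flow
respirometry, hemolysate oxygen-equilibrium analysis, hemoglobin-subunit
qPCR expression and gill morphometrics, together with a synthetic-data
generator that gives every estimator a known ground truth. This vignette
is the package's own account of the models, the defaults and the numerical
choices behind them.

## Gas conversions and oxygen solubility

Every module rests on three conversions.

**Percent air saturation to PO~2~.** The default is the dry-gas form,
$P_{\mathrm{O_2}} = \frac{\%\,\mathrm{airsat}}{100}\times 0.2095 \times
P_{\mathrm{baro}}$: 8% of air saturation at 760 mmHg gives 12.7 mmHg, and
30% gives 48 mmHg (rounded). A vapor-corrected variant, which subtracts
the saturated water vapor pressure first, is available via
`vapor_corrected = TRUE`; the dry form is the default because the
12.7 mmHg figure the workflow is anchored to back-computes exactly from
it.

**Oxygen solubility** $\alpha_{\mathrm{O_2}}$ (µmol L^-1^ mmHg^-1^) comes
from the Garcia & Gordon (1992) re-fit of the Benson & Krause data
(volumetric coefficients, converted with the 22.3916 L mol^-1^ molar
volume), referenced to water-saturated air:
$\alpha = C_{\mathrm{sat}}(T,S) / (0.2095\,(P_{\mathrm{baro}} -
p_{\mathrm{H_2O}}))$, with the Weiss & Price (1980) vapor-pressure
formulation. The implementation reproduces the correlation's published
check value (6.315 mL L^-1^ at 10 °C, 35 psu) and is kept behind the
single function `o2_solubility()` so the correlation can be swapped. At
the respirometry conditions used throughout (24 °C, 35 psu),
$\alpha \approx 1.39$ µmol L^-1^ mmHg^-1^.

**Rate units.** The chamber equation yields µmol O~2~ kg^-1^ min^-1^;
reporting uses mg O~2~ kg^-1^ h^-1^. `mo2_unit_convert()` applies the
exact factor $60 \times 32/1000 = 1.92$ and round-trips to floating-point
precision.

## The respirometry model and its estimators

A closed respirometer obeys

$$\dot{M}\mathrm{O_2} = \frac{-\delta P_{\mathrm{O_2}} \times
\alpha_{\mathrm{O_2}} \times (V_{\mathrm{chamber}} - M_f)}{M_f},$$

with $\delta P_{\mathrm{O_2}}$ the OLS slope of the PO~2~ decline
(mmHg min^-1^), $V_{\mathrm{chamber}}$ in L and the fish mass $M_f$ in kg
(its volume displaces water, hence the effective volume $V - M_f$).

* **Per-cycle slopes** (`fit_cycle_slopes()`) are fitted over the last
  2 min of each 3-min closed phase. Cycles with regression $R^2 < 0.95$
  are flagged and excluded from downstream summaries. A constant-PO~2~
  cycle has an undefined $R^2$ (zero response variance) and carries no
  slope information; it is flagged rather than fitted.
* **Background correction** (`background_correct()`) subtracts a
  background respiration rate interpolated linearly in time between an
  empty-chamber rate measured before and one measured after the trial.
  Records driven negative are flagged, never silently dropped.
* **SMR** (`estimate_smr()`) is the mean of the lowest 10% of retained
  MO~2~ records, with the count taken as $\lceil 0.1\,n \rceil$ so at
  least one record is always used. The lowest-decile estimator is
  downward-biased by measurement noise (order 2-3% at the default noise
  level); this is a property of the estimator itself, shared with its use
  in practice, and is covered by the 5% recovery tolerance used in the
  tests.
* **Pcrit** (`estimate_pcrit()`) partitions a single closed run into
  consecutive, non-overlapping 2-min bins (matching the measurement
  cadence; bins do not slide), converts each bin's slope to MO~2~, and
  finds where MO~2~ falls below the SMR measured for the same individual
  immediately beforehand. The reported value interpolates MO~2~ linearly
  between the bracketing bins. Two policies deal with awkward cases:
  * *Noise-induced multiple crossings*: the crossing belonging to the
    longest run of consecutive below-SMR bins is used (ties resolved to
    the latest), so a single noisy bin cannot set the estimate.
  * *Plateau ties*: on clean data the last above-SMR bin sits exactly on
    the regulation plateau (MO~2~ = SMR), which makes the bracketing
    interpolation degenerate — it would return that bin's mean PO~2~,
    biased high by one to three minutes of decline. When the upstream bin
    equals SMR within numerical tolerance ($10^{-6}$ relative), the
    estimate is therefore placed at the first below-SMR bin's mean PO~2~,
    the point at which conformity is first observed; its expected error
    is zero and its worst-case error is half a bin-width.
  The conservative "first bin below" value is always reported alongside
  (`value_first_below`), and a run that never conforms is censored at the
  minimum observed PO~2~ rather than given a number.

One bin-width of PO~2~ decline — about 4.3 mmHg at the default geometry
(91 g fish, 2.5 L chamber, SMR near 151 mg kg^-1^ h^-1^) — is the
resolution limit of the binned estimator and the tolerance used for its
recovery checks.

## The synthetic trace generator

`simulate_trace()` integrates chamber PO~2~ by forward Euler at 1-s steps
(the integration error is orders of magnitude below measurement noise at
these rates, and is verified against the analytic conformer solution in
the tests). The fish model is the simplest one consistent with an
SMR-crossing breakpoint: an oxyregulator holding $\dot{M}\mathrm{O_2} =
\mathrm{SMR}$ at or above the true Pcrit, and a linear conformer through
the origin, $\dot{M}\mathrm{O_2} = \mathrm{SMR}\times
P_{\mathrm{O_2}}/P_{\mathrm{crit}}$, below it. Spontaneous activity is a
Poisson process (default 6 bursts h^-1^ of one minute at +50% SMR) whose
excursions are strictly non-negative, so the lowest-decile SMR estimator
stays asymptotically unbiased. Background respiration ramps linearly in
time between configured endpoints, mirroring the linear correction applied
downstream. Flush phases relax PO~2~ exponentially toward ambient (time
constant one quarter of the flush length); flush-phase mixing dynamics,
temperature drift and instrument artifacts are deliberately not modelled,
so passing recovery tests demonstrates estimator correctness under the
stated model, not robustness to those real-world effects. Gaussian noise
(default sd 0.2 mmHg, typical of optical probes) is added to the sampled
record only, never to the state, and every generator is bit-reproducible
under a fixed seed. An oxygen budget is attached to each trace: at zero
noise the O~2~ removed over a closed phase equals the effective-volume
PO~2~ drop to 10^-13^ relative.

## Hemoglobin-oxygen equilibria

Absorbance plateaus at each gas step are normalized between the 0% and
100% O~2~ endpoints, $S = (A - A_{0\%})/(A_{100\%} - A_{0\%})$, which
removes any gain or offset in the optical channel (the Hill fit is
invariant to affine rescaling of absorbance, and single-channel
normalization is assumed throughout). Tonometry gas conversions default to
humidified gas, $P_{\mathrm{O_2}} = \frac{\%}{100}(P_{\mathrm{baro}} -
p_{\mathrm{H_2O}})$, since the gas is equilibrated with an aqueous sample;
the dry variant exists for cross-checks. The generator writes the 0% and
100% steps as the fully deoxygenated and fully oxygenated plateaus the
normalization assumes.

The Hill fit regresses $\log_{10}(S/(1-S))$ on $\log_{10}
P_{\mathrm{O_2}}$; the slope is $n_H$ and $P_{50} =
10^{-\mathrm{intercept}/\mathrm{slope}}$. Points with saturation outside a
central window are excluded because Hill plots curve away from linearity
at the extremes; the default window is (0.2, 0.8), configurable and
logged. The study orchestrator widens it to (0.1, 0.9) because the 15-step
gas series (0, 0.05, ..., 21, 100% O~2~) leaves as few as two points
inside the default window at the P~50~ values of interest; with the wider
window four to five points remain and exact-model recovery is unchanged. A
direct monotone interpolation of $S = 0.5$ is emitted as a diagnostic, but
the Hill fit is the estimator. The Bohr coefficient $\varphi =
\Delta\log_{10}P_{50}/\Delta\mathrm{pH}$ is the OLS slope over all
(pH, P~50~) pairs — identical to the pairwise quotient for two pH values —
and all pairwise values are reported as well, since with three buffers
(pH 7, 7.4, 7.8) either convention is defensible.

## qPCR expression

Amplification efficiency comes from a dilution standard curve, $E =
10^{-1/\mathrm{slope}}$. Ct values relate to transcript amount $X$ through
$E^{\mathrm{ct}} = N_{\mathrm{thr}}/X$, which fixes both estimators:

* **Fold change** uses the efficiency-corrected (Pfaffl-style) ratio with
  each primer pair's own $E$ for target and reference separately; the
  classic $2^{-\Delta\Delta ct}$ is the $E = 2$ special case and is
  available as `method = "classic"`. The corrected form is the default
  because measured efficiencies span 77-96%, and it is the only form that
  inverts the generator exactly under per-sample loading offsets.
* **Relative abundance** within a sample is the anchored ratio
  $E_{\mathrm{anchor}}^{ct_{\mathrm{anchor}}}/E_n^{ct_n}$, which equals
  $X_n/X_{\mathrm{anchor}}$ exactly; the anchor's own value is 1 by
  construction, and a 6-cycle separation at $E = 2$ is exactly 64-fold.

Undetectable transcripts are censored (NA), excluded from summaries and
listed — never imputed as zero. Group summaries are mean ± SEM. No
multiple-testing correction is applied across subunit isoforms by default
(matching the analysis the package reproduces); `p.adjust` can be applied
to the output table where desired.

## Gill morphometrics

Hughes' method: $A = LfB$ with $L$ the total filament length, $f$ the
lamellar frequency counting both sides of the filament and $B$ the mean
bilateral lamellar area; `mass_specific_area = A / body mass`. Since only
every tenth filament is measured, $L$ is reconstructed by linear
interpolation of the length profile across all positions (constant
extrapolation at the arch ends); the plain-mean variant is reported as a
diagnostic, and the two coincide for flat profiles. $f = 2/\overline{s}$
from one-side interlamellar spacing $s$ (a constructor accepting direct
counts per mm would bypass this step). Diffusion distance averages
hierarchically — per-image means averaged across images, SEM across
images — because the image is the sampling unit (15 images of 10
measurements each); the pooled mean is also emitted.

## Group statistics

Unpaired comparisons default to Welch's t (the pooled-variance classical
form is available, since the variance assumption of the original analyses
is unstated); Pcrit pre/post uses a one-tailed paired t under the a-priori
hypothesis of a decrease. P~50~ is analysed by two-way fixed-effects ANOVA
(acclimation × pH); balanced designs use the standard orthogonal
decomposition, unbalanced designs (the P~50~ data have 4-7 per cell)
Type-II sums of squares — the standard choice when the interaction is not
of primary interest. Degenerate inputs follow explicit conventions:
zero-variance equal groups give p = 1, a constant non-zero difference
gives p = 0, both flagged. Type-I error of each test is verified at
0.05 ± 0.02 over 1000 null simulations.

## The study orchestrator and problem sizes

`run_study()` simulates and analyses the full two-treatment experiment (7
fish per treatment by default) deterministically from a single base seed,
from which every stage derives a recorded sub-seed. Desk-scale sizes keep
a full run near ten seconds: SMR traces default to 6 h per fish inside the
orchestrator (the dedicated SMR recovery check uses the protocol-length
20 h trace), Pcrit runs go from 150 mmHg down to 12.7 mmHg, and plates,
Ct tables and morphometry use the per-fish sampling designs described
above. Group-mean truths follow the reported values (SMR 151-167
mg kg^-1^ h^-1^; hypoxia-treatment Pcrit 36.2 before and 28.1 mmHg after
acclimation; gill area 348.9 and 369.9 mm^2^ g^-1^; diffusion distance
1.22 and 1.18 µm; Hbα-3.2 at 12% relative abundance with up-regulation of
Hbα-2, Hbα-3.2 and Hbβ-3.1 under hypoxia). Where the emulated study
reports no number, defaults are ordinary values for a sub-adult sciaenid:
P~50~ near 20 mmHg with a 3 mmHg acclimation drop, $n_H$ 1.8, Bohr
coefficient −0.45, 6% between-individual CV, 10% measurement CV on
morphometrics.

## Known limitations

* The conformer limb is linear through the origin by construction; real
  fish may conform non-linearly, and the SMR-crossing estimator inherits
  any such misspecification.
* The Pcrit estimator's resolution is one 2-min bin of PO~2~ decline;
  faster declines (smaller chambers, larger fish) coarsen it
  proportionally.
* Hemolysate curves are single-channel and assume complete saturation at
  100% O~2~; methemoglobin formation, Root effects and NTP modulation are
  out of scope.
* The activity-burst model is a stand-in chosen for its estimator
  properties, not an inference about real fish behaviour.
* Synthetic recovery demonstrates correctness of the estimators under the
  stated generating models, not performance on instrument data with
  artifacts those models exclude.
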