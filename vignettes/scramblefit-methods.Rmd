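---
title: "Models and methods behind scramblefit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind scramblefit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scramblefit)
```

scramblefit packages the quantitative machinery used to decide whether a
membrane protein reconstitutes into lipid vesicles — and scrambles
phospholipids — as a monomer or an oligomer. Four analysis stages are
implemented, each behind its own small set of functions, together with
synthetic-data generators so that every stage can be exercised end to end
with known ground truth. This vignette explains the models, the defaults
and the numerical choices; it states no empirical result that the test
suite and the acceptance script do not themselves compute.

## 1. Dithionite quench kinetics

In the scramblase activity assay, vesicles carry a trace of NBD-labelled
phosphatidylcholine in both leaflets. Dithionite, added at $t = 0$ and
unable to cross the membrane, destroys the fluorophore in the outer
leaflet only — unless a scramblase moves inner-leaflet lipid outward. The
normalized fluorescence follows

$$F(t) = (1 - P)\,e^{-Kt} + P - S\,t,$$

an exponential decay at the dithionite reduction rate $K$ towards a
protected plateau $P$, with a small linear term $S$ absorbing slow
photobleaching or leak. `fit_trace()` estimates $(P, K, S)$ by
Levenberg–Marquardt least squares (`minpack.lm`), with deterministic
starting values: $P$ from the mean of the last decile of samples, $K$
from a log-linear fit of the early decay, $S = 0$. The reported half-life
is $0.69/K$ — we keep the conventional rounded constant rather than
$\ln 2$ so half-lives are bit-comparable with published parameter tables.
The end-point reduction fed to the occupancy analysis is the *fitted*
$100(1 - P)$, not the last raw sample: only the plateau varies with
protein load, and the fitted value is insensitive to the drift term.
Traces should cover several half-lives (the assay convention is
$> 300$ s); when the rate is so poorly determined that its standard error
exceeds the estimate, the fit warns.

## 2. Poisson vesicle occupancy and the molar mass of the functional unit

The end point of each trace is rescaled between the protein-free baseline
$F_o$ (typically about 45%) and the saturating value $F_{max}$ (82.5%):

$$p(\geq 1\,\text{scramblase}) = \frac{F - F_o}{F_{max} - F_o},$$

interpreted as the probability that a reconstitutable vesicle carries at
least one functional scramblase. Because roughly 35% of vesicles are
refractory to reconstitution, the measured protein/phospholipid ratio
(PPR, mg/mmol $\equiv$ g/mol) is concentrated into the remaining
fraction: $x = \text{PPR}^\ast = \text{PPR}/0.65$.

A vesicle of radius $r$ (nm) has $8 r^2 / \varepsilon^2$ phospholipids
(two leaflets of area $4\pi r^2$, one lipid per $\pi\varepsilon^2$ with
$\varepsilon = 0.472$ nm), so at protein:lipid molar ratio $x/M$ the
scramblase count is Poisson with mean $\mu(r) = \alpha x r^2/2$, where
$\alpha = 16/(M\varepsilon^2)$ and $M$ is the molar mass of the
functional unit. Averaging $1 - e^{-\mu(r)}$ over a Gaussian vesicle
ensemble $r \sim N(\bar r, \sigma)$ gives the closed form

$$p(\geq 1) = 1 - \frac{1}{\sqrt{1 + \alpha x \sigma^2}}
  \exp\!\left(-\frac{\alpha x \bar r^2 / 2}{1 + \alpha x \sigma^2}\right).$$

With the default ensemble ($\bar r = 88$ nm, $\sigma = 28$ nm) the two
coefficients multiplying $\alpha x$ are exactly $\sigma^2 = 784$ and
$\bar r^2/2 = 3872$ nm². The Gaussian integral runs over the whole real
line; the simulator instead truncates radii at zero and resamples. At
$\bar r / \sigma \approx 3.14$ the truncated mass is
$\Phi(-3.14) \approx 8\times10^{-4}$, so closed form and ensemble differ
by less than $10^{-3}$ in $p$; every test comparing the two uses a
tolerance of three binomial standard errors plus this $10^{-3}$ budget.

`fit_alpha()` estimates $\alpha$ by unweighted Levenberg–Marquardt least
squares, takes its standard error from the Jacobian at the optimum,
propagates it to the mass first order ($SE_M/M = SE_\alpha/\alpha$) and
draws the 95% confidence band by evaluating the (monotone-in-$\alpha$)
curve at $\alpha \pm t_{0.975,\,n-1}\,SE_\alpha$. The published analyses
report a fit SE and a 95% band without naming a method; this is the
plainest construction consistent with both. Probabilities are clamped to
$[0,1]$ before fitting, and end points below $F_o$ are kept as $p = 0$
with a warning — measurement noise near baseline should not abort a
series. Note that clamping saturated points makes the reported
$SE_\alpha$ mildly optimistic (in simulation, the empirical spread of
$\hat\alpha$ is $\sim$20% larger than the nominal SE).

`oligomer_order()` divides the fitted mass by the monomer mass (41,700
g/mol for opsin), rounds to the nearest integer $\geq 1$, and flags the
result as a lower bound (`">=n"`) when the ratio exceeds that integer by
more than 0.05 — the margin that renders a mass "slightly heavier than a
dimer" as at-least-2 while an exact dimer stays 2.

### Simulated assay design

`simulate_assay_series()` generates end points over a PPR grid either by
explicit vesicle sampling (`method = "ensemble"`) or from the closed form.
For recovery studies we use 12 points spanning PPR 0–3 g/mol placed
densely around PPR $\approx 0.1$, because the sensitivity
$\partial p/\partial \alpha$ at the monomer-scale $\alpha$ peaks near
PPR 0.08 (where $p \approx 0.57$) and vanishes in the saturated tail;
this placement roughly halves the relative SE of $\hat\alpha$ compared
with equal spacing. Default end-point noise is 1 percentage point on
$F$; recovery tests that perturb $p$ directly use SD 0.03.

## 3. Photobleaching step counting

Single complexes captured on a passivated surface are imaged by TIRF at
20 Hz until their fluorophores bleach; the number of discrete intensity
drops reports the number of labelled protomers. Published analyses
classified traces by eye into 1–5 steps or "uncountable"; `detect_steps()`
automates this with binary change-point segmentation on a
piecewise-constant + Gaussian-noise model: recursively split at the
minimum-SSE change point, accept a split only when both segments last at
least 5 frames and the level change exceeds 3 estimated noise SDs (noise
estimated robustly from successive differences), then merge adjacent
levels closer than that threshold. A trace is *uncountable* when it
re-brightens by more than half a step, when residual noise exceeds a
third of a step, when it never steps down at all, or when it ends still
holding more than half a fluorophore's intensity (incomplete bleaching).
These mirror the situations a manual classifier discards, and accuracy
statements in the tests are therefore made over countable spots.

Counting divides the *total* bleached intensity by a unit step size —
the median detected drop across the movie (`count_spot_steps()`) —
rather than counting change points: two fluorophores bleaching within
the minimum dwell of each other produce one double-height drop, which
division correctly counts as two steps.

The observed fractions are compared against
`expected_step_distribution()`: each of the $n$ protomers carries a label
independently with probability $q$ (SNAP-tag labelling is expected to be
$> 0.8$; default 0.8), a spot is visible only when at least one label is
present, and with probability $c$ a second, independently labelled
complex shares the diffraction-limited spot. Coincidence is capped at one
extra complex because experimental spot densities are chosen to keep
higher-order coincidence negligible; $c$'s default of 0.08 is a
calibration choice consistent with the published few-percent two-step
background on monomeric controls, not a measured value.
`infer_oligomer()` picks the $n \in \{1..4\}$ minimizing the squared
distance between observed and expected fractions and flags near-ties or
flat distributions as inconclusive.

The generator (`simulate_spot_traces()`) draws the labelled count from
the conditioned binomial, bleach times i.i.d. exponential with mean
10 s — putting ~95% of single-fluorophore bleach events inside the first
30 s, as observed in such fields — over a 60 s movie, at step:noise
ratio 8. It does not emulate blinking, antibody bivalency, stage drift
or spatial effects (spot detection is outside the package boundary), so
passing tests demonstrate the counting and inference machinery, not
robustness to those artefacts.

## 4. Residual hydrophobic mismatch (RHM)

A transmembrane helix pays a free-energy penalty for hydrophobic surface
exposed outside the bilayer's acyl-chain core and for polar surface
buried inside it, when the membrane cannot deform to cover the mismatch.
Per residue, the penalized area is

- hydrophobic residues: $SA_{res} = SA_{mem}$, the accessible area
  outside the hydrophobic core;
- polar residues: $SA_{res} = SA_{prot} - SA_{mem}$, the accessible area
  inside the core;

and the helix energy is $\sum_i \sigma_{res} SA_{res,i}$ with
$\sigma_{res} = 0.0028$ kcal/(mol·Å²). Three classes of residues are
exempt: Ser/Thr always (their polar groups hydrogen-bond to the helix
backbone), interfacial Trp, and Arg/Lys near the headgroups (snorkeling);
"near" means the side-chain reference position (Cβ, falling back to Cα)
lies within `headgroup_margin` (default 3 Å — the literature does not
quantify "interfacial", so the margin is configurable) of a slab
boundary. Whether Gly and Pro count as hydrophobic is likewise not
settled; the default hydrophobic set {Ala, Val, Leu, Ile, Phe, Met, Pro,
Gly, Cys} is overridable.

The reference treatment computes $SA_{mem}$ with the lipid bilayer
included in the solute, using bilayer surfaces extracted from molecular
dynamics ensembles. This package deliberately replaces that with a planar
slab normal to $z$ (default a 30 Å core): `compute_sasa()` runs a
Shrake–Rupley-style calculation (probe 1.4 Å, NACCESS-compatible
element radii, a deterministic Fibonacci point set, 960 points per atom
by default) and *retains the accessible surface points*, so the
partition of each residue's area into inside-slab and outside-slab is a
point classification by $z$. This makes the decomposition exactly
additive (inside + outside = protein-only SASA) and converges to better
than 2% between 960 and 4000 points on helix-scale systems. Absolute
energies from a crystal structure in a slab are therefore *not*
comparable to values computed against MD bilayer ensembles — the package
does not attempt to reproduce those — but differences, rankings and the
statistical machinery are. For exact reproduction of an external
workflow, `exposure_from_rsa()` accepts a precomputed per-residue
$SA_{mem}/SA_{prot}$ table and applies only the penalty and exemption
rules.

Replicate uncertainty follows the published protocol exactly:
`bootstrap_sd()` averages three of the $\geq 4$ replicate energies drawn
without replacement, repeats four times, and reports the SD of the four
means. Construct comparisons use the classic pooled-variance unpaired
t-test per helix (`compare_constructs()`); with both groups constant and
equal the p-value is 1 by convention.

## 5. Numerical and interface conventions

- All stochastic functions take a mandatory `seed` and restore the
  caller's RNG state; identical seed and configuration reproduce output
  bit for bit.
- CSV is comma-separated with a mandatory header; percentages are 0–100,
  probabilities 0–1; reports are JSON written without rounding.
- Degenerate inputs fail loudly: all-zero occupancy series, fewer than
  three distinct protein loads, empty helices, fewer than four bootstrap
  replicates, traces that never bleach.
- Test problem sizes were chosen to keep the whole suite under about a
  minute while leaving Monte-Carlo tolerances meaningful: $10^6$ vesicles
  for closed-form-versus-ensemble checks, $10^5$ vesicles per point for
  mass-recovery series, 500-spot fields with 50 replicates for the
  monomer/dimer discrimination study, and helix-scale structures (10–20
  residues) for SASA oracles.

## 6. Known limitations

- The occupancy model assumes unilamellar vesicles, ideal mixing of
  protein over reconstitutable vesicles and activity independent of
  protein orientation; lamellarity and orientation effects are out of
  scope.
- The trace model's linear term is phenomenological; dithionite
  permeation controls are experimental and not modelled.
- Step counting assumes equal-brightness, independently bleaching
  fluorophores; blinking-induced re-brightening is classified
  uncountable rather than modelled.
- The slab RHM ignores membrane deformation entirely — it quantifies the
  *residual* mismatch only, and only against an idealized planar core.
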