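# scramblefit

Quantitative analysis of phospholipid scramblase reconstitution assays —
for membrane-protein groups asking a deceptively simple question: **what
is the oligomeric state of the functional unit?**

Opsin-class GPCRs scramble phospholipids when reconstituted into
vesicles. Whether a monomer suffices cannot be read from a gel; it is
inferred statistically. scramblefit implements the full inference chain:

1. **Quench kinetics** (`fit_trace`). Dithionite destroys outer-leaflet
   NBD-lipid fluorescence; traces follow
   `F(t) = (1 − P)·exp(−K·t) + P − S·t`. The fitted plateau gives the
   end-point reduction; the half-life `0.69/K` checks that chemistry,
   not scrambling, is rate limiting.
2. **Poisson vesicle occupancy** (`fit_alpha`). End points are rescaled
   to `p(≥1 scramblase) = (F − F_o)/(F_max − F_o)` and fit against the
   effective protein load `x = PPR/0.65` with the closed form

   ```
   p(≥1) = 1 − (1 + αxσ²)^(−1/2) · exp(−αx·r̄²/2 / (1 + αxσ²))
   ```

   for a Gaussian vesicle ensemble (r̄ = 88 nm, σ = 28 nm: coefficients
   784 and 3872). The fit constant converts to the molar mass of the
   functional unit via `M = 16/(α·ε²)` (ε = 0.472 nm), and
   `oligomer_order()` turns masses into "1", "2", "≥2", ...
3. **Single-molecule subunit counting** (`detect_steps`,
   `infer_oligomer`). Automated change-point counting of photobleaching
   steps in TIRF spot traces, compared against a conditioned-binomial
   labelling model with a coincidence term.
4. **Residual hydrophobic mismatch** (`rhm_profile`). Sphere-sampling
   SASA with surface points partitioned by a membrane slab; per-helix
   energies `Σ σ_res·SA_res` (σ_res = 0.0028 kcal/(mol·Å²)) with the
   Ser/Thr, interfacial-Trp and Arg/Lys exemptions, replicate bootstrap
   and unpaired t-tests between constructs.

Synthetic generators (`simulate_assay_series`, `simulate_dithionite_trace`,
`simulate_spot_traces`, `toy_helix_structure`) produce every input with
known ground truth, so the whole pipeline runs without external data.

## Worked example

Simulate an assay series at a monomer-mass scramblase (38,000 g/mol) and
recover the mass and order:

```r
library(scramblefit)
pop <- vesicle_population()   # r̄ 88 nm, σ 28 nm, 35% refractory, ε 0.472
ppr <- c(0, 0.03, 0.05, 0.08, 0.1, 0.13, 0.17, 0.22, 0.3, 0.5, 1, 3)
ser <- simulate_assay_series(ppr, molar_mass = 38000, population = pop,
                             n_vesicles = 1e5, seed = 42)
fit_alpha(ser, pop)
#> Occupancy fit (Poisson vesicle-occupancy model)
#>   n points: 12
#>   alpha: 0.001968 +/- 5.3e-05 mol g^-1 nm^-2
#>   molar mass: 36,502 +/- 986 g/mol (epsilon = 0.472 nm)
#>   oligomer order: 1
```

The recovered mass (36,502 ± 986 g/mol) agrees with the generating
38,000 g/mol to ~4%, and the order call is "1": a monomer. A quench
trace and a 500-spot bleaching field round-trip the same way:

```r
fit_trace(simulate_dithionite_trace(82.5, seed = 42))
#>   plateau P: 0.1751 +/- 0.0011
#>   rate K: 0.03052 +/- 0.00009 s^-1 (half-life 22.61 +/- 0.06 s)
#>   slope S: 0.000141 +/- 4.92e-06 s^-1
#>   end-point reduction: 82.5%  (n = 601, residual SD 0.0049)

fld <- simulate_spot_traces(500, n_mer = 1, seed = 42)
dist <- step_distribution(list(count_spot_steps(fld$traces)))
dist$fractions[1:2]            # 1-step 0.926, 2-step 0.062
infer_oligomer(dist)$n_mer     # 1
```

A ~93% one-step fraction with a few-percent two-step background is the
signature of a monomeric protein under ~80% labelling with occasional
spot coincidence.

File-level wrappers (`fit_occupancy_csv`, `fit_traces_dir`,
`count_steps_csv`, `rhm_report`) read the CSV/PDB formats described in
their help pages; `inst/cli/scramblefit.R` exposes them as a small
command line. See `vignettes/scramblefit-methods.Rmd` for the models,
defaults and limitations.

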