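# granulizer

Quantitative analysis of small-molecule stress-granule modulator studies.

Stress granules are cytoplasmic condensates of RNA-binding proteins and
mRNA that form by liquid–liquid phase separation under cell stress; their
aberrant solidification is linked to neurodegenerative disease, which makes
compounds that modulate granule condensation attractive probes and leads.
Characterizing such a compound end to end requires a chain of quantitative
machinery that is usually scattered across ad hoc scripts. `granulizer`
packages that chain as tested, reusable R functions:

- **Thermal proteome profiling (TPP) stability scoring** — from
  protein × temperature × condition soluble-fraction intensity tables to
  per-protein abundance and thermal-stability scores, z-values, robust
  empirical-null significance with FDR control, and
  stabilized/destabilized/unaffected calls.
- **NMR uptake and condensate partitioning** — closed-form
  mass-conservation models turning amide-proton signal intensities and
  pellet geometry into fractional uptake, intracellular concentration, a
  membrane-binding bound, condensate partition coefficients and phase
  concentrations.
- **Image quantification** — nuclei segmentation, cytoplasmic granule
  detection (unsharp enhancement, nuclei masking), granules per cell,
  nuclear partition, percent cells with ≥ k granules, and compartment
  partition coefficients.
- **High-content screen scoring** — per-plate control-referenced z-scores
  combined into a shrinkage-regularized Mahalanobis distance for hit
  ranking, linear time-drift normalization, monotone dose checks, and
  four-parameter logistic EC50 fitting.
- **Consensus IDR calling** — intrinsically disordered regions from
  multi-predictor per-residue tracks (strict >75 % agreement, runs of
  >10 residues), class-wise IDR-proportion comparisons, and amino-acid
  composition enrichment against a background.
- **Synthetic data** — seeded generators emulating every input so the
  entire pipeline runs and is testable without any external download.

## The models in brief

**TPP scores.** With FC_T the treatment/control intensity ratio at
temperature T,

    abundance score  = (log2 FC_37.0 + log2 FC_40.4) / 2
    stability score  = Σ_T (log2 FC_T − abundance score)

both z-transformed across proteins; significance comes from a robust
(median/MAD) empirical null with precision weights proportional to the
number of quantified temperatures, followed by Benjamini–Hochberg FDR.
Proteins with |z| > 1.5 and FDR < 0.05 are called
stabilized/destabilized.

**NMR mass conservation.** Fractional uptake U = 1 − S₊cells/S₋cells;
C_out = (1−U)·c_add·V_add/V_out; C_cell = U·c_add·V_add/(V₁·N_cell);
membrane bound R = A_L·N_A·U·c_add·V_add/(A₁·N_cell). The condensate
pellet volume is the spherical cap V = π/3·r³(2+cos θ)(1−cos θ)² with
θ = asin(a/r), the partition coefficient
PC = (V_cond + V_added)/(SF·V_cond), and the phase concentrations follow
from [L]_cond = L_tot·V_tot/(V_cond + (V_tot−V_cond)/PC),
[L]_dil = [L]_cond/PC.

**Screen scoring.** Per feature and plate, z = (x − μ)/σ against the DMSO
control wells; a well's z-vector is combined into
D = √(zᵀS⁻¹z) with S the control covariance (Ledoit–Wolf-style shrinkage
toward the diagonal). Dose–response series are fitted with the
four-parameter logistic y = bottom + (top − bottom)/(1 + (x/EC₅₀)^slope)
on the log-concentration axis.

## Worked example

```r
library(granulizer)

# a synthetic TPP experiment: 1,000 proteins on the 10-temperature grid,
# 50 of them thermally stabilized by +2 °C, 5 % multiplicative noise
sim <- gen_tpp(n_proteins = 1000, n_stabilized = 50, delta_tm = 2,
               noise_cv = 0.05, seed = 42)
fit <- tpp_stability(sim$curves, treatment = "treated")
fit
#> TPP stability analysis: treated vs DMSO
#>   1000 proteins, 1000 scored (min_points = 10)
#>   stabilized: 42  destabilized: 0  unaffected: 958
#>   cutoffs: |z| > 1.5, FDR < 0.05 (BH)
```

42 of the 50 planted +2 °C shifts pass the |z| > 1.5, FDR < 0.05 double
cutoff and nothing is called in the wrong direction — the score separates
a 2 °C melting shift from 5 % noise but the cutoff keeps a few borderline
proteins out, as intended.

```r
# NMR uptake: signal drops from 1.0 to 0.65 when cells are present
up <- nmr_uptake_report(s_plus = 0.65, s_minus = 1.0, c_add = 100e-6,
                        v_add = 600e-6, n_cell = 1e6)
sprintf("U = %.2f, C_cell = %.2f mM, R = %.2f molecules/lipid",
        up$u, 1e3 * up$c_cell, up$lipid_ratio)
#> "U = 0.35, C_cell = 5.01 mM, R = 5.03 molecules/lipid"
```

35 % uptake of 100 µM compound into 10⁶ cells implies a millimolar
intracellular concentration; R ≈ 5 compound molecules per plasma-membrane
lipid rules out the lost signal being mere membrane absorption. (Here R
uses the exact sphere area 4πr²; with the area rounded to 1.3 × 10⁻⁹ m²
the ratio is 4.9.)

```r
# EC50 from a noisy synthetic dose-response (truth: 2 µM, slope 1.5)
dr <- gen_dose_response(ec50 = 2e-6, slope = 1.5, noise_cv = 0.1, seed = 42)
fit_dose_response(dr$curves$concentration, dr$curves$response)
#> Four-parameter logistic dose-response fit
#>   EC50: 2.053e-06   slope: 1.34
#>   top (low dose): 2.901   bottom (high dose): 0.08437
#>   RSS: 0.4376 over 12 points
```

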