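# pdcsim

Quantitative machinery for single-cell studies of interferon-α (IFNα)
production by plasmacytoid dendritic cells (pDCs) stimulated individually
inside picoliter droplets.

Only a small, stochastically determined subset of pDCs secretes IFNα when
each cell is isolated in its own droplet microenvironment, even under
saturating TLR9/TLR7 stimulation — while essentially all cells switch on the
NF-κB branch (TNFα, CCR7, CD40, CD86) in a dose-graded way. The population-wide
IFNα response of bulk cultures emerges from paracrine type-I-IFN
amplification: rare early responders prime their neighbours and raise their
probability of producing IFNα. `pdcsim` implements the models and count
formulas needed to analyse and simulate such experiments:

- **Droplet occupancy** (Poisson loading): with mean occupancy
  λ = c·d·V, the occupancy pmf is P(K = k) = e^{−λ} λ^k / k!, the occupied
  fraction is 1 − e^{−λ}, and the single-cell purity is
  λ e^{−λ}/(1 − e^{−λ}). Calibration from a measured occupied fraction is
  λ = −ln(1 − f).
- **Stochastic activation model**: pDC₀ → pDC₁ (IFNα-secreting) → pDC₂
  (refractory) → Φ (death), with a constant constitutive hazard a₀
  multiplied ×20 by TLR triggering (digital in dose) and ×π by type-I-IFN
  priming. P(IFNα⁺ by T) = 1 − e^{−aT}; the hazard ratio is recovered from
  two arms as ln(1 − f₁)/ln(1 − f₂). Droplet-confined priming
  (`simulate_droplet_cohort`) and well-mixed bulk priming (`simulate_bulk`)
  are both available.
- **Co-encapsulation model comparison**: model A (random-pair interaction)
  regresses the % IFNα⁺ cells on the % of cells in multi-cell droplets,
  x = 200p/(100 + p); model B (early responder) fits
  y = e·(1 + p/100) with a single early-responder fraction e. Models are
  compared by the mean test RMSE over 100 random 75/25 train/test splits
  (`compare_models`).
- **UMI count processing** (SORT-Seq/CEL-Seq2): a 6-bp barcode gives
  4096 UMIs; collision correction m = −K ln(1 − k/K); cells below 1700
  transcripts are dropped and the rest down-sampled (without replacement)
  to exactly 1700.
- **Synthetic data generators** for all of the above, seeded and pure, so
  the complete pipeline is testable without any external data.

## Worked example

```r
library(pdcsim)

# loading 2.6e6 cells/mL, halved by on-chip co-flow, into 92 pL droplets
design <- droplet_design(2.6e6, 92, dilution_factor = 0.5)
mean_occupancy(design)
#> 0.1196  cells per droplet predicted from the nominal concentration

# the measured occupancy is lower (~6% occupied droplets); calibrate:
lam <- calibrate_lambda(0.06)
100 * single_cell_purity(lam)
#> 96.94   — at 6% occupancy, ~97% of cell-containing droplets are singlets

# co-encapsulation series (24 points) under an early-responder truth
ds  <- generate_coencap_series(generator_config(seed = 1))
fit <- coencap_fit(ds, "early_responder")
coef(fit)
#> early_responder_fraction
#>                  1.56315   — % of early-responding cells (truth: 1.5)

compare_models(ds, seed = 1)
#> Repeated train/test comparison of co-encapsulation models
#>   100 repeats, 18/6 train/test records
#>   mean RMSE, model A (random pair):     0.2777%
#>   mean RMSE, model B (early responder): 0.2618%
#>   preferred model: early responder (B)

# recover the TLR fold increase from two simulated arms of 1e5 cells
params <- activation_params()                        # fold_tlr = 20
f_un  <- mean(simulate_single_cells(params, stimulus_condition("IL3"),
                                    1e5, seed = 1)$ifn_pos)
f_tlr <- mean(simulate_single_cells(params, stimulus_condition("TLR", 50),
                                    1e5, seed = 2)$ifn_pos)
fit_fold_change(f_un, f_tlr)
#> 21.14   — hazard-ratio estimate of the 20-fold TLR rate increase
```

The mean RMSE numbers say that on data generated under the early-responder
truth, the one-parameter early-responder model predicts held-out points
better than the two-parameter random-pair regression — the model-selection
logic of the co-encapsulation experiment.

`run_reproduction(seed = 1, out_dir = "report")` runs the whole synthetic
pipeline (occupancy goodness of fit, dose-flatness of the IFN branch,
model comparison, fold recovery, UMI round trip) and writes a JSON + text
report stamped with the package version, seed and configuration hash.

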