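# aafscreen

Drug-sensitivity and combination-synergy analysis for viability screens of
ovarian cancer cell lines cultured with patient-derived acellular ascites
fluid (AAF).

Malignant ascites reprograms epithelial ovarian cancer cells toward
chemoresistance. Screens that quantify this expose each (cell line x
medium) *condition* — plain culture media or media conditioned with an
individual patient's cell-free ascites — to titrations of standard-of-care
drugs (carboplatin, paclitaxel) and repurposed compounds, alone and in
anchored combinations, and ask which treatment works best per condition.
`aafscreen` implements that analysis end to end for anyone working with
384-well luminescence viability screens and phospho-flow marker tables:

* **Plate QC and normalization** — Z′ = 1 − 3(σ₊ + σ₋)/|μ₊ − μ₋| per
  plate; percent viability from negative/positive controls or from DMSO
  vehicle gradients.
* **Dose-response fitting** — the four-parameter log-logistic model
  V(x) = c + (d − c)/(1 + exp{b(ln x − ln e)}) with the lower asymptote
  fixed at 0 by default, studentized-residual outlier removal, closed-form
  ICp inversion.
* **DSS** — drug sensitivity score: the normalized area of fitted
  inhibition above a 10% activity threshold over the tested log10-dose
  window, computed from the closed-form antiderivative (variants 1-3 of
  the DSS family).
* **Combination scoring** — Combination Ratio
  CR = (DSS₊₁₀₀ combo)/(DSS₊₁₀₀ mono), ZIP synergy deltas versus the
  Bliss zero-interaction surface with directional logistic refits, 100−VUS
  trapezoid surface scores, 95th-percentile synergy calls, CR < 0.75
  non-improvement flags, and deterministic best-treatment ranking.
* **Downstream statistics** — two-way ANOVA (type II) with Tukey HSD on
  DSS tables, Holm-corrected Pearson correlation matrices, Ward-D2
  hierarchical clustering with Newick export, IgG-normalized phospho-marker
  fold changes with (paired) t tests.
* **Synthetic-screen generator** — a first-class module that emulates the
  full study design (5 cell lines x media + 5 AAFs = 30 conditions, 11
  drugs, 3 technical x 2 biological replicates, log-normal plate noise,
  per-plate gain, condition-specific resistance shifts, injectable Bliss
  interaction) with exact ground truth, so every scoring stage is testable
  without patient data.

See `vignettes/aafscreen-methods.Rmd` for the models, conventions and
design decisions.

## Worked example

```r
library(aafscreen)

cfg   <- screen_config(seed = 42)                    # the full study design
truth <- set_condition_resistance(truth_set(cfg), "A19",
                                  resistance_shift = 10, efficacy_loss = 50)
wells <- generate_screen(cfg, truth)                 # 60 plates, 18,720 wells

head(plate_qc(wells)[c("plate_id", "z_prime", "pass_flag")], 3)
#>           plate_id   z_prime pass_flag
#>   P_SKOV3_media_b1 0.8257987      TRUE
#>  P_OVCAR3_media_b1 0.8183383      TRUE
#>  P_OVCAR5_media_b1 0.9020455      TRUE

res <- screen_dss(wells)       # normalize, fit LL4, score DSS per condition
res[res$cell_line == "SKOV3" & res$drug == "paclitaxel",
    c("condition", "e", "ic50", "dss")]
#>  condition            e         ic50       dss
#>         A1 9.922970e-05 1.093602e-04 18.879830
#>        A16 1.272352e-04 1.664241e-04 16.334361
#>        A18 3.319895e-04 3.366775e-04 12.615379
#>        A19 5.080768e-03 5.209456e-03  3.097105
#>         A9 1.715742e-04 1.763925e-04 16.241012
#>      media 7.625416e-05 7.756293e-05 21.266630

round(dss_wide(res)[grep("SKOV3", rownames(dss_wide(res))),
                    c("carboplatin", "paclitaxel")], 1)
#>             carboplatin paclitaxel
#> SKOV3.A1           18.7       18.9
#> SKOV3.A16          15.2       16.3
#> SKOV3.A18          11.4       12.6
#> SKOV3.A19           2.5        3.1
#> SKOV3.A9           14.0       16.2
#> SKOV3.media        20.0       21.3

combination_ratio(35.2, 21.7)$cr   # combo DSS 35.2 vs carboplatin mono 21.7
#> [1] 1.111
```

Every AAF lowers the DSS relative to media, and the engineered
fully-resistant ascites A19 (10x potency shift, 50-point efficacy loss)
collapses sensitivity across both standard-of-care drugs — midpoints shift
right by an order of magnitude and the DSS drops from ~21 to ~3. A CR of
1.11 says the combination improves on carboplatin monotherapy in that
condition; values below 0.75 would flag a non-improvement.

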