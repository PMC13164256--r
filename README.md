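# anodpore

Process–structure–property modelling for nanoporous anodic alumina (NAA)
drug-releasing implant coatings, in R.

NAA is made by electrochemically anodizing aluminium in an acidic
electrolyte, which self-organises a hexagonal array of cylindrical
nanopores. The pore diameter — the main knob controlling how fast a drug
loaded into the pores is released — depends on the anodization recipe:
electrolyte (sulphuric, oxalic or phosphoric acid), voltage, bath
temperature and time. Choosing a recipe for a target release profile is
traditionally trial and error. `anodpore` implements a computational
pipeline that closes the loop:

1. **Process → structure.** Two surrogate regressions of pore diameter on
   the anodization parameters: ordinary least squares (MLR) and a
   feed-forward neural network (64-32-16 rectifier units, Adam optimizer,
   early stopping), compared by k-fold cross-validation and ranked by
   weight/coefficient-based feature importance.
2. **Structure → release.** A Renkin-corrected Higuchi model. Cumulative
   release follows the square-root law *Q(t) = K·√t* (Q in %, t in h).
   The effective diffusivity in a pore of diameter *d* is
   *D_eff = D_bulk·(1−λ)²(1 − 2.104λ + 2.09λ³ − 0.95λ⁵)* with
   *λ = r_molecule/r_pore*, and the release constant, characteristic times
   *t50 = (50/K)²*, *t90 = (90/K)²*, loading capacity and hexagonal-array
   porosity *ε = (π/2√3)(d_p/D_int)²* follow from the pore geometry.
3. **Synthetic data.** Public compilations of anodization experiments are
   scarce, so the package ships a seeded generator that emulates their
   statistical structure (electrolyte-specific diameter baselines and
   voltage slopes, −0.4 nm/°C temperature sensitivity, pore/interpore ratio
   0.35, case-wise missingness in temperature/time), making every stage of
   the pipeline testable end to end.

## Worked example

```r
library(anodpore)

# a synthetic 99-record compilation with realistic missingness
cfg <- generator_config(n_records = 99, seed = 42)
ds  <- inject_missingness(generate_dataset(cfg))
rec <- complete_cases(ds$records)
#> complete_cases: kept 75 of 99 records

fm  <- encode_features(rec)            # one-hot + standardized, 6 columns
mlr <- fit_mlr(fm)
evaluate_predictions(fm$y, predict(mlr, fm))
#> n = 75  R2 = 0.9141  RMSE = 12.35 nm  MAE = 9.21 nm

kfold_cv(rec, "mlr", seed = 123)
#> 5-fold CV, MLR: R2 per fold 0.9087 0.9200 0.7095 0.8890 0.9486; mean 0.8752, SD 0.0850

mlr_importance(mlr)
#> Feature importance (absolute standardized coefficient, MLR)
#>           feature importance_pct rank
#>         voltage_V          39.13    2
#>     temperature_C           3.08    3
#>          time_min           1.46    4
#>  electrolyte_type          56.33    1

voltage_response(mlr, "H2C2O4")        # oxalic acid, 10 °C, 60 min
#> Sweep of voltage_V over [ 20 , 150 ]: 27 points; mean slope 1.2924 nm per unit
```

The surrogate recovers the generator's oxalic-acid voltage slope
(1.29 nm/V, the classical empirical proportionality) and the dominance of
voltage + electrolyte chemistry over temperature and time.

Release kinetics for the five reference pore configurations:

```r
release_table()
#>   pore_diameter_nm k_per_sqrt_h t50_h t90_h initial_rate_pct_h
#> 1               30         0.68  54.1 175.2                6.8
#> 2               50         0.80  39.1 126.6                8.0
#> 3               75         0.95  27.7  89.8                9.5
#> 4              100         1.10  20.7  66.9               11.0
#> 5              150         1.40  12.8  41.3               14.0
```

Reading across the table: widening pores from 50 to 100 nm nearly doubles
the first-hour release (8 → 11 %) and halves the time to 50 % release
(39.1 → 20.7 h) — small pores for sustained delivery, large pores for a
fast therapeutic onset. `run_pipeline(pipeline_config())` executes the
whole chain (generate → preprocess → fit both surrogates → CV →
importance → sweeps → release table) and returns all tables as one
reproducible bundle.

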