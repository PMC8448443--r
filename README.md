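# glipnet

Temporal lipidome–growth network analysis for longitudinal infant cohorts.

## The problem

In cohorts from low-income settings, infant growth falters over the first
two years: weight-for-age (WAZ), length-for-age (LAZ) and weight-for-length
(WLZ) z-scores decline, and a substantial fraction of children end up
stunted (LAZ < −2), wasted (WLZ < −2) or underweight (WAZ < −2). Plasma
lipids — the fuel and building material for early growth — are measured
repeatedly alongside anthropometry, and the scientific question is not just
whether lipids *correlate* with growth but whether current lipid levels
*predict future* growth (and vice versa): a Granger-type, directed, temporal
association.

`glipnet` implements the full analysis chain for such data:

1. **Feature QC** (`apply_qc_filters`) — four conjunctive filters on raw
   lipid features: mean mass deviation > 5 ppm, mean study/blank intensity
   ratio < 5, zeros in > 10 % of study samples, dilution-series Pearson
   r < 0.9.
2. **Signed weighted correlation network** (`signed_adjacency`,
   `topological_overlap`, `detect_modules`, `module_eigenlipids`) — the
   adjacency a_ij = ((1 + s_ij)/2)^β with β = 18, topological-overlap
   dissimilarity, average-linkage module detection (minimum module size 10),
   and one *eigenlipid* ME_q per module: the leading left singular vector of
   the module's standardized intensities, the module's representative time
   course.
3. **Fixed-effects panel models** (`within_fe_fit`, `trend_screen`,
   `bh_fdr`, `consecutive_paired_ttests`) — within-child (fixed-effects)
   regressions Y_it = α_i + β T_t + (ME_q,it) + ε_it with cluster-robust
   standard errors, Benjamini–Hochberg screening of per-lipid time trends,
   and paired t-tests between consecutive visits.
4. **Latent-class growth trajectories** (`fit_latent_class_mixed`,
   `select_num_classes`) — a K-class mixture of linear mixed models over a
   natural cubic spline basis with knots at five age quantiles, random
   intercept + slope, fitted by EM with monotone log-likelihood, K chosen
   by AIC over 2–4.
5. **Panel vector autoregression by system GMM** (`fit_pvar`,
   `mmsc_lag_select`, `hansen_j`, `stability_check`,
   `extract_temporal_network`) — Y_it = Σ_l A_l y_i,t−l + v_i + e_it on
   unbalanced panels, first-difference or forward-orthogonal-deviation
   transform, lagged levels and lagged differences as instruments
   (system GMM), Andrews–Lu moment selection for the lag order, Hansen
   overidentification test, companion-matrix stability check, and a signed
   directed temporal network of all lag-1 coefficients with p < α.
6. **Synthetic cohort generator** (`simulate_study`, `simulate_var_panel`,
   `simulate_raw_features`) — cohorts with known latent classes, module
   structure, VAR(1) dynamics and engineered QC violations, so every stage
   is testable by parameter recovery.

## Worked example

```r
library(glipnet)

cfg <- sim_config(n_children = 200, seed = 42, n_modules = 4,
                  lipids_per_module = 15, noise_sd = 0.4)
sim <- simulate_study(cfg)

x    <- scale(as.matrix(sim$panel[, grep("^lipid_", names(sim$panel))]))
adj  <- signed_adjacency(x, beta = 18)
part <- detect_modules(topological_overlap(adj), min_size = 10)
part
#> module_partition: 60 of 60 lipids in 4 modules (min size 10 )
#>  1  2  3  4
#> 15 15 15 15

me <- module_eigenlipids(x, part)
round(me$variance_explained, 2)
#> 0.81 0.81 0.81 0.82

within_fe_fit(sim$panel, "laz", "visit_index")
#> within fixed-effects fit: laz ( 918 obs, 200 children )
#>         term   estimate  std_error statistic      p_value
#>  visit_index -0.2698279 0.01758235 -15.34653 3.736709e-53

pdat  <- cbind(sim$panel[, c("child_id", "visit_index", "sex",
                             "waz", "laz", "wlz")],
               as.data.frame(me$values))
spec  <- pvar_spec(c("waz", "laz", "wlz", colnames(me$values)),
                   exogenous = "sex", transform = "fod", system = TRUE)
model <- fit_pvar(pdat, spec, scale = TRUE)
model
#> panel VAR(1), 7 endogenous, twostep system GMM (fod)
#>   children: 200  rows: 1154  instruments/eq: 67
#>   Hansen J = 418.27 (df 413, p = 0.419)  stable: TRUE

extract_temporal_network(model, alpha = 0.05)
#> temporal network: 7 nodes, 12 edges at alpha = 0.05
#>  source target    weight     sign      p_value
#>     laz    laz 0.5302633 positive 9.413866e-12
#>     waz    waz 0.6099128 positive 2.325901e-14
#>     waz    wlz 0.2572341 positive 2.533715e-04
#>     wlz    laz 0.3037257 positive 2.616108e-06
#>     ...
```

Reading the output: the LAZ trend (−0.27 z-score units per visit) quantifies
progressive growth faltering; each module's eigenlipid captures ~81 % of its
module's variance; the Hansen test does not reject instrument validity
(p = 0.42); the model is stable (all companion eigenvalues inside the unit
circle); and the temporal network recovers the cross-lagged structure the
generator planted — current WAZ predicts next-visit WLZ, and current WLZ
predicts next-visit LAZ, with strong self-loops for all variables.

The entire chain can also be run as one pipeline with artifact export and a
run manifest:

```r
run_pipeline(pipeline_config(sim = cfg, out_dir = "run1", seed = 42))
```

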