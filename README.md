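# cordgrass

Phenology-based mapping and potential-distribution analysis of the
invasive salt-marsh grass *Spartina alterniflora* (smooth cordgrass).

Coastal monitoring teams track cordgrass invasion from satellite
reflectance time series: the plant's strong seasonal cycle (summer peak,
winter senescence) separates it from evergreen mangrove, bare mudflat,
aquaculture rafts, seawater and artificial surfaces. This package
implements that workflow end to end, driven by a seeded synthetic-scene
generator so every stage runs — and is tested — with no external data.

The pipeline:

1. **Spectral indices** per observation and pixel: NDVI, EVI, LSWI, NDWI
   and the water frequency WF = N_water / N_observation (water iff
   NDWI > 0).
2. **Harmonic regression** per pixel and index:
   `y(t) = a0 + Σ_j a_j cos(2πjt) + b_j sin(2πjt)` (default m = 2
   harmonics), fitted by OLS to the valid observations of an irregular,
   cloud-gapped series; phenological features are the reconstructed
   curve's maximum, minimum and range.
3. **Tree-ensemble classification** of the 13 features (4 indices ×
   max/min/range, plus WF) with bagging and random feature subsets, then
   stratified validation (150 / 300 points) and confusion-matrix
   statistics: OA, PA, UA and kappa = (p_o − p_e)/(1 − p_e).
4. **Expansion analytics** from binary maps: 8-connected patches, areas in
   hm², yearly growth rates, and the area-weighted centroid
   X = Σ S_i x_i / Σ S_i whose displacement tracks the spread direction.
5. **Maximum-entropy distribution modelling** written from first
   principles: grid de-duplication of occurrences, |r| ≥ 0.75 correlation
   pruning, L1-penalised fitting of linear + categorical features by
   coordinate descent, percent contribution and permutation importance,
   response curves, rank AUC, the maximum sensitivity + specificity
   threshold, and three-tier zoning of the potential region
   (high / moderate / least).

## Worked example

```r
library(cordgrass)

# simulate a labelled 64x64 scene: 23 dates, 20% seasonal cloud gaps,
# band noise, outlier spikes
scene <- generate_scene(scene_config(seed = 1))

# harmonic features -> ensemble classifier -> cordgrass map -> assessment
feat  <- scene_features(scene, m = 2)
train <- make_training_set(feat, scene$class_raster, seed = 2)
model <- train_classifier(train, seed = 2)
map   <- predict_map(model, feat, scene$class_raster)
val   <- stratified_validation_sample(map, seed = 3)
map_accuracy(map, scene$class_raster, cells = val$cell)
#>               predicted
#> reference      spartina non_spartina
#>   spartina          143            1
#>   non_spartina        7          299
#> OA = 98.22%   kappa = 0.9596
#>   spartina       PA =  99.31%  UA =  95.33%
#>   non_spartina   PA =  97.71%  UA =  99.67%

weighted_centroid(extract_patches(map$binary), epoch = "2019")
#> <centroid_record> epoch 2019: (424.9, 1373.3), 65.16 hm^2 in 39 patches

# potential-distribution analysis on the packaged study conditions
sdm <- simulate_sdm_scene(seed = 4)
ev  <- evaluate_replicates(sdm$occurrences, sdm$stack, n_replicates = 10, seed = 4)
ev$mean_auc
#> [1] 0.8619...   # held-out presences vs background, mean of 10 replicates

full <- fit_maxent(sdm$occurrences, sdm$stack, seed = 4)
round(percent_contribution(full), 1)
#> env1 env2
#> 99.3  0.7      # env1 is the variable that truly drives suitability
threshold_max_ss(logistic_output(full, cells = sdm$occurrences$cell),
                 logistic_output(full))
#> [1] 0.1505...  # suitability cut separating potential from non-potential
```

The validation table reads: of 144 reference cordgrass points, 143 were
mapped as cordgrass (producer's accuracy 99.3%); of 150 points mapped as
cordgrass, 143 were truly cordgrass (user's accuracy 95.3%); overall
accuracy 98.2% with chance-corrected agreement kappa 0.96. The centroid
record gives the area-weighted centre of all mapped patches in projected
metres with the mapped area in hm² (1 hm² = 1 ha).

See `vignettes/cordgrass-methods.Rmd` for the model details, generator
assumptions and numerical choices.

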