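# leafnitro

Estimates rice leaf nitrogen content (g/kg) from visible-light images of
leaves photographed on a calibration board. For plant-phenotyping and
precision-fertilization work where chemical nitrogen assays are too slow or
destructive: leaf greenness tracks chlorophyll and hence nitrogen status,
and leaf area is recoverable from pixels once a board of known square size
is in the frame.

The chain is:

1. **Segment** the leaf (green-dominance thresholding with Otsu fallback,
   morphological cleanup, hole filling) and **detect** the board squares.
2. **Calibrate**: with `S1` the physical area of one square (cm²) and `S2`
   its pixel area (median over detected squares), the coefficient
   `Kc = S1/S2` converts a pixel count `A` to physical area `A·Kc`.
3. **Extract features**: leaf area (cm²), G-channel mean and variance over
   the leaf mask.
4. **Predict** nitrogen with a hybrid model — partial least-squares
   regression on Gaussian radial-basis-function activations,
   `H_ij = exp(-||x_i - c_j||² / 2σ²)` — whose hyperparameters
   `(log σ, #centers, #latent variables)` are tuned by a genetic procedure
   minimizing the cross-validated absolute-error fitness
   `F = k·Σ|y_i - o_i|` with inverse-fitness roulette selection. Linear
   (GRL) and Nadaraya–Watson general-regression (GRM) baselines are
   included, with MAE/MAPE/RMSE, signed per-sample error rates and
   predicted-vs-actual fit diagnostics.

A synthetic bench renders leaf-on-board scenes with exact ground truth and
simulates feature→nitrogen datasets in the per-stage nitrogen ranges
(9–11 g/kg growing, 15–19 g/kg mature), so the whole chain is testable
without any field data. See `vignettes/leafnitro-methods.Rmd` for the
model, assumptions and design decisions.

## Worked example

```r
library(leafnitro)

# render a synthetic acquisition with exact ground truth
sc  <- render_scene(scene_spec(seed = 3))
seg <- segment_leaf(sc$image)
bd  <- detect_board(sc$image, seg$leaf_mask)
extract_features(sc$image, seg, bd, sample_id = "leaf_003")
#>  sample_id   stage area_px area_cm2   g_mean    g_var nitrogen_gkg
#>   leaf_003 growing   24176    15.11 148.0965 68.85249           NA
sc$truth$leaf_area_cm2    # 15.11  — measured area matches truth exactly
sc$truth$g_channel_mean   # 148.0965
```

The leaf occupies 24 176 pixels; with 40-px / 1-cm board squares
(`Kc = 1/1600 cm²/px`) that is 15.11 cm², and the G statistics match the
rendered truth. Running the full study protocol (35 training / 10 test
samples per stage, three models) on simulated data:

```r
res <- run_experiment(experiment_config(seed = 7,
         ga = ga_config(population_size = 16L, n_generations = 12L)))
res$comparison
#>       model   stage mae_gkg mape_pct rmse_gkg r_squared fit_slope pearson_r
#>  rbfnn_plsr growing  0.1969   1.9388   0.2346    0.4213    0.5444    0.6491
#>         grl growing  0.2072   2.0453   0.2328    0.4226    0.4719    0.6501
#>         grm growing  0.1582   1.5554   0.1917    0.6061    0.5006    0.7785
#>  rbfnn_plsr  mature  0.1543   0.8885   0.2049    0.9193    0.7362    0.9588
#>         grl  mature  0.1887   1.0876   0.2550    0.6831    0.6626    0.8265
#>         grm  mature  0.1704   0.9855   0.2052    0.8150    0.6985    0.9028
```

Columns are test-set mean absolute error and root-mean-square error in
g/kg, mean absolute percentage error in percent, and the
predicted-vs-actual fit (R², slope, Pearson r) per stage. At this small
protocol scale (10 test samples) model ordering fluctuates with the seed;
the hybrid's advantage over the linear baseline is systematic at larger n
(see the signal-recovery test and the acceptance script).

## Command line

```sh
Rscript inst/cli/leafnitro.R simulate --stage growing --n 45 --seed 7 --out data/
Rscript inst/cli/leafnitro.R extract --image scene.png --board-size-cm 1.0 --out features.csv
Rscript inst/cli/leafnitro.R train --features features.csv --stage growing --model m.json --seed 7
Rscript inst/cli/leafnitro.R evaluate --model m.json --features test.csv --out report.json --plot fit.png
Rscript inst/cli/leafnitro.R experiment --out run1/ --seed 7
```

Exit codes: 0 ok, 1 user error, 2 internal error.

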