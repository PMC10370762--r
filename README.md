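# gclstm — graph-convolutional LSTM for regional food-access diabetes risk

`gclstm` builds early-warning risk surfaces for type 2 diabetes (T2D) from
food-environment visit behaviour. The idea: geotagged social-media check-ins
evidence visits to food venues (POIs); the weekly visit frequency per
food-access category (fast food, convenience stores, supercenters, ...) in a
map tile carries signal about the local diet structure; and a spatio-temporal
neural model can score each tile's early risk and render it as a heatmap.

The pipeline, end to end:

1. **Feature splicing** — a check-in joins a POI when its text similarity
   exceeds 3.5 on a 0–10 cosine scale *and* its haversine distance is under
   3 km (strict gates); matched check-ins are counted into weekly visit
   frequencies per POI.
2. **Tile graphs** — within each Web-Mercator tile (slippy `z/x/y`, zoom 14),
   POIs are nodes and each diabetes case's weekly food-access category is a
   hyperedge over the POIs of that category; hyperedge features are pulled
   onto nodes by multi-head additive attention, and the GCN adjacency is the
   clique expansion.
3. **GCN + LSTM** — two spectral graph-convolution layers with the symmetric
   normalized operator `D^(-1/2)(A+I)D^(-1/2)`, fused with the raw features
   (`X_p = delta*X + (1-alpha)*H`), drive a shared per-node LSTM across weeks;
   pooled hidden states plus a linear skip feed an affine head with a sigmoid
   tile-risk score. Training is full-batch Adam on binary cross-entropy with
   analytic gradients, warm-started from the convex skip-head solution.
4. **Risk surfaces** — per-POI scores aggregate into a 10-category x regions
   matrix by Gaussian-kernel geographically weighted means, and four GeoJSON
   map layers (boundaries, check-ins, POIs, risk heatmap) are exported.

Everything runs on a bundled synthetic-world generator with a planted,
recoverable risk signal, so the package is buildable and testable completely
offline. See the methods vignette
(`vignettes/tile-risk-modelling.Rmd`) for the model, the generator's design
and its limitations.

## Worked example

The reference world (60 tiles, 20 POIs each, 12 weekly bins, noiseless
planted signal) takes ~30 s to generate and ~2 min to fit on one CPU:

```r
library(gclstm)

world <- generate_world(world_config(seed = 1))
world
#> Synthetic food-access world
#>   tiles: 60 (zoom 14)   POIs: 1200   check-ins: 28923   cases: 180
#>   weeks: 12   risk threshold: 14.421   positive tiles: 30/60

fit <- glstm(world, seed = 1)   # splice, build graphs, train end to end
fit
#> Graph-convolutional LSTM tile-risk model
#>   tiles: 42 train / 0 validation / 18 test
#>   GCN hidden 32, LSTM hidden 16, attention heads 2
#>   epochs run: 200, final training loss 0.0552

evaluate(fit)
#> Tile-risk evaluation
#>   tiles: 18   accuracy: 94.44%   recall: 88.21%   rmse: 18.0185
```

`accuracy` is the share of held-out tiles whose predicted label (score > 0.5)
matches the planted label; `recall` weights truly-risky tiles by their
matched check-ins (the visit-evidence reading of recall); `rmse` compares the
sigmoid scores against the planted frequency-scale scores and is therefore
large by construction — it is a relative diagnostic only.

Map export:

```r
surf <- risk_surface(predict(fit), predict(fit, unit = "poi"), world$pois)
export_layers(world, surf, "maps/")   # four GeoJSON layers
```

A thin end-to-end driver lives in `inst/scripts/pipeline.R`
(`Rscript pipeline.R --config run.yaml --out outdir`).

## Tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "gclstm",
                               load_package = "installed")'
```

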