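# woundsight

Quantification of exo-endocytic dynamics during plasma-membrane wound
repair.

When the plasma membrane of an endothelial cell is wounded (e.g. by
two-photon laser ablation), repair proceeds in stages: Ca²⁺-triggered
exocytosis of early endosomes near the wound within the first ~10 s,
resealing of the bilayer within ~30 s (read out by the arrest of influx of
a membrane-impermeable dye such as FM4-64), and a later wave of
clathrin-mediated endocytosis that is spatially coupled to the sites of
the earlier exocytic events. `woundsight` implements the quantitative
pipeline for such experiments as a tidyverse-native R package:

- **Punctae detection** — a deterministic band-pass / threshold /
  connected-components / size-filter detector for diffraction-limited
  fluorescent spots, plus ingestion of externally trained probability
  maps (`detect_punctae()`, `binarize_probability_maps()`).
- **Concentric-ring quantification** — circles of increasing diameter
  (20 µm increments by default) around the 2.5 µm² wound ROI; event
  counts per ring per frame normalized to the pre-wound baseline (null
  baselines clamped to 1) and to ring area, rendered as ring × time
  heatmaps (`build_rings()`, `count_matrix()`, `autoplot()`).
- **Resealing kinetics** — background-corrected, baseline-normalized dye
  influx curves and a slope-ratio plateau-versus-linear classifier, plus
  the hydrogel metrics (around-wound ROI intensity, delineation area
  fraction) and the scrape-assay repair percentage (`influx_curve()`,
  `classify_resealing()`, `scrape_repair_percentage()`).
- **Spatial statistics** — object-based colocalization and the
  nearest-neighbor association series from endocytic punctae to prior
  exocytic sites, with a far-field (circle 6) control (`colocalize()`,
  `nn_series()`, `nn_control()`).
- **Membrane biophysics** — the hole-energetics model and
  optical-tweezers tether-force plateau extraction (`hole_enthalpy()`,
  `critical_radius()`, `plateau_force()`).
- **Synthetic data with ground truth** — a generator that emulates the
  imaging experiments (Poisson punctae birth–death, a wound-evoked
  exocytic burst, a delayed spatially coupled endocytic burst,
  saturating vs. linear dye influx, bleaching, noise) so every stage is
  testable without microscope data (`simulate_movie()`,
  `simulate_events()`, `simulate_force_trace()`).

## The core model

A circular hole of radius *R* in a membrane has effective enthalpy

H(R) = 2E + 2πRλ − πR²σ

where λ is the line tension of the open hole edge, σ the membrane
tension, and *E* an additive system energy. H is concave in *R*
(d²H/dR² = −2πσ), so its stationary point at dH/dR = 0,

**R_c = λ / σ**,

is an energy barrier: holes with R < R_c lower their enthalpy by
shrinking and self-reseal, holes with R > R_c grow. With standard values
λ ≈ 1 pN and σ ≈ 10⁻⁵ N m⁻¹ this gives R_c = 100 nm; lowering membrane
tension by an order of magnitude (as exocytic membrane supply and actin
depolymerization do locally at a wound) moves the bound to 1 µm —
tension reduction as a robust mechanism for resealing large wounds.

## Worked example

```r
library(woundsight)

cfg  <- sim_config(image_shape = c(256, 256), pixel_size = 0.25,
                   n_frames = 46, rng_seed = 42)
proc <- event_params(steady_rate = 1e-3, exo_boost_by_ring = c(25, 8, 3, 1, 1, 1),
                     endo_boost = 8, assoc_prob = 0.9, assoc_sd = 0.5,
                     ring_increment = 8, spot_sigma = 0.3)
sim  <- simulate_movie(cfg, proc, resealed = TRUE)
sim$movie
#> <wound_movie> 46 frames x 3 channels x 256 x 256 px (0.2500 um/px, 1.00 s/frame)
#>   wound frame 3; wound 2.50 um^2 at (32.0, 32.0) um; channels: dye, exo, endo

exo   <- detect_punctae(sim$movie, "exo",  detector_params(band_pass_sigma = 0.3))
endo  <- detect_punctae(sim$movie, "endo", detector_params(band_pass_sigma = 0.3))
rings <- build_rings(sim$movie$wound_center, sim$movie$wound_area,
                     n_rings = 6, diameter_increment = 8)

cm <- count_matrix(exo, rings)   # ring x time heatmap, autoplot(cm) to draw
win <- cm$time_s > 0 & cm$time_s <= 10
mean(cm$value[cm$ring == 1 & win]) / mean(cm$value[cm$ring == 6 & win])
#> ring-1 normalized density is ~95x ring 6 during the exocytic burst
#> (0.0825 vs 0.00087 events / baseline / um^2)

classify_resealing(influx_curve(sim$movie))
#> <wound_reseal_call> resealed (early slope 0.2243, late slope -0.01852,
#>   ratio -0.0826, threshold 0.2)

ref <- reference_events(exo, rings, window = c(0, 10), ring_set = 1)
ser <- nn_series(endo, ref, region_label = "circle1")
# normalized NN distance: ~1.01 before resealing, ~0.49 after --
# endocytosis lands at or near the prior exocytic sites

pf <- plateau_force(simulate_force_trace(45, 20, noise_sd = 1,
                                         n_samples = 1000, seed = 42)$trace)
pf
#> <wound_tether_fit> peak 45.67 pN, plateau 19.97 pN over 408 samples
#>   (baseline 0.09 pN, noise 0.94 pN)

critical_radius(membrane_params()) * 1e9
#> [1] 100   # nm
```

The numbers mean: the wound-evoked exocytic burst is confined to the
innermost circle during the first 10 s; the dye-influx curve plateaus, so
the cell resealed; after resealing the endocytic punctae sit roughly
half as far from the compiled exocytic sites as before (the
nearest-neighbor dip); the tether plateau force — the membrane-tension
indicator — is recovered to within the noise floor of its 20 pN ground
truth.

A full run (`run_pipeline()`, or the thin wrapper in
`inst/scripts/woundsight`) chains simulate → detect → quantify →
kinetics → nnassoc from one YAML/`list` configuration and writes CSV/JSON
artifacts plus a checksummed manifest.

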