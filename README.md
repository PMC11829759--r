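# tailbudkit

Quantitative image analysis of zebrafish tailbud ablation experiments.

During posterior body elongation, the zebrafish tailbud supplies the
progenitors — including *sox2*/*tbxta* co-expressing neuromesodermal-competent
(NMC) cells — that build the spinal cord and paraxial mesoderm. Studying how
the tissue responds when dorsal or lateral progenitors are removed by
two-photon ablation requires a chain of quantitative steps: segmenting nuclei
in 3D confocal stacks, measuring per-nucleus HCR expression and classifying
NMC states, registering tailbuds from many embryos into one frame and
averaging expression locally, scoring cell-track directionality from
lightsheet movies, and measuring tail tissue lengths normalised by somite
number. `tailbudkit` implements that chain as composable, tested R functions,
together with a synthetic phantom generator that carries ground truth so
every stage can be validated end to end without any raw imaging data.

## Methods at a glance

* **3D nuclear segmentation** — intensities are equalised by exact
  sliding-window adaptive histogram equalisation with a 10 µm kernel cube
  (the average nuclear diameter), band-passed with a difference of Gaussians
  (σ = 1, 3; negative values clipped at 0), labelled per z-slice, and the 2D
  labels are stitched into 3D nuclei by greedy one-to-one matching of
  footprint overlap with an intersection-over-union threshold of 0.6.
* **Expression quantification** — HCR channels get two rounds of 0.8 µm
  median filtering; per-channel background is the median nuclear intensity
  of a reference region (*sox2* in notochord, *tbxta*/*tbx16* in spinal
  cord); nuclei above background in both channels are double positive, and
  their relative NMC level is `(a − b) / (a + b)` on background-subtracted
  intensities (+1 pure *sox2*, −1 pure *tbxta*).
* **Registration and averaging** — closed-form (Kabsch) rigid landmark
  alignment with an ICP fallback; expression attributes are averaged over all
  registered nuclei within 11 µm of each reference nucleus, which in a
  perfect lattice collects 14 nearest neighbours.
* **Track metrics** — per-track time-averaged mean squared displacement
  MSD(τ); its log–log slope α classifies motion (α ≈ 1 diffusive, α > 1.1
  directional, α ≈ 2 ballistic), alongside duration-corrected straightness,
  mean turning-angle cosine, dorsoventral displacement, and TCF-GFP
  intensity dynamics for tracks starting within 60 µm of the ablation.
* **Morphometry** — segmented-line tissue lengths, per-somite segments,
  µm/somite normalisation, spinal-cord/mesoderm ratios, Caspase-3 fractions,
  and two-sided Mann–Whitney–Wilcoxon comparisons (exact by enumeration up
  to combined n = 20) with `*`–`****` significance tiers.

## Worked example

```r
library(tailbudkit)

# a 50-nucleus tailbud phantom with opposing sox2/tbxta gradients
spec <- embryo_phantom_spec(shape_voxels = c(48, 96, 96), n_nuclei = 6,
                            separation_factor = 1.3, seed = 2)
sim <- generate_nuclear_stack(spec)
seg <- segment_stack(sim$stack)
seg
#> <segmentation_result> 6 nuclei in a 48 x 96 x 96-voxel volume
seg$nuclei[1:3, c("id", "z_um", "y_um", "x_um", "volume_um3")]
#> # A tibble: 3 x 5
#>      id  z_um  y_um  x_um volume_um3
#>   <int> <dbl> <dbl> <dbl>      <dbl>
#> 1     1  6.22  11.9  35.2       371
#> 2     2  8.02  40.0  40.0       461.
#> 3     3  8.24  31.3  26.7       324.
```

All six ground-truth nuclei are recovered; centroids agree with the
generator's truth table to well under a nucleus radius, and the per-nucleus
`mean_sox2` / `mean_tbxta` columns separate expressing (≈ 0.2–0.3) from
non-expressing (≈ 0.05) nuclei, from which `classify_expression()` and
`nmc_relative_level()` reproduce the phantom's known class composition.

Track directionality on simulated motion:

```r
tr <- generate_tracks(track_sim_spec("diffusive", n_tracks = 200,
                                     n_steps = 100, seed = 1))
alphas <- vapply(split(tr, tr$track_id),
                 function(g) msd_exponent(msd_curve(g))$alpha, numeric(1))
mean(alphas)
#> [1] 0.9528474
```

A Brownian ensemble calibrates the fitted MSD exponent to ≈ 1, the
diffusive reference against which directional tracks (α > 1.1) are called.

## Command line

A thin CLI over `run_pipeline()` lives at `inst/cli/pipeline.R`:

```sh
Rscript inst/cli/pipeline.R simulate --config cfg.yaml --out out/
Rscript inst/cli/pipeline.R segment  --config cfg.yaml --out out/
```

Configuration defaults (`pipeline_config()`) are the analysis parameters
above; a run manifest with the config hash and seed is written next to every
output, and identical config + seed gives identical outputs.
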