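# livespot

Quantification of single-molecule live-cell fluorescence microscopy movies
in R: from a raw two-channel time-lapse TIFF to the kinetic parameters of
translation.

Live-cell reporters such as MS2/MCP stem-loops (labelling single mRNAs) and
epitope-tag/antibody-fragment systems (labelling nascent proteins) produce
movies in which each translation site is a diffraction-limited spot whose
intensity tracks its ribosome load. Turning such movies into numbers
requires a chain of steps — photobleaching correction, cell segmentation,
spot detection, particle tracking, intensity extraction, two-channel
colocalization, and fluctuation-correlation analysis — that `livespot`
provides as a single scriptable pipeline, together with a ground-truth
simulator so every stage can be validated without any external data.

## The model at the core

Each mRNA is a translation site: ribosome initiations are Poisson with rate
`ki` (1/s), ribosomes elongate at `ke` (codons/s) over a construct of
`L_total` codons, and a ribosome's fluorescence is the fraction of epitopes
it has translated. The fluctuation autocorrelation of a spot's intensity
trace,

    G(tau) = <dI(t) dI(t+tau)> / <I>^2,

decays to zero at the mean transit time from the average probe position to
the stop codon, tau_c = L_eff / ke, and its zero-lag amplitude scales
inversely with the ribosome load, G(0) = 1 / (ki * tau_c). Measuring G from
tracked spot traces therefore yields both rates:

    ke = L_eff / tau_c        ki = 1 / (G(0) * tau_c)

Photobleaching is modelled as `I(t) = A exp(-kb t) + c` and corrected before
intensities are extracted. Spot detection is a scale-normalized
Laplacian-of-Gaussian filter with automated hybrid threshold selection
(elbow + plateau of the count-versus-threshold curve); tracking is optimal
one-to-one assignment with tunable displacement and gap memory;
colocalization is distance-gated one-to-one matching between channels.

## Worked example

Simulate the benchmark movie (360 frames at 5-s intervals, 512 x 512
pixels, 80 membrane-tethered mRNA spots, `ki = 0.04`/s, `ke = 5` codons/s,
photobleaching `kb = 0.001`/s), then recover the kinetics:

```r
library(livespot)

sim <- benchmark_fixture(seed = 1)        # movie + ground truth

# photobleaching: fit on per-frame means, correct the nascent channel
fit <- fit_bleach(sim$movie, channel = 1)
fit
#> bleach_model: I(t) = 0.9636 * exp(-0.001002 t) + 100  (R2 = 0.9923)

# detect spots in every frame of the mRNA channel, automatic threshold
spots <- detect_movie(sim$movie, channel = 1, sigma_px = 1.3)
mean(tabulate(spots$frame, 360))
#> [1] 80.52778

# kinetic rates from simulated nascent-protein traces (L_eff = 1900 codons)
p  <- simulation_params(seed = 1, fov_yx = c(64, 64), min_separation_px = 1)
tr <- simulate_translation_traces(p)
m  <- tr$intensity; attr(m, "time_s") <- (seq_len(nrow(m)) - 1) * 5
kin <- translation_kinetics(m, L_eff = 1900, max_lag_s = 1200)
kin$estimates
#> kinetic_estimates: ki = 0.04027 1/s, ke = 5.095 codons/s
#>   (tau_c = 372.9 s, G0 = 0.06659, L_eff = 1900)
```

The fitted decay rate (0.001002/s) matches the simulated 0.001/s; detection
recovers on average 80.5 of the 80 spots per frame across the 6-fold
photobleaching decay; and the correlation analysis returns the transit time
(373 s vs the true 380 s) and both rates within a few percent of the
simulation inputs. Applying the estimator to the textbook pair
`G(0) = 0.08`, `tau_c = 380 s` gives `ki = 0.0329`/s:

```r
estimate_rates(g0 = 0.08, tau_c_s = 380, L_eff = 1900)
#> kinetic_estimates: ki = 0.03289 1/s, ke = 5 codons/s (tau_c = 380 s, ...)
```

A whole run can also be driven from a YAML configuration
(`run_pipeline("config.yaml")`, or the `inst/scripts/livespot` command-line
wrapper), which writes `spots.csv`, `traces.csv`, `coloc.csv`,
`correlation.csv`, `kinetics.json` and a `metadata.json` capturing every
parameter and threshold, so identical config + seed reproduce byte-identical
outputs.

See the methods vignette (`vignettes/livespot-methods.Rmd`) for the models,
conventions and numerical choices, including why detection runs on the raw
movie, why the de-correlation time uses the initial-decay intercept, and
what the synthetic benchmark does and does not demonstrate.

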