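# chromtrap

Quantitative analysis of single bacterial chromosomes in semi-open
microfluidic compartments.

When an *E. coli* cell is trapped in a flat microchamber and gently lysed,
its chromosome stays behind as a compact, blob-like body that can be stained,
stretched, fed with a cell-free transcription–translation (TxTl) system, and
watched for hours — because the chamber exchanges molecules with the flow
channels only through thin capillaries, by diffusion. chromtrap implements
the quantitative pipeline for such experiments, for microscopists and
bottom-up synthetic biologists who need numbers out of these movies:

* **Compartment design** — the analytic residence time
  τ = πR²L/(2DW) of a species with diffusivity *D* in a chamber of radius
  *R* with an exchange capillary of length *L* and width *W*, and its
  inversion for layout design.
* **Single-molecule analysis** — spot detection with variance-stabilized
  band-pass filtering and sub-pixel localization, greedy track linking,
  time-averaged MSD curves and ⟨r²⟩ = 4Dt diffusion fits, and
  density-based clustering of repeated detections into protein-synthesis
  **arrival events** whose waiting-time CDF is fitted with
  1 − exp(−t/τ).
* **Dissociation kinetics** — normalized ensemble decay traces fitted to
  I(t) = (1 − A)·exp(−t/τ) + A, where *A* is the tightly bound (immobile)
  protein fraction; bound fractions from pre-/post-lysis signals;
  transcription elongation rates from RNAP release timescales; stretch/relax
  kinetics of field-pulled chromosomes.
* **Chromosome conformation** — classical nucleoid segmentation (background
  opening, smoothing, Otsu-seeded midpoint threshold, 8-connected
  components), overlap-based time linking, normalized summed-area series,
  DNA-blob detection, condensin/blob colocalization under the strict
  < 0.32 µm rule, per-chromosome cluster counts, crowding (PEG)
  dose-response curves with 15.9/84.1% quantile bands, and Mann-Whitney
  group comparisons.
* **A ground-truth-known scene generator** — Brownian tracks, Poisson
  surface arrivals with photobleaching and blinking, EM-CCD image formation
  (Poisson shot noise, gamma-distributed EM gain, read noise), multi-blob
  nucleoid scenes with exactly known mask areas, and stretch kymographs —
  so every stage of the pipeline is testable without experimental data.

## Worked example

Design a chamber, then recover a dissociation constant from synthetic decay
traces:

```r
library(chromtrap)

geom <- compartment_geometry(radius_um = 10, capillary_length_um = 40,
                             capillary_width_um = 1.5)
compartment_lifetime(geom, diffusion_um2_per_s = 10)   # an mRNA-like species
#> Compartment lifetime: 418.9 s (7.0 min) at D = 10 um^2/s
compartment_lifetime(geom, diffusion_um2_per_s = 1.7)  # a plasmid
#> Compartment lifetime: 2464.0 s (41.1 min) at D = 1.7 um^2/s

# four replicate condensin decay traces at tau = 6.89 min, A = 0.27,
# sampled every 5 s for 25 min with 2% Gaussian noise
sim <- simulate_decay_trace(tau_s = 6.89 * 60, immobile_fraction = 0.27,
                            noise_sd = 0.02, frame_interval_s = 5,
                            duration_s = 25 * 60, seed = 1, n_traces = 4)
trace <- normalize_trace(sim$t_s, sim$intensity)
fit_decay(trace)
#> Decay fit: tau = 412.6 s (6.88 min), A = 0.271 [ok]
```

The lifetimes say the layout holds an mRNA for about 7 minutes and a plasmid
for about 40, long enough for expression experiments; the decay fit recovers
the generator's time constant and immobile fraction to about a percent.

An end-to-end chain — simulate a 60-minute surface-capture movie at
0.67 arrivals/min, detect spots, cluster them into arrival events, fit the
waiting-time CDF:

```r
cam <- camera_model(frame_interval_s = 2)
truth <- simulate_arrivals(rate_per_min = 0.67, duration_min = 60, seed = 7)
stack <- render_frames(truth, cam, seed = 7)
events <- cluster_arrivals(detect_spots(stack), cam$frame_interval_s)
fit_arrival_cdf(waiting_times(events$arrival_time_s), "mono")
#> Arrival CDF (mono): tau = 81.1 s, rate = 0.74 /min [ok]
```

A YAML-driven command-line front-end over the same functions ships in
`inst/scripts/chromtrap.R` (subcommands `lifetime`, `simulate`, `detect`,
`track`, `msd`, `arrivals`, `decay`, `segment`, `areas`, `coloc`,
`doseresponse`, `compare`), each writing its artifacts plus a JSON run log.

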