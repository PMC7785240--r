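# gastrosync

Phase-locking analysis between the gastric basal electrical rhythm and
brain resting-state networks.

## The problem

The stomach's pacemaker — a network of myenteric interstitial cells of
Cajal — generates a continuous ~0.05 Hz electrical slow wave that is
relayed to the brain chiefly by vagal afferents. Cutaneous
electrogastrography (EGG) records this rhythm from electrodes on the
epigastrium while resting-state fMRI records brain network activity, and
the question is whether any resting-state network (RSN) time courses are
phase-locked with the stomach. `gastrosync` is for researchers running
concurrent EGG + rsfMRI studies (and for methodologists probing this
design): it implements the full analysis chain from raw multichannel EGG
to per-network significance decisions, together with a synthetic-data
generator that provides ground truth for validation and power analysis.

## The method

For each run, the EGG is low-pass filtered and downsampled to 10 Hz, the
gastric spectral peak is located within the normogastric band
(0.033–0.066 Hz) by Welch's method (200 s windows, 150 s overlap), the
best channel is bandpass-filtered with a zero-phase linear-phase FIR
(peak ± 0.015 Hz, five gastric cycles long), and the narrowband signal is
decimated to the BOLD rate (0.5 Hz, 450 volumes per 15-minute run). RSN
time courses are filtered with the same per-run parameters; after
discarding 15 volumes per end (840 s analysis window), instantaneous
phases φ(t) come from the analytic signal, and synchrony is the
phase-locking value

    PLV = | (1/T) Σ_t exp(i (φ_EGG(t) − φ_RSN(t))) |  ∈ [0, 1],

which ignores amplitudes and constant phase lags. Chance-level PLV is
estimated per network from *mismatched* pairs — every (RSN run, EGG run)
combination recorded on different days (1368 surrogate pairs for 19
sessions × 2 runs) — and matched vs mismatched distributions are compared
with one-sided Wilcoxon rank-sum tests, Benjamini–Hochberg-adjusted
across the 18 networks at FDR 0.05. The gastric contribution to each
network is summarized as the phase-adjusted variance explained
(P.V.A.F.): the von Mises location μ̂ of the phase difference rotates the
analytic RSN signal, and R² between the gastric series and the rotated
signal's real part — pooled over matched runs — estimates the gastric
share of narrowband variance. Gastric rhythm stability is assessed by
comparing same-day against different-day gastric–gastric PLVs.

See the methods vignette
(`vignettes/gastric-brain-phase-locking.Rmd`) for the model, parameter
defaults, numerical choices, and known limitations.

## Worked example

Simulate a full-size study (19 sessions × two 15-minute runs; three
networks truly coupled at gastric variance fractions 0.1124, 0.0291,
0.0150), preprocess every run, and test all 18 networks:

```r
library(gastrosync)

cfg    <- sim_config(seed = 42, egg_rate = 10)
bundle <- synthesize_study(cfg)

gastric <- lapply(bundle$runs, function(r) extract_gastric_signal(r$egg))
res <- run_full_analysis(gastric, lapply(bundle$runs, `[[`, "rsn"),
                         bundle$manifest)
res
#> <sync_analysis> 18 networks, 38 matched / 1368 mismatched pairs
#> significant at FDR 0.05: CB

head(res$table[order(res$table$p_uncorrected), ], 3)
#>  network plv_mean mismatched_mean p_uncorrected    p_fdr significant pvaf_mean mu_hat
#>       CB    0.341           0.245      1.22e-06 2.19e-05        TRUE    0.0956 -0.839
#>    DMN_b    0.263           0.222      4.16e-02 2.71e-01       FALSE    0.0365 -2.118
#> ATTN_ven1   0.235           0.209      4.52e-02 2.71e-01       FALSE    0.0009  0.584

res$stability$p_value
#> [1] 0.01059
```

Read: the strongly coupled cerebellar network is detected (matched PLV
0.341 vs chance 0.245; FDR-adjusted p = 2.2e-05) and its gastric variance
share is recovered as 0.096 (truth 0.1124) with phase lag −μ̂ ≈ 0.84 rad
(truth 0.8); the weakly coupled networks (1.5–3% variance) land near the
top of the ranking but do not clear FDR in this draw — see the vignette's
power discussion. Same-day gastric rhythms are more mutually phase-locked
than different-day ones (p = 0.011), which is why same-day pairs are kept
out of the surrogate null.

A thin command-line wrapper covers the same stages:

```sh
inst/cli/gastrosync simulate --out study/ --seed 7 --egg-rate 10
inst/cli/gastrosync sync --study study/ --out results/
inst/cli/gastrosync stability --study study/
```

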