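# ffpecorrect

Mutational-signature analysis of formalin-fixed, paraffin-embedded (FFPE)
tumour samples, for cancer genomicists who need signature activities from
archival material. Formalin deaminates cytosine (and, at CpG sites,
5-methylcytosine), flooding FFPE sequencing data with artefactual C>T calls
that masquerade as the clock-like CpG signature (repaired libraries) or a
base-excision-repair-deficiency-like spectrum (unrepaired libraries).
Feeding raw FFPE catalogues into signature refitting grossly misassigns
activities; `ffpecorrect` removes the artefact component first.

## The model

An observed 96-channel SBS catalogue *V* is decomposed as

```
V ≈ W1·H1 + W2·H2
```

where *W1* is a fixed FFPE artefact signature (bundled, protocol-specific),
*W2* a free biological spectrum, and *H1*, *H2* non-negative activities.
The fit minimises the generalized Kullback–Leibler divergence
`D(V‖V̂) = Σ V_i log(V_i/V̂_i) − V_i + V̂_i` with Lee–Seung multiplicative
updates (artefact column frozen), batched-plateau convergence (ratio of
successive 20-iteration KL means ≥ 0.95, 200–3000 iterations), and
averaging over 100 random restarts. The corrected catalogue is
`max(V − H1·W1, 0)`. The package also derives artefact signatures from
labelled cohorts (t-SNE embedding of cosine distances + Gaussian-KDE
representative selection, averaged over 100 seeds), refits fixed signature
sets with presence calls and error metrics, handles the 80-channel
(non-T>C) spectrum, and includes a Poisson-noise simulator for end-to-end
validation. See `vignette source in vignettes/ffpe-artefact-correction.Rmd`
for the full methods account.

## Worked example

Simulate an FFPE colorectal-like tumour (30,000 biological mutations,
10,000 unrepaired-formalin artefacts), correct it, and refit activities:

```r
library(ffpecorrect)

bio <- synth_biological_profile(total = 30000, seed = 2, sample_id = "crc01")
smp <- add_ffpe_noise(bio, "unrepaired", noise_total = 1e4, seed = 3)
smp
#> Synthetic FFPE sample 'crc01.ffpe' (unrepaired)
#>   bio 30000 + noise 9963 mutations; SNR 1.042, SNS 0.366; T>C dropped

fit <- ffpe_correct(smp$observed, "unrepaired",
                    control = correction_control(n_restarts = 20), seed = 1)
fit
#> FFPE artefact correction (96c) for 'crc01.ffpe'
#>   observed mutations: 37285
#>   artefact activity H1: 12074.9 (32.4% of total)
#>   biological activity H2: 25210.1
#>   restarts: 20; iterations 300-1460

evaluate_correction(smp, fit)$accuracy   # cosine vs truth on C>T channels
#> [1] 0.9950658
```

The artefact activity (~12,100) brackets the injected burden; the corrected
catalogue matches the hidden biology at 0.995 cosine on the C>T channels —
the channels where correction matters. Refitting the bundled reference
signatures on the non-T>C spectrum shows why correction is necessary:

```r
sigs <- reference_signatures()[, c("SBS1like", "SBS5like", "SBS18like")]
s80  <- apply(sigs, 2, reduce_to_80c, renormalize = TRUE)
rf   <- refit_activities(reduce_to_80c(fit$corrected), s80)
rf
#> Signature refit (80c), 3 signatures, 200 iterations, final KL 815
#>          SBS1like  SBS5like SBS18like
#> absolute 6974.343 12024.029  6211.704
#> relative    0.277     0.477     0.246
```

Against activities refit from the true biological catalogue, the corrected
profile errs by a mean absolute relative activity of 0.016; the uncorrected
profile errs by 0.060 — nearly four times more.

A command-line shim wrapping the same functions (subcommands `correct`,
`refit`, `simulate`, `benchmark`, `derive`, `advise`) is installed at
`system.file("cli", "ffpecorrect", package = "ffpecorrect")`; every run
writes a JSON sidecar with its options and seeds.

Note: the bundled artefact and reference signatures are deterministic
**synthetic stand-ins** shaped after the published spectra (see the
vignette); comparisons against the COSMIC catalogue require user-supplied
matrices.

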