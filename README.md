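# embryotrace

Analysis toolkit for live imaging of endogenous mRNAs labelled with
catalytically dead Cas13 (dCas13) in early zebrafish embryos. A single
zygotic injection of purified dCas13–fluorescent-protein/gRNA complexes
lights up transcripts that carry many near-identical ~20-nt repeat units,
which makes three kinds of quantitative questions tractable in vivo:

* **Which transcripts can be labelled at all?** Multi-copy targeting needs
  a transcript with many repeats of one 20-nt unit that are unique to one
  gene. `embryotrace` screens a transcriptome for clusters of k-mers whose
  pairwise Hamming distance is at most 1, filters out motifs shared
  between genes, and flags transcripts with ≥ 8 usable copies.
* **How do the two alleles of one gene behave?** From per-allele ROI
  intensity traces the package computes the normalized transcription
  activity `(ROI1_max − ROI2_mean) / ROI2_mean` (which cancels
  photobleaching exactly), detects initiation times, classifies activation
  patterns (none / one allele / same time / sequential), measures plateau
  kinetics, and summarizes transcriptional memory as the mean ± SD of
  inter-allele initiation-time differences per cell cycle. Intrinsic vs
  extrinsic expression noise is separated by correlating the cumulative
  outputs of the two alleles against randomized-pair controls.
* **How do exported mRNPs move?** Single-particle tracks are classified
  into four motion modes by mean-squared-displacement model fits —
  directed (`MSD = (vt)²`), diffusive (`MSD = 4 D t^α`), corralled
  (`MSD = (L²/3)(1 − e^(−t/τ))`, `D = L²/(12τ)`) and stationary — using
  the gyration-ratio / max-displacement decision protocol, and
  nucleocytoplasmic export events are timed from dock to release at the
  nuclear boundary.

A regularized denoiser (`argmin_g ‖f − H⊗g‖₂² + λ‖g‖₁ + μ‖∇g‖₂²`, solved
by proximal gradient descent) reproduces the preprocessing applied to the
tracking movies, and seeded synthetic-data generators produce every input
the pipeline consumes — trajectories of all four motion modes, paired
allelic traces with shared extrinsic and independent intrinsic noise,
Gaussian-spot movies, and transcriptomes with planted repeat clusters —
with ground truth returned alongside, so every stage can be validated
end to end.

## Worked example

```r
library(embryotrace)

# two cohorts of paired allelic traces: slow, asynchronous de novo
# transcription vs fast, synchronous post-mitotic re-activation
de_novo <- gen_trace_pairs(n_cells = 55, n_timepoints = 150, dt_min = 2,
                           offset_mean_min = 44.2, offset_sd_min = 33.5,
                           plateau_time_min = 60, cycle = "de_novo",
                           seed = 1)
reactiv <- gen_trace_pairs(n_cells = 36, n_timepoints = 150, dt_min = 2,
                           offset_mean_min = 11.9, offset_sd_min = 14.6,
                           plateau_time_min = 25, cycle = "reactivation",
                           seed = 1001)
rec <- rbind(activation_records(de_novo$traces),
             activation_records(reactiv$traces))
memory_statistics(rec)$per_group
#>          group  n     mean       sd
#> 1      de_novo 55 40.00000 25.40341
#> 2 reactivation 36 12.55556 17.93073
```

The de novo cohort re-fires its second allele ~40 min after the first
(sample mean of a 44.2 ± 33.5 min offset distribution at n = 55), while
re-activated cells fire both alleles within ~13 min — the signature of an
inherited active transcriptional state.

```r
# motion classification at the study's nuclear kinetics
tr <- gen_trajectory("corralled", n_frames = 3000, dt = 0.01,
                     D_micro = 0.2818, L_box = 0.5, seed = 2)
classify_motion(tr)
#> <motion_classification> corralled: D = 0.2718 um^2/s,
#>   gyration ratio = 0.899, max disp = 1.03 um
```

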