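# minicircle

Toolkit for locating and characterising protein-bound segments of small
circular DNAs ("minicircles"), built around four analyses that recur when
interpreting cryo-EM structures of DNA-bound enzymes such as bacterial
gyrase:

1. **R/Y register mapping.** A density map often resolves whether each base
   is purine-shaped (R) or pyrimidine-shaped (Y) long before it resolves
   identity. `ry_scan()` matches such an R/Y profile (with `X` for
   unresolved bases) against both strands of a circular reference under a
   tolerance budget, and `match_probability()` gives the exact chance of a
   random match,

   *p* = 2^(−n) · Σ_{i=0..f} C(n, i),

   for a profile of length *n* with up to *f* free (mismatched or
   unresolved) positions. `assign_register()` substitutes the reference
   sequence back into a matched window; `find_palindromes()` and
   `interval_overlap()` characterise the mapped sites.

2. **Deformability profiling.** Each base-pair step has a
   sequence-dependent deformability *V*_step (deg³·Å³) determined by its
   tetramer context. `step_values()` looks these up around a circle,
   `kmer_profile()` averages the k−1 steps inside a sliding k-bp window
   (periodic boundaries, one-base stride), and `rank_region()` turns a
   window into a "top X % most flexible" statement.

3. **Step conformation and 3-D rebuild.** `classify_zp()` / `classify_zph()`
   assign A/B/intermediate and B/TA forms from the phosphorus descriptors
   z_P and z_P(h) (B: z_P ≤ 0.5 Å; A: z_P ≥ 1.5 Å; TA: z_P(h) > 4 Å);
   `is_melted()` flags base pairs whose rigid-body parameters leave their
   acceptance intervals. `rebuild_helix()` composes the six rigid-body step
   parameters (Shift, Slide, Rise, Tilt, Roll, Twist) into base-pair
   frames with the standard mid-step-triad convention, and `handedness()`
   reports the superhelical sense of the rebuilt axis — inserting
   underwound A-like stretches into B-DNA folds a right-handed (negative)
   superhelix, overwound C-like stretches a left-handed one.

4. **Motif scanning.** `motif_scan()` scores every window of a circular
   sequence against a position weight matrix (plain additive weights,
   positive = fits the motif), `split_pwm()` produces the
   first-region+core / core / core+second-region sub-matrices of a
   periodic–core–periodic motif such as the 130-bp gyrase cleavage motif
   (47/36/47), and `positive_near_center()` asks whether any positive
   score falls within ±5 bp of a stated centre.

Everything takes and returns tidyverse-style tibbles, so results chain with
the pipe; `autoplot()`, `tidy()` and `glance()` methods cover the profile
and helix-model result types. Seeded generators (`synth_sequence()`,
`synth_tetramer_table()`, `synth_pwm()`) make every analysis reproducible
without downloads; published deformability tables and motif PWMs drop in as
TSV files (`read_tetramer_table()`, `read_pwm()`). The files under
`inst/extdata/` are clearly-labelled synthetic examples of those formats.

## Worked example

Map a density-derived 24-base R/Y profile (one mismatch, one unresolved
base) onto a 601-bp circular reference:

```r
library(minicircle)

match_probability(c(24, 30), c(2, 2))
#>       n     f probability  one_in
#> 1    24     2 0.0000179     55738
#> 2    30     2 0.000000434 2304167

t1      <- fixture("table1")$payload
profile <- ry_profile(paste(t1$assign_e, collapse = ""))   # contains one X
ref     <- synth_sequence(42, 601,
             plant = list(profile = paste(t1$pattern_e, collapse = ""),
                          position = 112))

hits <- ry_scan(profile, ref, max_free = 2)
hits[hits$is_best, ]
#>   start strand      n n_agree n_mismatch n_unresolved  free probability is_best
#> 1   112 forward    24      22          1            1     2   0.0000179 TRUE

assign_register(hits[hits$is_best, ][1, ], ref, extend_left = 3, extend_right = 3)
#>   map_start map_end strand  length chain_sequence
#> 1       109     138 forward     30 TCTGCTATAGGATAATAATTGGTAGATTAC
```

The unique best hit recovers the planted register at position 112 with
22/24 agreements; widening by 3 bp on each side maps base pairs 109–138
and substitutes the actual sequence back in. The random-match odds of that
24-base profile with two free positions are 1 in 55,738.

Profile deformability and rank a window:

```r
tab    <- read_tetramer_table(system.file("extdata",
            "synthetic_tetramer_table.tsv", package = "minicircle"))
prof35 <- kmer_profile(step_values(ref, tab), k = 35)
rank_region(prof35, center = which.max(prof35$score))
#>   center score frac_above frac_below  rank n_tied
#> 1     74  5.37          0      0.998     1      1
```

The most deformable 35-mer of this reference centres on position 74
(top 0 %, rank 1 of 601); the profile baseline — the mean deformability of
all 601 steps — is 4.30 deg³·Å³ for this synthetic table.

Rebuild the superhelix demonstration chains and read their handedness:

```r
handedness(rebuild_helix(helix_preset("fig-s4-a")))
#>   handedness mean_torsion n_axis_points smooth_window
#> 1 right           -0.0219            37            10
handedness(rebuild_helix(helix_preset("fig-s4-c")))$handedness
#> [1] "left"
```

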