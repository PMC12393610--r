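---
title: "Methods: register mapping, deformability profiling, step geometry and motif scanning on circular DNA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: register mapping, deformability profiling, step geometry and motif scanning on circular DNA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minicircle)
```

This vignette documents the models and procedures the package implements,
the conventions it fixes where the underlying methods literature leaves a
choice open, and what its synthetic-data generators do and do not emulate.

## Coordinates and circularity

All positions are 1-based and all intervals inclusive; on a circular
sequence of length $L$, position $L$ is followed by position 1 and windows
may wrap through the origin. Wrapping windows are reported in *wrap
notation* (`start > end`). The `circular_sequence` container carries an
`origin_label` naming the numbering convention, because register
assignments are only meaningful relative to a declared origin. How to
number an alignment that crosses the origin is not standardised anywhere we
know of; we adopt wrap notation rather than inventing a renumbering.

## R/Y register mapping

A cryo-EM map frequently resolves base *shape* (purine vs pyrimidine)
before base identity. The mapping model is deliberately minimal: a
density-derived profile is a string over $\{R, Y, X\}$, where $X$ marks a
base whose density supported neither call. The sequence side is the exact
two-letter reduction $A,G \to R$; $C,T \to Y$.

**Scanning.** `ry_scan()` compares the profile to every start position of
the circular reference (all $L$ of them, both strands). The reverse-strand
comparison uses the reversed, R/Y-complemented profile against the forward
reference string, and reports the forward-strand position aligned with the
profile's 5'-most symbol after reversal — the reporting convention had to
be fixed by us, and is stated in the function documentation.

**X semantics.** An $X$ is compatible with both $R$ and $Y$ but consumes
the same tolerance budget as a mismatch: a hit requires
$n_\text{mismatch} + n_\text{unresolved} \le f$. This makes the tolerance
budget mean "positions at which the profile did not confirm the sequence",
which is also what the analytic probability below counts, so observed hits
and their probabilities stay mutually consistent.

**Random-match probability.** For a fixed profile of length $n$ and budget
$f$, the chance that a uniformly random R/Y string matches at a given
offset is exactly
$$p(n, f) \;=\; 2^{-n} \sum_{i=0}^{f} \binom{n}{i}.$$
The complementary "1 in $N$" form uses $N = \operatorname{round}(1/p)$;
rounding to the nearest integer is the only convention that reproduces
both published odds denominators for the $(24, 2)$ and $(30, 2)$ cases at
once. Note $p$ is a per-offset probability; across a circular reference of
length $L$ scanned on both strands the expected number of random hits is
$2 L p$, an identity the test suite checks empirically over 200 seeded
replicates.

**Ties and uniqueness.** All minimal-budget hits are reported; a
`unique_best` attribute records whether exactly one hit attains the
minimum. Nothing is silently dropped — ambiguity is a result, not an
error.

**Palindromes.** Reverse-complement palindromes are necessarily
even-length, so the finder expands symmetrically around each of the $L$
inter-base gaps and reports the maximal palindrome per gap when it reaches
`min_len`. Maximality (not extensible on either side) is what the centred
expansion yields by construction; the exhaustive all-substrings oracle in
the tests confirms the equivalence. On circles the expansion radius is
capped at $\lfloor L/2 \rfloor$ so a fully palindromic circle is reported
once per register rather than infinitely.

## Deformability profiling

Each base-pair step is assigned a deformability value $V_\text{step}$
(units deg³·Å³) by its tetramer context — the step plus one flanking base
pair on each side. Published tables derived from high-resolution structure
surveys supply the 136 reverse-complement-unique values; the loader closes
such tables under reverse complementation and **refuses** tables whose
reverse-complement pairs disagree rather than averaging them, because
silent averaging hides transcription errors in user-supplied data. The
numeric values themselves are user-supplied inputs: the package ships only
a clearly-labelled synthetic example table
(`inst/extdata/synthetic_tetramer_table.tsv`) to document the format.

Conventions fixed here, since "the tetramer at a step" admits an offset
ambiguity: step $i$ sits between base pairs $i$ and $i+1$ (mod $L$) and
reads positions $i-1 \dots i+2$, first flank 5' on the reference strand. A
circular sequence therefore yields exactly $L$ step values.

**Windows.** The $k$-mer score at centre $c$ is the mean of the $k-1$
steps *internal* to the $k$ base pairs spanning
$c - \lceil k/2 \rceil + 1 \dots c + \lfloor k/2 \rfloor$ — internal
steps is the minimal reading of "steps within the segment", and excludes
the two boundary-straddling steps. For odd $k$ the window is symmetric
($k = 35$ spans $c \pm 17$); for even $k$, $\lceil k/2 \rceil$ of the
positions sit at or before the centre, a choice pinned down by requiring
the $k = 2$ profile to equal the step series itself. Two exact identities
follow and are tested: the profile mean equals the step-series mean (each
step lies in exactly $k-1$ windows), and rotating the sequence rotates the
profile.

**Percentiles.** "Top $X\,\%$" is the fraction of window scores *strictly
greater* than the queried score; "bottom" the strictly-smaller fraction;
ties are reported separately (`n_tied`) and rank counts ties once. On a
uniform profile every centre is simultaneously top 0 % and bottom 0 % with
$n_\text{tied} = L$ — the semantics are documented rather than hidden.

These window scores describe how deformable the *individual steps inside*
a window are on average; they are not the physical deformability of the
$k$-mer as a unit, and averaging necessarily dampens extremes as $k$
grows.

## Step conformation and the 3-D rebuild

**Classification.** $z_P$ (mean out-of-plane phosphorus $z$ in the step
frame) separates B ($z_P \le 0.5$ Å) from A ($z_P \ge 1.5$ Å) with an
explicit intermediate class between. $z_P(h)$ (helical-axis projection of
the inter-strand phosphorus vector) separates B ($< 4$ Å) from TA
($> 4$ Å); the published criteria are strict on both sides and leave
exactly 4 Å unassigned, so we assign the boundary to B and say so. The
overwound C-like pattern is representable in rebuild presets but is never
emitted as a $z_P$ class, since it does not occur in the complexes this
toolkit targets. These descriptors are *consumed* from helical-analysis
software output (`read_step_table()`); computing them from atomic
coordinates is that software's job and out of scope here.

**Melted pairs.** A base pair is melted when any of Shear, Stretch,
Stagger, Buckle, Propeller, Opening leaves its closed acceptance interval.
The survey-derived intervals of the structural literature are not shipped;
`default_bp_ranges()` provides package defaults documented as such, and
any serious analysis should pass its own ranges.

**Rebuild.** `rebuild_helix()` uses the standard mid-step-triad
convention: with $\Gamma = \sqrt{\text{Tilt}^2 + \text{Roll}^2}$ and
$\phi = \operatorname{atan2}(\text{Tilt}, \text{Roll})$, the relative
rotation is $R_z(\omega/2 - \phi)\, R_y(\Gamma)\, R_z(\omega/2 + \phi)$
and the displacement (Shift, Slide, Rise) is applied in the mid-step triad
(rotation split half before, half after). The inverse
(`step_parameters()`) extracts the Euler $z$-$y$-$z$ factorisation and
canonicalises Twist into $(-180°, 180°]$; the paired branch
$(\omega \mp 360°, \phi + 180°)$ generates the same rotation, and
canonicalising keeps round-trips exact (tested to $10^{-8}$ against an
independently coded hinge/bisector extraction). Degenerate steps
($\Gamma \to 0$) reduce to pure twist about the local $z$ axis.

**Handedness.** The superhelical sense of a rebuilt axis is measured on
the base-pair origins after *two* passes of a centred moving average of
`smooth_window` (default 10 bp, about one helical turn). One boxcar pass
leaves a residual wiggle at the double-helix period whenever the window
does not divide the helical repeat exactly, and that residue can dominate
— and flip — a pointwise torsion sign; the second pass (equivalently, a
triangular kernel) suppresses it. On the smoothed polyline we accumulate
the signed dihedral angle between successive osculating planes (the
discrete torsion) and compare its mean against a dead band of
`tau_min = 1e-3` rad/step; a straight axis gives exactly zero.

The sign-to-label mapping follows the DNA supercoiling convention:
inserting *underwound* A-like stretches produces an axis of negative
Frenet torsion, and that is precisely the geometry the field calls a
**right-handed (negative) superhelix** — the solenoidal counterpart of
negative supercoiling. So mean torsion below $-\tau_\min$ is labelled
`right`, above $+\tau_\min$ is `left`. The demonstration chains (55 bp,
alternating 5-bp stretches of ideal B with A-like or C-like inserts, step
$i$ taking the stretch label of base pair $i$) give opposite labels under
every smoothing window from 8 to 12 bp, which the acceptance tests assert.

## Motif scanning

Scores are plain additive lookups of the supplied 4×W weight matrix: the
published motif weights already define sign (positive = fits the motif),
and the exact transformation used to derive them varies between motif
papers, so the package scores whatever matrix it is given and leaves any
log-odds or background transformation to the user. Window anchoring aligns
the PWM's centre column with the stated reference position; even widths
round the centre toward 5'. `split_pwm()` copies columns verbatim into the
first+core / core / core+second sub-matrices (widths 83/36/83 for the
130-column 47/36/47 motif), and `positive_near_center()` uses an
inclusive ±radius window under circular distance (default ±5 bp).

## Synthetic data: what it does and does not emulate

The generators exist so that every pipeline is exercised end-to-end with
known ground truth and a single integer seed:

* `synth_sequence()` draws i.i.d. bases at a requested expected GC
  fraction and can overwrite one window with a realization of an R/Y
  profile carrying an exact number of mismatches at seeded-random
  positions. Defaults (601 bp in the examples, GC 0.5) mirror a
  minicircle-sized, compositionally unbiased substrate.
* `synth_tetramer_table()` draws reverse-complement-symmetric values
  uniformly on an interval — it reproduces the *format and symmetry* of
  published deformability tables, not their values or their correlation
  structure (real tables are far from i.i.d. across tetramers).
* `synth_pwm()` builds matrices with a known consensus and a guaranteed
  global maximum.

Consequences for interpretation: passing tests demonstrate algorithmic
correctness (oracle equivalence, exact identities, recovery of planted
signal at the matched budget), not biological claims. Real minicircle
sequences have dinucleotide and codon-level composition the i.i.d. model
lacks; real deformability landscapes are smoother and multi-modal; real
motifs have correlated columns. Analyses of real systems must supply the
published tetramer table and motif PWM as inputs.

## Problem sizes and numerical tolerances

The test suite runs brute-force oracle comparisons on references up to
64 bp, exhaustive palindrome enumeration at 200 bp, 200-replicate
planted-recovery and expected-hit-count experiments at 150–200 bp, and
round-trip frame/parameter recovery on chains of 12–30 steps; these sizes
make every oracle exact while keeping the whole suite near half a minute.
Orthonormality of rebuilt triads is enforced to $10^{-9}$, parameter
round-trips to $10^{-8}$, and the probability identities are exact in
double precision (they are ratios of integers below $2^{31}$ over powers
of two).

## Known limitations

* Density-side base calling (deciding R vs Y vs X from a map) is manual,
  upstream, and out of scope; the package starts from the called profile.
* Linear (non-circular) step series lose their two terminal tetramer
  contexts (`NA`), and window profiles are defined only for circular
  series.
* `handedness()` assumes a solenoidal, roughly uniform superhelix; a
  plectonemic or strongly irregular axis would need a writhe-based
  treatment.
* The "melted" defaults are package conventions, not survey values.
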