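---
title: "Locating exons by period-3 wavelet energy: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating exons by period-3 wavelet energy: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wavexon)
```

## The signal model

Coding DNA is organised in codons, and the three codon positions have
systematically different base compositions. Writing the sequence as a
numeric signal therefore produces, inside exons, a deterministic component
with period 3 — equivalently, a spectral line at ω = 2π/3 radians/sample —
superimposed on compositional noise. Introns, lacking codon structure,
contribute only the noise. Exon detection reduces to estimating, at every
position, how much local signal energy sits at 2π/3.

wavexon's estimator is a chain of five linear/quadratic steps:

1. **Numeric mapping.** Each base is replaced by its electron–ion
   interaction potential (EIIP): A = 0.1260, G = 0.0806, T = 0.1335,
   C = 0.1340 (dimensionless, Rydberg scale). One real channel carries the
   whole record, as opposed to the four binary indicator channels of a
   one-hot encoding; the EIIP values are unequal across bases, so codon
   bias translates into a period-3 mean structure. The table is
   configurable; any injective assignment works, differing only in
   per-composition gain.
2. **Band-pass.** A zero-phase band-pass centred on 2π/3 suppresses the
   compositional baseline (DC), low-frequency GC structure and
   out-of-band noise before the energy estimate.
3. **Wavelet decomposition.** A multilevel discrete wavelet transform
   (Mallat pyramid) splits the filtered signal into octave bands. At unit
   sampling rate the level-1 detail band spans (π/2, π], which contains
   2π/3 ≈ 2.09; after band-passing, essentially all retained energy falls
   there. We use Coiflet-5, a compactly supported orthogonal wavelet with
   many vanishing moments, whose smooth, near-symmetric filters produce a
   clean energy envelope; any orthogonal wavelet of comparable support
   behaves similarly (Daubechies-4 and Haar are built in for comparison).
4. **Energy profile.** Selected coefficients are squared and mapped back to
   sequence coordinates (details below), then smoothed.
5. **Thresholding.** The profile is normalized per sequence to [0, 1] and
   maximal runs ≥ threshold become candidate exons, after gap merging and
   minimum-length filtering.

The key assumptions are: exons are long enough (≳ 100 nt) for a narrow-band
energy estimate to stabilise; the period-3 contrast between exons and
introns dominates other narrow-band structure; and one normalization scale
per sequence is adequate (calls are relative to the strongest exon of that
record).

## Parameters and defaults

| parameter | default | units | rationale |
|---|---|---|---|
| band-pass centre | 2π/3 | rad/sample | the codon frequency |
| band-pass width | 0.04π | rad/sample | ≈ 50 nt energy correlation length: narrow enough to reject background, wide enough that a 150 nt exon holds several independent energy samples |
| band-pass design | order-4 Butterworth, forward–backward | — | zero phase, so peaks are not displaced; measured response: ≥ 0.9 power retention at 2π/3, ≤ 1e-4 at DC. A centred linear-phase FIR design (unit-gain–renormalized at 2π/3) is available |
| wavelet, levels | coif5, 2 | — | see step 3 above; level 2 adds robustness to slow envelope drift while level 1 carries the band of interest |
| boundary mode | symmetric | — | reflection minimises edge artefacts on exons near record ends |
| energy source | detail levels | — | the 2π/3 band lives in the details after band-passing; the approximation band holds only residual baseline |
| energy smoothing window | 101 | nt | averages the squared narrow-band amplitude over roughly ⅔ of the shortest exon the caller keeps; the raw squared signal ripples at twice the carrier frequency and, through the 0.04π band-pass, has ≈ 50 nt correlation length, so shorter windows leave the exon plateau noisy |
| denoiser | moving average, window 51 | nt | below the minimum exon length; removes residual ripple. Alternatives: normalized-LMS adaptive line enhancer (`mu` = 0.05, 16 taps) predicting the correlated component of the profile from its own past, and universal-threshold wavelet shrinkage |
| call threshold | 0.35 | fraction of per-sequence max | the lowest threshold at which the worked benchmark metric tables reach perfect scores |
| min region length | 50 | nt | real exons shorter than ~50 nt are rare; shorter runs are ripple artefacts |
| merge gap | 20 | nt | dips narrower than the smoothing scale within one exon plateau are artefacts |
| segment overlap rule | 0.5 | fraction of exon | an exon "found" when calls cover at least half of it |
| noncoding units | n_exons + 1 | segments | the gaps between and flanking the truth exons, the natural segment-level negative class |

All of these live in one nested configuration (`default_config()`, YAML via
`load_config()`); unknown keys are rejected, and every CLI run writes the
fully resolved configuration next to its outputs.

## Numerical choices

**Boundary handling and energy conservation.** The extension modes
(symmetric, zero, periodic) follow the conventional redundant layout: a
level with n inputs yields ⌊(n + L − 1)/2⌋ coefficients per band (L = 30
for Coiflet-5). Reconstruction is exact in every mode (residuals at the
1e-15 level, asserted at 1e-8 relative error in tests), but the redundant
boundary coefficients mean Parseval's identity holds only approximately. A
fourth mode, `periodization`, implements the circular, exactly orthogonal
transform (n/2 coefficients per band, length divisible by 2^levels) and is
the configuration under which the energy-conservation property is asserted
exactly. The pipeline default stays symmetric: genes are not circular, and
reflection avoids wrap-around artefacts.

**Coefficient-to-position mapping.** A level-l coefficient spans 2^l
positions. The energy profile spreads each squared coefficient uniformly
over its span (value /2^l), after trimming the boundary-padding
coefficients symmetrically so that the retained core aligns with the
sequence. Uniform spreading is the least-commitment choice; any smooth
interpolation is washed out by the subsequent smoothing window.

**Peak positions and the carrier ripple.** The squared 2π/3 carrier ripples
with a 6 nt period on the upsampled coefficient grid, so the raw argmax of
an energy profile can snap between ripple crests. Shift covariance
therefore holds for the profile as a whole (a 3 nt input shift moves the
profile, measured by its cross-correlation peak, by 3 ± 1 nt at default
smoothing) even when the argmax alone jumps by 0 or 6. Tests measure
displacement accordingly.

**Ties and degenerate inputs.** Thresholding is inclusive (≥), so ties are
deterministic. An all-zero profile cannot be normalized and raises a
degenerate-input error rather than returning NaNs. Metrics with zero
denominators are reported as `NA` ("undefined"), never silently as 0 or 1;
the complement identities error rate = 1 − accuracy, FDR = 1 − positive
precision and FOR = 1 − negative precision hold exactly whenever both sides
are defined (negative precision is always the literal ratio TN/(TN+FN)).
`N` bases map to the mean EIIP value (0.118525) with a warning by default;
a strict mode aborts with the offending position. Records shorter than
support × 2^levels (120 nt at the defaults) are skipped with a warning
rather than failing a whole multi-record run.

**ROC construction.** One (FPR, TPR) point per threshold at the chosen
granularity, anchored at (0,0) and (1,1), integrated by the trapezoid rule
after sorting by FPR. With thresholds at every distinct profile value and
inclusive thresholding, the nucleotide-level AUC coincides with the
Mann–Whitney statistic; the test suite checks this equivalence against a
brute-force pair count at 1e-9.

**Coordinates.** Intervals are 0-based half-open everywhere inside the
package; conversion happens only at format boundaries (BED is native; GFF3's
1-based closed [s, e] becomes [s−1, e)). Overlapping intervals are merged on
construction. Analysis is single-strand; minus-strand annotations are
rejected outright rather than silently reverse-complemented.

## The synthetic generator

`generate_gene()` emulates the alternating exon/intron architecture of a
eukaryotic gene. Introns — including a leading and a trailing one, so a
gene with k exons has k + 1 noncoding units — are drawn i.i.d. from a
background with configurable GC fraction. Exon positions are drawn from
three codon-position-specific distributions obtained by linear mixing
between the background and a fixed biased profile (position 1 G-rich,
position 2 A-rich, position 3 pyrimidine-rich): mixing weight 0 gives exons
statistically identical to introns; weight 1 gives the full bias and a
strong period-3 line. Defaults — 5 exons of 150–300 nt, introns of
200–400 nt, codon bias 0.8, GC 0.5 — describe a compact gene with moderate,
realistic codon bias; the recovery tests run 20 such replicates and the
suite as a whole uses genes of roughly 1–3 kb, sizes at which every test
completes in seconds.

What the generator does **not** emulate: splice-site motifs, codon usage of
any particular organism, length distributions of real introns (often much
longer), and the long-range 1/f correlations of real genomes. Passing the
recovery tests therefore demonstrates that the pipeline finds
codon-position composition bias planted on an i.i.d. background at the
stated strength — not that it matches any published per-gene accuracy on
real accessions. On real data the background is harder: 1/f noise leaks
into the band-pass, and weak or short exons fall below the per-sequence
threshold more often than the synthetic figures suggest.

`period3_strength()` is the independent check on all of this: a
sliding-window Fourier score (squared magnitude at 2π/3 of the four base
indicator tracks, summed, per window) that shares no code with the wavelet
path. Its closed-form extremes — W/3 for an exact period-3 repeat, 0 for a
homopolymer when the window is a multiple of 3 — anchor the oracle itself,
and ranking agreement between oracle and pipeline is asserted on instances
where the top decile of positions is commensurate with the planted exon.
(With exons covering several deciles, both methods place their whole top
set inside exon plateaus and the comparison degenerates into ranking noise
within flat regions, which says nothing about either method.)

## Design choices that were genuinely open

* **Which coefficients carry the signal.** Detail levels by default (the
  band-passed signal has no energy elsewhere); configurable to
  approximation or all bands for exploratory use.
* **The "adaptive" denoiser.** Three structures are provided behind one
  switch. The moving average is the default because on profiles that are
  piecewise-constant plus ripple it is the best-behaved and the cheapest;
  the LMS line enhancer adapts its own coefficients (hence "adaptive") and
  is useful when the noise floor drifts along the sequence; wavelet
  shrinkage is natural when exon plateaus vary on several scales at once.
* **Per-sequence normalization.** Scaling by each record's own maximum makes
  the 0–1 threshold scale comparable across genes of very different overall
  signal strength, at the cost that a single dominant exon can push weaker
  exons of the same record below threshold. A pooled normalization would
  behave oppositely; per-sequence matches the per-gene evaluation the
  package reports.
* **Segment-level negatives.** "How many noncoding things were there to get
  wrong" has no canonical answer; we count the gaps between and flanking
  the truth exons, which makes specificity fall by one unit per spurious
  call, and expose the count as a parameter (`noncoding_units`).

## Known limitations

Boundary placement is resolution-limited: calls localise exons to within
the smoothing scale (~50–100 nt), not to the splice site. Exons shorter
than about the smoothing window are attenuated and may be missed at the
default threshold. Genes whose exons differ greatly in bias strength suffer
from per-sequence normalization (see above). The detector reads only
composition periodicity: reading frames, ORF integrity and strand are out
of scope.
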