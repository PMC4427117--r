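# wavexon

Protein-coding regions (exons) of eukaryotic genes carry a periodicity that
introns lack: because synonymous codon positions have different base
compositions, coding sequence shows excess spectral power at the angular
frequency 2π/3 radians/sample (a period of 3 nt). **wavexon** turns that
period-3 signature into exon calls:

1. **EIIP mapping** — each base is replaced by its electron-ion interaction
   potential (A = 0.1260, G = 0.0806, T = 0.1335, C = 0.1340), giving one
   real-valued signal per sequence.
2. **Band-pass at 2π/3** — a zero-phase (forward–backward) order-4 IIR
   band-pass of width 0.04π isolates the codon frequency without displacing
   peaks.
3. **Discrete wavelet transform** — a multilevel Mallat decomposition
   (Coiflet-5, 2 levels by default) localises the band energy in position;
   squared detail coefficients, mapped back to sequence coordinates, form a
   per-position energy profile.
4. **Denoise, normalize, threshold** — the profile is smoothed (moving
   average by default; an LMS adaptive line enhancer and wavelet shrinkage
   are available), scaled to [0, 1] by its per-sequence maximum, and maximal
   runs above a threshold (default 0.35) become predicted exons after gap
   merging and minimum-length filtering.

The package also contains the full evaluation suite — segment- and
nucleotide-level confusion counts, the eight derived metrics (sensitivity,
specificity, accuracy, positive/negative precision, error rate, FDR, FOR),
ROC/AUC over threshold sweeps, and a coding/noncoding SNR in dB — plus a
synthetic gene generator with tunable codon-position bias and an independent
sliding-window Fourier period-3 oracle, so everything is testable without
downloading any accession.

It is aimed at people working on genomic signal processing: the whole
pipeline is exposed as composable, pipe-friendly functions over tibbles, and
a command-line interface covers the common predict / evaluate / roc /
simulate workflows.

## Worked example

Generate a synthetic three-exon gene (codon-position bias 0.8), run the
default pipeline, and score the calls:

```r
library(wavexon)

g <- generate_gene(n_exons = 3, exon_length_range = c(150, 300),
                   intron_length_range = c(200, 400),
                   codon_bias = 0.8, seed = 42)
g
#> <wx_gene> synth_seed42: 1936 nt, 3 exon(s), codon_bias 0.80, seed 42

scan <- detect_exons(g$sequences)
tidy(scan)
#> # A tibble: 3 × 4
#>   sequence_id  start   end label
#>   <chr>        <int> <int> <chr>
#> 1 synth_seed42   249   521 predicted
#> 2 synth_seed42   893  1078 predicted
#> 3 synth_seed42  1481  1677 predicted
```

The three called regions sit inside the three planted exons
([248, 542), [836, 1104), [1454, 1709)). Scoring at the segment level —
an exon counts as found when calls cover at least half of it:

```r
tidy(compute_metrics(segment_confusion(scan$regions, g$exons)))
#> # A tibble: 8 × 2
#>   metric               value
#> 1 sensitivity              1
#> 2 specificity              1
#> 3 accuracy                 1
#> ...

roc_curve(scan$profiles, g$exons)
#> <wx_roc> nucleotide-level ROC, 19 thresholds, AUC = 0.9960

snr_db(scan$profiles, g$exons)
#> [1] 6.99
```

All three exons are recovered with no false calls; the normalized energy
profile separates coding from noncoding positions almost perfectly
(AUC 0.996), with mean in-exon energy ~7 dB above the intron background.
`autoplot(scan, truth = g$exons)` overlays the profile, the calls and the
truth.

The EIIP mapping itself is exposed directly:

```r
map_eiip("TTCACTAGCA")$value
#>  [1] 0.1335 0.1335 0.1340 0.1260 0.1340 0.1335 0.1260 0.0806 0.1340 0.1260
```

## Command line

A thin wrapper is installed with the package
(`system.file("scripts", "wavexon", package = "wavexon")`):

```sh
wavexon simulate --out gene --seed 7 --codon-bias 1      # gene.fasta + gene.bed
wavexon predict  --out calls.bed gene.fasta              # exon calls (BED)
wavexon evaluate --out report calls.bed gene.bed         # metrics TSV + JSON
wavexon roc      --out roc.tsv gene.fasta gene.bed       # ROC table, AUC
```

Every run writes its fully resolved configuration next to the output;
parameters come from a YAML config (`--config`) with CLI flag overrides.
Exit codes: 0 success, 1 usage/config error, 2 data error, 3 internal.

## Scope and limitations

Single-strand analysis only; no reading-frame assignment or splice-site
refinement of boundaries. The synthetic generator plants codon-position
composition bias on an i.i.d. background — it does not emulate splice
motifs or long-range (1/f) correlations of real genomes. See the methods
vignette (`vignettes/period3-wavelet-detection.Rmd`) for the model,
parameter choices and their rationale.
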