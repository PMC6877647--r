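# m6Aribo

Transcript-level analysis of **N6-methyladenosine (m6A) in coding
sequences** and its consequences for translation, for researchers working
with MeRIP/m6A-seq, ribosome profiling, RNA-seq and RNA structure probing
data on a common transcript coordinate system.

CDS methylation sits at the crossroads of two opposing effects: an m6A in
the ribosomal A site delays decoding (a localized pause), while the same
modification destabilises local mRNA secondary structure and thereby *helps*
elongation globally. Quantifying both requires a consistent chain of
analyses, which this package implements end to end:

* **POM/POI peak calling.** For 50-nt windows sliding in 25-nt steps,
  POM = mean(window) / median(transcript); IP windows with POM > 3 that are
  not matched by input enrichment are merged into clusters, scored with
  POI = POM_IP / POM_input, and kept at POI > 3. Summits, nearest-RRAC m6A
  residues (R = A/G), replicate intersection, regional classification with
  start/stop exclusion zones, and knockdown sensitivity (POI drop ≥ 50%)
  included.
* **Translation efficiency.** TE = RPKM_footprint / RPKM_mRNA with an
  RPKM ≥ 1 filter, k-nearest-neighbour non-methylated controls matched on
  baseline density (K = 3, ±10%), per-group fold-change ECDFs and Wilcoxon
  rank-sum tests.
* **Ribosome dynamics.** A-site metagene profiles over −60..+60 nt around
  methylated codons (per-region normalization, < 20-read exclusion), pause
  scores at the −15-nt 5′-end offset, codon-resolved pausing,
  upstream/downstream density ratios, and condition-contrast detection of
  pausing regions (30-nt/3-nt scan, fold change > 3 = Inc, < 1/3 = Dec).
* **Secondary structure.** Sliding-window MFE (30/3) through ViennaRNA's
  `RNAfold` or a built-in base-pair-maximization fallback,
  dinucleotide-preserving Eulerian shuffles with MFE z-scores, GC profiles,
  icSHAPE-like reactivity aggregation around anchors, and Gini indices.
* **Conservation.** Lifting peak summits through pairwise one-to-one
  ortholog alignments and labelling peaks conserved/non-conserved.
* **Synthetic data.** A seed-deterministic generator that plants m6A sites,
  IP enrichment, A-site dwell, structured pausing spans and reactivity
  contrasts with full ground truth, so the whole pipeline is testable
  without downloads.

## Worked example

```r
library(m6Aribo)

p <- sim_params(n_transcripts = 10, n_methylated_sites = 6, seed = 42)
sim <- simulate_transcriptome(p)
reps <- lapply(1:2, function(r) {
  tr <- simulate_merip_tracks(sim$txs, sim$truth, p, "ctrl", r)
  call_peaks_all(tr$ip, tr$input, sim$txs)
})
peaks <- intersect_replicates(reps)
print(peaks, digits = 3)
#>   transcript_id cluster_start cluster_end summit m6a_residue pom_ip pom_input
#> 1        tx0001           675         775    730         727   4.48      1.07
#> 2        tx0002           525         625    582         584   4.45      1.09
#> 3        tx0003           800         900    852         854   4.75      1.01
#> 4        tx0004           450         550    496         493   4.56      1.03
#> 5        tx0005           275         375    319         325   4.84      1.01
#> 6        tx0006           325         425    372         372   5.07      1.07
#>    poi region
#> 1 4.17    CDS
#> 2 4.09    CDS
#> ...
```

All six peaks reproduce across both replicates; each cluster's POI ~4–5
(IP enrichment over a matched input of POM ≈ 1) and every assigned m6A
residue lands on or next to a planted site (`sim$truth$sites`: 727, 572,
854, 493, 325, 372). Ribosome pausing at those sites is read off the
metagene:

```r
rb <- simulate_ribo_track(sim$txs, sim$truth, p)
anchors <- data.frame(transcript_id = sim$truth$sites$transcript_id,
                      pos = sim$truth$sites$codon_start)
pause_score_at_a_site(metagene_profile(rb, anchors))
#> 3.75
```

i.e. footprint density at the −15-nt 5′-end offset (the methylated codon in
the A site) is ~3–4× the in-frame flank background, reflecting the planted
3-fold dwell at this small sample size. And a designed stable hairpin is a
clear structural outlier against its dinucleotide-shuffle null:

```r
mfe_zscore("GGCAGUCCAUAGCAUGAAAAUGCUAUGGACUGCC", seed = 4)$z
#> -12.25
```

A thin command-line front end over the same functions lives in
`inst/cli/m6aribo.R` (subcommands `simulate`, `model`, `callpeaks`, `te`,
`metagene`, `pause`, `structure`, `conserve`).

## Documentation

The methods vignette (`vignettes/m6Aribo-methods.Rmd`) describes the model
and every numerical decision: coordinate conventions, the caller's
tie-breaks and degenerate cases, frame-matched pause backgrounds, shuffle
construction, folding backends, and what the synthetic generator does and
does not emulate.
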