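---
title: "Methods: CDS m6A, ribosome pausing and mRNA structure in m6Aribo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CDS m6A, ribosome pausing and mRNA structure in m6Aribo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(m6Aribo)
```

# Scope and coordinate conventions

m6Aribo analyses N6-methyladenosine (m6A) in mRNA coding sequences and its
consequences for translation, working entirely in *transcript* coordinates:
every transcript is a linear sequence with a 5′UTR, a CDS and a 3′UTR given
by a half-open CDS span. Internally all coordinates are 0-based half-open;
every file writer states its convention in a header line. Sequences are
normalised to the RNA alphabet (`T` → `U`) at load time, so DNA- and
RNA-form inputs are equivalent.

When a gene has several isoforms, one representative is chosen: the isoform
with the longest CDS, ties broken by the longest transcript, remaining ties
lexicographically by transcript id. The last tie-break is ours (any rule
works; this one is deterministic).

Positions are classified as 5′UTR / CDS / 3′UTR, except inside the
start-codon zone (−15..+100 nt around the first CDS nucleotide) and the
stop-codon zone (−100..+15 nt), which are excluded from region-level m6A
analyses because peak density there reflects initiation/termination
artefacts rather than internal methylation. The stop zone is anchored on the
*last* nucleotide of the stop codon; the anchor base is not dictated by the
analysis itself, so it is documented here and both zones are parameters.
Both zones are closed intervals — with zones given to ±1 nt precision the
inclusive reading is the natural one, and the boundary choice moves a
handful of positions at most.

# The POM/POI peak caller

MeRIP/m6A-seq yields an IP (antibody-enriched) and an input library per
sample. For each transcript, a 50-nt window sliding in 25-nt steps is
scored, for windows whose maximum coverage exceeds 10 reads, with a
**peak-over-median** score:

POM = mean(window coverage) / median(whole-transcript coverage).

IP windows with POM > 3 are candidates; any candidate overlapping (≥ 1 nt)
an input window that itself has POM > 3 is discarded (local artefacts
enriched in both libraries). Survivors are merged into maximal overlapping
clusters, POM is recomputed over the *full cluster span* in both libraries,
and their ratio is the cluster's **peak-over-input** score; clusters with
POI > 3 become peaks. The summit is the IP-coverage argmax (leftmost on
ties) and the m6A residue is the adenosine of the RRAC motif (R = A/G)
nearest the summit, the upstream one on distance ties.

Numerical decisions, all configurable:

* The transcript median includes zero positions. A transcript whose median
  is 0 has no finite POM and is skipped (reported, not silently dropped);
  pseudo-counts would make the score depend on sequencing depth.
* Cluster POI recomputes POM over the merged span rather than reusing any
  single window's score: the cluster is the unit being reported, so it is
  the unit being scored.
* All thresholds are strict inequalities ("higher than").
* Only full-length windows are emitted (no clipped trailing window), keeping
  window statistics comparable along the transcript.
* Input elimination is overlap-based by default; a transcript-wide mode is
  available (`input_filter = "transcript"`).

Peaks are kept only if reproduced (cluster overlap ≥ 1 nt) in *every*
biological replicate; the reported coordinates are replicate 1's. A
wild-type peak whose POI drops by ≥ 50% after knockdown of a methylation
writer (METTL3/WTAP-type experiment) is flagged *sensitive* — evidence the
enrichment reflects genuine methylation. A wild-type peak with no
overlapping knockdown cluster is treated as fully lost (knockdown POI 0),
hence sensitive.

# Translation efficiency and matched controls

Ribosome density per transcript is the footprint RPKM
(10⁹ · count / (length · library size)); translation efficiency (TE) is
footprint RPKM over mRNA RPKM, with transcripts below RPKM 1 in either assay
excluded. Because CDS methylation concentrates on lowly translated mRNAs, a
plain methylated-vs-rest comparison confounds basal TE with methylation
status; instead each methylated transcript is matched to up to K = 3
non-methylated transcripts whose baseline density lies within ±10%, ranked
by closeness, and the control level is their mean. Matching is on wild-type
TE by default (raw footprint RPKM is available); if fewer than K candidates
fall inside the band, those that do are used — discarding a target is only
necessary when *no* candidate exists. Between-condition TE fold changes are
compared between groups with Wilcoxon rank-sum tests (two-sided and both
one-sided), with empirical CDFs returned for cumulative-fraction plots.

# Ribosome dynamics

Footprints are represented by their 5′-end counts. With the A site ~15 nt
downstream of the 5′ end, a dwell at a codon appears at offset −15 when
profiles are anchored at the codon's first nucleotide — which is why the
metagene anchor for pause analysis is the methylated codon's first
nucleotide rather than the adenosine itself (anchoring at the A would shift
the peak by the codon phase).

The metagene averages per-region *normalized* densities over −60..+60 nt:
each region is divided by its own total so deep transcripts do not dominate;
regions with fewer than 20 reads are excluded as too noisy to normalise.
The A-site pause score divides the profile value at −15 by the mean over
flank offsets (−60..−30 and +30..+60). Because 5′-end counts are 3-nt
periodic, the background is restricted by default to flank offsets in the
same reading frame as the A-site offset; an all-offset background would
count structurally empty out-of-frame positions and inflate the score about
threefold. This frame matching is our choice (the underlying profile leaves
the background definition open) and can be disabled.

Pausing regions between conditions are found by scanning 30-nt windows in
3-nt steps: per window and condition, (window sum + 0.5 pseudo-count)/30,
normalised by that condition's mean CDS density; the knockdown/control ratio
above 3 labels the window *Inc*, below 1/3 *Dec*. The 0.5 pseudo-count
stabilises ratios in sparse windows (with `pseudo = 0` fold changes are
exactly scale-invariant, and the scan is oracle-checked both ways).
Overlapping same-label windows are merged for reporting, keeping the extreme
fold change; raw windows are also returned. Each region's structure score is
the mean 30/3 sliding-window MFE over its span.

# Secondary structure

Sliding MFE profiles use 30-nt windows in 3-nt steps, aligned at window
centres. Folding is pluggable: the ViennaRNA `RNAfold` binary when available
(thermodynamic energies in kcal/mol), otherwise a built-in
base-pair-maximization folder (Watson–Crick + G:U, minimum hairpin loop 3,
−1 per pair). All conclusions drawn in the tests are backend-agnostic —
signs, orderings and calibrations, never absolute energies.

The structural null for a sequence is built from 30 shuffles that preserve
its exact dinucleotide composition, generated by an Eulerian-path
(Altschul–Erickson-style) shuffle; naive swap-based shuffling does not
conserve dinucleotides and would confound stacking content with structure.
Dinucleotide conservation is asserted as a hard invariant on every output.
The z-score is (native − shuffle mean)/shuffle sd, undefined (NA) when the
shuffles are degenerate (e.g. homopolymers).

Methylated regions for structure/reactivity contrasts span −400..+100 nt
around the methylated codon; non-methylated RRAC adenosines of the *same*
transcripts provide the control spans, which cancels transcript-level
covariates. icSHAPE-like reactivities live in [0,1] with missing values as
`NA`, never 0 — probing data cannot distinguish "unreactive" from
"unprobed", so the two must not be conflated. Aggregation is a positionwise
mean ignoring missing values, with per-region means for group tests, and the
Gini index (mean absolute difference / 2·mean, computed from the sorted
closed form) summarises reactivity inequality within a region.

# Conservation

Cross-species comparison consumes precomputed pairwise alignments of
one-to-one orthologs (aligned FASTA; running the aligner is out of scope).
Peak summits are lifted through alignment columns — strictly monotone where
defined, `NA` when the column is a gap in the partner — and a peak is
*conserved* when a partner-species summit lies within ±25 nt of the lifted
position. The 25-nt default is half the calling window: peaks from 50-nt
windows cannot be meaningfully matched at single-nucleotide identity;
`tolerance = 0` restores strict same-column matching. Peaks on transcripts
without a one-to-one ortholog are excluded rather than labelled.

# The synthetic-data generator

`sim_params()` fixes the study conditions; the seed fully determines every
track. The generator emulates, per transcript of Gamma-distributed relative
abundance:

* **MeRIP**: negative-binomial input counts (mean `background_mean` = 20
  reads/nt at unit abundance, dispersion 0.1); IP counts multiply the local
  mean by a triangular kernel peaking at `ip_enrichment` = 8 over each
  planted site with half-width 50 nt (the simplest unimodal shape with a
  well-defined summit, mirroring the 50-nt calling window).
* **Ribo-seq**: multinomial allocation of ~`mean_footprints` reads over CDS
  codons with dwell weights: `pause_factor` = 3 at methylated codons; a
  4-fold block over codons at and ≤ 15 nt upstream of structured spans in
  the condition where that span impedes elongation. The 5′ end of each read
  sits 15 nt upstream of its codon, matching the analysis convention
  (configurable for robustness tests).
* **Knockdown**: scales the *excess* IP enrichment and the *excess* m6A
  dwell by `kd_enrichment_scale` = 0.3, and methylated transcripts'
  footprint totals by `kd_te_scale` = 0.75 (a 25% TE loss).
* **Reactivity**: Beta draws with mean 0.4, elevated to 0.6 over methylated
  regions (−400..+100), emulating the methylation-linked single-strandedness
  contrast.

Planted m6A sites are written as `GGAC` with the adenosine at codon position
2, at in-frame CDS positions outside the exclusion zones. Structured spans
are GC-rich 10-bp hairpins planted in the CDS; the knockdown pause is
applied *at and slightly upstream of* the span so that detected Inc windows
coincide with the structured sequence, which is what the downstream
Inc-vs-Dec MFE contrast measures. A second class of plain-sequence spans is
paused in the *control* condition only ("relief" regions): they emulate
regions whose ribosome occupancy drops after knockdown and guarantee that
the Dec class is populated — a single paused codon can change a 30-nt window
by at most ~30%, never below the 1/3 threshold, so Dec regions cannot arise
from loss of a one-codon pause alone.

What the generator does *not* emulate: read-level errors and mapping
ambiguity, splicing, isoform mixtures, codon-usage-dependent elongation,
sequence-dependent MeRIP fragmentation bias, or any coupling between
structure and the reactivity track beyond the planted region contrast.
Passing the recovery tests therefore demonstrates the *pipeline's*
correctness on data matching its model assumptions, not robustness to every
artefact of real libraries.

# Validation problem sizes

The recovery checks run at sizes chosen to give stable statistics on a
single CPU: peak recovery on 50 transcripts with 30 planted sites and 2
replicates; the pause metagene on 200 methylated codons with ~10⁵
footprints; the pausing scan on 40 transcripts with 20 structured and 20
relief spans; shuffle invariance over 1000 random sequences with a 200-draw
z-score null; TE shift detection with 120 methylated transcripts against
kNN-matched controls. Oracle-equivalence checks (caller and pausing scan
against brute-force nested-loop reimplementations) run on random transcripts
up to 0.5–1 kb.

# Known limitations

* The caller is threshold-based (as is the analysis it implements); it
  assigns no statistical significance to peaks.
* Transcripts whose coverage median is 0 are unscoreable by POM and are
  skipped; extremely uneven coverage can likewise inflate POM.
* The base-pair-maximization fallback folder ranks structures by pair count
  only; absolute values are not energies, so only comparisons within one
  backend are meaningful.
* Position lifting assumes the supplied pairwise alignment is correct;
  alignment errors propagate directly into conservation labels.
* With very short CDSs the exclusion zones can cover the entire CDS, leaving
  no usable m6A positions; the generator refuses such geometries rather
  than silently bending them.

# A worked micro-example

The 31-nt structural fragment of the MALAT1 non-coding RNA (transcript
coordinates 2556–2586) contains exactly one RRAC motif; its adenosine is the
well-characterised methylation site at position 2577:

```{r malat1}
fragment <- "AACUUAAUGUUUUUGCAUUGGACUUUGAGUU"
2556 + find_rrac_sites(fragment)
```

A minimal end-to-end run on synthetic data:

```{r pipeline, eval = FALSE}
p <- sim_params(seed = 42)
sim <- simulate_transcriptome(p)
reps <- lapply(1:2, function(r) {
  tr <- simulate_merip_tracks(sim$txs, sim$truth, p, "ctrl", r)
  call_peaks_all(tr$ip, tr$input, sim$txs)
})
peaks <- intersect_replicates(reps)
head(peaks)
```
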