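---
title: "Methods: synthetic iCLIP, peak calling and 3'UTR motif statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic iCLIP, peak calling and 3'UTR motif statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`crosslinkr` reconstructs, as reusable and tested code, the computational
core of an iCLIP-based characterization of an RNA-binding protein (RBP) that
recognizes uridine-rich sequences in mRNA 3'UTRs, together with the
morphometric analysis used to quantify the downstream dendritic phenotype.
Because the analysis pipeline must be verifiable without access to a real
sequencing run, the package is built around a synthetic-data generator with
complete ground truth: every statistical claim the pipeline makes can be
checked against what was actually planted.

# The truncation model and crosslink events

In iCLIP, reverse transcription stalls at the crosslinked (protein-bound)
nucleotide, so the cDNA's 5' end sits one nucleotide 3' of the contact site.
The generator and the caller share this convention exactly:

* a simulated signal molecule crosslinked at position $p$ yields an insert
  starting at $p + 1$;
* `call_crosslink_events()` infers the crosslink as `start - 1` from each
  placed read.

Reads carry a 5' barcode of 3 random + 4 sample + 2 random nucleotides, a
standard iCLIP layout; the 5 random positions form the unique molecular
identifier (UMI). PCR duplicates are collapsed by exact identity of
(transcript, position, sample, UMI); `unique_count` is the number of
distinct UMIs per position. Collapse uses exact UMI matching, not
edit-distance clustering — adequate for error-free synthetic reads, and a
deliberate simplification flagged for real data (sequencing errors inflate
unique counts slightly). Reads whose insert maps at transcript position 0
would imply a crosslink at $-1$; they are dropped and counted, since the
upstream coordinate does not exist in transcript space.

Read placement is by unique exact substring match over the transcript set
(Biostrings `PDict`). This is not an aligner: it is the appropriate
idealization for error-free reads, and multi-mapping inserts are discarded
(conservative CLIP practice) rather than fractionally assigned so that truth
checking stays exact.

# What the generator emulates — and what it does not

One sequence per transcript is simulated in *unspliced* transcript
coordinates: 5'UTR, CDS (optionally split by an intron), 3'UTR for
protein-coding transcripts; noncoding exons and an intron for lincRNAs
(10% of transcripts). This gives every feature class of the crosslink
distribution a home without needing a genome model.

Defaults were fixed once, from the experiment the package emulates:

* **3'UTR lengths**: log-normal, median 1.99 kb for designated RBP targets
  and 0.72 kb for the background — the reported medians for bound versus
  unbound mRNAs. `sdlog = 0.6` gives a realistic right tail.
* **PCR duplication**: each unique molecule is emitted
  $1 + \mathrm{Poisson}(\mu - 1)$ times with $\mu = 3.5$, matching an
  average duplicate rate below 4 with a single interpretable parameter.
* **Planted motif**: 2 uridine-rich sites per target 3'UTR, lengths 10–20 nt,
  each base U with probability 0.9 (so all sites have ≥ 80% U content in
  expectation and the motif is a genuine U run). Signal crosslinks fall
  uniformly *within* planted sites.
* **Seed sites**: miRNA targets receive the exact 7mer-A1 site of the
  configured miRNA (default miR-128-3p, site `ACUGUGA`); half of the RBP
  targets are also miRNA targets, so the bound set genuinely overlaps the
  seed-bearing set.
* **Depth and purity**: 200,000 total reads, 75% of unique molecules signal.
  Background molecules crosslink uniformly along transcripts with
  expression weights drawn log-normally (`sdlog = 1`), emulating the broad
  dynamic range of expression.
* **Base composition**: i.i.d. uniform A/C/G/U by default, configurable to
  stress-test motif statistics.

Not emulated: sequencing errors, splice-isoform mixtures, genome-coordinate
mapping, crosslink-induced mutations, and library-size/read-length
distributions of any particular sequencing run. Passing tests on synthetic
data therefore demonstrate the *correctness of the computations under the
stated generative model*, not robustness to alignment noise or annotation
ambiguity in real data.

# Peak calling

Per transcript, the score of a candidate position (any position with ≥ 1
unique event, samples pooled) is the unique-event count within
$\pm(w-1)/2$ for window width $w = 15$. The null scatters the transcript's
total unique events uniformly over its length and records the maximal
windowed score, using the same scanning rule as the observed statistic; the
empirical p-value is $(1 + \#\{\text{maxima} \ge s\}) / (1 + n_{perm})$.
Benjamini–Hochberg correction is applied *pipeline-wide across all candidate
windows* so that the target set is controlled by a single interpretable FDR;
significant positions closer than $w$ merge into peaks, with the leftmost
maximal-score position as summit.

**Why `n_perm = 1000`.** The empirical p-value cannot go below
$1/(n_{perm}+1)$. With tens of thousands of candidate windows tested
pipeline-wide, the BH threshold for the strongest candidates is roughly
$\alpha \cdot (\text{discoveries}) / (\text{candidates})$ — of order
$10^{-3}$ at typical depth. At 100 permutations the attainable floor
($\approx 10^{-2}$) sits *above* that threshold and no window can ever be
significant; 1000 permutations put the floor comfortably below it. The
permutation count is therefore not a precision luxury but a structural
requirement of pipeline-wide FDR control. (Null calibration itself is
insensitive to this choice and is tested at 100 permutations as well.)

The target universe is all annotated transcripts — the synthetic
transcriptome has no unexpressed genes. For real data an expression filter
would be required before interpreting the unbound group.

# 3'UTR motif statistics

* `count_kmer()` counts **overlapping** occurrences (a 9-U run contains
  three `UUUUUUU`), the naive occurrence semantics; a non-overlapping mode
  exists behind a flag. The poly-U proxy for the binding motif is fixed as
  the exact homopolymer `UUUUUUU`.
* The 7mer-A1 site is the reverse complement of miRNA positions 2–7
  followed by `A`; 7mer-m8 and 8mer site types are deliberately not counted.
* Bound/unbound comparisons are reported on two scales: per-3'UTR counts
  (which confound motif content with UTR length) and per-kilobase densities
  (which do not). Both use a hand-implemented Welch t-test
  (Welch–Satterthwaite degrees of freedom), cross-checked in the test suite
  against `stats::t.test` to $10^{-10}$.
* Set-overlap enrichment between the called target set and seed-bearing
  transcripts uses the exact hypergeometric upper tail with the full
  annotated transcriptome as universe (the universe is a reported field, as
  the choice materially affects the p-value).
* The positional nucleotide profile is computed from events *inside called
  peaks*, weighted by unique counts, over windows fully contained in the
  transcript; out-of-range windows are skipped and counted.
* The seed-proximity test asks whether binding sites sit nearer to seed
  sites than chance: the unit is the *peak summit* (one value per binding
  site, avoiding the pseudo-replication of correlated per-read distances),
  the statistic the median absolute distance to the nearest seed-site start
  within the same 3'UTR, and the null re-places the same number of positions
  uniformly within the same 3'UTRs.

# Sholl morphometry

Reconstructions are polylines in SWC format. Profiles are computed on the
XY projection (z discarded), matching analysis of maximum-intensity
projections; radii default to 10–350 µm in 10 µm steps (35 radii). A
segment crosses radius $r$ iff its endpoint distances to the soma straddle
it: $d_{near} < r \le d_{far}$ — the standard one-crossing-per-segment
convention, with tangential contacts counted via the half-open test.

The arbor generator grows segments whose direction always stays within 60°
of the outward radial direction, so the distance to the soma increases
monotonically along every segment. Under monotone growth the endpoint
straddle test is *exact* (a segment cannot dip below a radius and re-emerge),
which is what lets the test suite demand exact equality against a
dense-resampling crossing counter on random arbors. Real reconstructions can
contain re-entrant segments; for those the straddle convention counts one
crossing per straddling segment, the common choice of Sholl implementations
on polyline data.

Group comparison mirrors the usual presentation: omnibus two-way ANOVA
(group × radius, neurons as replicates), per-radius two-sample t-tests with
Bonferroni correction across the radii grid, and mean ± s.e.m. per radius.
When both groups are constant at a radius (e.g. beyond both arbors) the
per-radius p is defined as 1 for equal means.

# Numerical and design choices

* Coordinates are 0-based half-open everywhere in tables; BED output keeps
  transcript-space positions with strand `+`.
* All sequence matching happens in DNA alphabet (U→T on input, T→U on
  display).
* One top-level seed is fanned out per stage by a fixed affine map into
  32-bit range, so stages are independently reproducible and a run is
  fully determined by its configuration (hashed into the report).
* Summit ties break leftmost; BH is `stats::p.adjust(method = "BH")`;
  the Mann–Whitney U test for UTR lengths uses the normal approximation
  (`exact = FALSE`) since tied lengths are expected. The rank test itself is
  a package choice — the original figure does not name its test — and is
  labelled as such in the output.
* Problem sizes in tests and the acceptance script (500 transcripts /
  200,000 reads for recovery; 200 transcripts / 40,000 reads for null
  calibration; 200 repeats for p-value calibration; 100 random arbors for
  the Sholl oracle) were chosen as the smallest sizes at which the studied
  effects are unambiguous, and are stated in the respective scripts.

# Known limitations

* Exact-match placement cannot model mismatches/indels; mapped fractions on
  real data would be far below the synthetic ~100%.
* Exact-UMI collapse slightly overcounts unique molecules under sequencing
  error.
* The permutation null assumes within-transcript positional exchangeability
  of background events; real iCLIP background has positional biases
  (e.g. toward expressed exons) that this null does not capture.
* The seed-proximity permutation inherits the same exchangeability
  assumption within 3'UTRs.
* `welch_t_test` on heavily discrete low counts (near-empty UTRs) is
  approximate; the density scale with adequately long UTRs is the intended
  use.
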