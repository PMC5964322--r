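# crosslinkr

Characterizing the mRNA interactome of an RNA-binding protein (RBP) from
iCLIP data — and verifying every step against ground truth.

iCLIP experiments map protein–RNA contacts at nucleotide resolution: reverse
transcription truncates at the crosslinked base, so the contact site is one
nucleotide 5' of each cDNA's start, and random barcodes (UMIs) introduced
during reverse transcription distinguish unique molecules from PCR copies.
`crosslinkr` implements the complete downstream analysis for an RBP that
binds uridine-rich motifs in 3'UTRs, the regime where such a protein
intersects miRNA regulation:

* **Synthetic-data generator** — transcript models (5'UTR/CDS/intron/3'UTR,
  lincRNAs), sequences with planted U-rich motifs and miRNA 7mer-A1 seed
  sites, multiplexed reads with a 3+4+2 nt random/sample/random barcode,
  truncation at the crosslink, and Poisson PCR duplication — with full
  ground truth for parameter-recovery testing.
* **Crosslink-event calling** — demultiplexing, exact-match read placement,
  UMI-based duplicate collapse, crosslink position = insert start − 1.
* **Peak calling and target derivation** — per-transcript windowed scores
  (w = 15 nt) against a permutation null (uniform re-scatter of the
  transcript's unique events), empirical p-values, pipeline-wide
  Benjamini–Hochberg FDR, peak merging and summits; bound transcripts are
  those with ≥ 1 significant peak.
* **Feature statistics** — crosslink distribution over transcript features,
  and the bound-vs-unbound 3'UTR length comparison (medians in kb,
  Mann–Whitney U).
* **Motif and seed statistics** — overlapping k-mer counts and per-kb
  densities per 3'UTR (poly-U heptamer `UUUUUUU`; miRNA 7mer-A1 sites, e.g.
  `ACUGUGA` for miR-128-3p), Welch two-sample t-tests on both scales, exact
  hypergeometric set-overlap enrichment, crosslink-centered positional
  nucleotide profiles, and a permutation test for binding-site proximity to
  seed sites.
* **Sholl morphometry** — SWC reconstruction parsing, planar intersection
  profiles (radii 10–350 µm, step 10 µm), and group comparison via two-way
  ANOVA with Bonferroni-corrected per-radius t-tests.

A bundled panel of ten conserved mature miRNAs (`mirna_panel()`) supports
seed-match profiling across tissue-representative miRNAs.

## Worked example

```r
library(crosslinkr)

config <- run_config(rng_seed = 1)   # 500 transcripts, 100 true targets,
report <- run_pipeline(config)       # 200k reads, PCR duplication mean 3.5
print(report)
```

```
run_report (config 1de695e8, seed 1)
  reads: 199686 total, 199460 mapped
  unique CEs: 55839 (duplication ratio 3.57)
  peaks: 200; bound transcripts: 102/500
  3'UTR CE fraction: 0.823
  target recall 1, precision 0.98
```

Reading this: of ~200k reads, UMI collapse leaves ~56k unique crosslink
events (PCR duplication ratio 3.57, matching the configured mean 3.5); 102
transcripts carry significant peaks, recovering all 100 truly motif-bearing
transcripts with 2 false positives (recall 1.0, precision 0.98); 82% of
unique events fall in 3'UTRs, within 0.001 of the generator's truth. The
report also carries the 3'UTR length medians (bound ≈ 1.8 kb vs unbound
≈ 0.67 kb, rank-test p ≈ 1e-30), the poly-U density enrichment in bound
UTRs (Welch p ≈ 1e-19), the overlap between the bound set and
seed-bearing transcripts (fold 1.66 over chance, hypergeometric
p ≈ 1e-7), the central uridine frequency of the crosslink-centered profile
(0.89), and the seed-proximity permutation p (0.71 — no proximity bias, as
expected when motifs and seeds are planted independently).

Individual stages are ordinary functions (`simulate_transcriptome()`,
`demultiplex()`, `call_peaks()`, `profile_utrs()`, `sholl_profile()`, ...)
usable on their own; `inst/scripts/run-pipeline.R` is a command-line wrapper
around the pipeline.

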