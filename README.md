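# foldscan

Discovery and downstream analysis of locally folded, potentially functional
secondary-structure motifs in mRNAs.

Long transcripts are mostly unstructured, but short elements — IRES
domains, hairpins that occlude miRNA sites, protein-binding stem-loops —
can dominate post-transcriptional regulation. `foldscan` slides a fixed
window (default 70 nt, 1-nt step) along a transcript, folds every window
with a bundled nearest-neighbor thermodynamic engine (Zuker MFE +
McCaskill partition function), and standardizes each window's stability
against mononucleotide-shuffled controls:

    z = (ΔG°_native − mean ΔG°_random) / σ

where σ is the population SD over the native plus randomized energies.
Negative z marks sequence *ordered to fold* — more stable than its own
composition predicts. Per-window MFE pairs are then combined into
z-score-weighted consensus base pairs (per-nucleotide competition by
z-sum, mutual selection, strict z-avg cutoffs at −1/−2), filled in by
constrained refolding (maximum pair span 300 nt), and grouped into motifs
with tetraloop annotation and comparison against the unconstrained global
fold. Companion stages classify structural conservation across a sequence
alignment (consistent / compensatory / disruptive mutations), score miRNA
target-site accessibility as ΔΔG = ΔG(duplex) − ΔG(open) with 70-nt
flanks, and analyse dual-luciferase translational-efficiency assays
(TE = RRR / 2^(−ΔΔCt), Welch t-tests). Seeded synthetic-data generators
make every stage testable offline; an enumeration oracle certifies the
folding engine exactly at small sizes. See `vignettes/foldscan-methods.Rmd`
for the model, conventions and limitations.

## Worked example

A 300-nt random background with one designed 12-bp hairpin (stem at
nt 140–167), scanned and passed through the consensus stage
(`analysis/02_motif_discovery.R`):

```r
library(foldscan)
em  <- embed_motif(synthetic_motif_spec(
         length = 300, inserts = list(list(position = 140, stem = 12,
                                           loop = "GAAA")), seed = 2026))
res <- run_pipeline(em$seq, pipeline_config(window = 70, n_randomizations = 100,
                                            seed = 7, out_dir = "results/demo"))
```

prints (timings vary):

```
scan: 231 windows; z range [-5.45, 1.99], mean -0.81
most negative window starts at nt 129 (z = -5.45) - it overlaps the insert
cutoff_-1: 41 bp called, 12/12 designed pairs recovered, 29 outside the design
cutoff_-2: 20 bp called, 12/12 designed pairs recovered, 8 outside the design
fill-in added 2 bp; 2 motifs
global-model overlap: 91% of motif pairs appear in the unconstrained fold
tetraloops: GAAA ( GNRA )
```

Reading this: the designed hairpin owns the scan's minimum z-score (−5.45,
about five SDs more stable than composition-matched shuffles) and every
designed pair is recovered at both cutoffs. The pairs called outside the
design sit on chance fold-ordered background regions and stack extensions —
see the vignette's discussion of why an i.i.d. random background is not a
specificity gold standard at cutoff −1 (the −2 cutoff removes most of
them). The accessibility stage on the same miR-34a seed site in three
contexts (`analysis/04_accessibility.R`):

```
open    dG(duplex) -19.57  dG(open)  -0.00  ddG -19.57 kcal/mol
partly  dG(duplex) -19.57  dG(open)  -0.29  ddG -19.28
locked  dG(duplex) -19.57  dG(open)  -8.73  ddG -10.84
```

burying the site in a stem charges an opening penalty, raising ΔΔG (less
accessible), while the duplex term is context-independent.

The numbered scripts under `analysis/` run the full set of studies (null
calibration, motif discovery, covariation, accessibility, reporter TE) and
write their tables under `results/`.

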