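---
title: "Methods: window scanning, z-score-weighted consensus structure, and downstream analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: window scanning, z-score-weighted consensus structure, and downstream analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foldscan)
```

# The question the package answers

Long mRNAs are mostly unstructured, but short, locally folded elements —
IRES domains, miRNA-site-occluding hairpins, protein-binding stem-loops —
can dominate post-transcriptional regulation. The package asks, for every
position of a transcript: *is the local sequence more thermodynamically
stable than its own composition predicts?* Sequence that folds more stably
than shuffled controls is "ordered to fold" and a candidate functional
element. Around this core the package carries a motif from discovery through
comparative, accessibility and reporter-assay evidence.

# The thermodynamic model

## Energy function

Structures are nested sets of canonical pairs (AU, UA, GC, CG, GU, UG) with
a minimum hairpin loop of 3 nt. The free energy of a structure is a sum over
its loops:

* **stacks**: Watson–Crick/Watson–Crick stack free energies are the
  published Turner 2004 dinucleotide values (kcal/mol, 37 °C); stacks
  involving a GU wobble are approximated by class (−1.4 for one wobble,
  −2.1 next to a GC, −0.5 for tandem wobbles);
* **hairpin, bulge and internal loops**: length-only initiation penalties
  with Jacobson–Stockmayer (`1.75·RT·log`) extrapolation beyond the
  tabulated sizes; interior loops larger than 30 unpaired nt are
  disallowed, following standard practice;
* **multibranch loops**: linear model `a + b·branches + c·unpaired` with
  `a = 3.4`, `b = 0.4`, `c = 0.4` kcal/mol;
* exterior bases are free. There are no terminal-mismatch, dangling-end or
  coaxial-stacking terms.

This deliberately compact parameterization keeps every quantity checkable by
exhaustive enumeration (below) while behaving like a realistic folding
model: a 12-bp GC-rich stem-loop scores ≈ −25 kcal/mol, a random uniform
70-mer ≈ −13 ± 4. For fidelity runs the fold step can delegate to an
installed ViennaRNA `RNAfold` binary (`backend = "vienna"`); all published
whole-transcript numbers in this field depend on the exact Turner
parameterization, so reproduction of such numbers requires that backend.

## Algorithms and their certification

MFE folding is a Zuker-style dynamic program; ensemble quantities come from
a McCaskill partition function with an inside–outside pass for base-pair
probabilities, both over the same unambiguous grammar. Derived metrics:
ensemble diversity `ED = Σ 2·p(1−p)` (the expected base-pair distance
between two independent ensemble draws — the paper-style "structural
diversity" defined here explicitly), `fMFE = exp(−ΔG_MFE/RT)/Z`, and the
centroid = all pairs with `p > 0.5` (exactly; ties at 0.5 are excluded).

The engine is certified against an **independent enumeration oracle**:
every nested structure of sequences up to 14 nt is generated
combinatorially and scored by explicit loop decomposition in R, sharing
only the parameter tables with the C++ DP. MFE energies agree to 1e−15 and
pair probabilities to ~1e−10 over hundreds of seeded sequences (the
acceptance suite re-runs 500).

Numerical choices: energies are doubles in kcal/mol; the Boltzmann sums are
unscaled, which is safe to roughly 500 nt at 37 °C (the package's analyses
fold ≤ ~300-nt contexts); MFE traceback resolves energy ties
deterministically, preferring the maximally stacked, then 5′-most
decomposition, so identical inputs give byte-identical structures. Hard
constraints (forced pairs, forced-unpaired, maximum pair span) are honored
by the MFE fold; in the partition function a forced pair is soft — the two
positions may only pair with each other — which is the semantics used
everywhere the ensemble is constrained here.

# The scan stage

Defaults: 70-nt window, 1-nt step, 100 mononucleotide shuffles per window
(50 in the test suite and acceptance runs, which keeps the suite in minutes;
the window/step defaults are the method's standard settings). Each window
records ΔG°, the z-score, the empirical P-value, ED, fMFE, the MFE and
centroid structures, base frequencies and GC%.

The z-score is

$$z = \frac{\Delta G^\circ_{native} - \overline{\Delta G^\circ}_{random}}{\sigma}$$

with σ the **population** standard deviation over the native energy plus
all randomized energies. Including the native energy in σ is unusual but is
the stated convention of the method this package implements; a randoms-only
mode (`sigma_mode = "randoms"`) is provided for sensitivity analysis. When
σ = 0 (e.g. homopolymer windows) z is defined as 0 and flagged. The
P-value counts randomized sequences *strictly* more stable than native —
ties count against significance. Each scan consumes one seeded generator
window-by-window, so a scan is a pure function of (sequence, parameters,
seed); every shuffle is asserted to conserve the window's base composition.

Calibration, recomputed by `analysis/01_null_calibration.R` and the
acceptance suite: over 200 independent random 70-mers the mean z is ≈ 0
(|mean| well under 0.1) and P-values are uniform (KS p ≈ 0.9). Note the
mean-z check at n = 200 has a Monte-Carlo SE of ≈ 0.07, so it is a coarse
gate by construction.

# The consensus stage

Per-window MFE pairs are tallied per nucleotide in transcript coordinates;
each candidate (partner j, or unpaired) accumulates an occurrence count and
the sum of the z-scores of its supporting windows. The calling rules:

1. per nucleotide, the candidate with the most negative **z-sum** wins
   (ties prefer unpaired, then the smaller partner index);
2. a pair is emitted only when both ends select each other (mutuality);
3. crossing conflicts among mutual winners are resolved greedily by the
   more negative z-sum; losers are demoted to unpaired, never to a
   second-choice partner;
4. emitted pairs carry `z_avg = z_sum / n_windows`, and the cutoff filter
   (defaults −1 and −2, strict `<`) applies to `z_avg`.

z-sum decides the competition while z-avg decides the filter: the first
mirrors the "most favorable arrangements when weighting by z-score" output,
the second the average-z semantics used for motif coloring and cutoffs.
The greedy crossing resolution is deterministic and auditable; it is not a
global maximum-weight guarantee, and the original tool's exact competition
rules are published only in outline, so whole-transcript pair counts are
reproduction targets only under a matched backend and algorithm.

Retained pairs seed a **constrained refold** of the full sequence with a
maximum pair distance of 300 nt; new pairs are kept only if they stack
contiguously onto a constrained helix or fall within an existing motif span
("extending helices or closing unpaired bases"), and fill-in can never
remove or cross a consensus pair. Pairs are then grouped into motifs:
connected spans (nesting/overlap) merged across gaps of ≤ 10 unpaired nt —
the boundary rule is not stated by the source method, so 10 nt is this
package's explicit, configurable choice. Motifs are numbered 5′→3′,
compared pair-by-pair against the unconstrained global fold, and scanned
for 4-nt hairpin loops, classified UNCG > GNRA > RNYA > other (most to
least specific; `GAAA` matches GNRA before RNYA).

## What the synthetic recovery experiment shows — and what it does not

The generator embeds a perfect 12-bp GC-rich stem-loop in a 300-nt i.i.d.
uniform background. Across 20 seeded replicates the consensus at cutoff −1
recovers 100% of designed pairs; windows over the insert carry the scan's
minimum z (≈ −5). However, roughly half of all called pairs lie outside
the design. These are not an engine artifact: the shuffle null is
calibrated (above), and re-running the identical consensus code with the
full Turner model as backend produces a similar fraction. They arise
because (a) pairs stack directly onto the designed stem when flanking bases
happen to complement, and (b) a few hundred nt of random sequence
typically contains regions that are genuinely more stable than their own
shuffles (z-avg −1.3 to −2.6 sustained over dozens of windows) — the
z-score is *designed* to report such regions. A uniform random background
is therefore not a specificity gold standard at cutoff −1; the stricter −2
cutoff removes most background calls (see
`analysis/02_motif_discovery.R`). Real transcripts differ from this
background in composition, local dependence and the presence of many true
elements, so recovery rates here bound what the pipeline does on synthetic
truth, not its false-discovery rate on biological sequence.

# Covariation

Motif pairs are mapped through a gap-aware alignment coordinate map and
classified per homolog: `conserved` (identical to the canonical reference
pair), `consistent` (one side changed, pairing still canonical, GU
included), `compensatory` (both changed, pairing kept — the strongest
structural evidence), `disruptive` (non-canonical), `gapped` (excluded from
both numerator and denominator of the conservation fraction — indels are
not structural disruption). "Conserved" requires identity, not mere
canonicity, matching the mutation-centric framing of comparative figures.
A motif's conservation percent is the per-pair mean of conservation
fractions × 100; a per-homolog aggregation is exposed as an option because
published percentages rarely state which was used. The synthetic alignment
generator applies programmed category draws at non-overlapping sites, so
classifier output can be required to equal the truth table exactly — and
is, over 50 homologs in the acceptance suite.

Chemical-probing overlays count a modified (strong/weak single-strand
reactivity) nucleotide as inconsistent with a model iff it is
Watson–Crick paired (a GU wobble does not count, reflecting how probing
conflicts are assessed against helices of canonical WC pairs).

# miRNA site accessibility

For a seed match (6mer = miRNA 2–7, 7mer = 2–8, 8mer = 2–8 plus a
target-side A opposite position 1; Watson–Crick only in the seed match,
GU allowed in the duplex), the site's **footprint** extends the match
upstream by the miRNA length beyond the seed and 1 nt downstream — the
full region the miRNA could cover; an explicitly supplied interval (for
seedless sites) is its own footprint. Then

$$\Delta\Delta G = \Delta G_{duplex} - \Delta G_{open},$$

where ΔG(duplex) is the minimum hybridization energy of the whole miRNA
against the footprint (intermolecular pairs only, per-strand gaps ≤ 10 nt)
and ΔG(open) = G(ensemble of footprint ± 70 nt) − G(same with every
footprint nt forced single-stranded) ≤ 0, from partition-function free
energies (an MFE variant is available). More negative ΔΔG = more
accessible. The 70-nt flank is the method's stated setting; results are
exactly invariant to residues beyond it. The published ΔΔG values for the
reporter constructs come from an external implementation with unstated
internal parameters, so the bundled engine asserts the *ordering* of
constructs (open < locked), not the printed numbers.

# Reporter statistics

Per sample: RRR = RL/FF luminescence; ΔCt = Ct_RL − Ct_FF; ΔΔCt is taken
against the control construct's mean ΔCt (the reference grouping is a
package choice — per-assay — since raw-data layouts rarely state it);
relative abundance = 2^(−ΔΔCt); TE = RRR / 2^(−ΔΔCt), rescaled so the
control mean is 1. The chain makes TE invariant to plate-wide luminescence
factors and to transcript-abundance shifts, which the tests assert as exact
identities. Group comparisons use the two-sample unpaired Welch t-test
(Satterthwaite df, two-tailed; `*` p < 0.05, `**` p < 0.005). Worth
knowing: at triplicate scale a 3-SD effect is detected only ~68% of the
time (the suite checks the simulated detection rate against that value),
so non-significant rescues at n = 3 are weak evidence of equivalence.

# Synthetic data: scope of realism

The generators are pure functions of their seeds and emit standard formats
so the real readers are exercised. They emulate: composition-controlled
i.i.d. backgrounds, perfect embedded stems with chosen loops,
ungapped alignments with exact per-pair mutation categories, and reporter
tables whose programmed TE effects survive the normalization chain by
construction. They do **not** emulate: local compositional autocorrelation
of real UTRs, indels/gaps in alignments (gap handling is tested on
handcrafted fixtures), partial or bulged "true" motifs, correlated
replicate structure in assays, or chemical-probing noise beyond a
strong/weak/none overlay. Passing tests therefore certify the machinery
and its calibration, not performance on biological data.

# Problem sizes and runtime

Test-suite and acceptance scales: 500 enumeration-certified folds (≤ 14
nt), 200-window null calibration at 50 shuffles, 20 motif-recovery
replicates of 300 nt, 50-homolog alignments — together a few minutes on one
CPU. Whole-mRNA runs (thousands of nt, 100 shuffles) use the same code
paths and scale linearly in windows; the dense DP matrices cap practical
single-fold length at a few thousand nt.

# Known limitations

No pseudoknots anywhere (consensus, refold, or models — pseudoknotted
elements such as IRES helices that cross nested pairs are out of scope); no
dangling ends or coaxial stacking; GU stack energies are class
approximations; the partition function treats forced pairs softly; duplex
hybridization has no initiation term (only differences and orderings are
meaningful); alignment construction, homolog retrieval and covariation
E-value statistics are upstream of this package — alignments are inputs.
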