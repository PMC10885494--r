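---
title: "Detecting programmed ribosomal frameshifts from translational signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting programmed ribosomal frameshifts from translational signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

A programmed ribosomal frameshift (PRF) is a regulated ±1-nt slip of the
ribosome at a defined mRNA site. The site model implemented here combines
the signals generally thought to drive the slip:

* a **slippery motif** occupying the ribosome's E and P sites, on which the
  two bound tRNAs can re-pair after the shift;
* an internal **Shine-Dalgarno-like sequence** a few nt upstream, which
  pairs with the 16S anti-SD and pauses the ribosome;
* **downstream RNA structure** (hairpin or pseudoknot) beginning just after
  the A-site codon, which blocks forward progress;
* **codon usage** of the two possible A-site codons — a rare waiting codon
  with a more abundant shifted alternative favors slipping;
* a short **distance to the in-frame stop codon**, because annotated
  shifts cluster near the end of the upstream open reading frame.

No single signal is decisive, so candidates are classified jointly by a
3-class gradient-boosted tree model over eleven features
(`DIR, RBS1, RBS2, MOTIF, A0, A1, LF50, LF100, HK50, HK100, N`), with the
class being the shift direction (−1, 0, +1). Ground truth comes from
GenBank `join` annotations: a coding gene stored in two locations joined
within 10 nt is treated as a known frameshifted gene, with the shift at the
junction of the two fragments.

## Coordinate and geometry conventions

All internal coordinates are 1-based inclusive, the native convention of
both GenBank and R string handling; window and frame arithmetic happens in
*view coordinates* — positions on the coding strand, i.e. the genome itself
for plus-strand gene pairs and the reverse complement for minus-strand
pairs.

**Joined genes.** A joined CDS with fragment separation `d` (nt between
the fragments, in reading direction) is interpreted by `d mod 3`:
`{0,3,6,9} → −1` (backward), `{1,4,7,10} → +1` (forward); `d mod 3 = 2`,
`d > 10` (introns, inteins, mis-annotations) and `d < 0` (overlapping
fragments) are rejected. Annotation practice varies in how far from the
true slip the junction is placed, which is why the mapping uses the residue
class rather than requiring `d ∈ {0, 1}`. Rejecting `d < 0` excludes the
RefSeq convention for some viral genomes in which the two fragments share
one base — a known limitation; the training-style corpora this package
targets annotate backward shifts with `d = 0`.

**Overlap windows.** For consecutive same-strand genes A and B in
different frames, a shift out of A's frame into B's frame is tenable
between the nearest B-frame stop codon upstream of B's start and the last
base of A's in-frame stop codon. A's stop codon is located by an in-frame
walk from A's start rather than read off the annotation, because the
upstream fragment of a split join legitimately ends before its stop. B must
start no more than 10 nt past A's stop-codon end, mirroring the 10-nt join
rule. The candidate motif must lie entirely inside the window.

## The motif catalog

Ten motif classes are named by their run structure: `threethree` is
`XXXYYY` (the canonical slippery sequence without its leading base),
`fivetwo` is `XXXXXYY` (e.g. `GGGGGAA`), and so on. Adjacent runs must use
different nucleotides; non-adjacent runs and base identities are otherwise
unconstrained — observed motif instances show no positional base
limitations. Eight classes (spans 5–7 nt) describe backward shifts, and the
two short classes `four`/`three` describe forward shifts; forward
candidates additionally require the shifted A-site codon to be more
abundant than the waiting one (`A1 > A0`), without which runs of 3–4
identical bases would flood the candidate set.

Every class is anchored at the last base of the P-site codon, so
classification slides over in-frame codon boundaries and examines the
right-anchored 7-mer. Because some classes are subsets of others (every
6-run is two 3-runs at some other anchor, every 4-run contains a 3-run),
precedence goes to the class with the lowest probability of occurring in
uniform random sequence: a template of `g` runs spanning `n` nt matches
`4·3^(g−1)` of the `4^n` possible strings. Ties are broken by longer span,
then by class code. The test suite verifies the classifier against an
independent run-length-encoding oracle over all 16,384 heptamers.

## Signal features

**RBS1** re-implements a 28-bin Shine-Dalgarno scheme in the style of the
Prodigal gene caller: every contiguous submotif of `AGGAGG` of length 3–6
found in the 21 nt upstream of the E-site codon is binned by match score
and spacer class (3–4, 5–10, 11–12, 13–15 nt from motif end to the E-site
codon start), and the best bin wins; the full motif at 5–10 nt spacer
scores 27. Only the exact-match bins are assigned; the bins that the
original scheme reserves for single-mismatch variants of the 6-mer are left
unassigned, which narrows score resolution slightly but preserves the 0–27
range and ordering of exact matches.

**RBS2** is a max-over-table score in the style of the RAST annotation
server's RBS scorer. The empirical motif-frequency weights of that scorer
are not redistributable, so the package ships a *synthetic* table
(`inst/extdata/rbs2_weights_synthetic.tsv`): exact and one-mismatch
submotifs of `AGGAGG` weighted by match length and a spacer-size factor
peaking at 5–8 nt, capped at the documented 6.3 maximum. The table is a
plain TSV (`motif`, `spacer_size`, `weight`) and can be replaced by any
empirically derived table with the same columns.

**Folding.** `LF*` uses a thermodynamic nearest-neighbor fold (ViennaRNA's
`RNAfold`); the `HK*` columns are defined by a pluggable pseudoknot-engine
contract. No pseudoknot-capable backend is currently bundled, so both
engines resolve to the same fold and `HK50`/`HK100` duplicate
`LF50`/`LF100`; trained models record this in their metadata. The effect is
that the pseudoknot columns add no information — not that the pipeline is
invalid — and models trained in this configuration must be used with the
same engine configuration. Windows of 50 and 100 nt start 3 nt past the
P-site codon end (immediately after the A-site codon); windows truncated by
the contig end are folded and normalized at their actual length. MFE is
normalized as `clamp(−MFE / (L · max(GC, 0.01)), 0, 1)`: dividing by length
makes window sizes comparable, dividing by GC removes the strong GC bias of
MFE, the 0.01 floor keeps AT-only windows finite, and the clamp enforces
the documented [0, 1] range.

**N** counts the nucleotides strictly between the P-site codon end and the
first base of the in-frame stop codon, so a candidate whose A-site codon
*is* the stop has `N = 0`. An alternative convention measuring to the stop
codon's end was considered and rejected because it cannot represent the
boundary case as 0; the two conventions differ by a constant 3.

## Classifier

The model is a histogram-based gradient-boosted tree ensemble (xgboost:
`tree_method = "hist"`, loss-guided growth, 31 leaves, learning rate 0.1,
100 rounds, single-threaded) with L2 regularization fixed at 1.0 to damp
overfitting on repetitive corpora. Early stopping is not used and the seed
and data order are fixed, so training and prediction are fully
deterministic — two runs on the same data produce identical models. Because
several motifs can occur within one overlap, prediction keeps at most the
single highest-probability non-zero-class candidate per gene pair; ties are
broken toward smaller `N` (shifts near the stop codon are a priori more
plausible) and then the 5′-most position. Model files embed the
feature-schema and motif-catalog versions and refuse to load under a
mismatched build, since silent feature reordering would corrupt
predictions.

## Evaluation

Redundant corpora make plain leave-one-out optimistic, so validation is
grouped: GENOME (each genome its own group), MASH95, or metadata-derived
CLUSTER/SUBCLUSTER. MASH95 groups are connected components (single
linkage) of the pairwise MinHash-distance graph thresholded at 0.05
(≈95% identity), with sketch size 400 and k = 16 over canonical k-mers and
distance `d = −(1/k)·ln(2j/(1+j))` from the merged-sketch Jaccard estimate
`j`. Hashes are produced by a fixed 64-bit mixer and truncated to 53 bits
so they remain exact in R doubles. Scoring follows the 10-nt rule: a
prediction is a true positive if it belongs to a join-derived pair and its
P-site codon end lies within 10 nt of the annotated junction; false
negatives are joined genes with no such prediction; true negatives are
counted over candidate pairs (a per-gene accounting would only rescale
accuracy). With zero predictions, precision is reported as 1.0 with an
explicit flag so summaries stay total.

## The synthetic corpus generator

`fixture_spec()` / `make_corpus()` generate GenBank corpora in which every
signal of the site model is planted with known coordinates: a motif
right-anchored at a codon boundary near the upstream fragment's end, an
internal `AGGAGG` at 6-nt spacer, a GC stem-loop starting immediately after
the A-site codon, the in-frame stop `N` nt downstream, and a joined CDS
annotation whose junction is within the 10-nt tolerance of the motif.
Overlap regions are written over the T-free alphabet {A, C, G} so that
neither reading frame of the fused gene can terminate prematurely (every
stop codon contains T). Negative signal comes from planted non-joined
overlapping gene pairs whose overlap holds a motif but no hairpin or SD,
and from spurious motif hits inside true overlap windows, which are labeled
0 under the 10-nt rule.

Defaults are chosen to resemble the kind of phage corpora such models are
trained on while keeping generation fast: 30 genomes of 20 kb with 10 genes
each in 5 families; GC 0.60 (actinobacteriophage-like); one backward
`threethree` site per genome; stem length 12 bp at GC 1.0, giving 50-nt
windows a normalized MFE well separated from unstructured sequence;
`N = 33` nt, within the range reported for annotated shifts and the
smallest multiple of 3 that clears the planted hairpin; within-family
mutation rate 0.02 per base versus independent founders between families,
bracketing the 0.05 MinHash threshold so family recovery is non-trivial.

What the generator does **not** emulate: real codon-bias evolution,
sequence homology between families, pseudoknots, annotation errors, and
ambiguous bases. Passing the end-to-end tests therefore demonstrates that
the pipeline recovers the site model's signals when they are present — not
field accuracy on real genomes, which depends on how far real signals
deviate from this model.

## Numerical and degenerate-input choices

* Windows containing N never match a motif; codons containing N are skipped
  in usage counts; a CDS whose spliced length is not a multiple of 3 loses
  its trailing partial codon (logged).
* Fuzzy GenBank location qualifiers (`<`, `>`) are accepted and dropped
  with a warning; features with more than two joined segments are rejected.
* Probability ties in per-pair selection are resolved by smaller `N`, then
  position, making reports byte-reproducible.
* Folding results are cached by sequence within a session; all RNA windows
  of a genome are folded in one batch.

## Problem sizes

The test suite and the reproduction script run entirely on generated data:
the shared test corpus is 6 genomes in 2 families; the end-to-end
validation corpus is 30 genomes (20 kb, 10 genes) in 5 families, ~190
candidate sites; the motif engine is checked exhaustively over all 16,384
heptamers. These sizes were chosen so a full check of every module,
including 35 model fits for leave-one-out validation, completes in well
under a minute on one CPU while still exercising multi-family structure.

## Known limitations

* Backward-shift joins annotated with overlapping fragments (`d < 0`) are
  rejected rather than interpreted.
* Stop-adjacent forward motifs (`CUU` / `UCC` before a stop codon, as in
  bacterial `prfB`) are outside the catalog, as are motif variants defined
  through G:U pairing constraints.
* The pseudoknot feature columns currently duplicate the hairpin fold (see
  above).
* `RBS2` weights are synthetic stand-ins, ordered sensibly but not fitted
  to observed RBS frequencies.
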