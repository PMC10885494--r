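# prfscan

Detection of programmed ribosomal frameshift (PRF) sites in annotated
prokaryotic and viral genomes.

## The problem

During translation a ribosome normally advances three nucleotides at a
time. At a *slippery sequence* — canonically the heptamer `X XXY YYZ` — a
stalled ribosome can slip one nucleotide backward (−1) or forward (+1) and
continue in the new frame, bypassing the original stop codon and producing
a fusion protein. In GenBank annotations such genes appear as CDS features
with two locations linked by the `join` keyword (the classic example being
the phage tail assembly chaperone). There is no sequence-homology signature
for these sites; they are recognizable only by the convergence of several
weak translational signals.

`prfscan` scans the overlap regions of consecutive same-strand genes for
slippery-site motifs, describes every candidate by eleven translation
signals, and classifies it with a gradient-boosted tree model as backward
(−1), forward (+1), or not a frameshift:

| signal | meaning | range |
|---|---|---|
| `DIR` | direction of the candidate shift | −1, +1 |
| `RBS1` | Shine-Dalgarno bin score (Prodigal-style 28 bins) of the upstream window | 0–27 |
| `RBS2` | weighted SD-motif score (RAST-style table) | 0.0–6.3 |
| `MOTIF` | slippery-motif class code | 0–9 |
| `A0` | genome codon-usage frequency of the waiting in-frame A-site codon | 0–1 |
| `A1` | usage frequency of the shifted A-site codon | 0–1 |
| `LF50`, `LF100` | normalized minimum free energy (−MFE / (L·GC)) of the 50/100-nt window starting 3 nt past the P-site codon, hairpin engine | 0–1 |
| `HK50`, `HK100` | same windows under the pseudoknot engine contract | 0–1 |
| `N` | nt between the P-site codon end and the in-frame stop codon | 0–∞ |

Training labels come from `join`-annotated genomes: each joined gene is
split into its two fragments, re-inserted as a pseudo gene pair, and every
candidate within 10 nt of the annotated junction inherits the join's
direction. Validation is taxon-aware: leave-one-out at GENOME, MASH95
(MinHash clustering at distance ≤ 0.05, sketch size 400, k = 16), or
metadata CLUSTER/SUBCLUSTER level, so that recall is not inflated by
near-identical training genomes.

RNA minimum free energies are computed with ViennaRNA's `RNAfold`, which
must be on the PATH.

## Worked example

Everything below runs offline: the synthetic-corpus generator plants
frameshift genes with known junctions, so the whole pipeline is exercised
without downloads.

```r
library(prfscan)

spec   <- fixture_spec(n_genomes = 6, n_families = 2, seed = 11)
corpus <- make_corpus(spec)

sites <- assemble_training_set(corpus$genomes)
model <- train_prf_model(sites, seed = 1)
model
#> <prf_model> 3-class gradient-boosted frameshift classifier
#>   features: DIR, RBS1, RBS2, MOTIF, A0, A1, LF50, LF100, HK50, HK100, N
#>   training class counts: -1=9 0=38 1=0

res <- predict_genome(model, corpus$genomes[[1]])
res$predictions[, c("genome", "position", "direction", "motif_name",
                    "score", "N", "RBS1", "LF50")]
#>      genome position direction motif_name     score  N RBS1 LF50
#> 1 synF01M01     2100        -1 threethree 0.9468717 33   27  0.8
```

The single prediction is a backward (−1) shift on a `threethree`
(`XXXYYY`) motif at genome position 2100, with probability 0.95, 33 nt
upstream of the in-frame stop, a maximal upstream SD score (27), and a
strong downstream fold (LF50 = 0.8). The planted truth for this genome is
the junction at 2107 with the motif's P-site codon ending at 2105 — the
prediction sits on the planted site, inside the 10-nt tolerance. The
returned `res$record` carries the two genes merged back into one CDS with
a `join(...)` location, and `write_predictions()` / `write_genbank()` emit
the TSV report and annotated GenBank file.

The same workflows are available from a shell via the installed script:

```sh
prfscan fixtures -o corpus --seed 11 --n-genomes 6
prfscan train corpus -o model.rds
prfscan predict corpus/synF01M01.gbk --model model.rds -o out
prfscan eval corpus --level genome
```

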