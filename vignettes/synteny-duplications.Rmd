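---
title: "Detecting lineage-specific interchromosomal gene duplications"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting lineage-specific interchromosomal gene duplications}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(syntenica)
```

## The question and the method

Grass genomes retain extensive synteny: most genes still sit on the
chromosome orthologous to their ancestral location. A gene that has moved
to a different chromosome in one lineage — through a small-scale
duplication or translocation — breaks that pattern, and counting such
*non-syntenic* genes per lineage measures how actively a genome reshuffles
its gene complement. `syntenica` implements the full comparative procedure
around that count:

1. **Filtration.** Raw annotations are reduced to a comparable *core* gene
   set by four sequential filters: one representative transcript per locus
   (longest CDS; ties broken by genomic span, then transcript id),
   removal of transposable-element-related genes (annotation flag or a
   "transposon" substring in the description), removal of genes without a
   protein hit in at least one other species at e-value <= 1e-5, >= 35%
   identity and >= 35% query coverage, and removal of pseudogenes (internal
   stop, CDS length not a multiple of 3, or protein shorter than 70% of the
   best surviving homolog). Each removed gene records its first failing
   filter, so the report reproduces the sequential-count semantics.
2. **Classification.** For each core gene the best protein hit (highest bit
   score; ties by e-value, identity, then subject id) is located in every
   other species. A gene with at least one best hit inside an orthology
   block of its own chromosome is *syntenic*; a gene whose best hits all
   fall on non-orthologous chromosomes is *non-syntenic*. Because a single
   syntenic best hit suffices, the two rules partition the core set.
3. **Reclassification.** A gene can look non-syntenic merely because its
   ortholog was never annotated. Each non-syntenic gene's CDS is therefore
   searched against the genomic sequence (pseudomolecules) of the
   orthologous chromosomes; a nucleotide hit at >= 80% identity and >= 50%
   query coverage inside an orthology block flips the call to syntenic.
4. **Rates and landscapes.** The fixation rate is
   `non-syntenic / core / MY` per lineage, with the divergence time to the
   nearest compared relative. Sliding windows (gene midpoints, window
   advancing by a fixed step, last window truncated, empty windows missing)
   yield the chromosomal landscape, summarised by the Pearson correlation
   between window proportion and distance to the centromere.
5. **Selection and function.** Each gene is paired with its best hit in a
   designated outgroup; the proteins are aligned globally (BLOSUM62), the
   alignment is back-translated, and Ka/Ks is estimated by the
   Nei-Gojobori method. Fisher/hypergeometric term enrichment with
   Benjamini-Hochberg correction and Mann-Whitney / chi-squared feature
   comparisons complete the toolkit.

## Nei-Gojobori details

Synonymous sites per codon follow the convention also used by codeml's NG
implementation: each codon position contributes one site, split by the
fraction of its possible single-base changes that are synonymous, with
changes creating a stop codon excluded from the denominator. This keeps
`s + n = 3` exactly. Differences between codons are averaged over all
minimal mutational pathways with equal weights; pathways through stop
codons are excluded, and if every pathway is excluded the average falls
back to all pathways (so `sd + nd` always equals the number of differing
positions). Proportions are corrected with Jukes-Cantor,
`d = -(3/4) log(1 - (4/3) p)`, undefined at `p >= 0.75` (flagged as
saturated). Pairs with a frameshift or internal stop are rejected before
alignment, and pairs with `Ks = 0` are excluded from ratio summaries —
degenerate ratios would otherwise dominate the tails.

## The clade simulator

Real chromosome-scale annotations are far beyond a test suite, so the
package ships a generative model of everything the pipeline consumes, with
event-level ground truth. Its defaults are the study conditions and were
fixed once, up front:

* Four taxa on the fixed grass-like topology (focal lineage `taes`;
  relatives `bdis`, `osat`, `sbic` splitting 39, 54 and 60 MY ago),
  optionally extended by two homeolog lineages (6.5 MY) and a sister
  lineage (11.6 MY) for age stratification.
* Per-lineage interchromosomal duplication rates default to the published
  per-locus fixation rates (7.0e-3, 2.0e-3, 1.7e-3, 2.3e-3 events per locus
  per MY); internal branches take the mean of their descendants, since
  rates are only defined per terminal lineage.
* An event copies a locus to a uniformly chosen different chromosome. With
  probability 0.52 the ancestral copy is retained (duplication; the
  published fraction of non-syntenic genes with a surviving copy
  elsewhere), otherwise it is removed (translocation). New copies are
  pseudogenized with probability 0.10 (internal stop, 1-2 bp frameshift,
  or truncation to 50-65% of length, chosen uniformly).
* Coding sequences are 300 codons by default and evolve by per-site
  proposals at a synonymous rate of 0.005 per site per MY — grass-realistic
  synonymous divergence of roughly 0.4-0.6 at the deepest split —
  with non-synonymous proposals accepted at probability omega (0.3) and
  stop codons never created or destroyed, so the instantaneous Ka/Ks
  equals omega by construction.
* Decoys exercise the filters: 10% extra TE-annotated genes with random
  sequences, and 30% of genes carry one or two strictly shorter splice
  variants.
* Insertion positions are uniform by default; `insertion_bias` weights
  them towards chromosome ends ("distal", density proportional to the
  distance from the centre) or towards the centromere ("centromeric"),
  emulating biased retention.

A gene's *true* class applies the best-hit rule to the true copy
genealogy: its closest homolog in each other species is the copy with the
smallest divergence time on the copy tree (floored at the species split),
and a gene is also truth-syntenic when any copy of its locus — annotated
or not, pseudogenized or not — lies on the orthologous chromosome of a
compared species, since the sequence-level reclassification search would
find it. Rare coincident moves of the same locus in two lineages are
therefore classified the way the operational definition classifies them.

What the simulator deliberately does not model: TE sequence evolution
(decoys are annotation-level), indels within coding sequence, rate
variation among sites and lineages beyond the configured omega, gene loss
other than by translocation, and recombination. Passing the recovery tests
therefore shows that the pipeline's logic is correct under the generative
assumptions, not that real annotations are free of the artefacts the
filters target — that is exactly why the filters exist.

## Numerical and design choices

* Thresholds are parameters with published defaults (`scan_params()`),
  never constants; the reclassification thresholds reuse the 80%/50%
  printed for the survey-sequence search, as none are printed for the
  orthologous-chromosome search.
* The homolog length for the 70% pseudogene rule is the best hit surviving
  the homology filter.
* The built-in protein search is a word-seeded Smith-Waterman (BLOSUM62,
  affine gaps 11/1, word size 3). Its e-values use fixed Karlin-Altschul
  constants and are approximate by design; the identity and coverage
  thresholds downstream do the real filtering. Precomputed 12/13-column
  hit tables are the fidelity path for real data. The pipeline default
  raises the word size to 5 with two required seed words, a pure
  performance setting at the sequence divergences involved.
* The nucleotide search is seed-and-extend (11-mers, +2/-3, gaps 5/2),
  both strands, extending only seed clusters with at least two co-diagonal
  words, inside a window derived from the cluster's diagonal range with a
  64 bp gap allowance.
* Overlap denominators are query lengths (`"min"` available); gene
  positions are interval midpoints; coordinates are 1-based inclusive
  throughout; all stochastic steps (simulation, family representatives)
  derive from explicit integer seeds.
* Ties everywhere (isoform collapse, best hits, representatives) break
  deterministically, so identical inputs give byte-identical outputs.

## Problem sizes used by the tests

The test suite validates parameter recovery on 20 clades of 1,000 loci and
four taxa at 300-codon genes, and the landscape sign contrast on 100
position-only clades of 600 loci per bias direction; unit tests use
smaller clades (25-300 loci). These sizes give binomial standard errors
around 1-2 percentage points for the recovered non-syntenic fraction,
which is the precision at which the recovery tests assert agreement;
larger simulations change runtimes, not conclusions.

## A small worked example

```{r example, eval = FALSE}
cfg <- simulation_config(n_ancestral_genes = 300, cds_length = 300,
                         seed = 1)
sim <- simulate_clade(cfg)
scan <- synteny_scan(sim, params = scan_params(window = 1e5, step = 1e4))
print(scan)
summary(scan)

# compare the estimate with the generative truth
truth <- sim$truth
mean(truth$true_class[match(scan$calls$gene_id, truth$gene_id)] ==
       scan$calls$class, na.rm = TRUE)
```

## Known limitations

* Collinearity (conserved gene order within blocks) is intentionally out
  of scope: classification is at the level of orthologous chromosomal
  location only.
* The Fisher enrichment is the classic per-term test; graph-aware
  decorrelation of nested ontology terms (as in topGO's elim) is not
  implemented, so published graph-adjusted p-values are not comparable.
* E-values of the built-in searches are approximate; do not compare them
  across databases of very different sizes.
* The age stratification requires close-relative gene sets; with none
  supplied every non-syntenic gene remains unstratified.
* The 70% truncation rule measures against the best surviving homolog; when
  every surviving homolog of a truncated gene is itself equally truncated
  (a duplication fixed before several lineages split, then annotated short
  everywhere) the rule cannot see the truncation. This is a property of the
  published rule, not of the implementation.
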