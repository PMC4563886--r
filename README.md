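# syntenica

Synteny-based detection and characterisation of lineage-specific
interchromosomal gene duplications in comparative genome annotations.

## The problem

Grass genomes (and plant genomes generally) conserve synteny: most genes
remain on the chromosome orthologous to their ancestral location across
tens of millions of years. Genes that violate this — located on one
chromosome but with all their best homologs on non-orthologous chromosomes
of related species — mark small-scale duplications or translocations fixed
in one lineage. Quantifying them requires care: spurious gene models,
transposon-derived genes, splice variants and pseudogenes all inflate the
count, so the raw annotations must first be reduced to a comparable "core"
gene set.

`syntenica` is for comparative genomicists who have per-species gene
annotations (GFF3 + FASTA), all-vs-all protein homology (precomputed
tabular hit files, or the package's built-in seeded Smith-Waterman
search), and a chromosome-level synteny map, and who want, per species:

* a filtered **core gene set** (isoform collapse → TE removal →
  cross-species homology support at e ≤ 1e-5, ≥ 35 % identity, ≥ 35 %
  overlap → pseudogene removal at the 70 % truncation rule);
* a **syntenic / non-syntenic call** for every core gene from best-hit
  locations ("at least one best hit on a syntenic counterpart ⇒
  syntenic"), with an annotation-independent nucleotide reclassification
  against orthologous pseudomolecules (≥ 80 % identity, ≥ 50 % overlap);
* the **fixation rate** `non-syntenic / core genes / MY` per lineage, the
  statistic at the core of the package:

  rate = n_nonsyntenic / n_total / T   [locus⁻¹ MY⁻¹]

* **chromosomal landscapes**: sliding-window proportions of non-syntenic
  genes and their Pearson correlation with distance to the centromere,
  optionally stratified into recent/old relocations using close-relative
  gene sets and one random representative per duplicate family;
* **selection pressure**: Nei–Gojobori Ka/Ks on back-translated codon
  alignments against an outgroup (pathway-averaged differences,
  stop-excluded site counting, Jukes–Cantor correction, Ks = 0 exclusion),
  compared between classes with a Mann–Whitney test;
* **functional enrichment**: per-term hypergeometric (Fisher) tests with
  Benjamini–Hochberg FDR, plus class-wise feature comparisons
  (Mann–Whitney / chi-squared).

A bundled clade simulator (`simulate_clade()`) generates multi-species
genomes on a fixed grass-like topology with known duplication events,
pseudogenization, TE/splice-variant decoys and codon-level divergence at a
configurable Ka/Ks, so every stage can be validated against event-level
ground truth.

## Worked example

```r
library(syntenica)

cfg  <- simulation_config(n_ancestral_genes = 300, cds_length = 300, seed = 1)
sim  <- simulate_clade(cfg)
scan <- synteny_scan(sim, params = scan_params(window = 1e5, step = 1e4))
print(scan)
```

```
synteny_scan over 4 species
 species core_genes syntenic nonsyntenic pct_nonsyntenic divergence_my   rate
    taes        345      284          61            17.7            39 0.0045
    bdis        313      295          18             5.8            39 0.0015
    osat        305      285          20             6.6            54 0.0012
    sbic        315      287          28             8.9            60 0.0015
```

Reading this: of the focal lineage's 345 core genes, 61 (17.7 %) have all
their best hits on non-orthologous chromosomes and no sequence match on the
orthologous pseudomolecules — interchromosomal duplicates fixed since the
39-MY split — giving a fixation rate of 4.5 × 10⁻³ locus⁻¹ MY⁻¹, roughly
3× the relatives' rates, reflecting the configured per-lineage rates. On
this run the calls agree with the simulator's ground truth for 99.7 % of
core genes. `summary(scan)` adds the filtration stages and per-chromosome
centromere-distance correlations; `plot(scan)` draws a window profile.

Individual stages are exported (`collapse_isoforms()`, `remove_te_genes()`,
`homology_support_filter()`, `detect_pseudogene()`, `classify_genes()`,
`reclassify_by_genomic_search()`, `detect_duplicate_origin()`,
`stratify_age()`, `build_duplicate_families()`, `fixation_rate()`,
`sliding_proportion()`, `nei_gojobori()`, `kaks_cohort()`, `enrich()`,
`compare_features()`), and a thin command-line wrapper ships at
`inst/scripts/syntenica` (subcommands `simulate`, `run-all`, `search`,
`filter`, `rates`, `landscape`, `kaks`, `enrich`).

See the vignette (`vignettes/synteny-duplications.Rmd`) for the model, the
simulator's assumptions and all numerical choices.

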