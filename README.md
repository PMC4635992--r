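# arffam

Genome-wide characterization of auxin response factor (ARF)
transcription-factor families, as a tidy, fully reproducible R
pipeline.

ARFs sit at the core of auxin signaling in plants: they bind auxin
response elements (AuxREs, canonical core `TGTCTC`) in the promoters of
auxin-responsive genes and either activate or repress them, depending
on the amino-acid composition of the middle region (MR) between their
B3 DNA-binding domain (DBD) and C-terminal dimerization domain (CTD).
Surveying an ARF family in a newly sequenced genome is a standard,
multi-stage analysis. `arffam` implements every stage for people who
want the whole survey scripted, seeded and tested:

* **Family identification** from Pfam-style domain tables
  (PF02362/PF06507/PF02309): retain proteins with a DBD and an ARF
  domain, exclude Aux/IAA-only architectures, collapse duplicates, and
  name members after their nearest cross-species homolog.
* **Protein characterization**: deduced length (`orf_len / 3`, stop
  codon excluded), average molecular weight (residue masses + one
  water, 18.0153 Da), and isoelectric point (bisection on the
  Henderson–Hasselbalch net charge, swappable pKa sets).
* **Activator/repressor classification** from MR composition:
  activator iff `freq(Q) > freq(P) + freq(G)`, repressors split by CTD
  presence, with per-protein scores, published-call overrides, and
  family summaries (activator/repressor ratio, % CTD-truncated).
* **Gene structure**: intron counts (`n_exons − 1`) and exon–intron
  drawing tracks in transcript orientation.
* **Phylogeny**: p-distance / Poisson distances with pairwise deletion,
  deterministic Saitou–Nei neighbor joining (lexicographic
  tie-breaks, negative branches clamped), Felsenstein bootstrap
  support, cross-species sister-pair (cherry) detection, and reference
  group propagation.
* **Promoter scanning**: IUPAC-degenerate AuxRE matching (AUX1
  `TGTCTC`, AUX2 `TGTVYS`) on both strands with 0-based hit
  coordinates and per-gene summaries.
* **Expression**: 2^−ΔΔCt relative expression from long-format Ct
  tables, reference-scaled profiles, row-anchored log2 heatmap
  matrices, the 2× significance rule, abundance shares and
  tissue-specificity calls.
* **Synthetic data**: `simulate_arf_family()` generates every input
  above with a ground-truth manifest — planted domain architectures,
  MR composition classes, intron counts, cherries, AuxREs and
  expression folds — so the whole pipeline is testable offline.

Everything takes a data frame and returns a tibble, so stages compose
with the pipe; trees are `ape::phylo` objects, heatmaps have
`tidy()`/`autoplot()` methods.

## Worked example

The package ships the published summary of the 11-member papaya ARF
family. Its functional classification:

```r
library(arffam)
family_summary(papaya_arf_classes())
#>   n_activators n_repressors n_ctd_truncated n_total activator_repressor_ratio ctd_truncated_pct
#> 1            4            7               4      11                 0.5714286          36.36364
```

Four activators against seven repressors (the single DBD-only protein
counts in the repressor denominator) gives the ratio 0.57; four members
lack a CTD, i.e. 36.4 % of the family. Deduced lengths follow the
stop-codon-excluded ORF convention — `deduced_length(2814)` is 938,
`deduced_length(933)` is 311 — and the one published row that violates
divisibility by three raises a structured warning instead of rounding
silently.

Scanning a promoter for AuxREs on both strands:

```r
prom <- tibble::tibble(id = "CpETR1_prom", seq = my_1500bp_sequence)
scan_promoter(prom)
#> # A tibble: 4 × 5
#>   gene_id     motif_id start strand matched
#> 1 CpETR1_prom AUX1        80 +      TGTCTC
#> 2 CpETR1_prom AUX2        80 +      TGTCTC
#> 3 CpETR1_prom AUX1       146 -      TGTCTC
#> 4 CpETR1_prom AUX2       146 -      TGTCTC
```

(The concrete AUX1 core also satisfies the degenerate AUX2 pattern, so
both ids are reported at that offset; a `GAGACA` on the forward strand
is an AUX1 site on the minus strand.)

Relative expression from a five-replicate Ct table, scaled so the
reference gene reads 1000:

```r
ct <- simulate_ct(tibble::tibble(gene = "CpARF6",
                                 condition = c("stage1", "stage8"),
                                 level = c(1, 8)),
                  reference_gene = "CpACTIN", noise_sd = 0.2, seed = 42)
relative_expression(ct)
#> # A tibble: 2 × 5
#>   gene   condition rel_expr n_reps    sd
#> 1 CpARF6 stage1       1034.      5  224.
#> 2 CpARF6 stage8      10068.      5 3345.
ddct_fold_change(ct, "CpARF6", "stage8", "stage1")
#> [1] 9.520408
```

A full end-to-end run on a synthetic family (11 focal genes, 23 + 25
reference proteins, 27 promoters):

```r
bundle <- simulate_arf_family(seed = 1)
report <- run_arf_pipeline(bundle, arf_config(bootstrap_reps = 200, rng_seed = 1))
report
#> <arf_report> arffam 0.1.0 seed 1
#>   stages: candidates, characteristics, classifications, family_summary,
#>           structure, tree, sister_pairs, motif_hits, promoter_summary, ...
#>   family: 4 activators / 7 repressors (ratio 0.57 ), 36.4 % CTD-truncated
#>   sister pairs: 7
#>   promoters with AuxRE: 16 / 27
```

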