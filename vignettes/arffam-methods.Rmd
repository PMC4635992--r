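---
title: "Methods: ARF gene-family characterization with arffam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ARF gene-family characterization with arffam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arffam)
```

## The problem

Auxin response factors (ARFs) are plant transcription factors that bind
auxin response elements (AuxREs) in promoters and either activate or
repress auxin-responsive genes. A genome-wide family survey answers a
standard set of questions: which gene models are true ARFs, what are
their physico-chemical characteristics, which members are activators
versus repressors, how are their genes structured, how do they relate
phylogenetically to the well-annotated Arabidopsis and rice families,
which candidate target promoters carry AuxREs, and how do the genes
behave across tissues, developmental stages and treatments. `arffam`
implements each of these steps as a tidy, seed-reproducible pipeline,
with a synthetic-data generator that makes every stage testable without
any downloads.

## Family identification

Discovery starts from a domain-annotation table (InterProScan-style;
the package maps PF02362 to the B3 DNA-binding domain `DBD`, PF06507 to
the ARF domain `AUX_RESP`, and PF02309 to the Aux/IAA C-terminal
dimerization domain `AUX_IAA`). Running the domain scanner itself is out
of scope: the package's contribution is the filtering logic, which is
exact and testable. The default retention rule is

> keep a protein iff it has ≥ 1 `DBD` and (≥ 1 `AUX_RESP` or an
> explicit allow-list entry).

Proteins with only an `AUX_IAA` domain are members of the Aux/IAA
repressor family, not ARFs, and are excluded with that reason recorded.
DBD-only proteins are excluded by default and admitted via the
allow-list: genuinely truncated ARFs with nothing but a B3 domain do
occur (the papaya family contains one), but without the ARF domain the
architecture alone cannot distinguish them from other B3 proteins, so
the call is left to the analyst and is always logged. Exact duplicate
sequences are collapsed to the lexicographically smallest id, which
makes deduplication order-independent and idempotent.

New members are named after their nearest reference homolog: the cherry
partner when the focal gene forms a two-leaf clade with a reference
leaf, otherwise the reference leaf at minimum patristic distance, with
distance ties resolved toward the lowest-numbered reference name and
name collisions resolved by letter suffixes. Both tie-breaks are
deterministic so repeated runs give identical names.

## Protein characterization

*Deduced length.* The package fixes the convention `length_aa =
orf_len / 3`, i.e. the ORF nucleotide length excludes the stop codon.
In the papaya family table this convention reproduces 10 of 11 printed
rows exactly (2814 nt → 938 aa; 933 nt → 311 aa); the remaining row
(1855 nt, not divisible by 3) is internally inconsistent in the source
and triggers a structured warning rather than silent rounding.

*Molecular weight* is the sum of average residue masses plus one water
(18.0153 Da). The mass table is the standard average-isotope table
(`aa_residue_masses()`); correctness is pinned by a hand-summed
single-residue case, an exact additivity identity
`MW(s1 s2) = MW(s1) + MW(s2) − 18.0153`, and agreement with an
independent implementation.

*Isoelectric point* is the root of the Henderson–Hasselbalch net-charge
function with contributions from the free termini and the D, E, C, Y,
H, K, R side chains. The charge is strictly decreasing in pH, so
bisection on [0, 14] converges to the unique root; the tolerance is
1e-4 pH. The pKa set matters at the second decimal, published pI values
rarely name their tool, and different servers use different sets — so
the table is swappable (`arf_pka("expasy")` and `arf_pka("emboss")`
ship; any named vector with the same entries works). Tests compare the
bisection against a brute-force 1e-5 pH grid scan of an independently
written charge function.

## Activator/repressor classification

The middle region (MR) is the sequence strictly between the DBD end and
the CTD start (or the sequence end when no CTD exists). Its amino-acid
composition separates activators (glutamine/serine/leucine-rich) from
repressors (serine/proline/glycine/leucine-rich, or glycine-rich in
CTD-less repressors). "Rich" is never quantified in the literature this
convention comes from; since serine and leucine appear on both sides,
the minimal monotone separator consistent with the class descriptions
is

> activator iff `freq(Q) > freq(P) + freq(G)` over the MR.

This is the package default, the margin `freq(Q) − freq(P) − freq(G)`
is reported as a per-protein score, and an override table reproduces
any published assignment irrespective of the rule (flagged
`source = "override"`). A protein with neither MR nor CTD is
`dbd_only`.

The family summary counts `dbd_only` proteins in the repressor
denominator by default (they lack the activation-competent MR; this is
also the only reading under which the published papaya ratio
4/x = 0.57 resolves, with x = 7). CTD-truncated members are the
`repressor_no_CTD` plus `dbd_only` categories. With zero repressors the
ratio is reported as `NA`, never as infinity.

## Gene structure

Introns are defined purely as gaps between consecutive exons
(`n_exons − 1`), so UTR introns count; the source convention does not
distinguish them. Drawing tracks are emitted in transcript orientation
(minus-strand models reversed so offset 0 is the transcription start),
and reversal conserves total exon length by construction.

## Phylogeny

Distances come from pairwise-complete columns (pairwise deletion;
complete deletion available): `p` = mismatches / shared columns, with
the Poisson correction `−ln(1 − p)` as the default protein model. The
correction is undefined at `p = 1`; that raises an informative error
suggesting the p-distance model rather than producing infinities.

The tree is built by the classic Saitou–Nei neighbor-joining
agglomeration. Two numerical choices are pinned down because NJ
implementations differ in exactly these places:

* **Tie-breaking.** When several pairs minimize the Q-criterion within
  a relative tolerance of 1e-9, the pair whose (smallest-contained-leaf)
  labels sort lexicographically first is joined. This makes topologies
  deterministic, which the bootstrap and the tests require.
* **Negative branch estimates** are clamped to zero (with a message),
  the convention of the mainstream distance-phylogeny tools, rather
  than redistributed onto adjacent edges.

On additive matrices NJ is exact; the tests verify this against an
exhaustive oracle that enumerates every unrooted topology (≤ 6 taxa),
fits branch lengths by least squares and confirms the NJ topology is
the unique zero-residual one.

Bootstrap support follows the standard Felsenstein procedure: columns
are resampled with replacement, a replicate NJ tree is built each time,
and support of each original-tree bipartition is the percentage of
replicate trees containing it (mapped onto the original tree, not a
consensus). Degenerate replicates — e.g. a resample that saturates the
Poisson correction — are skipped with a log message and the denominator
is adjusted. Sister pairs are cherries whose two leaves belong to
different species with support at or above the configurable threshold
(default 99 %).

Group labels propagate from reference leaves: each unlabelled leaf
takes the group of its smallest enclosing clade whose reference leaves
are group-homogeneous, and is `"unplaced"` when every enclosing clade
mixes groups. The walk uses the stored rooted representation of the
(unrooted) NJ tree; with reference groups that are clades of the true
tree this is insensitive to the arbitrary basal node.

## Promoter scanning

AuxRE patterns are IUPAC-degenerate strings. The canonical preset
(`aux_motifs("methods")`) is AUX1 = `TGTCTC`, AUX2 = `TGTVYS`; a
variant spelling that circulates in figure legends
(AUX1 = `TGTGTC`, AUX2 with an `X` that is not an IUPAC code, read
here as `N`) ships as the `"figure7"` preset. Scanning reports every
position × motif match, overlapping hits included; both-strand mode
(the default — AuxREs are functional on either strand) matches the
reverse complement of each pattern against the forward string and
reports forward 0-based offsets with strand `"-"`. A concrete AUX1 site
also satisfies the degenerate AUX2 pattern and is reported under both
ids; consumers that want distinct sites can deduplicate on position.
Equality with a brute-force oracle that slides every expanded word is a
test invariant, as is the bijection of hit sets under
reverse-complementing the input.

## Expression

Relative expression is `scale × 2^−(Ct_target − Ct_reference)` per
replicate (default scale 1000, i.e. reference-level expression reads
1000), with ΔCt paired by replicate index by default (an unpaired mode
uses the mean reference Ct). Fold changes between conditions use the
comparative 2^−ΔΔCt form on replicate means, which equals the ratio of
relative expressions on noiseless tables — an identity the tests check.
Significance is primarily the boundary-inclusive 2× rule (`fold ≥ 2`
up, `fold ≤ 0.5` down); a Welch t-test on replicate ΔCt values is
available as a secondary flag (`ddct_test()`) because published figures
sometimes carry `P < 0.05` asterisks whose test is unstated — the
package does not guess which, it just offers the standard one.

Heatmap matrices are row-normalized to `log2(value / row max)`, so each
row's maximum is exactly 0 and all entries are ≤ 0; a zero cell is
replaced by the row's smallest positive value × 1e-3 (logged) and an
all-zero row is an error naming the gene. Abundance shares and tissue
specificity are simple row-fraction computations with a 0.5 dominance
threshold by default.

## The synthetic-data generator

`simulate_arf_family()` emits every input the pipeline consumes,
together with a manifest that fully determines every expected output.
Its defaults emulate a small dicot ARF family survey: 11 focal genes
(4 activators, 3 repressors with CTD, 3 CTD-less repressors, 1
DBD-only), 23 + 25 reference proteins from two outgroup species with 7
planted focal/At cherries and none with the second outgroup, intron
counts spanning 1–13, a 27-promoter panel with AuxREs planted in
exactly 16, and five-replicate Ct tables (0.2-cycle noise) including an
8-fold flower-stage ramp on the DBD-only gene. Everything is a pure
function of `(arguments, seed)`; writing a bundle twice produces
byte-identical files.

Design choices, and what they mean for the tests:

* **Motif-free background by rejection.** Promoter backgrounds are
  uniform ACGT, resampled until no unplanned match of any target motif
  exists on either strand. Planted counts are therefore exact, which
  is what acceptance testing needs; the cost is that the background is
  not GC-matched to any real genome.
* **Uniform-replacement protein evolution.** Sequences evolve along the
  true tree with Poisson(b) substitution events per site and uniform
  replacement — the amino-acid analogue of Jukes–Cantor. Expected
  divergence has the closed form
  `p = (19/20)(1 − e^{−20t/19})`, which the tests check at 10,000
  sites. Empirical substitution matrices (JTT and friends) are out of
  scope; they would change distances, not the correctness of NJ or the
  bootstrap bookkeeping.
* **Composition margins are enforced on realizations.** MR sequences
  are resampled until the realized `freq(Q) − freq(P) − freq(G)`
  respects the requested margin (default 0.05), so classifier recovery
  on the manifest is exact by construction, not just in expectation.
* **What the generator does not emulate:** indels and alignment error
  (the evolved alignment is gap-free by construction), paralog loss,
  GC-biased promoter composition, primer efficiency and plate effects
  in qPCR. Passing the synthetic recovery tests therefore demonstrates
  the pipeline's internal correctness, not robustness to those
  real-data artifacts.

## Problem sizes and runtime choices

The test suite runs the full 59-taxon bootstrap at 200 replicates and
the acceptance script at 1000 replicates (about 15 s; the
alignment is 300 columns). The NJ-versus-exhaustive-topology oracle is
run at 5 and 6 taxa (15 and 105 topologies), the scanner oracle on
1,000 random 60-bp sequences, and the pI grid oracle on 100 random
peptides at a 1e-5 pH step. These sizes were chosen so each property is
exercised well past its edge cases while the whole suite stays
desk-scale.

## Known limitations

* Candidate discovery consumes domain tables; it does not run HMMER,
  BLAST or InterProScan, and it cannot rescue ARFs the upstream scan
  missed (beyond the allow-list).
* MSA construction is out of scope; the phylogeny stage consumes a
  pre-aligned FASTA.
* The pKa and mass tables are conventions; agreement with any given
  published pI/MW table to 2 decimals depends on the tool that produced
  it, which is why the pKa set is a parameter.
* Multi-reference-gene normalization and primer-efficiency correction
  are not implemented; the ΔΔCt model assumes ~100 % amplification
  efficiency for both target and reference.

## A worked end-to-end run

```{r pipeline, eval = FALSE}
bundle <- simulate_arf_family(seed = 1)
report <- run_arf_pipeline(bundle, arf_config(bootstrap_reps = 200,
                                              rng_seed = 1))
report$family_summary
report$sister_pairs
attr(report$promoter_summary, "n_with_hits")
```
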