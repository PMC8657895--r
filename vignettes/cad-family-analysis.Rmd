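---
title: "Methods: CAD gene-family classification, phylogeny and co-expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CAD gene-family classification, phylogeny and co-expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cadfam)
```

## The problem

Cinnamyl alcohol dehydrogenase (CAD) catalyses the last step of monolignol
biosynthesis, reducing hydroxycinnamaldehydes to the alcohols that polymerise
into lignin. Studies of CAD gene families — in bamboo and other grasses as in
many other plants — follow a recurring computational chain: identify family
members in a genome by their signature sites, place them on a phylogeny with
bootstrap support, scan their promoters for stress- and hormone-responsive
cis-acting elements, profile their expression across tissues, call
stress-responsive members by fold change, and relate them to other pathway
genes through a Pearson co-expression network.

`cadfam` implements that chain as a set of tested, composable functions plus
an orchestrating pipeline. Because the genome and transcriptome inputs of any
particular study are external resources, the package ships a synthetic-data
module that generates all inputs with a recorded ground-truth ledger; every
stage is therefore testable end to end, offline, against known answers.

## Signature-site classification

A protein is called a CAD-family member when three signature sites are
simultaneously present: the catalytic Zn-binding site `GHE(X)2G(X)5V`, the
structural Zn-binding site `GD(X)10C(X)2C(X)7C`, and the NADP(H)-binding site
`G(X)3G(X)2GLGG(X)GH(X)2VK(X)2K(X)2G-(X)VTV(X)S(X)S(X)2K`.

The pattern grammar treats residue letters as literal positions and `(X)n` as
a wildcard run of exactly `n` positions. Two points were genuinely open and
decided as follows:

* **`(X)` without a count.** The NADP(H) pattern contains `(X)` groups
  followed directly by letters. We read these, like a bare `X`, as wildcard
  runs of length 1 — the only reading under which the pattern parses at all.
  Mid-pattern hyphens are treated as typographic and stripped. Parsed spans
  are 12, 24 and 35 residues with 5, 5 and 18 literal positions.
* **Mismatch tolerance.** Family surveys routinely accept signature sites
  carrying minor mutations, without quantifying "minor". The budget is
  therefore configurable per site, with a default of 2 mismatched literal
  positions per site. A lenient NADP(H) budget matters in practice: diverged
  family members can carry several substitutions in that long site.

The scanner slides the fixed-span window along the sequence and counts
mismatches at literal positions only; wildcards accept anything. Two further
conventions: the unknown residue `X` in a protein always counts as a mismatch
at a literal position (conservative — an unsequenced region never supports
family membership), and ties between equal-mismatch windows are broken by the
smallest start, so the reported evidence is deterministic. Raising the
tolerance can only add matches, so classification is monotone in the budget —
a property the test suite checks directly.

## Distance phylogeny with bootstrap

The phylogeny stage rebuilds the distance-based half of the usual
MEGA-style analysis: neighbor joining on aligned peptides with
column-resampling bootstrap. Maximum-likelihood tree search is deliberately
out of scope — NJ is fully specified, fast, and exactly testable: on an
additive (tree-realisable) distance matrix it provably returns the generating
topology with the exact path metric, which the suite verifies on hundreds of
random additive matrices and against an exhaustive least-squares topology
search for up to six taxa.

Concrete choices, since alignment-program defaults are rarely printed in
family studies:

* **Distance model.** Default Poisson correction `d = -ln(1 - p)` on the
  proportion of differing residues `p`; plain p-distance available. A
  saturated pair (`p = 1`) is an error naming the pair rather than a silent
  infinity.
* **Gap handling.** Pairwise deletion by default (each pair compared over the
  columns where neither has a gap), complete deletion as an option.
* **Negative branch estimates** are clamped to zero, standard NJ practice
  that leaves additive inputs exact.
* **Ties** in the Q criterion join the lowest-index pair, making degenerate
  inputs (e.g. equidistant matrices) deterministic.
* **Support** is the percentage of replicate NJ trees containing each
  internal bipartition of the full-data tree, mapped onto that tree — not a
  consensus topology — because that is how published family trees annotate
  support. Replicates with undefined distances are skipped and counted; more
  than half skipped aborts. The conventional replicate count is 1000 (the
  pipeline default); the test suite uses 100–200 replicates on 4–6-taxon
  alignments to keep runs fast.

Trees are `ape::phylo` objects throughout; Newick output quotes labels
containing metacharacters and writes lengths at 15 significant digits so that
re-parsing round-trips the topology, lengths and supports.

## Promoter cis-element scanning

Promoters — conventionally the 2 kb upstream region — are scanned for a
configurable table of named elements (ABRE, CGTCA-motif, GARE-motif, LTR,
MBS, MRE, MYB, P-box, TCA-element, TCT-motif, TGACG-motif). Family studies
name these elements but not their consensus sequences; the shipped table
(`inst/extdata/cis_elements.tsv`) carries PlantCARE-derived working defaults,
clearly documented as defaults and replaceable wholesale.

Matching is exact IUPAC matching on both strands. Minus-strand hits are
reported in forward coordinates with the matched sequence in element
orientation, so one planted `CGTCA` yields both a forward CGTCA-motif hit
and, at the same coordinate, a minus-strand TGACG-motif hit — the two
consensi are reverse complements. An `N` in the promoter matches only an `N`
in the consensus: an unsequenced base never fabricates a hit. Overlapping
matches are all reported and all counted, since counting conventions are
unstated in the literature; the count matrix keeps all-zero rows so absence
is visible.

## Expression filtering and stress calls

The expression stage applies the standard breadth filter for multi-tissue
FPKM panels: keep genes with at least 0.05 FPKM in more than six — read
literally as at least seven — of the 26 tissues. Both numbers are
parameters; the threshold is inclusive and the filter is idempotent. Heatmap
matrices use `log2(FPKM + 1)`, the offset keeping zeros at zero.

Stress responsiveness uses a plain two-fold rule, not a statistical test,
matching field practice for these calls: replicates are averaged
(arithmetic mean), treated means are compared to the matched control at the
same timepoint, and `fc = (treated + eps) / (control + eps)` with a
pseudocount `eps = 0.1` FPKM by default. The pseudocount is the package's
answer to an underdetermined corner: genes silent in control but strongly
induced under stress have an infinite raw ratio, yet finite induction values
are what such analyses report. With `eps = 0.1`, a control of 0 and a
treated value of 10 give `fc = 101` — finite, large, called up. Genes whose
maximum FPKM never reaches 1 (configurable) are flagged too low for analysis
and excluded from calls rather than contributing noise-driven ratios.

## Co-expression networks

Pairwise Pearson correlation over the sample columns, thresholded directly:
pairs with PCC at or above 0.7 are positive edges, at or below −0.5 negative
edges. The boundaries are inclusive (methods statements of the form
"0.7 to 1" and "−0.5 to −1" include the endpoints; where a results section
says strictly "> 0.7", the difference only affects measure-zero boundary
cases — the thresholds are configurable regardless). No p-values and no
multiple-testing correction are applied: the thresholded raw PCC *is* the
method. Zero-variance genes are skipped with a warning naming them. A
seed-gene mode evaluates only seed × universe pairs, for the common design
where a gene family is correlated against a pathway gene list. Edge lists
export as TSV or Cytoscape-readable SIF with deterministic ordering.

## What the synthetic data emulates — and what it does not

Each generator is a pure function of its parameters and seed, and returns a
ledger that fully determines the expected downstream output:

* **Protein families** plant all three signature sites in positives (with
  0–2 recorded literal mutations per site) and destroy exactly one site in
  each decoy, re-sampling the background until no window of the destroyed
  pattern matches within the budget — so decoys are true negatives by
  construction, checked by an independent plain-loop matcher.
* **Alignments** evolve i.i.d. columns along a given tree: along a branch of
  length `b`, each site is hit with probability `1 - exp(-b)` and redrawn
  uniformly from the 20 residues, so the expected difference from the parent
  is `(1 - exp(-b)) * 19/20`, saturating at 19/20. This is a deliberately
  simple, fully specified contract — sufficient for NJ-recovery and
  bootstrap testing — not an empirical substitution matrix.
* **Tissue panels** use a latent-factor model: within a module, gene latents
  share a factor with loadings chosen so the pairwise latent correlation
  equals the target exactly in expectation; latents are standardised and
  mapped to FPKM as `2^(3 + z)`. Exponentiation attenuates a latent
  correlation `rho` to `(exp(rho * a^2) - 1)/(exp(a^2) - 1)` with
  `a = log2_sd * ln 2`; the default `log2_sd = 1` was chosen from that
  closed form so a latent 0.9 stays near 0.88 on the FPKM scale the network
  actually sees, while keeping the skewed non-negative shape of FPKM data.
* **Stress experiments** give each gene a lognormal baseline, multiply
  planted gene × condition × timepoint cells by the planted fold, and add
  small multiplicative replicate noise; low-expression genes sit below the
  analysis cutoff in every sample.
* **Promoters** are uniform A/C/G/T backgrounds with concrete realisations
  of element consensi inserted at recorded positions and strands
  (minus-strand plantings insert the reverse complement).

Passing tests on these fixtures show that the implementation does what the
method definitions say — recovery of planted truth, exactness on additive
metrics, agreement with exhaustive oracles. They do not show that the
defaults are optimal for real genomes: real protein families have correlated
backgrounds and partial sites, real FPKM matrices have structured technical
noise and shared-factor correlations between modules, and real promoters are
far from uniform random, so background hit rates of short consensi (4–6 bp
elements match a random 2 kb window many times by chance) must be interpreted
accordingly.

## Problem sizes and numerical conventions

The test suite runs at sizes chosen to exercise every property well inside a
minute or two per file: 20 seed-swept synthetic families of 40 proteins for
classifier recovery; 200 random additive matrices (4–8 taxa) plus an
exhaustive least-squares cross-check at 5–6 taxa for NJ; 500-column
simulated alignments with 100–200 bootstrap replicates; 100 seeds of the
two-module, 26-sample latent-factor fixture for network recovery; and a full
pipeline double-run for byte-level determinism. `scripts/acceptance.R`
recomputes all of these from scratch under a caller-supplied seed.

Numerical conventions worth knowing: distances must be finite, symmetric to
1e-8 and zero-diagonal; NJ tie-breaks prefer the earliest pair at equal Q
(with a 1e-12 comparison margin); branch lengths are clamped at zero after
estimation; Newick is written with 15 significant digits; correlations are
computed by `stats::cor` and validated in tests against a two-pass formula
oracle at 1e-12.

## Known limitations

* Maximum-likelihood phylogenetics, multiple sequence alignment, de novo
  motif discovery, BLAST-based candidate retrieval and upstream RNA-seq
  quantification are out of scope; inputs are pre-aligned peptides, promoter
  FASTA and FPKM matrices.
* The element consensus table is a working default, not a curated database;
  analyses that depend on exact PlantCARE definitions should supply their
  own table.
* The two-fold rule makes no claim of statistical significance; it
  reproduces the field's descriptive convention.
* Bootstrap support is reported on the full-data topology; poorly resolved
  full-data edges are reported with low support rather than collapsed.
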