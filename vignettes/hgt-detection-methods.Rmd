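---
title: "Detecting horizontal gene transfer by phylogenetic screening: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting horizontal gene transfer by phylogenetic screening: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the models behind
each stage, the tunable parameters and why their defaults are what they
are, what the synthetic benchmark does and does not emulate, and the
numerical choices a maintainer would want written down.

## The detection problem

A horizontally transferred gene in an insect genome betrays itself in
three largely independent ways: its closest homologs, by alignment
score, sit in a foreign lineage (bacteria or plants) rather than in
related arthropods; its gene tree places it *inside* a well-supported
foreign clade, which vertical inheritance plus loss cannot easily
explain; and — for recent prokaryote-to-insect transfers — it is
intronless, lacks within-genome paralogs, and is absent from close wild
relatives. The pipeline operationalizes each signal as an explicit
filter with a recorded decision, so the final candidate list is an
auditable consequence of stated thresholds rather than of manual
curation.

## Homology search and E-values

The search engine is exact Smith–Waterman with affine gaps (opening a
gap costs `gap_open`, each further gapped residue `gap_extend`;
BLOSUM62 by default), run as a compiled batch kernel. Significance uses
the Karlin–Altschul form `E = K·m·n·exp(−λS)` with the published gapped
BLOSUM62 constants (λ = 0.267, K = 0.041). These constants are not
re-estimated: every decision downstream depends only on the *ordering*
of scores and on one fixed cutoff (`E ≤ 10⁻²⁰`), for which a monotone,
scale-consistent E-value suffices. Per (query, species) only the best
hit is kept — ties broken by percent identity, then subject id, so runs
are reproducible.

Heuristic seeding (k-mer words) is deliberately absent: the package
targets benchmark-scale databases where exact scan cost is acceptable,
and an exact engine can be verified against enumeration oracles, which
the test suite does on small peptides.

## The filter cascade

Stages run in a fixed order and write one ledger row each,
`(name, n_in, n_excluded, n_out)`, with `n_out = n_in − n_excluded`
enforced and stages required to chain. Inconsistent counts are an error,
never repaired.

* **Insect-only exclusion** removes genes whose qualifying hits all lie
  in `arthropod_insect` — and also genes with *no* qualifying hits,
  since a gene without foreign homologs cannot evidence transfer (the
  choice for no-hit genes is a design decision; they could equally be
  tracked as a separate class).
* **Clustering** groups homologs by reciprocal best hits (RBH) between
  species and takes connected components. This stands in for
  inflation-based ortholog clustering: components preserve the one
  property later stages use, namely which homologs belong together.
* **Taxon profile**: a query survives only if its best non-Arthropoda
  bit score strictly beats its best Arthropoda bit score (no Arthropoda
  hits at all also survives). Insect cluster members other than the
  query are not part of its phylogeny.
* **Tree membership**: each candidate's phylogeny uses the query plus
  its per-species best hits outside the insects. Strict RBH components
  are not used here, because a recent transfer's cross-group homologs
  reciprocate with the recipient's *vertical* paralog of the same
  family and would be stripped from the implant's component — the
  extraction rule ("best hit from each species, insects removed except
  the query") is the behavior the decision contract needs.
* **Few-hit rule**: fewer than 5 sequences cannot make a meaningful
  phylogeny; the count includes the query. Whether "5" counts sequences
  or species is ambiguous in the tradition this follows; sequences are
  counted here, and with one best hit per species the two coincide.

Post-tree screens: EST confirmation (some EST aligns at ≥95% identity
over ≥100 nt — standard EST-confirmation practice; both thresholds are
arguments), transposon exclusion (best library hit with `E ≤ 10⁻¹⁰` and
≥50% query coverage; "high similarity to a transposon" is not a
standardized quantity, so both knobs are explicit), within-genome
duplication count at the search cutoff, intron count from exon records
(single-transcript assumption: introns = exons − 1), and an absence
screen against wild-relative EST sets using the EST criterion.

## Substitution model and likelihood

All phylogenetics runs under JTT exchangeabilities with stationary
frequencies, discrete-gamma rate variation (4 categories, category
*medians*, rescaled to mean 1) and an invariant-site class. The rate
matrix is normalized so the expected substitution rate over variable
*and* invariant sites is 1 — branch lengths are expected substitutions
per site; with invariant proportion `p` the variable class is scaled by
`1/(1−p)`.

The likelihood is Felsenstein pruning over site patterns, with gaps as
missing data and the invariant class added as
`p·π(constant residue)` for constant sites. The engine caches pattern
compression, tip partials and traversal order per (topology, alignment),
so model fitting and per-branch optimization pay only the per-category
matrix work. The test suite pins the pruning value to brute-force
enumeration over internal-node states (tolerance 1e-10) and to an
independent likelihood implementation.

`fit_model()` estimates `(α, p_inv)` by nested golden-section searches
(outer in log α over [0.05, 20], inner in `p_inv` over [0, 0.8]),
parameter tolerance 1e-4, exceeding the iteration cap is an error that
reports the best-so-far point. Parameter recovery is verified by
simulation (α = 1, 2000 sites, 8 taxa, ±0.25).

## Distances, trees, support

Pairwise ML distances maximize the two-sequence likelihood in the
branch length. For speed the optimizer evaluates the likelihood on a
precomputed log-spaced grid of 160 mixture transition matrices
(t ∈ [2·10⁻⁴, 10]) and refines the best grid point by parabolic
interpolation in log t; against an independent golden-section optimizer
this agrees to better than 0.1% across the relevant divergence range,
far below bootstrap resampling noise. Identical pairs are 0; pairs with
no shared ungapped columns get the ceiling (10.0) and a flag.

Topologies come from Saitou–Nei neighbor joining on those distances
(negative branch lengths clamped to 0), and support from resampling
alignment columns with replacement, rebuilding the tree per replicate,
and counting bipartitions. NJ-on-ML-distances plus bootstrap is the
single tree/support engine: the downstream HGT criterion consumes only
(topology, support) pairs, and a full ML topology search or an MCMC
sampler would dominate the build without changing that contract. The
traditional dual requirement (ML bootstrap ≥ 80% *and* Bayesian
posterior ≥ 85%) is kept as two gates applied to the same bootstrap
value when `dual_threshold = TRUE` (the default), emulating "both
methods agree"; with a single inference engine the 85% gate is simply
the stricter of the two.

## Alignment and trimming

Multiple alignment is progressive: a k-mer distance guide tree (UPGMA)
and profile–profile global alignment with affine gaps, expected-score
column profiles. Two-sequence alignments provably attain the global DP
optimum (checked against an independent R implementation).

Conserved-block trimming follows the classical rules: a column with any
gap is never kept; otherwise the majority residue's frequency classifies
the column (> 50% conserved, > 85% highly conserved); runs of more than
8 nonconserved columns split blocks; blocks are trimmed so both flanks
are highly conserved and blocks shorter than 10 columns are dropped. The
published "stringent settings" this mirrors are not recoverable exactly,
so the strict end of the classical defaults is used and every parameter
is an argument. An alignment whose every column is removed is flagged
and its gene is reported `untestable` rather than silently passed.

## HGT classification and the SH test

Rooting the tree at the query, the nested clades containing it are built
by repeatedly absorbing the smaller subtree at each node and descending
into the larger; each such clade is one side of an edge bipartition and
inherits that edge's bootstrap support. The verdict is `hgt` when the
smallest clade's non-query members are all of one foreign class
(prokaryote = bacterium/archaeon, or plant; fungus and other-eukaryote
donors sit behind `allow_other_donors` since interdomain and plant
transfers are the classes this screen was built for) and support passes
the gate(s). Mixed clades tolerate at most one minority leaf — the
majority class is assigned — otherwise the gene is `untestable`; how
impure clades should be handled is genuinely open, and this rule is the
most conservative one that still calls the textbook case.
`nested_depth` counts how many successively larger clades stay
foreign-only; depth ≥ 1 plus intronlessness gives
`direction = to_recipient`.

Each `hgt` verdict is confirmed by a Shimodaira–Hasegawa test against
the constrained vertical topology: the query is pruned and regrafted
onto the stem of the native (insect + other-metazoan) clade, branch
lengths of both topologies get one sweep of per-branch optimization
(tolerance 1e-3 — SH is rank-based and insensitive to finer
optimization at this scale), and RELL resampling of per-site
log-likelihoods yields `p` = the fraction of replicates in which the
constrained topology's centered deficit reaches the observed one.
Identical topologies return p = 1 by definition. The reported value is
the rejection p of the *vertical* topology — small p supports transfer;
trees with no native-group leaf have nothing to constrain and report
`NA` rather than a fabricated confirmation.

## Functional analysis

Expression is `log2(x+1)` then quantile normalization (limma), probe
rows without a gene id dropped, duplicates averaged. Coexpression lists
keep partners with |r| strictly above 0.5 (0.5 itself is excluded),
sorted by |r|, truncated to the top 300, ranks from 1. The pathway score
is `S = (1/G) Σ rᵢ·(N+1−Rᵢ)/N` over a pathway's G genes in the list — a
rank-weighted mean absolute correlation built from exactly the
quantities the tradition names (G, Rᵢ, rᵢ, top-N); the formula is a
reconstruction (the source text's formula is lost) and is therefore a
plain function that can be swapped. Ranks are per-focal-gene lists, not
pooled across candidates. Overrepresentation is the upper-tail
hypergeometric `P(X ≥ k)`; SNP overlap is set intersection with
per-gene flags.

## The synthetic benchmark

`synth_config()` defaults define the reference conditions used by the
acceptance tests: 6 taxonomic groups × 4 database species plus the
recipient, 200 shared gene families, 20 insect-only families, 8
implanted transfers at divergence 0.1 (one plant donor, the rest
bacterial — mirroring the one-plant-among-bacteria pattern such screens
report), 5 transposon-derived genes, ESTs covering 90% of genes with
implants always expressed, and an expression matrix over the 10-tissue
larval panel of the silkworm microarray atlas (3 replicates each) with
3 planted 20-gene coexpression modules, implants distributed among them.

Families evolve along a fixed balanced species tree: group ancestors at
0.6 substitutions/site from the family root, species at 0.2 from their
group ancestor. The depths are a deliberate compromise: within-group
distance 0.4 (~69% identity) keeps insect hits dominant for every
vertical gene, while cross-group distance 1.2 (~37% identity) keeps
cross-group homology detectable at `E ≤ 10⁻²⁰` across the whole
150–500 aa length range — pushing groups further apart (e.g. depth 1.0,
~22% identity) silently drops eukaryote homologs of short proteins
below the cutoff, which would leave implant trees without native leaves
and make the vertical-constraint test vacuous. Proteins are 150–500 aa,
spanning realistic single-domain to multi-domain gene sizes without
inflating alignment cost.

Simulation is site-wise JTT with no indels inside families (the EST
error model is the only indel source), so expected implant–donor
identity has a closed form the tests check by Monte Carlo. ESTs are
200–600 nt CDS subsequences at 1% error; wild-relative sets are built
from native genes only, so implants are absent from them by
construction.

What the benchmark does *not* emulate — and hence what green tests do
not show about real data: domain-level mosaicism and partial transfers,
nucleotide-level composition signals (the pipeline deliberately uses
none), indel evolution inside families, paralog families beyond the
single vertical copy, contamination (assembly-borne bacterial reads
mimicking HGT), and database mislabeling. On real proteomes those are
the dominant failure modes, and the thresholds here (support, E-value,
EST identity) should be treated as starting points, not validated
constants.

## Numerical choices and degenerate inputs

* Transition probabilities via spectral decomposition of the
  symmetrized generator; tiny negative round-off entries clamped to 0.
* Site likelihoods floored at 1e-300 before logs.
* Golden-section searches: fit tolerance 1e-4 in the parameter;
  exceeding 200 iterations errors with best-so-far.
* Distance grid: 160 points, log-spaced; parabolic refinement clamped
  to the bracketing cell; boundary optima returned as the boundary.
* Ties: per-species best hits by (bit score, identity, subject id);
  nested-clade construction breaks equal-size subtrees by child order;
  NJ follows its standard agglomeration order.
* Degenerate inputs: empty trimmed alignments → `untestable`; constant
  alignments drive `p_inv` to its interval top; zero-variance focal
  genes are an error in coexpression; all-zero expression samples are
  an error in normalization.
* Every stochastic step (simulation, bootstrap, RELL) takes an explicit
  seed; the pipeline derives per-stage child seeds from one master seed
  so toggling a stage does not shift another stage's stream.

## Problem sizes

The acceptance suite runs the full cascade at the default benchmark
scale (233 queries against 4,880 database proteins, 8 gene trees with
200 bootstrap replicates and 1,000 RELL replicates) — a few minutes on
one core. Unit tests use smaller instances: enumeration oracles on ≤15
residue peptides and ≤5-taxon trees, parameter recovery at 8 taxa ×
2,000 sites, SH calibration at 8 taxa × 1,000 sites × 10 seeds. The
1,000-replicate bootstrap default matches common practice; the
acceptance runs use 200 replicates, which resolves the 80/85% gates to
within ±3% while keeping tree building a small fraction of total
runtime.

## Known limitations

Single tree engine (no ML topology search or posterior sampling);
no composition-based statistics or profile searches; transfers into the
common ancestor of the insects are invisible by construction (they look
vertical); the direction heuristic (intronless + nesting) cannot
distinguish a recent transfer from an intronless native gene inside an
artifactual clade; and the pathway score is a documented reconstruction,
not a published formula.
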