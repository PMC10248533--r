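---
title: "Tracing Get3/ArsA subfamilies at desk scale: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracing Get3/ArsA subfamilies at desk scale: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(Get3Atlas)
```

## The problem

Get3/ArsA proteins are SIMIBI-class P-loop NTPases: cytoplasmic Get3
targets tail-anchored (TA) membrane proteins post-translationally,
while ArsA is an arsenite-resistance ATPase that occurs naturally as a
*pseudodimer* — one polypeptide carrying two tandem Get3/ArsA domains.
Plants carry several Get3 paralogs, among them a chloroplast-localised
subfamily (Get3d) distinguished by a C-terminal
alpha-crystallin domain (aCD) and conserved from photosynthetic
bacteria through land plants, yet absent from single-celled plants.

`Get3Atlas` re-implements, at desk scale and fully testably, the
comparative pipeline by which such a subfamily is traced across
taxa — domain harvesting, clustering, seed-anchored alignment,
maximum-likelihood phylogenetics with bootstrap collapse and
likelihood-based placement, anchor-based clade assignment and
taxonomic presence/absence mapping — together with the quantitative
structure comparisons (superposition RMSD, buried interface area,
salt bridges, cis-peptides, chamber hydrophobicity and volume) used
to characterise the two Get3d crystal structures.

## Domain harvesting

Monomer Get3/ArsA-like domains are found with a position-specific
scoring model (PSSM) with affine gaps, standing in for the profile
HMMs a full-scale analysis would use.  The choice is deliberate: a
PSSM with affine gap penalties preserves the pipeline's logic
(iterative search, inclusion threshold, coverage rule, pseudodimer
splitting) while every score is checkable against a brute-force
dynamic-programming oracle.

* `buildProfile()` turns a seed alignment into per-column log-odds
  (bits), `log2((obs + c*bg) / ((n + c)*bg))` with pseudocount
  `c = 1`; columns with more than 50% gaps are excluded from the
  match-state set.
* `iterativeSearch()` runs three rounds (the convention of iterative
  profile searches): local alignment of the profile against every
  database sequence, admission of hits at or above the bit threshold,
  augmentation of the seed and rebuild.  Repeated search with masking
  exposes every domain copy on one parent, so tandem pseudodimers
  yield two separate hits.
* The inclusion threshold is not fixed by convention anywhere, so it
  is **calibrated per profile** as mean + 4 SD of the local-alignment
  scores of 200 residue-shuffled database sequences — an empirical
  null that adapts to profile width and composition.
* `completenessFilter()` keeps a hit iff it covers at least 90% of
  the best-scoring query, measured on the query profile's match
  columns.
* `splitPseudodimer()` cuts a two-domain parent midway between the
  end of the first domain and the start of the second
  (`s = floor((end1 + start2)/2)`); the halves tile the parent
  exactly and carry symmetric partner links.
* aCD (ArsA_HSP20-like) carriers are flagged by the same local
  profile search against an aCD seed, with its own shuffle-null
  threshold.

## Clustering and alignment

Sequence identity uses one fixed convention everywhere: global
alignment with BLOSUM62, gap open 11 / extend 1 (the aligner's
convention charges `open + k * extend` for a length-`k` gap), and
identity = identical aligned pairs / aligned columns excluding
double-gap columns, terminal gaps included.  The tiered thresholds of
the emulated analysis (plants 85%, aCD-bearing photosynthetic
bacteria 70%, other photosynthetic bacteria 65%, everything else 60%)
are defaults of the pipeline driver.  `greedyCluster()` visits
sequences by decreasing length (ties by id) and joins the earliest
representative at or above the threshold — a centroid-greedy rule;
the cited tool's additional coverage criterion is not emulated, and a
post hoc verification pass (`verifyClusters()`) recomputes every
member-to-representative identity.  Where one half of a pseudodimer
is a representative, `keepPairHalves()` retains the other half too.

`alignToSeed()` is a progressive profile aligner anchored on the
structure-based seed: seed columns are never re-arranged, new
sequences only insert shared columns, and the guide order is
decreasing profile score to the seed.  `addKeepLength()` aligns a
query against a fixed-width alignment and discards (but reports)
residues falling in insertions, so reference coordinates never
change — the precondition for placement.

## Maximum-likelihood phylogenetics

The inference stack is written for verifiability:

* **Models.** LG and VT exchangeabilities and frequencies are bundled
  as plain-text files with provenance notes; "empirical" frequencies
  are counted from the input alignment (add-one smoothed), "model"
  frequencies are the published ones.  A deliberately small 3-state
  model (TOY3) makes exhaustive-enumeration oracles tractable in
  tests.  Rate matrices are normalised to one expected substitution
  per site; `P(t) = exp(Qt)` comes from a symmetrised
  eigendecomposition and is cross-checked against scaling-and-squaring
  in the tests.  Rate heterogeneity is off by default (the emulated
  model strings carry no gamma term); `treeLogLik()` accepts an
  optional discrete-gamma mixture (shape parameter, 4 equal-weight
  median-discretised categories, mean rate one).
* **Likelihood.** Felsenstein pruning over compressed site patterns,
  gaps as missing data, per-node rescaling; the inner loops are in
  C++.
* **Search.** A neighbor-joining start tree on maximum-likelihood
  pairwise distances (negative branches clamped to zero; the 3-taxon
  case solved in closed form), per-branch 1D optimization in sweeps
  (outside partial likelihoods are rebuilt along a preorder traversal
  so each branch sees the updates already made in its sweep; a sweep
  that fails to improve the joint likelihood is rejected, making the
  log-likelihood non-decreasing by construction), and an NNI search
  accepting the best strictly improving move per round.  Branch
  lengths live in [1e-8, 20] substitutions/site.
* **Bootstrap.** Plain nonparametric column resampling with a fixed
  replicate count; each replicate is inferred by NJ on ML distances,
  one branch-length sweep and one NNI round.  The "rapid bootstrap"
  heuristic and automatic replicate-number convergence of the
  emulated tool are not reproduced — the full-scale analysis printed
  fixed totals (400 family-wide, 100 for the representative tree),
  and the synthetic study defaults to 20 replicates, which resolves
  the 70% collapse threshold at 5% support granularity while keeping
  a 20-run recovery study inside a desk-scale compute budget.
* **Collapse.** `collapseLowSupport()` contracts every internal edge
  with support strictly below 70%, the figure-legend convention of
  the emulated study; surviving edges keep their lengths.
* **Placement.** `epaPlace()` attaches the query at every edge
  midpoint by a pendant branch, optimizes only the pendant length,
  and reports the per-edge log-likelihood table and its argmax.
* **Rooting.** `rootAtMrca()` places the root on the edge ancestral
  to the MRCA of two anchor taxa, split at its midpoint.  On an
  unrooted tree the MRCA needs an orientation, so the tree is first
  oriented from the tip farthest from both anchors — a deterministic
  choice that does not depend on internal storage order.

## Clade assignment and taxonomic summaries

The emulated study assigns plant proteins "by the presence of the
corresponding *A. thaliana* protein in that clade".  That informal
rule is formalised as: each anchor set's clade is the **largest clade
containing every anchor of the set and no anchor of any other set**;
interleaved anchors raise an "anchors not separable" error, and
leaves inside no anchor clade are "unassigned".  Assignment runs on
the collapsed tree, so weakly supported attachments fall to
"unassigned" rather than forcing a label; placed queries inherit the
uniform label of the leaf set flanking their placement edge.

Downstream summaries are deliberately plain: a genus x subfamily
presence matrix ("a homolog in at least one member of the genus"),
per-organism copy counts, a strict `> 10` GO:0015979-protein rule for
calling an organism putatively photosynthetic, and a proteome-quality
filter keeping reference or nonredundant proteomes or BUSCO
completeness `> 75`.

## Structure comparison

* `kabschSuperpose()` is the SVD solution with the reflection
  excluded (det = +1); tests pin it against the quaternion closed
  form at 1e-8.
* `backboneRmsd()` pairs chains greedily by sequence identity, maps
  residues by global sequence alignment, and superposes all N/CA/C/O
  atoms of completely resolved aligned pairs as **one rigid body**
  across the whole dimer — the printed dimer-level figure is a single
  number, and which residue ranges entered it is not stated, so
  agreement with published values is necessarily tolerance-based.
* `shrakeRupleySasa()` samples 960 deterministic golden-spiral points
  per atom with a 1.4 A probe and a fixed vdW table (C 1.70, N 1.55,
  O 1.52, S 1.80, H 1.20, P 1.80 A) — fixed for reproducibility over
  configurability.  Because the sampling lattice is fixed in space,
  rotational invariance holds to the sampling resolution (about 1%),
  not to machine precision.
* `buriedInterfaceArea()` reports both the total
  `SASA(A) + SASA(B) - SASA(A+B)` and the half convention: published
  "buries ~X A^2" statements rarely name their convention, so both
  are always carried and the half value (the common interface-area
  definition) is the headline number.
* Salt bridges: side-chain N of Arg/Lys/His within 4.0 A of a
  side-chain carboxylate O of Asp/Glu across the partition.
  Cis-peptides: omega dihedral (CA, C, N', CA') within 30 degrees of
  zero, with chain breaks (C-N > 2.5 A) skipped — both standard
  conventions, stated here because the source material gives none.
* `cavityVolume()` flood-fills a 0.5 A grid from the bounding box;
  interior voids are open cells unreachable from outside.  The
  helix-capacity estimate divides by an explicit 170 A^3 per helical
  residue; it is an order-of-magnitude aid, not a measured quantity.

## The synthetic study

`familySimulation()` generates the complete study the pipeline is
validated on.  Its defaults are the study conditions, not tuning
knobs:

* Eight species in three clades — two photosynthetic bacteria, two
  single-celled plants, four land plants — on a fixed ultrametric
  species tree of root-to-tip depth 0.5 substitutions/site.
* Four subfamilies on a hierarchically structured family tree — a
  basal split (0.15 substitutions/site per side) separates
  (Get3a, Get3b/c) from (Get3d, ArsA), with subfamily ancestors
  0.5-0.6 substitutions/site from the family root and
  within-pseudodimer half divergence 0.3.  Get3a and Get3b/c occur in
  all plants, Get3d in photosynthetic bacteria and land plants with a
  110-residue aCD appended and a **deterministic loss in
  single-celled plants**, and the ArsA-like subfamily only in the
  photosynthetic bacteria, every copy an ancient tandem fusion of two
  500-residue half-domains around a 20-residue linker.  Root-to-tip
  divergence stays at or below about 1.1 substitutions/site.  The
  pipeline roots between the two pseudodimer half-clades' common
  ancestor and everything else — the ArsA-like subfamily is the
  outgroup, as in the emulated study's rooting between the bacterial
  ArsA and archaeal Get3 anchors.
* Gene-level birth-death dynamics (duplication 0.08, loss 0 per
  lineage per substitution/site) create occasional extra copies — the
  real data show multiple Get3d copies in some species — without
  risking the loss of an anchor species' copy, which would make the
  anchor rule inapplicable rather than wrong.
* Domains are 500 sites evolved indel-free under LG, so the true
  alignment is exact and alignment error cannot masquerade as
  phylogenetic error; the aligner is tested separately on indel-mode
  outputs of `evolveSequences()`.
* Proteome metadata: photosynthetic species draw GO:0015979 counts
  `11 + Poisson(30)`, the rest uniform on 0..10; BUSCO uniform on
  [60, 100] with 20% missing; reference/nonredundant flags are coin
  flips (p = 0.5/0.3).
* Tree inference in the pipeline driver defaults to VT with its
  published frequencies — the emulated representative-tree stage's
  model — while sequences evolve under LG, so recovery does not
  depend on inferring under the generating model.

What passing the recovery study shows — and what it does not: with
well-separated subfamilies, indel-free 500-site domains and complete
sampling, the pipeline reassembles the truth essentially perfectly.
Real data add alignment error, heterogeneous rates across sites and
lineages, incomplete and biased taxon sampling, horizontal transfer
and annotation noise; none of these are emulated, so the synthetic
study validates the machinery, not the biology.

## Numerical choices and degenerate inputs

Branch lengths are bounded to [1e-8, 20]; identical sequences get the
lower bound as their ML distance.  Site likelihoods are floored at
1e-300 inside logs; the C++ pruning rescales partials per node.
Ties in greedy clustering fall to the earlier-created representative;
NJ ties follow the neighbor-joining implementation's deterministic
order; altloc ties in PDB reading go to the alphabetically first
identifier.  Empty FASTA input, duplicate ids, gap characters in
unaligned input, all-gap placement queries, overlapping pseudodimer
intervals, non-symmetric distance matrices and absent anchors all
raise errors rather than guessing.

## Known limitations

The profile search has no E-value statistics (bit scores against an
empirical null only); the aligner is progressive, not
consistency-based; the tree search is NNI-only (no SPR) with a single
partition; model choice is explicit rather than automatic; the
structural numbers printed for the deposited crystal structures can
only be recomputed when those coordinate files are supplied, since
they are not redistributable inside the package.  All simulation
sizes quoted above (500 sites, 20 bootstrap replicates, 20 seeds, 50
placement trials) are the package's chosen study sizes; they keep
every check exhaustive at small scale rather than approximate at full
scale.
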