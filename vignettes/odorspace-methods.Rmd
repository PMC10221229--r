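---
title: "Methods: chemical-space clustering and common-feature pharmacophores of odorants"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chemical-space clustering and common-feature pharmacophores of odorants}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models and procedures implemented in
`odorspace`, the parameter choices that matter, and the limits of what
the synthetic benchmarks can show. It states no empirical result that
the test suite or `scripts/acceptance.R` does not itself compute.

## Data model

An odorant dataset is a tibble of molecules — `id`, `name`, optional
`cas`, canonical `smiles`, and a list-column `notes` of lowercase odor
descriptors — plus a *vocabulary*: the set of notes carried by at least
`min_note_occurrence` molecules (default 5). Notes are normalised on
load (lowercase, trimmed, internal whitespace collapsed, deduplicated
within a molecule) and whitespace-separated composites are split into
their constituent notes, so "powdery orris" contributes "powdery" and
"orris". One *occurrence* of a note is one molecule carrying it; this
makes the `%ON` denominator the count of molecules carrying the note.
SMILES are canonicalised (Open Babel) on load so structurally identical
inputs compare equal; rows that fail to parse are reported and skipped,
never silently dropped.

The bundled component table carries the seven mixture molecules with
curated SMILES. Its vocabulary excludes "maple" and "lovage", which the
source flags as occurring fewer than five times in the parent database;
an `external_counts` argument generalises this mechanism: when a small
excerpt is analysed against a larger database's statistics, vocabulary
membership can be decided on externally supplied counts. The curated
55-note panel records the stated composition (25 frequent + 39 mixture
notes, 10 shared) even though those numbers sum to 54, not 55; the
discrepancy is surfaced as attributes rather than resolved.

## Fingerprints, embedding, clustering

Structures are encoded as extended-connectivity fingerprints. The
radius default is 2 (the ECFP4-equivalent community default; the source
protocol names only the bit width) and the native 4096-bit output is
folded to 1024 bits by OR-ing congruent positions. Similarity between
binary fingerprints is Tanimoto; embeddings use the Jaccard distance
`1 - Tanimoto` by default, which respects the binary nature of the
vectors (Euclidean on raw bits is available behind the `metric`
argument).

UMAP (via `uwot` on the precomputed distance matrix) maps the
fingerprint space to 3D with `n_neighbors = 15` and `min_dist = 0.1` —
library defaults, recorded in the result's metadata since the source
names no values — single-threaded so a fixed seed reproduces
coordinates exactly. Clustering operates on the raw embedded
coordinates (not rescaled: the embedding axes are already commensurate).

Two partitioners are provided:

* **k-means** (`stats::kmeans`, best of 20 restarts, seeded). Every
  cluster is non-empty; `k = n` is handled exactly (singletons,
  WSS = 0).
* **SOM**: an online Kohonen map on a rectangular grid, implemented in
  compiled code. The learning rate decays linearly 0.5 → 0.01 and the
  Gaussian neighbourhood radius from half the larger grid dimension to
  0.5 over 500 epochs (defaults). Prototypes initialise from a seeded
  sample of the data and the presentation order is a seeded permutation
  per epoch, so training is fully reproducible. Units that attract no
  molecules are legitimate — the number of effective clusters can be
  below the grid size — and cluster indices are 1-based row-major to
  match the "SOM16-Cl-2" naming convention.

**Cluster-number selection** combines the elbow curve (WSS per k) with
a Kelley-style penalty applied to flat partitions: the spread of the
partition at k is the mean, over clusters of size ≥ 2, of the cluster's
mean pairwise member distance; spreads are min–max normalised over the
evaluated range to `[1, |k_range| - 1]`; the penalty adds k and its
argmin (smallest k on ties) is the optimum. The penalty was originally
defined for level selection in hierarchical trees; applying it to flat
partitions per k is a design choice, with the normalisation documented
in the output so the numbers are interpretable. A k at which every
cluster is a singleton has no defined spread; it is flagged and
excluded.

On the four-family synthetic benchmark the penalty optimum is k = 4 and
clustering **at that selected optimum** (a 2×2 SOM, or k-means with
k = 4) recovers the planted families (adjusted Rand index asserted
≥ 0.6 in the tests, with k-means typically at 1.0). A 4×4 SOM on the
same data is deliberately finer than the structure: UMAP collapses each
family to a tight blob and the map spreads several adjacent units into
each blob, so families split across units and the Rand index against
the 4-label truth drops. That behaviour is a property of comparing a
16-unit refinement to a 4-class truth, not a recovery failure; the
recovery claims are therefore made at the selection-chosen level.

## Odor-note statistics

For note *j* and cluster *c*: `pct_ON = 100 · n_jc / n_j` and
`pct_OM = 100 · n_jc / |c|`. Every (note, non-empty cluster) pair gets
a row, zero counts included; `pct_ON` sums to 100 over clusters for
every note present in the data (the partition-conservation property is
asserted to ±0.1). Notes absent from the dataset are flagged with `NA`
rather than propagating NaN. Empty SOM units are skipped — they have no
molecules to profile.

Co-occurrence uses the same occurrence notion: `counts[i, j]` is the
number of molecules carrying both notes (diagonal: the note's
occurrence count), and the nonsymmetric relative matrix divides each
row by its diagonal (`relative[i, j]` = percentage of note i's
occurrences shared with j; rows for notes with zero occurrences in a
restriction are flagged `NA`). Restricting to a cluster restricts both
the counts and the normalisation. Exports round percentages to one
decimal; the tests compare at ±0.1.

Frequency ranking breaks ties alphabetically, so "the 25 most frequent
notes" is deterministic.

## Odor-profile subset selection

Against a reference odorant, each cluster member gets four descriptors:
`n_common` (notes shared with the reference), `n_noncommon` (candidate
notes absent from the reference — the candidate side carries the
"foreign" count), `pct_common = 100 · n_common / |reference notes|`,
`pct_noncommon = 100 · n_noncommon / |candidate notes|`. The source
never defines the denominators; this convention makes "no more than two
uncommon notes" a parsimony constraint on the candidate's description.
A union-denominator variant is available behind the `convention`
argument.

Selection keeps candidates with `n_common ≥ 3` and `n_noncommon ≤ 2`
(boundary values retained), then — if more than `cap = 10` survive —
sorts by ascending `pct_noncommon`, descending `pct_common`, candidate
id, and truncates at the cap. "Approximately 10" is implemented as a
hard cap with under-full subsets allowed. The reference is excluded
from the candidate pool but listed first in the subset, so a subset of
size s is the reference plus s − 1 selected molecules. The audit table
records every candidate with its descriptors and a pass/fail reason.

## Conformer ensembles

Ensembles are generated by seeded distance-geometry embedding (ETKDGv3)
followed by MMFF94 minimisation (UFF when MMFF parameters are missing,
recorded per molecule), in a Python/RDKit subprocess shipped with the
package. Twice the target count is embedded, energies are taken
relative to the ensemble minimum, conformers above the 21 kJ/mol window
are discarded, duplicates are removed greedily at 0.5 Å symmetry-aware
heavy-atom RMSD (lowest-energy representative kept), and at most 50
conformers are returned in ascending energy order. Every step is
deterministic for a fixed seed, and the same molecule yields the same
ensemble regardless of batch composition because the embedding seed is
shared, not positional. Defaults (50 conformers, 21 kJ/mol) follow the
published protocol.

## Feature perception

Features are perceived from the molecular graph with positions taken
per conformer; the rules ship as an editable data file
(`extdata/feature_rules.csv`):

* **A** — acceptors at the oxygen/nitrogen nucleus: carbonyl O,
  ether/ester O, hydroxyl O, lone-pair N (amide and nitro N excluded;
  aromatic O excluded as a poor acceptor). Donors are deliberately not
  emitted: every donor hydroxyl is already an acceptor, so acceptors
  subsume them.
* **H** — hydrophobes at the heavy-atom centroid of each connected
  group of non-polar carbons (no bond to any heteroatom, non-aromatic),
  with isolated terminal methyls (e.g. the acetate methyl) as
  single-atom hydrophobes. Grouping by connected component is coarser
  than commercial implementations, which subdivide long chains; feature
  counts are therefore smaller but the A-feature geometry — which the
  benchmarks measure — is unaffected.
* **R** — aromatic rings at the ring centroid with the unit plane
  normal. Rings are found as smallest cycles through each bond;
  aromaticity requires size 5–6, C/N/O/S members, a double bond on
  every ring carbon and near-planarity (≤ 0.15 Å from the least-squares
  plane), which works on kekulised 3D structures without relying on
  aromatic bond-order annotations. The `aromatic_as_hydrophobic` option
  re-types R → H, mirroring protocols that treat rings as hydrophobic
  groups; the default keeps R distinct, and ring–hydrophobe pairing can
  instead be allowed at alignment time (`r_as_h`).

## Common-feature pharmacophore search

A hypothesis is an arrangement of 3–6 typed features that at least
`match_fraction = 0.5` of the molecules realise within
`tolerance = 2 Å`. The search: (1) enumerate feature subsets per
conformer; (2) key each subset by kind signature and its sorted
interfeature distances binned at 1 Å, with adjacent-bin matching — this
operationalises the 2 Å tolerance for candidate grouping and is a
pruning heuristic, not the decision rule; (3) keys present in enough
molecules survive; (4) the reference arrangement comes from the
molecule with the fewest conformers (its lowest-energy matching
conformer, first subset in enumeration order — all deterministic
tie-breaks), and every other molecule's best-matching subset is
superposed by least-squares rigid fit, the molecule matching if its
feature RMSD is at most the tolerance; (5) the score is

    0.4 · matched fraction
  + 0.4 · (1 − mean RMSD / tolerance)
  + 0.2 · (n_features − 3 + 1) / 4

bounded by (0, 1]. The commercial score it replaces is proprietary and
undefined in the public record; this transparent form preserves its
ranking semantics — coverage, geometric tightness, feature richness —
with configurable weights. Ranking breaks ties toward more features,
then lexicographic signature. With a single molecule the conformers
play the role of the molecules, giving the pharmacophore of the
molecule's own conformational space. An empty result is valid and
reported as such.

The tests verify the search against exhaustive enumeration (every
subset, every type-preserving bijection, exact tolerance checking) on
small planted-geometry instances, and verify rigid-motion invariance of
signatures, distances and scores to 1e-6.

Hypothesis alignment searches all type-preserving feature pairings of
size ≥ 3 between two hypotheses (feature counts are ≤ 6, so the search
is exhaustive, with a provable distance-mismatch bound used for safe
pruning), superposes each by Kabsch fit and returns the minimum-RMSD
pairing; failure — mirroring "no reliable alignment" outcomes — is
declared when no pairing of the required size exists or the best RMSD
exceeds the 2 Å cutoff. Least-squares RMSD is symmetric in the template
role, which the tests assert.

## The synthetic generator

The generator emulates the statistical structure the analysis assumes:
structural families whose members share fingerprint similarity and
family-typical notes. Molecules are built by template substitution
(scaffold SMILES with attachment slots × substituent fragments), which
guarantees valid, family-coherent chemistry; the default four families
are aliphatic esters (150 molecules; fruity/banana/pear-rich),
vanilloid phenolics (80; vanilla/sweet/creamy), aliphatic lactones (75;
coconut/lactonic/coumarinic) and ionone-like terpenoids (44;
woody/floral/violet) — sizes chosen so that, with 2–5 notes per
molecule, every family's note types clear the occurrence-5 vocabulary
threshold with margin (the tests assert ≥ 90 % retention). An optional
background family (alcohols, aldehydes, ketones, alkylbenzenes,
pyridines, thiols with a broad note distribution) is off by default, so
the stock configuration is a pure four-family benchmark with
unambiguous ground truth.

Notes are drawn per molecule (2–5, weighted sampling without
replacement from the family distribution); with probability
`noise_rate = 0.05` a draw comes instead from the global pool weighted
by pooled family emission mass — the noise reproduces the heavy-tailed
note marginals of real databases rather than flattening them, and keeps
the retained-vocabulary property stable. One random sub-stream is
derived per family, so editing one family's specification does not
perturb the draws of the others.

What the generator does **not** emulate: the real databases' note
marginals (only their qualitative shape), synonym structure and
annotation noise of verbal descriptors, the long tail of singleton
chemistry between families, and any quantitative cluster composition.
Passing recovery tests therefore shows the pipeline recovers planted
structure of this kind at desk scale — not that a particular real
database splits into four families.

## Problem sizes and reproducibility

The test suite runs the full stack at deliberately compact sizes: the
shared synthetic benchmark is 349 molecules; conformer work uses the
bundled real components at the published ensemble settings (50
conformers, 21 kJ/mol); exhaustive oracles run at ≤ 10 points
(clustering) and ≤ 4 features × ≤ 2 conformers × 3 molecules
(pharmacophores). The demonstration pipeline configuration uses 25
target conformers for its pharmacophore stage. Every stage is seeded,
single-threaded and deterministic; the pipeline manifest records
per-stage derived seeds and output checksums, and a rerun from the same
configuration reproduces identical files.

## Known limitations

* Feature perception is rule-based on the molecular graph; it does not
  reproduce any commercial package's feature counts (notably, connected
  non-polar carbon groups give one hydrophobe where finer schemes give
  several), and perception of unusual heteroatom environments follows
  the shipped rules only.
* The distance-bin pruning can in principle miss matches whose paired
  distances differ by more than one 1 Å bin yet still superpose within
  tolerance; on the geometries exercised here the exhaustive oracle
  finds no such case, but the heuristic is documented as such.
* Conformer energies are classical force-field values; the 21 kJ/mol
  window is applied to relative minimised energies, not free energies.
* The Kelley penalty on flat partitions is a transparent adaptation;
  its absolute values are not comparable across datasets, only within
  one evaluated range.
* UMAP coordinates have arbitrary units and are seed-dependent;
  cluster *identities* (which molecules group together) are the
  meaningful output, not coordinate values.
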