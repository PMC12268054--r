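---
title: "SAR landscape analysis with sarscape: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SAR landscape analysis with sarscape: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`sarscape` implements a complete structure-activity relationship (SAR)
landscape analysis for compound potency datasets of the kind assembled
for kinase targets such as c-MET: a table of SMILES structures with
IC50 measurements. This vignette is the package's account of the
methods — the models and statistics each stage computes, the
parameters that matter, the numerical choices, and what the synthetic
validation data does and does not establish.

## Curation model

Raw records carry a SMILES, a positive IC50 and a unit (`nM`, `uM`, or
`M`). Standardization parses the SMILES through OpenBabel, strips
salts and solvents by keeping the single largest organic fragment
(most heavy atoms; ties broken by molecular weight, then by canonical
SMILES order), canonicalizes, and converts the potency to nM. Records
failing any step are rejected with a machine-readable reason
(`invalid_smiles`, `bad_activity`, `bad_unit`). OpenBabel silently
repairs some malformed SMILES, so a structural sanity screen
(balanced parentheses and brackets, even ring-bond digit counts) runs
before parsing.

Activity is a two-class label: **active iff IC50 ≤ 100 nM**, with the
boundary active; the threshold is a configuration parameter so the
pipeline generalizes to other targets. The potency scale used
throughout is pIC50 = −log10(IC50 in molar) = 9 − log10(IC50 in nM).
The literature sometimes prints the defining formula without the
molar conversion; this package always converts, because pIC50 values
around 7–9 (not negative numbers) are what the field's figures show.

Duplicates are keyed on the canonical desalted SMILES. If all copies
agree in label, their IC50s are averaged — arithmetic mean by
default, geometric mean (the usual choice for log-normal potencies)
via configuration — and one record is kept. If labels conflict, all
copies are dropped and counted: a compound with contradictory
measurements is evidence of assay noise, not of either class. The
curation report reconciles exactly: output = input − invalid −
bad-activity − bad-unit − conflicting − (merged copies).

Fold changes between two potencies are reported as max/min at
2-decimal precision, the convention used when comparing analog pairs
(e.g. 4 nM vs. 720 nM is a 180.00-fold change).

## Molecular representation

**Fingerprints.** Similarity throughout the package is Tanimoto
similarity of circular (Morgan/ECFP-type) fingerprints, radius 2,
1024 bits. The implementation hashes atom environments iteratively:
the radius-0 invariant combines atomic number, heavy-atom degree,
implicit hydrogen count, formal charge and ring membership; each
subsequent radius re-hashes the invariant with the sorted
(bond code, neighbor invariant) pairs. Sorting makes the identifiers
invariant to the atom order of the input SMILES (a property the test
suite checks over alternative renderings), and aromatic bonds share a
single bond code so kekulization is irrelevant. An atom whose
neighborhood stops growing keeps its identifier, so a lone atom
contributes exactly one environment. Two all-zero fingerprints have
defined similarity 1; the case cannot arise from a real molecule.

Aromaticity and rings are perceived from the smallest set of smallest
rings via ChemmineR/OpenBabel. Formal charges are treated as zero in
the internal graph: inputs are desalted neutral organics, and the
approximation only touches fingerprint invariants, deterministically.

**Descriptor panel.** A fixed, versioned panel of 39 named 2D
descriptors: OpenBabel bulk properties (MolWt, MolLogP, MolMR, TPSA,
H-bond donor and acceptor counts) plus graph-derived counts and
indices — ring counts by aromaticity and fusion, heteroatom and
halogen counts, `fr_pyridine` (aromatic six-membered rings with
exactly one nitrogen and no exocyclic carbonyl, so pyridinones do not
count), `fr_Ar_N` (aromatic nitrogens), `fr_bicyclic` (edge-fused ring
pairs), rotatable bonds, fraction of sp3 carbons, and Burden-matrix
eigenvalue descriptors `BCUT2D_MWHI`/`BCUT2D_MWLOW` (extreme
eigenvalues of the bond-order-weighted adjacency with atomic masses on
the diagonal). Partial-charge-based surface-area descriptors (the
PEOE_VSA/SMR_VSA families) are deliberately out of the panel: they
require a charge model and the MOE surface parameterization, and the
rule machinery is agnostic to the panel's composition — any named
numeric matrix works. The panel version string is recorded in all
rule output.

**Scaffolds.** Murcko scaffolds keep ring systems plus the linkers
between them, iteratively pruning terminal atoms and then re-attaching
terminal atoms held by a double or triple bond (carbonyl oxygens stay
with their framework). Acyclic molecules have the empty scaffold, and
the operation is idempotent.

**MCS.** The maximum common substructure of a compound set is a
connected common induced substructure found by seeded backtracking
over atom mappings. Atoms must agree on element — and, with
`ring_matches_ring_only = TRUE` (the default everywhere), on ring
membership; bonds must agree on bond class (single/double/triple/
aromatic) and ring membership. Sets of more than two molecules are
folded pairwise starting from the smallest member, so the result can
only shrink as molecules are added. MCS is NP-hard; the search carries
a deadline (default 10 s) and returns the best substructure found so
far, flagged `complete = FALSE`, when it expires. Reported MCS and
scaffold SMILES are reconstructed from the reference molecule's
subgraph and are best-effort canonical.

**2D embedding.** `embed_chemspace_2d()` is classical
multidimensional scaling of Tanimoto distance. It is
visualization-grade only — it supports chemical-space maps and enters
no quantitative result — and it is fully deterministic (the `seed`
argument is recorded for interface stability, not consumed).

## Clustering

Hierarchical clustering runs on the raw 1024-bit fingerprint vectors
with Euclidean distance and the Ward criterion (`hclust` method
`ward.D2`), with no prior dimensionality reduction. Euclidean-on-bits
is unusual — Tanimoto-based metrics are more conventional in
cheminformatics — but it is the configuration this analysis style
uses, and on binary vectors squared Euclidean distance is the size of
the symmetric difference of the bit sets, a close cousin of Tanimoto
distance.

The cluster count is a user choice informed by `silhouette_scan()`
(mean silhouette width over a k grid); nothing is hard-coded. Cluster
summaries report the activity composition, IC50 statistics, the
minimum and median pairwise intracluster Tanimoto similarity (the
median is the cluster-cohesion score used to describe clusters), and
the cluster's MCS scaffold. Singleton clusters take similarity 1.0
with an explicit flag — a convention that keeps summary tables
arithmetic-safe rather than propagating NaN. Clusters with more than
80% actives (strict inequality) are called activity-enriched; the
cuts are configurable.

## Chemical space networks

The CSN is built over the most potent compounds (default: top 100
actives by IC50 in the reference conditions; ties at the cutoff are
broken by canonical SMILES order so selection is deterministic). All
C(n,2) pairs are evaluated; an edge joins pairs with Tanimoto **≥**
the threshold (0.6 by default). Isolated nodes are dropped by default
and density 2E/(N(N−1)) is computed over the retained node set — the
convention that reproduces the "fewer nodes than selected compounds"
behavior of published CSNs; both conventions are available via
`drop_isolated`. Components come from undirected reachability; each
is reported with its pIC50 range. GraphML export carries all node and
edge attributes and round-trips exactly; the edge CSV (4-decimal
similarities) is paired with a node CSV for the same guarantee.

Note the deliberate asymmetry: the CSN edge rule is inclusive (≥),
the cliff rule below is strict (>). Published definitions use both
phrasings; both are exposed through the `strict` flag.

## Activity cliffs

All unordered pairs with Tanimoto strictly above 0.6 are enumerated
and classified by their label pair: both-active, both-inactive, or
**cliff** (opposite labels). The cliff definition is label-based; no
additional potency-gap minimum is imposed, though every pair carries
its fold change. Pairs are counted once (unordered), with ids in
canonical order.

Per-compound profiles tally opposing-class partners: an **active**
compound with at least `min_partners` (default 10, matching the
reported 10–34 partner range of such analyses) inactive neighbors is
a *dead end* — its neighborhood shows that small changes keep killing
activity; an **inactive** compound with that many active neighbors is
a *safe bet*. The categories are label-disjoint by construction. A
per-cluster cliff census counts each cliff pair toward both members'
clusters and ranks clusters by cliff load.

## Structural alerts

The alert statistic asks, for every circular atom environment up to
radius 3: is this substructure carried by significantly more (or
fewer) actives than the dataset's active fraction predicts? Counting
is presence/absence — a compound contributes each distinct
environment once — because the hypergeometric urn model requires
per-compound indicators. Environments are the same unfolded hash
identifiers that underlie the fingerprint, so there are no bit
collisions. (The ECFP4 label conventionally means radius 2; the alert
radius here is 3, following the analysis convention this package
reproduces, and it is configurable.)

With N compounds, K active, an environment in n compounds of which k
active, the tails P(X ≥ k) and P(X ≤ k) of the hypergeometric law are
computed with `stats::phyper`; the test suite checks them against
exhaustive combinatorial enumeration over every urn with N ≤ 25.
Environments with n ≥ 30 and min(p) ≤ 0.05 are reported, ranked by
p-value, with direction (enriched → active alert, depleted → inactive
alert) and act% = 100·k/n. No multiple-testing correction is applied
by default, matching the practice this analysis style follows;
Bonferroni and Benjamini-Hochberg are available via `p_adjust`.
Reported substructure SMILES are reconstructed from a carrier
molecule's neighborhood and are for reporting only; the environment
identifier is the ground truth. Output is invariant to record order
(example carriers are chosen by smallest canonical SMILES).

## Anchor rules

A classification tree (rpart, Gini splits) of activity on the
descriptor panel is grown to depth 10 with no complexity pruning
(`cp = 0`, `minsplit = 2`, `minbucket = 1`), mirroring an
unregularized default classifier; the depth bound is the only
regularizer, and the model exists solely for rule extraction — it is
not, and should not be read as, a virtual-screening predictor. Its
training accuracy is reported for transparency.

Rule extraction is a decision-path reimplementation of the anchors
idea rather than a port of the published anchors algorithm: candidate
rules are the root-to-leaf paths of leaves predicting the target
class; each is greedily pruned — always removing the predicate whose
removal most increases coverage — as long as empirical precision
(fraction of matching training compounds in the target class) stays
at or above the 0.80 threshold. rpart splits at midpoints between
observed values, so its `x >= t` / `x < t` conditions are converted
to the `>` / `≤` predicate algebra without changing any compound's
membership. Rules are deduplicated and ranked by coverage.
Thresholds are displayed at 2 decimals but applied at full precision.

Each rule also carries a perturbation-based **anchor precision**: the
tree's precision on synthetic descriptor vectors drawn from the
per-descriptor empirical marginals, with columns under a predicate
drawn from the satisfying values (seeded, 500 draws by default). This
estimate and the empirical percentage-of-actives are reported
separately and are not interchangeable — the perturbation estimate
depends on the sampling distribution, the empirical one is exact
counting.

## The synthetic study dataset

The generator emulates the statistical structure of a curated kinase
inhibitor corpus without copying any real data. Its defaults are the
package's reference study conditions:

- **Six scaffold families, 60 compounds each**, built by decorating
  large template cores — pyridazinone-morpholinopyrimidine, quinoline
  cyclopropane-dicarboxamide, triazolopyrazine-quinoline, bipyridine
  amide, naphthyridinone, pyrrolopyrimidine chemotypes (a seventh,
  dimethoxyquinoline, is available) — with small substituents
  (halogens, methyl/ethyl, methoxy, amino, nitrile, hydroxyl,
  pyridyl). Decoration is deterministic template string assembly,
  validated by parsing; all structures are unique by canonical
  SMILES. Measured over the template enumeration, intra-family
  Tanimoto similarity is ≈ 0.5–0.7 and inter-family ≈ 0.1–0.2, the
  separation a clustered medicinal-chemistry corpus shows.
- **Potencies**: log10(IC50/nM) is normal with mean 1 (10 nM) for
  active-state and mean 3 (1000 nM) for inactive-state compounds,
  sd 0.4 — two populations straddling the 100 nM label threshold with
  ≈ 0.6% label noise, like a real actives/inactives split. A fixed
  subset of records is emitted in µM to exercise unit conversion.
- **Family activity fractions** (0.85 … 0.15 across chemotypes) are
  imposed as exact stratified counts — round(p·m) actives with
  randomized identities — not binomial draws, so the composition of
  every run matches the design and planted-signal contracts do not
  wobble with the seed.
- **Planted cliffs** (10 pairs): single-substituent variant pairs of
  one parent, potencies on opposite sides of the threshold at ≥
  100-fold ratio, pair similarity verified > 0.6 at generation time
  (unsatisfiable pairs are skipped with a warning).
- **Planted enriched fragment**: the pyridazinone family's carriers
  are re-labeled to an exact 95% active fraction, making the family
  core a recoverable enrichment alert (the act% mirrors the ~94%
  pyridazinone enrichment that motivates this analysis).
- **Planted rule**: `fr_nitrile > 0`. The nitrile substituent is drawn
  independently of scaffold family, and its carriers are re-labeled to
  an exact 85% active fraction, so the rule is a substituent-borne,
  cross-family activity driver. An earlier design tied the rule to a
  single chemotype; that is not a rule but a family proxy, and a
  tree will legitimately prefer any other descriptor that identifies
  the same family. Plantings never undo each other: cliff pairs keep
  their potencies through fragment planting, and both keep them
  through rule planting.

Under these conditions (verified across seeds, and asserted in the
acceptance suite at its fixed seed): Ward clustering recovers the
families with adjusted Rand index 1.0; all planted cliffs are
recovered at Tc > 0.6; the planted fragment is the top-ranked
enrichment alert with its support inside the carrier set; and the
planted rule is extracted literally with empirical precision ≈ 85%.
One deliberate subtlety: because the conditions also contain naturally
inactive chemotypes, environments shared by those families produce
*depletion* alerts with two to three times the support of any single
family, and those can outrank the planted enrichment in the overall
p-value ordering. That is correct behavior of a two-sided statistic,
so the recovery contract is "first among enrichment-direction alerts",
not "first overall".

**What passing these tests does not show.** The generator's chemistry
is template assembly: it has no stereochemistry, no tautomers, no
charged species, no assay noise structure beyond log-normal spread,
and family separations cleaner than a real corpus, where scaffolds
blend into each other and cluster recovery would be partial. The
synthetic results validate the machinery — the statistics, the
bookkeeping, the determinism — not any claim about a particular
target's SAR.

## Numerical and reproducibility choices

- Environment/fingerprint hashing is integer arithmetic modulo
  2^31 − 1 in doubles (exact well below the 2^53 limit), so
  fingerprints are bit-identical across platforms.
- Every stochastic step (generator, rule perturbation) derives from an
  explicit integer seed; the pipeline threads one manifest seed
  through all stages. `run_pipeline()` with an identical manifest
  reproduces all artifacts byte for byte, which the acceptance suite
  checks with checksums.
- Tie-breaks are deterministic everywhere: potency ties by canonical
  SMILES, cluster summaries by cluster id, alert order by (p-value,
  environment id), rule order by (coverage, rule text).
- Degenerate inputs have defined behavior rather than errors where a
  convention is safer: singleton clusters (similarity 1 + flag),
  empty rule match sets (flagged stats, not an exception), graphs
  with fewer than 2 nodes (density 0), all-zero fingerprints
  (similarity 1).
- The reference problem sizes (380-compound study set, top-100 CSN,
  depth-10 tree, radius-3 alerts) were chosen so a full analysis runs
  in about a minute on one CPU; every size is a configuration
  parameter, and the same code paths serve larger corpora unchanged.

## Known limitations

- Tautomer and charge standardization beyond desalting are out of
  scope; stereochemistry is carried through SMILES but ignored by the
  fingerprint invariants.
- The MCS is exact only within its deadline; on very large or very
  repetitive clusters the returned scaffold may be a lower bound
  (flagged).
- The descriptor panel omits charge-based surface-area descriptors
  (see above); rules over such descriptors cannot be expressed until
  a panel with them is supplied.
- Anchor precision depends on the marginal perturbation distribution;
  it is a diagnostic, not a calibrated probability.
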