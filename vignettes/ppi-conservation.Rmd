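---
title: "Consolidating PPI databases and measuring evolutionary conservation"
author: "ppiconserve"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consolidating PPI databases and measuring evolutionary conservation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppiconserve)
```

## Scope and model of the data

`ppiconserve` treats a protein–protein interaction (PPI) as an *unordered*
pair of protein accessions observed within one species. The comparison key
throughout is `(canonical pair, taxid)`: the same accession pair reported in
two species counts as two PPIs, because downstream analyses partition
interactions by species. Pairs are canonicalized lexicographically;
self-pairs (homodimers) are legitimate records. A database release reduces
to a `ppi_snapshot` — a deduplicated set of such keys plus ingestion
counters (malformed lines, interaction-type-filtered records, cross-species
records, records lacking a taxid).

Two assumptions are embedded at ingestion and worth making explicit:

* **Physical interactions only.** The default PSI-MITAB interaction-type
  allow-list is `{MI:0915 (physical association), MI:0407 (direct
  interaction)}`. Databases disagree on evidence vocabularies, and no
  public definition exists of exactly which evidence classes each resource
  treats as "physical", so the allow-list is a configurable surrogate:
  pass `allowed_interaction_types = character()` to disable the filter.
* **One species per record.** MITAB rows whose two interactor taxids differ
  are dropped (and counted): cross-species records cannot be assigned to a
  single species bin.

Accession normalization strips isoform suffixes (`-N`) from UniProt-shaped
accessions only — the regular expression guards against corrupting other
identifier schemes — and then applies a secondary-to-primary map. The
operation is idempotent and can only shrink a snapshot.

## Overlap statistics

Concordance between snapshots is summarized two ways:

* **Exclusive intersections** (the UpSet quantity): every key of the union
  is assigned to exactly one membership signature, so signature counts sum
  to the union size. Display order is fixed by descending snapshot size.
* **Overlap coefficient** (Szymkiewicz–Simpson),
  $OC(A,B) = |A\cap B| / \min(|A|,|B|)$. Unlike Jaccard it equals 1
  whenever one set contains the other, which is the right behaviour when
  one database redistributes a subset of another. The matrix median is
  taken over the strict upper triangle (each unordered database pair once,
  midpoint convention for ties). An empty snapshot yields a *missing*
  coefficient, never 0 — a 0 would fabricate disagreement.

The "found in two out of eight databases" convention is ambiguous between
exactly-two and at-least-two; both are implemented
(`shared_by_exactly()`, `shared_by_at_least()`) and the pipeline defaults
to at-least-2.

## Homology clustering as an identifier-artifact control

If database disagreement were an artifact of inconsistent identifiers
(isoforms, secondary accessions, species-specific paralog naming), merging
near-identical sequences should visibly raise the overlap coefficients.
The control works as follows:

* **Pairwise identity** is computed by Needleman–Wunsch global alignment
  (match +1, mismatch 0, linear gap −1, via `Biostrings`), normalized by
  the *shorter* sequence length — the CD-HIT convention, robust to
  fragment entries. The choice of denominator is documented because
  different clustering tools default differently and results are sensitive
  to it.
* **Greedy clustering** scans sequences longest-first (ties by accession),
  assigning each to the first representative at or above the identity
  threshold, else founding a new cluster. This is the standard centroid
  heuristic: deterministic, and representatives are mutually below
  threshold in scan order. Thresholds of 0.8 and 0.9 are the conventional
  pair to run. An import path (`read_clusters()`) accepts any external
  two-column member/representative TSV, so an MMseqs2-style clustering can
  replace the internal one; reproducing any particular external tool's
  coverage semantics is explicitly not a goal.
* **Remapping** replaces accessions by representatives and re-deduplicates;
  `overlap_delta()` then reports the maximum absolute off-diagonal change
  of the coefficient matrix, in percent. A small delta supports the
  conclusion that disagreement is real, not nomenclatural.

## Conservation spans and structure-coverage enrichment

Interactions are projected onto ortholog-group pairs through a supplied
accession-to-group table (orthology inference itself is out of scope; the
table is an input, one group per protein at the chosen taxonomic level —
multi-group rows are rejected and counted). The **span** of a group pair is
the number of distinct taxa in which any member pair was observed. Taxa
form a set: within-species paralog pairs mapping to the same group pair do
not inflate the span, and database provenance is carried but never affects
identity. A span of at least 2 defines an evolutionarily conserved PPI.
We count any observation per species; requiring experimental evidence in
*every* species would be a stricter reading, and the mapping-table input
leaves that choice to the user.

Structure coverage stratifies group pairs by span level (1…cap−1, ≥cap;
cap defaults to 6) and counts pairs with and without a PDB complex
structure in a supplied index. A group pair is "solved" if any member pair
has any PDB ID — the index is an explicit input because chain-level mapping
rules differ between studies. Enrichment at level *s* is the odds ratio
against the span-1 baseline,

$$OR_s = \frac{a_s / b_s}{c / d},$$

with the Haldane–Anscombe 0.5 correction applied to all four cells when any
cell is zero (on by default: top span levels are small and nearly fully
solved, so zero unsolved cells genuinely occur), a log-normal 95% CI, and
Fisher's exact p-value reported alongside. The unsolved listing
(`unsolved_pairs()`) orders span-descending, then lexicographically —
the prioritization view for structural follow-up.

The conserved network has ortholog groups as nodes and group pairs with
span ≥ `min_span` (default 5) as edges, annotated with span, solved flag
and PDB IDs. Self-loops (homo-oligomer group pairs) are kept but never
merge components and count as one edge in tiebreaks. "Largest" component
is defined by node count — the conventional figure caption does not define
it — with edge count and then smallest node ID as documented tiebreaks.
Multi-edges cannot arise: spans are collapsed per group pair before the
graph is built.

## Structural-ensemble analysis

All structure work is Cα-only, which keeps the PDB reader minimal and
matches the RMSF convention used for flexibility figures.

* **Superposition** is closed-form Kabsch: SVD of the weighted
  cross-covariance with a sign flip of the smallest singular vector to
  enforce a proper rotation. Collinear point sets are rejected (the
  rotation would not be unique).
* **RMSF** superposes every conformation onto an iteratively refined mean
  structure — fit to the first model, average, refit to the average,
  average again (two passes) — then reports
  $\mathrm{RMSF}_i = \sqrt{\overline{|x_{mi}-\bar x_i|^2}}$. The fit
  selection defaults to all residues; passing a rigid-core selection is
  recommended when large flexible regions would otherwise drag the fit.
  The two-pass mean protocol is a documented surrogate: published RMSF
  figures rarely state their fitting protocol.
* **Contact frequency** between two chains is the fraction of models with
  Cα–Cα distance at or below the cutoff (default 8 Å, configurable — the
  atom set and cutoff behind published contact maps are usually unstated).
* **TM-score** uses the standard normalization
  $d_0 = 1.24(L_t-15)^{1/3} - 1.8$ with $L_t$ the reference length
  (requiring $L_t \ge 16$), and the standard iterative maximization:
  seeds from full-length and sliding L, L/2, L/4 fragment fits, each
  refined by refitting on residues within a distance threshold that starts
  at $d_0 + 1$ Å and shrinks by 0.5 Å to a floor of 1.5 Å, the inner loop
  converging when the retained-residue set repeats. The residue
  correspondence is *supplied*, not searched — structural alignment search
  (TM-align) is out of scope, so scores are meaningful only under a given
  residue pairing. `fold_consistency()` applies the conventional
  TM > 0.5 same-fold threshold across an ensemble.

## The synthetic-data generator

Real database releases are large and unversionable inside a package, so the
generator emits every input the pipeline reads, with ground truth:

* **Snapshots** are drawn from a shared pair universe (default 5,000 pairs
  over 400 accessions, 10 species with model-organism-skewed assignment).
  The default specification has eight databases of decreasing size with one
  exact containment: the smallest database is sampled from within another
  at 11% of its size, emulating a resource that redistributes a subset of a
  larger one; its overlap coefficient is 1 by construction. Truth records
  store the sampled key sets, so every downstream overlap statistic has an
  enumerable expected value.
* **Orthology** plants a span per group pair (default distribution
  dominated by span 1, decreasing to span 8) and emits exactly one
  accession pair per selected taxon, so `build_spans()` recovers the
  planted spans *exactly* — this is a deterministic identity, not a
  statistical one.
* **Structure indices** mark each group pair solved with probability
  $p_\ell$ where $\mathrm{odds}(p_\ell) = OR_\ell \times
  \mathrm{odds}(p_1)$; defaults are baseline 0.05 and planted ORs
  (1, 6, 22, 80), so estimated log-ORs can be compared to planted ones.
* **Sequence families** use i.i.d. uniform centroids; the first member of
  each family is the unmutated centroid (the founder, mirroring the
  centroid convention of greedy clusterers) and the rest are per-site
  mutated copies. At 10% divergence a member sits ~90% identical to its
  centroid and ~5% to other families, so a 0.8 threshold cleanly recovers
  the planted partition.
* **Ensembles** place two chains as rigid bodies (3.8 Å Cα spacing, 20 Å
  apart) and displace flexible residues isotropically with per-residue
  amplitude, so expected RMSF is amplitude × √3. One interface residue
  pair is placed within contact distance in an exact fraction of models —
  deterministically, so the recovered contact frequency is exact; that
  residue is excluded from the planted RMSF profile since its motion is
  bimodal, not Gaussian.

Each generator draws from its own seeded stream (`seed` + fixed offset) and
restores the caller's RNG state, so changing one generator's draw count
never perturbs another, and every generator is byte-deterministic given its
seed.

**What passing on synthetic data does not show:** the generator plants
uniform random pairs and sequences, not the degree distributions, curation
biases, literature co-citation structure or real orthology depth of actual
databases. Synthetic recovery validates the *computations* — set algebra,
span aggregation, contingency statistics, superposition — not any empirical
claim about particular database releases.

## Numerical choices and degenerate inputs

* Overlap coefficient of an empty set: missing (`NA`), excluded from the
  matrix median.
* Empty span level: zero counts with an undefined (`NaN`) proportion, and
  an `NA` odds-ratio sentinel when the baseline is empty.
* Kabsch requires ≥ 3 non-collinear points (second singular value above
  1e-9 relative tolerance); rotations are orthonormal to 1e-8.
* TM-score seeds that hit degenerate fragments are skipped rather than
  failing the whole maximization; the score is capped at 1 against
  floating-point overshoot.
* Problem sizes in the tests and acceptance script (5,000-pair universes,
  600 group pairs, 20,000 pairs per span level for odds-ratio calibration,
  200-model ensembles, ≤ 200 sequences) were chosen as the smallest sizes
  at which the planted-parameter recoveries are statistically comfortable;
  all complete in well under a minute each on a laptop-class machine.

## Known limitations

* PSI-MI XML, mmCIF and live REST access are not supported; inputs are
  files (gzip accepted everywhere).
* The MITAB reader implements the minimal 15-column dialect (IDs, taxids,
  interaction type); controlled-vocabulary expansion beyond the MI
  identifier is not parsed.
* The greedy clusterer is quadratic in the number of representatives and
  intended for desk-scale controls, not proteome-scale clustering — use an
  external tool and `read_clusters()` for that.
* TM-scores are conditional on the supplied correspondence; no alignment
  search is performed.
* Structure "coverage" means presence of any PDB ID in the input index;
  whether a deposited structure truly covers the interaction interface is
  not assessed.
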