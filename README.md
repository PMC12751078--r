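# ppiconserve

Cross-database consolidation and evolutionary conservation analysis of
protein–protein interaction (PPI) networks.

## The problem

Public PPI databases (BioGRID, IntAct, MINT, DIP, STRING, …) disagree far
more than users expect: each release captures a different slice of the
literature, identifiers are used inconsistently, and no database holds a
core set of interactions. For a proteome of *n* proteins there are
*C(n, 2) = n(n−1)/2* potential unordered pairs — about 8 million for a
4,000-protein bacterium and 200 million for the ~20,000-protein human
proteome — so deciding which reported pairs are functional matters.
`ppiconserve` provides a tested pipeline for researchers who want to

1. **harmonize** database snapshots to canonical `(pair, taxid)` records
   (PSI-MITAB or edge-list input, secondary-accession and isoform cleanup);
2. **quantify concordance** via exclusive (UpSet-style) intersection counts
   and the Szymkiewicz–Simpson overlap coefficient
   *OC(A, B) = |A ∩ B| / min(|A|, |B|)*, which is 1 whenever one database
   contains the other;
3. **test the identifier-artifact hypothesis** by greedy identity-threshold
   clustering of protein sequences (Needleman–Wunsch identity, shorter-length
   normalization) and re-computing overlaps on cluster representatives;
4. **measure evolutionary conservation** by projecting interactions onto
   ortholog-group pairs: the *conservation span* of a group pair is the
   number of distinct species in which it was observed;
5. **quantify structure coverage** per span level against the Protein Data
   Bank as odds ratios *OR = (a/b)/(c/d)* versus the non-conserved (span-1)
   baseline, with Haldane–Anscombe correction and log-normal 95% CIs, plus a
   ranked listing of conserved pairs that remain structurally unsolved;
6. **extract conserved networks** (group-pair graphs at a minimum span, with
   solved/unsolved edge annotation, component ranking, GraphML/TSV export);
7. **analyse structural ensembles** of a complex: Kabsch superposition,
   per-residue Cα RMSF about an iterative mean structure, inter-chain
   contact frequency maps, and TM-scores
   *TM = (1/L_t) Σ 1/(1 + (d_i/d0)²)*, *d0 = 1.24 (L_t − 15)^{1/3} − 1.8*,
   against a reference fold.

Because real database releases are large, moving targets, the package ships
a first-class **synthetic-data generator** that emits every input format the
pipeline reads with planted ground truth (containment relations, spans,
per-span odds ratios, sequence families, flexibility profiles), so every
stage can be validated end to end.

## Worked example

```r
library(ppiconserve)
res <- run_demo("demo_out", seed = 1)

res$overlap$summary
#> $n_snapshots        8
#> $union_size         4841
#> $intersection_size  0
#> $n_shared           4053
#> $median_overlap     0.4638889

res$overlap$matrix$values["db_c", "db_h"]
#> [1] 1                     # db_h is drawn from within db_c: containment => OC = 1

res$conserve$histogram
#>   1   2   3   4   5 >=6
#> 270 146  66  39  39  40

res$conserve$enrichment[, c("level", "proportion", "odds_ratio")]
#>   level proportion odds_ratio
#> 1     1     0.0444       1.00
#> 2     2     0.2055       5.56
#> 3     3     0.5606      27.43
#> 4     4     0.7949      83.31
#> 5     5     0.7692      71.67
#> 6   >=6     0.6750      44.65
```

The demo simulates eight database snapshots over a shared pair universe
(union 4,841 records; the smallest snapshot is an exact subset of another,
so their overlap coefficient is exactly 1), plants conservation spans for
600 ortholog-group pairs (histogram above), and plants per-span
structure-coverage odds ratios of 1, 6, 22 and 80 — the enrichment table
recovers them (5.6, 27, 83 at spans 2–4; levels 5 and ≥6 reuse the last
planted value) together with the rising proportion of solved pairs. The
`demo_out/` directory holds all stage outputs (TSV/CSV/GraphML/JSON) plus
`truth.json` with the planted parameters; `res$conserve$unsolved` lists the
175 conserved-but-unsolved group pairs, span-descending.

A command-line wrapper with subcommands `demo`, `simulate`, `overlap`,
`cluster`, `conserve` and `ensemble` is installed at
`inst/cli/ppiconserve.R`:

```sh
Rscript inst/cli/ppiconserve.R demo --out demo_out --seed 1
```

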