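---
title: "Auditing annotation darkness and aggregating functional evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing annotation darkness and aggregating functional evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(darkgenes)
library(dplyr)
```

## The problem

Differential-expression analysis of toxicogenomics experiments routinely ends
with pathway or Gene Ontology enrichment — and silently discards every gene
that no annotation resource covers. In hepatocyte experiments contrasting
compounds with high and no risk of drug-induced liver injury (DILI), a
substantial minority of the responsive genes — many of them non-coding — fall
through this annotation net. We call a gene *dark* when it is absent from all
five configured biological-process/pathway resources: the GO biological
process branch, Reactome, MSigDB curated pathways, Pathway Commons (after
removing interactions without pathway annotation) and OmniPath (after
removing interactions supported only by pure protein–protein interaction
databases).

Darkness is not evidence of irrelevance. This package therefore assembles,
for each dark gene, every orthogonal line of evidence that does not depend on
process annotation: presence and degree in protein-interaction networks,
curated and text-mined disease associations, GeneRIF statements and
publication counts, membership in transcription-factor regulons and
signaling-pathway expression signatures, and rat-ortholog membership in
co-expression modules correlated with liver pathologies.

## Pipeline stages and their assumptions

### Identifier harmonization

All gene identity flows through Entrez IDs. Symbols resolve through a fixed
cascade — primary symbol, then synonym, then UniProt accession — and matching
is case-insensitive because the source files mix conventions. A token whose
winning step yields more than one candidate is *reported as ambiguous and
excluded* rather than arbitrarily resolved: a silent mis-mapping would
corrupt darkness calls downstream, and the mapping report makes the exclusion
auditable. The catalog is a frozen snapshot; withdrawn or historical IDs are
not resurrected.

### Differential expression

Each compound contributes one stratum (in the intended application: highest
dose, 24 h, versus time-matched controls). The per-gene statistic is a
two-sample t on log2 intensities. The default, `eb_moderated`, shrinks each
gene's pooled variance toward the grand mean variance with a fixed prior of
4 degrees of freedom before forming the statistic, adding 4 df to the null
distribution. We made the moderated statistic the default after a numerical
power check: with 3 replicates per arm and log2 noise sd 0.25, an
unmoderated pooled t recovers under 40% of planted 1.2-log2 effects once
Benjamini–Hochberg correction is applied across 2,000 genes, while the
moderated statistic recovers about 95% at an empirical false-discovery rate
under 0.01. This mirrors standard microarray practice, where
moderated statistics are the norm for small designs; the exact
empirical-Bayes machinery of those tools is intentionally not duplicated —
a fixed prior df and a pooled shrinkage target keep the estimator
reproducible from this package's code alone. `t_pooled` and `t_welch` remain
selectable for larger designs.

A gene is a DEG when both gates pass: BH-adjusted q below `fdr_alpha`
(default 0.05) and `|log2fc| >= log2(1.5)` — the *exact* logarithm
(0.5849625), not the conventionally printed 0.585, and the comparison is
inclusive because "an absolute fold change of 1.5" reads as attainable at
the boundary. Degenerate rows (zero variance in both arms, equal means) get
p = 1 by the no-signal convention; zero variance with unequal means gets
p = 0.

### The annotation universe and darkness

Each resource contributes a filtered set of annotated Entrez IDs:

* **GO**: only aspect `P` rows count; molecular function and cellular
  component say little about the biological mechanism. Evidence codes are
  all kept by default (electronic annotations included) — an exclusion list
  is exposed for stricter audits, since the sources do not agree on whether
  IEA-only genes are "annotated".
* **Pathway Commons**: rows whose pathway field is empty after whitespace
  stripping do not contribute; a gene seen only in such rows is unannotated.
* **OmniPath**: rows whose source list is a subset of {BioGRID, HPRD,
  IntAct} are dropped — pure PPI support is connectivity, not pathway
  membership. An empty source list is conservatively treated as PPI-only.
* **Reactome / MSigDB**: GMT membership as configured; the union of set
  members is the annotated set.

A gene is dark exactly when it appears in none of the resources, so adding a
resource can only shrink the dark set (tested as a monotonicity property).
The same classification runs over the full array background to show that
darkness is a property of the platform, not of the treatment response.
Because published reports mix display conventions for percentages (a 13.24%
dark fraction reported as "~13%", a 76.5% coverage reported as "76%"), the
coverage tables carry the raw fraction plus both round-half-up and floor
display values.

Biotype tallies collapse all pseudogene subtypes into a single `pseudogene`
category and report genes with unknown biotype in a separate uncategorized
row, excluded from the categorized total — matching how such audit tables
categorize only the subset with a recognized gene type.

### Interactome degrees

Each snapshot is cleaned to an undirected simple graph: direction and
duplicate orientation collapse, self-loops are removed, and rows flagged as
predicted interactions are dropped where the snapshot provides such a flag.
Presence in a snapshot means at least one retained edge — a gene appearing
only in removed rows is absent, the stricter of the two readable
conventions. Confidence scores are ignored by default, with a minimum-score
filter available. The ranking of "top connected" genes is by default the
maximum degree across snapshots (the "highly connected in at least one
resource" reading); sum and mean are selectable since the choice is not
canonical. Ties break by ascending Entrez ID so reports are deterministic.

### Literature counts

Disease associations count *distinct* disease IDs per gene, in two tiers:
curated rows only, or all rows including text mining — curated counts can
never exceed all-tier counts. GeneRIF entries count rows (each row is one
statement), with a highlight bar at 10 entries, configurable. Publication
counts are distinct PMIDs per gene; one publication mentioning several genes
increments each of them. Disease-vocabulary normalization is out of scope:
input tables must already carry stable disease identifiers.

### Regulons, signatures, consensus

A transcription factor (or pathway signature) is *mapped* for a compound
when its target set intersects that compound's dark genes — membership, not
an over-representation test, because the mapping is meant as a recall-first
audit of which regulatory contexts could explain a dark gene. An optional
hypergeometric mode (background: all dark genes) is available but off by
default, and regulon confidence grades are filterable.

The group consensus intersects per-compound regulator sets. Two empty-set
policies are exposed because both are defensible: `strict` (one compound
with no hit forces an empty consensus) and `exclude_empty` (compounds with
no mapped regulator at all — as happens for weakly active compounds with a
handful of dark genes — are excluded before intersecting). The pipeline
default is `exclude_empty`; the policy is recorded in the result. Venn
region counts are computed combinatorially for 2–6 sets, and the all-sets
region always equals the strict intersection (a tested invariant).

### Cross-species module context

Human dark genes map to rat orthologs; one-to-many pairs are all kept and
flagged, since dropping them would hide module hits. Module membership is a
free join table (soft assignment allowed), and the pathology report keeps
only modules carrying at least one pathology label, rendering absent GO-BP
context as a placeholder token. Pathology vocabulary is free text from the
input table; no ontology mapping is attempted.

### Evidence integration

Twelve binary sources are combined (four interactome presences, two disease
tiers, GeneRIF, publications, regulon, signature, rat ortholog, module
membership). The exact composition is configurable because any such list is
a reconstruction — the defensible core is that every flag is a "has at least
one" statement. Whether the two disease tiers should count as one or two
evidences is genuinely open; both appear as separate columns and the source
list can be trimmed. The score S is the row sum; tiers are `high` (S ≥ 8),
`moderate` (4 ≤ S < 8), `low`, `none` (S = 0), with both cutoffs
configurable. Exclusivity flags operationalize "not perturbed by no-DILI
drugs" as "not a called DEG in any no-DILI compound" (not as raw fold change
near zero): `most_dili_exclusive` needs ≥ 1 most-DILI hit and 0 no-DILI
hits, and the stronger flag needs ≥ 4 of the 5 most-DILI compounds, so it
implies the weaker one.

## The synthetic world

Real inputs are frozen database snapshots that cannot be redistributed, so
the package ships a seeded generator producing every input table with
planted ground truth. The default world has 2,000 genes, 5 + 5 compounds,
3 replicates per arm, log2 noise sd 0.25, and planted treatment effects of
1.2 log2 units (random sign) on 200 genes per compound, of which 15% are
drawn from the 150 planted dark genes. Those sizes are the conditions all
planted-truth tests refer to. Annotation coverage probabilities (0.30–0.70
per resource) produce a realistic spread of per-resource membership while
every non-planted gene is guaranteed membership in at least one resource —
so the planted dark set is exactly the truth, and darkness recovery can be
asserted with zero errors. Interactome edge lists draw endpoints with
power-law weights (tail exponent 0.8), giving the heavy-tailed degree
distributions the degree reports are designed around.

Planted group-consensus regulators are constructed to target at least one
dark DEG of *every* compound in their group, so a strict consensus must
recover them; recovery failures would indicate a defect in the mapping or
intersection code, not sampling noise. Each artifact draws from its own
named substream of the seed, so adding a new output file never perturbs
existing ones, and `write_world()` emits plain-text files with an MD5
manifest — identical config and seed give byte-identical bytes.

What the generator deliberately does **not** emulate: probe-level microarray
noise, batch effects, correlated gene-gene expression, realistic literature
count distributions (simple Poisson rates are used), ontology structure
inside GO, or module co-expression structure (module membership is sampled,
not derived from rat expression). Passing planted-truth tests therefore
demonstrates the correctness of the pipeline's logic under its stated
statistical model — not that the pipeline's numbers on real snapshots would
match any published audit, which depends on the snapshot dates and filters
of those databases.

## Numerical choices and degenerate inputs

* BH adjustment delegates to the standard step-up implementation and is
  property-tested against a quadratic-time reference.
* Zero-variance rows: p = 1 when means agree, p = 0 otherwise.
* Empty regulator sets: `consensus_sets()` warns and returns an empty
  consensus when every set is empty under either policy.
* A world with zero planted dark genes runs end-to-end and produces empty
  dark-gene downstream tables with a populated coverage report.
* Ranking ties break by ascending Entrez ID; all outputs are sorted so that
  reruns are byte-identical (the run log records versions and policies but
  no timestamps).

## A small worked run

```{r run, warning = FALSE}
world <- simulate_world(world_config(seed = 11, n_genes = 500,
                                     n_planted_dark = 50))
run <- run_all(world)
run
glance(run$darkness)
head(run$reports$regulon_overview)
```

The problem sizes used throughout the test suite (400–2,000 genes, 800–4,000
edges per snapshot, 200 null replicates for the false-positive audit) were
chosen so a full check runs in about a minute on one core while leaving the
statistical assertions comfortably away from their thresholds.

## Known limitations

* The evidence score weights all sources equally; probabilistic combination
  is out of scope by design.
* Darkness is resource-relative: a different GMT choice or GO release moves
  the dark set, which is why every resource records provenance.
* The moderated test's fixed prior df is a simplification; for designs with
  more replicates the unmoderated options are preferable.
* Ortholog mapping ignores orthology confidence classes; one-to-many
  fan-out is flagged but not resolved.
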