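---
title: "lncnet: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lncnet: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncnet)
```

# The analysis

`lncnet` implements the network stage of a lncRNA-centred
differential-expression study. The inputs are three standard artefacts a
practitioner already has: a DESeq2-style results table per contrast, a
lncRNA→mRNA interaction-prediction table (LongHorn-style, consumed as
given — the package never re-derives predictions), and GMT gene-set
collections; optionally a binary sample×gene alteration matrix
(cBioPortal-style calls) and a cytogenetic band table. The output is a
chain of interpretable objects: the significant transcript sets, a
bipartite regulatory network, a degree-centrality ranking, a structural
equivalence clustering, enrichment tables, pathway overlays, and
pairwise alteration co-occurrence statistics.

## Significance filtering

A transcript is significant when `q <= q_max` and
`|log2FC| >= log2(linear_fc_min)`, both inclusive. The fold threshold is
stated on the linear scale (default 1.5) because that is how biologists
state it, and applied to the magnitude of the signed log2 estimate
because DESeq2 reports log2 and direction must be preserved. Records
with missing `pvalue`/`padj` — DESeq2's independent filtering leaves
such rows — are carried through parsing but can never pass a filter;
they are flagged, not imputed, matching the semantics of the upstream
tool. Thresholds are per-contrast configuration: a strict primary
contrast (q ≤ 0.1) and relaxed secondary contrasts (e.g. q ≤ 0.4 for a
low-powered supplementation arm) are the common pattern, so nothing is
hard-coded.

Biotype classification partitions significant records into lncRNA /
mRNA / other using an explicit biotype list (`lncrna_biotypes()`,
overridable). Composition proportions are computed over the lncRNA
bucket only, which is how such compositions are reported.

## The bipartite network and degree centrality

The regulatory network keeps exactly the predicted edges whose lncRNA
and mRNA are both significant; lncRNAs left without any surviving target
are dropped. On real data this is a drastic reduction — typically the
large majority of DE lncRNAs lack any significantly DE predicted target
— and the run report records the count at each link of the chain so the
reduction is visible.

Degree centrality is the number of *distinct* target mRNAs, not
prediction rows: duplicate (lncRNA, mRNA) rows are collapsed at parse
time. Ranking ties are broken lexicographically by ID — published
rankings do contain ties and give no rule, and a deterministic
convention keeps runs byte-reproducible. `top_k` defaults to 11, a
typical hub-shortlist size, and is configurable. Because "n
interactions" is ambiguous between edge count and distinct-target count,
the report carries both (`n_edges`, `n_distinct_target_mrnas`).

## Structural equivalence

Two lncRNAs are structurally equivalent when they regulate (nearly) the
same mRNAs. The package measures this on target sets with Jaccard
similarity by default — the canonical set-overlap measure; Dice and
cosine are available — and defines:

* the **dendrogram**: UPGMA (average linkage) on distance 1 − similarity,
  the standard choice for similarity heatmaps; complete and single
  linkage are exposed. Trees export to Newick via `ape`.
* **equivalence groups**: connected components of the graph joining
  pairs with similarity ≥ threshold (default 0.5), kept at size ≥ 2,
  each with its mean within-group similarity and shared target core.
  Threshold components were chosen over tree cutting because they are
  deterministic, monotone in the threshold (lowering it can only merge
  groups, never split them — a property the tests check), and directly
  express "share relationships with the same set of nodes".

Empty target sets get similarity 0 to everything including themselves,
so similarity 1 always certifies identical non-empty neighbourhoods.
No claim is made that any particular threshold reproduces a published
group count; the threshold is an explicit parameter precisely because
published analyses rarely state theirs.

## Over-representation and pathway overlay

ORA is the hypergeometric upper tail including the observed overlap:
with universe size $N$, set size $K$, query size $n$ and overlap $k$,
$p = \sum_{x \ge k} \binom{K}{x}\binom{N-K}{n-x}/\binom{N}{n}$, computed
with `phyper`. BH correction (`p.adjust`) is applied per collection —
biological-process and pathway collections are adjusted independently,
mirroring how enrichment tools report them. The universe defaults to the
union of the collection's members and can be switched to the network's
mRNAs or all significant mRNAs: the choice materially changes $p$, so it
is an explicit, logged policy rather than a silent default. Query genes
outside the universe are dropped with a reported count.

The pathway overlay restricts the network to edges targeting a pathway's
genes (optionally to a lncRNA subset such as the top-ranked hubs) and
reports the participating lncRNAs and targeted genes — the data needed
to annotate a pathway diagram. Impact-style pathway scores beyond ORA
are deliberately out of scope.

## Alteration co-occurrence

For each gene pair the 2×2 table (neither / A-only / B-only / both) is
tallied and summarised by the sample odds ratio
$(n_{11} n_{00})/(n_{10} n_{01})$; when exactly one off-diagonal cell is
zero with $n_{11} > 0$ the OR is $+\infty$. The displayed log₂OR is
capped at ±3 ("\>3" / "\<−3"), the display convention of alteration
portals, while the numeric value is kept uncapped alongside. The default
test is one-sided Fisher toward the observed direction — the convention
of mutual-exclusivity modules — implemented as the conditional
hypergeometric tail (`phyper`), which for one-sided 2×2 tests is exactly
Fisher's test and vectorises; a two-sided option delegates to
`fisher.test`. No Haldane–Anscombe correction is applied by default
(the published tables this mirrors have no zero cells); `haldane = TRUE`
adds +0.5 to the OR cells only. Printed p-values from portals are not
comparable targets because their sidedness is unstated; the worked
log₂OR examples are, and the tests pin them.

# The synthetic-data generator

The generator emulates the full input bundle with known planted
structure, so every downstream stage has a recoverable ground truth. Its
defaults are the package's reference study conditions; they were chosen
once, as a realistic mid-sized screen, and the tests run against them:

| parameter | default | rationale |
|---|---|---|
| `n_transcripts` | 5000 | mid-sized annotated screen (keeps test runtimes in seconds) |
| `lncrna_fraction` | 0.30 | share of lncRNA biotypes in annotated catalogues |
| `n_significant` | 500 | 10% planted DE fraction |
| `effect_log2fc_mean/sd` | 1.5 / 0.5 | clear effects, floored at 0.585 log2 units |
| `n_hub_lncrnas` / `hub_degree` | 5 / 120 | hubs an order of magnitude above background |
| `background_degree_max` | 15 | non-hub degree cap |
| blocks: 3 × 4 at overlap 0.9 | | planted structural equivalence |
| `n_gene_sets` | 500 | collection large enough for meaningful BH |
| `planted_enriched_set_overlap` | 15 | enriched-set signal |
| `n_samples` | 5000 | alteration panel size |
| `alteration_base_rate` | 0.05 | sparse alteration calls, as in portal data |
| `planted_pair_odds_ratio` | 16 | log₂OR 4, matching strong co-occurrence |

Design points worth recording:

* **Planted p-values** are drawn from Beta(0.05, 1) — heavily
  left-skewed, as real signal p-values are — truncated (by inverse-CDF)
  to at most half the BH threshold at rank `n_significant`. The
  truncation guarantees algebraically that every planted row survives
  BH at q ≤ 0.1, so planted counts are deterministic enough to assert
  exactly; without it a material fraction of planted rows would land
  above the threshold and every downstream count would be noisy. Null
  rows draw p ~ Uniform(0,1), and BH false positives remain (that is
  correct behaviour, bounded by the FDR level, and the tests allow for
  them). Planted effect magnitudes are floored at 0.585 log2 units,
  strictly above log2(1.5), so an inclusive fold threshold keeps them
  even after tables round-trip through finite-precision text.
* **Transcript identity** (IDs, symbols, biotypes) depends only on the
  seed, while the statistics also vary with the contrast label — so
  multi-contrast bundles share one annotation, as real contrasts from
  one experiment do, and cross-contrast overlaps are meaningful.
* **Block geometry**: each block member's target set is a shared core
  (⌈overlap·d⌉ targets, cores disjoint across blocks) plus private
  targets, giving within-block Jaccard overlap/(2−overlap) (0.82 at
  overlap 0.9) and near-zero cross-block similarity, comfortably
  separated by the 0.5 group threshold.
* **The co-altered pair** is simulated from the exact joint Bernoulli:
  given marginal rate $r$ and odds ratio $\psi$, the cell $p_{11}$
  solves $p_{11}(1-2r+p_{11}) = \psi (r-p_{11})^2$ on its feasible
  interval, so the *population* OR equals the planted value exactly and
  the sample estimate converges to it. The panel is fixed at 12 genes
  with one planted pair — the simplest design that leaves 65 honest
  null pairs for the BH family.
* **Noise edges** from and to non-significant transcripts are included
  so that the network-construction intersection does real work, as on
  real data where most predictions are filtered away.

What the generator does **not** emulate: count-level RNA-seq noise and
dispersion (it plants the DESeq2 *output*, not its input), correlated
p-values, annotation errors, biased interaction-prediction coverage, and
multi-gene alteration correlation structure beyond the planted pair.
Passing tests therefore demonstrate that the pipeline's logic is exact
and its statistics correctly implemented — not that any particular
biological dataset will reproduce published counts, which depend on the
external data and annotation snapshots used.

# Numerical and degenerate-input choices

* Boundary comparisons in the filter are inclusive (q = 0.1 passes).
* Ranking and most-similar-pair ties break lexicographically; group and
  region listings are sorted — every output is a deterministic function
  of inputs plus seed, and reports hash the configuration (paths reduced
  to basenames) so reruns are byte-identical.
* Hypergeometric and Fisher tails are computed on the log scale by
  `phyper`; the test suite pins them to exhaustive enumeration oracles
  (1e-12 over all universes ≤ 15; 1e-10 over all 2×2 tables with total
  ≤ 60).
* Degenerate inputs return empty-but-typed results (empty network, empty
  composition, empty ORA) rather than errors, except where the input is
  unusable (missing columns, non-binary matrix, empty universe), which
  fail fast with the offending field named. Pipeline stages wrap errors
  with the stage name.
* The test and acceptance problem sizes (1500–5000 transcripts, 50,000
  alteration samples, three seeds per stochastic claim) were chosen to
  make planted-structure recovery statistically comfortable while
  keeping the full suite in the low minutes.

# Limitations

Degree is the only centrality implemented — for a bipartite
regulator→target graph it is the measure with a direct reading, and
betweenness/eigenvector variants were deliberately left out. Regular
equivalence (role-based) algorithms are out of scope; structural
equivalence here is strictly neighbourhood overlap. Enrichment is
ORA-only. The package consumes prediction and alteration calls as given
and inherits their biases.
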