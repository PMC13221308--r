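---
title: "Scoring protein-disease attributions in a literature text cube"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring protein-disease attributions in a literature text cube}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caseolap)
```

## The problem and the model

Large bodies of biomedical literature mention tens of thousands of proteins
across overlapping disease areas. `caseolap` quantifies how strongly each
protein is attributed to each disease domain by the published record alone.
The corpus is organised as a *text cube*: every document (a PubMed record
with title, abstract, keywords and MeSH descriptor annotations) is assigned
to zero or more *cells*, one cell per domain of interest (a cardiovascular
disease, a comorbidity, a pathological mechanism). Assignment uses only MeSH
descriptors: a domain is configured as a set of root descriptors, and a
document belongs to the cell if any of its descriptors sits at or below a
root in the MeSH hierarchy. Descent is a tree-number prefix test restricted
to dot boundaries (`C14.280` covers `C14.280.434` but not `C14.2801`), which
is exactly the semantics of the MeSH tree-number encoding. Documents are
multi-label by construction; documents without MeSH annotations stay in the
corpus but belong to no cell and therefore never contribute to scoring.

Protein mentions are counted with a curated synonym dictionary (UniProt-style
accession, gene symbol, names and abbreviations). Text and synonyms are both
normalized (Unicode NFKC, lower case, hyphens to spaces, whitespace
collapsed) and matching is leftmost-longest, non-overlapping and anchored at
alphanumeric token boundaries, so `cat` never fires inside `catalase` and
`bnp receptor` beats `bnp` when both start at one position. A synonym whose
normalized form is claimed by more than one protein is ambiguous; by default
it is excluded from the index and reported, because multi-assigning shared
abbreviations would inflate the attribution of paralogs (a `multiAssign`
flag restores the permissive behavior). Occurrences, not documents, are
counted: the popularity component below is defined on total phrase
frequencies.

For protein (phrase) $p$ and cell $c$, with $tf(p,c)$ the total occurrences
of $p$ in the documents of $c$ and $cntP(c) = \sum_p tf(p,c)$ the total
dictionary-phrase traffic of the cell, the three CaseOLAP components are

* **integrity** — the degree to which the phrase is a coherent semantic
  unit. A curated protein-name dictionary consists of integral units, so
  integrity is the constant $1.0$; `scoreCorpus()` accepts per-protein
  values as a hook for phrase-mining input.
* **popularity** — $\dfrac{\log(1 + tf(p,c))}{\log(1 + cntP(c))}$, the
  log-damped prevalence of the phrase within the cell, $0$ when the cell is
  empty and $1$ when the phrase monopolizes it.
* **distinctiveness** — with relevance $rel(p,c) = tf(p,c)/cntP(c)$,
  $\dfrac{rel(p,c)}{\sum_{c'} rel(p,c')}$ over an *explicit* comparison cell
  set. It is $1$ for a protein mentioned in a single cell and $1/k$ for a
  protein spread evenly over $k$ cells.

The composite score is the product of the three, in $[0,1]$. A protein
never mentioned in a cell carries *no record* there (it "has no score"),
and a protein never mentioned anywhere in the comparison set is entirely
unscored; a single supporting mention is however sufficient to be scored.
The published description of the scoring framework fixes the symbol
inventory ($tf$, $cntP$, $rel$) and the product form but not the closed
algebraic forms, so the popularity and relevance formulas above are this
package's choices: both are bounded, normalizing, and consistent with that
inventory, and both are injectable strategy functions of `scoreCorpus()` so
a variant can be swapped in without touching callers. The comparison cell
set is likewise always an explicit argument, never inferred, because
distinctiveness changes meaning with the set it is computed over.

## Downstream analyses

**Cutoffs and attribution classes.** Within a cell the score distribution
of real corpora shows a steep drop separating a bulk of weakly attributed
proteins from a tail of strongly attributed ones. `scoreHistogram()` bins
scores at a fixed width (default 0.005, a resolution that gives stable
derivative estimates on corpora of a few hundred scored proteins; both knobs
are exposed), `detectCutoff()` smooths the counts with a centered window-3
moving average, takes forward differences, and places the cutoff at the
edge between the adjacent bin pair with the most negative difference — the
right edge of the drop, so proteins sitting in the falling bin are *not*
called strong (a conservative choice). Ties resolve to the smallest score;
counts that never fall are flagged degenerate with the cutoff at the
maximum score; trailing empty bins are trimmed first so padding beyond the
maximum cannot move the cutoff. `classifyAttributions()` labels records
strong (above cutoff), loose (below `looseFraction` × cutoff, default 0.25
— the moderate/loose boundary is not quantified in the source framework,
so it is a reported, configurable parameter) or moderate (between).

**Overlap, regression, clustering.** `overlapSets()` counts, for every
non-empty subset of cells, the proteins scored in exactly that subset
(a multi-way Venn partition of the union; membership means "a record
exists", i.e. at least one mention, not strong attribution).
`crossDomainRegression()` fits OLS of one cell's scores on another over the
proteins scored in both, with raw-scale Pearson correlation.
`clusterProteins()` embeds proteins as vectors of per-cell scores, imputes
unscored coordinates as 0 (unscored means no literature attribution, not
missing at random), standardizes each dimension to zero mean and unit
variance — the reading of "normalized Euclidean distance" adopted here,
with unit-norm scaling available as an alternative — and agglomerates with
complete linkage, whose merge heights are monotone.

**Validation against expression data.** `differentialRank()` compares a
case group against controls per protein with a two-sample
Kolmogorov–Smirnov test and raw group-mean differences, sorting by absolute
mean difference (descending), then p-value, then id. The KS p-value uses
the asymptotic Kolmogorov distribution even at biopsy-scale n (9–10 per
group), matching common library behavior; an exact option exists for small
products $nm \le 10^4$. `hypergeomEnrichment()` tests the overlap between
the top-k literature list and the differential dataset with the exact
upper-tail $P(X \ge k)$ — the standard over-representation convention —
and reports the expected overlap $nK/N$ and enrichment factor $k/(nK/N)$.
The background $N$ defaults to the dictionary size, overridable (the
pipeline widens it to the union of dictionary and dataset identifiers when
the two universes differ, keeping the counts feasible).
`tissueMaxAssignment()` assigns each query protein to its tissue of
maximal expression, breaking ties by a fixed alphabetical order with a
warning and bucketing proteins absent from the table as "not detected".

## What the synthetic generators emulate

`simulateCorpus()` produces a corpus with known structure: one root
descriptor (plus two children) per cell in a synthetic MeSH tree, documents
annotated with a descriptor of their cell (a configurable fraction gets a
second domain's descriptor, making them multi-label), and abstracts
composed of dictionary phrases interleaved with filler tokens that are
provably outside the dictionary. Mention counts per document are Poisson
(default mean 8, a typical dictionary-hit load for an abstract with title
and keywords); background proteins receive rates drawn log-uniformly over
one decade, mimicking the heavy-tailed mention distribution of real
literature; planted cell-exclusive proteins are mentioned only in their
home cell at a multiplier (default 10×) of the mean background rate; the
default background dictionary holds 300 proteins. An optional *monopoly
cell* contains a single dedicated protein accounting for all of its phrase
traffic — the boundary case where popularity and distinctiveness both reach
1 and the composite attains its upper bound exactly.

Because the vocabulary is closed, a brute-force substring scan is a trivial
independent oracle for the matcher, and a naive loop recomputation for the
scorer; the test suite uses both. What the generator does *not* emulate:
real linguistic context (no ambiguity from natural prose), citation or
journal structure, temporal drift, and the long tail of synonym collisions
in a real 20k-protein dictionary. Passing tests therefore demonstrate
correctness of counting, scoring, ranking and recovery under the stated
generative model — not robustness to the NER pitfalls of free text.

`simulateExpression()` emulates a small two-group biopsy proteomics table
(defaults: 9 controls vs 10 cases, matching a realistic endomyocardial
cohort): Gaussian noise around per-protein baselines, with planted proteins
shifted by $\delta$ noise standard deviations in the case group.
`simulateTissueTable()` gives every protein one known dominant tissue
(values 50–100) over background (0–10), so argmax assignment recovers the
truth by construction.

## Numerical choices and degenerate inputs

* Zero-denominator conventions: popularity and relevance are 0 when
  $cntP(c) = 0$; distinctiveness is undefined (pair unscored) when a
  protein's total relevance is 0.
* Distinctiveness sums are exact to $10^{-12}$ per scored protein; the
  composite equals the three-way product at full floating-point precision.
* Duplicate documents: the first record per PMID wins, in input order —
  deterministic and auditable; deduplication is idempotent.
* Ranking ties break lexicographically by accession; clustering ties follow
  the deterministic `hclust` convention; tissue ties break alphabetically
  with a warning.
* Dates parse leniently (year-only allowed) and are carried but unused by
  scoring.
* Histogram bins are half-open with a closed last bin so the maximum score
  is always counted.

## Problem sizes used by the test suite

The suite exercises the full stack on corpora it generates on the fly: the
oracle-equivalence checks use twenty random corpora of at most 100
documents; planted-recovery uses ten seeds of a six-cell corpus with 200
documents per cell, 20 planted proteins per cell at 10× background over 300
background proteins; the stress corpus for the score-bound check uses six
cells of 333 documents each over 500 background proteins plus the monopoly
cell; bimodal cutoff recovery draws 2000 + 300 scores around modes 0.10 and
0.40. These sizes were chosen so every distributional claim is estimated
from comfortably large samples while the whole suite stays fast enough to
run routinely.

## Known limitations

* Dictionary-only matching: no novel-phrase discovery, no context
  disambiguation, no abbreviation expansion. Ambiguity handling is
  drop-or-multi-assign, nothing smarter.
* MeSH qualifiers (subheadings) are ignored; assignment uses descriptors
  only.
* The popularity/relevance forms are one consistent instantiation of the
  published symbol inventory; studies wanting a different damping can
  inject their own strategy functions.
* The KS test's asymptotic p-values are conservative and discrete at
  biopsy-scale group sizes; rankings (the quantity used downstream) are
  unaffected, but absolute p-values at n ≈ 10 should be read with care.
* Cutoff detection presumes a unimodal-bulk-plus-tail shape; genuinely
  flat or rising distributions are flagged degenerate rather than forced.
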