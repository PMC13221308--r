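# caseolap

Text-cube scoring of protein–disease associations in the biomedical
literature.

## What it does and for whom

Biomedical corpora mention tens of thousands of proteins across overlapping
disease areas. For researchers prioritizing disease-relevant proteins —
e.g. candidate biomarkers for cardiovascular diseases or heart failure with
preserved ejection fraction (HFpEF) — `caseolap` turns MEDLINE/PubMed
records into quantitative protein-to-domain attribution scores and
validates the top-ranked proteins against expression data.

The corpus is organised as a text cube: each domain of interest (a disease,
comorbidity or mechanism) is a *cell* holding the documents whose MeSH
descriptors fall at or below the domain's root descriptors in the MeSH
hierarchy. Protein mentions are counted with a curated synonym dictionary
(leftmost-longest, token-anchored matching on normalized text). For phrase
*p* and cell *c*, with tf(p,c) the occurrences of *p* in *c* and
cntP(c) the total dictionary-phrase traffic of *c*, each scored pair gets

* integrity — 1.0 for curated protein names (per-phrase values injectable),
* popularity — log(1 + tf(p,c)) / log(1 + cntP(c)),
* distinctiveness — rel(p,c) / Σ<sub>c′</sub> rel(p,c′), where
  rel(p,c) = tf(p,c)/cntP(c), over an explicit comparison cell set,

and the composite CaseOLAP score = integrity × popularity ×
distinctiveness ∈ [0, 1]. Downstream stages derive per-cell score cutoffs
at the steepest drop of the score histogram, classify attributions
(strong / moderate / loose), rank top-k proteins, quantify multi-domain
Venn overlaps, regress and cluster score vectors across domains, and
validate ranked lists against a sample × protein expression table
(Kolmogorov–Smirnov differential ranking + exact hypergeometric
enrichment) and a protein × tissue table (tissue of maximal expression).
Synthetic generators with planted ground truth make every stage testable
offline.

## Worked example

```r
library(caseolap)

spec <- syntheticCorpusSpec(nCells = 3, docsPerCell = 100,
  nBackgroundProteins = 50, plantedPerCell = 2, plantedMultiplier = 10,
  mentionsPerDocMean = 8, seed = 42)
sim  <- simulateCorpus(spec)
cube <- assignDomains(sim$documents, sim$meshTree, sim$domains)
cube
#> TextCube: 300 documents, 3 cells
#>   domain01: 110 docs
#>   domain02: 108 docs
#>   domain03: 104 docs

st <- scoreCorpus(countCorpusMentions(sim$documents, sim$lexicon), cube)
st
#> ScoreTable: 166 records, 56 proteins, 3 cells
#>   composite score range: [0.0007579, 0.6837]

topProteins(st, "domain01", 3)
#>   uniprot_id     cell integrity popularity distinctiveness     score
#> 1     X01001 domain01         1  0.7002102       0.9504541 0.6655176
#> 2     X01002 domain01         1  0.6669695       0.9190760 0.6129956
#> 3     B00012 domain01         1  0.4604592       0.4558135 0.2098835

detectCutoffs(st)
#>       cell cutoff degenerate
#> 1 domain01  0.180      FALSE
#> 2 domain02  0.055      FALSE
#> 3 domain03  0.140      FALSE
```

The two proteins planted as exclusive to `domain01` at ten times the
background mention rate (`sim$groundTruth$plantedByCell$domain01` is
`X01001`, `X01002`) top its ranking with near-1 distinctiveness and scores
far above the detected cutoff of 0.18, so `classifyAttributions()` labels
them strong; the best background protein trails at 0.21 because its
mentions spread over all three cells.

Validation-stage example — the enrichment of an overlap of 7 proteins
between a 20-protein literature list and a 2180-protein dataset on a
20,428-protein background:

```r
hypergeomEnrichment(N = 20428, K = 20, n = 2180, k = 7)
#> expected 2.1343   enrichment 3.280   p_value 0.0034467
```

A thin command-line front end over the same functions lives in
`inst/scripts/caseolap.R` (`simulate` and `run-all` subcommands; exit code
2 flags configuration errors). `runPipeline()` executes all stages —
corpus → lexicon → scoring → prioritize → stats → validate — writing TSV/
JSON outputs plus a manifest with parameters, input checksums and collected
warnings.

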