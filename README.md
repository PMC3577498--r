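# litnet

Literature co-occurrence mining for disease-related gene networks.

Biomedical abstracts encode, in aggregate, which genes are discussed with
which diseases and drugs. litnet turns a concept thesaurus (genes,
diseases, drugs, pathways) and a corpus of titled abstracts into
quantitative gene–disease biology: it tags documents against the
thesaurus, scores concept pairs by co-occurrence, builds rs-weighted
gene–gene networks, finds over-represented drug/disease keywords,
clusters disease profiles with bootstrap support, and ranks genes by a
neighbor-weighted literature score — the workflow used to nominate
biomarker candidates for drug side effects (for instance, genes strongly
tied to a glucocorticoid but weakly to inflammation, as candidate markers
of glucocorticoid-induced insulin resistance). It is aimed at
computational biologists who want this pipeline as a scriptable library
and CLI rather than a web service.

## The statistics at its core

For concepts $a,b$ in a corpus of $N$ documents, with marginal document
counts $c_a, c_b$ and joint count $lc$:

- **Association score.** lift $= lc\,N / (c_a c_b)$, rescaled as
  $rs = 100 \ln(\text{lift}) / \max_{\text{run}} \ln(\text{lift})$,
  clipped to $[0,100]$ and zero at or below independence. Pairs pass at
  strict thresholds $rs > 30$, $lc > 5$ by default ($rs > 35$ for
  disease-profile extraction). The rescaling is this package's own
  definition (documented prominently in the methods vignette); the
  historical 0–100 "R-scaled score" it emulates was never published in
  closed form.
- **Enrichment.** Hypergeometric upper tail for keyword
  over-representation in a gene set against the tagged background, with
  BH q-values.
- **Cluster support.** Complete-linkage clustering of disease profiles on
  correlation distance, with multiscale bootstrap: per scale $r$,
  $BP_r$ is each cluster's recurrence under gene resampling, and
  $AU = (1-\Phi(v-c)) \times 100$ from the weighted probit fit
  $\Phi^{-1}(1-BP_r) \approx v\sqrt{r} + c/\sqrt{r}$.
- **Neighbor-weighted gene score.** For gene $g$ and term $d$:
  $\mathrm{score} = (g_1 + Ns)/2$ with
  $Ns = \sum_i rg_i g_i / \sum_i rg_i$ — the direct association averaged
  with the rs-weighted mean of the network neighbors' associations.

A synthetic corpus generator with planted ground truth (known associated
pairs, disease blocks, a hub gene, an enriched drug) supports end-to-end
validation without access to a literature database.

## Worked example

Generate a synthetic corpus at the reference conditions (200 concepts,
2,000 documents), tag it, and run the pipeline:

```r
library(litnet)

cfg <- generator_config(seed = 42)
sim <- generate_corpus(cfg)
idx <- tag_corpus(sim$corpus, sim$thesaurus)
idx
#> <lit_index> 2000 docs, 200/200 concepts tagged, 7025 mention links

sc <- score_category_pairs(idx, "gene", "disease", lit_thresholds(35, 5))
head(as.data.frame(sc), 3)
#>   concept_a concept_b c_a c_b lc n_docs  lift     rs
#> 1     G0010     D0010  39  41 25   2000 31.27 100.00
#> 2     G0007     D0007  33  38 19   2000 30.30  99.09
#> 3     G0002     D0002  42  42 24   2000 27.21  95.96
```

The 36 passing pairs are exactly dominated by the planted gene–disease
associations; `rs = 100` marks the run's maximal log-lift pair. Building
the gene network and asking for hubs recovers the planted hub gene:

```r
net <- build_network(cfg$genes, idx, lit_thresholds(30, 5))
connectivity_report(net)[c("connected", "isolated", "total")]
#> $connected [1] 29   $isolated [1] 91   $total [1] 120
degree_analysis(net, hub_min_degree = 10)$hubs
#> [1] "G0100"
```

Keyword enrichment of the planted drug's gene set ranks that drug first:

```r
enrich(cfg$truth_groups$enriched$genes, idx, "drug")[1, ]
#>   keyword_id category  k  K  n N_bg  p_value  q_value
#> 1      R0001     drug 10 17 10  120 1.68e-10 5.03e-09
```

(k of n query genes are linked to the keyword, against K of N_bg
background genes; the p-value is the hypergeometric tail.) Finally, the
two-term quadrant: genes scoring high with the drug-like term and low
with a disease term, on neighbor-weighted literature scores:

```r
th  <- lit_thresholds(30, 5)
net <- annotate_nodes(net, idx, "R0001", "dex_like", th)
net <- annotate_nodes(net, idx, "D0011", "infl_like", th)
cand <- select_candidates(score_genes_for_term(net, "dex_like"),
                          score_genes_for_term(net, "infl_like"))
head(cand, 3)
#>    gene score_hi score_lo       mode
#> 1 G0048    90.05        0 literature
#> 2 G0043    88.38        0 literature
#> 3 G0041    87.69        0 literature
```

18 genes fall in the quadrant (score > 25 with the first term, < 25 with
the second) — the planted drug-linked genes, none of which carry the
disease association directly or through neighbors.

The same pipeline is scriptable from a shell via `exec/litnet`:
`litnet simulate | tag | associations | neighbours | network | enrich |
cluster | score | version | selftest`.

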