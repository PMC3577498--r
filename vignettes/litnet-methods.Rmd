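---
title: "Methods: co-occurrence scoring, clustering support and neighbor-weighted gene ranking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: co-occurrence scoring, clustering support and neighbor-weighted gene ranking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(litnet)
```

litnet builds disease-related gene networks from concept co-occurrences in
titles and abstracts. This vignette documents the statistical model behind
each stage, the tunable parameters and their defaults, the numerical
choices, and what the synthetic-data validation does and does not show
about behavior on real literature.

## Dictionary tagging

A thesaurus assigns each concept (gene, disease, drug or pathway) an
opaque identifier and a non-empty synonym set. Tagging links a document to
a concept when some synonym occurs in the title or abstract as a
case-insensitive, token-boundary match (flanked by non-alphanumeric
characters or string ends). Three semantic commitments matter downstream:

* **Presence, not frequency.** A concept counts once per document however
  often it is mentioned; the unit of co-occurrence is the abstract.
* **Longest match first.** Where candidate matches overlap ("insulin
  receptor" vs "insulin"), the longest span wins and shorter synonyms
  cannot fire inside a claimed span; ties go to the earlier start.
* **Exact matching after normalization.** Synonyms and text are compared
  after lowercasing, trimming and whitespace collapsing. No stemming is
  applied: stemming would inflate false hits on short gene symbols, and
  morphological variants belong in the synonym list. Ambiguous synonyms
  (one string, several concepts) link *all* matching concepts; the package
  does no disambiguation, so ambiguity surfaces as correlated counts
  rather than silently picking a winner.

When every synonym is a single alphanumeric token the tagger uses a hash
lookup over document tokens; otherwise it scans spans with the general
longest-match rule. Both paths implement the same contract and are
cross-checked against a naive per-document scan in the tests.

## Association scoring: lift and the R-scaled score

For concepts $a, b$ in a corpus of $N$ documents, with marginal document
counts $c_a, c_b$ and joint count $lc$ (the *literature count*), the
association strength is the lift

$$\mathrm{lift}(a,b) = \frac{lc \cdot N}{c_a \, c_b},$$

the ratio of observed to independence-expected co-occurrence. The 0–100
*R-scaled score* used throughout the package is a rescaled log-lift:

$$rs(a,b) = 100 \cdot \frac{\ln \mathrm{lift}(a,b)}{\max_{\text{run}} \ln \mathrm{lift}},
\qquad \text{clipped to } [0, 100],$$

with $rs = 0$ whenever $lc = 0$ or $\mathrm{lift} \le 1$. The denominator
(`scale_ref`) is the maximum log-lift among pairs meeting the
literature-count floor within the same scoring run.

**This rescaling is a reimplementation choice.** Historical
thesaurus-based Medline mining systems report an R-scaled score on this
range, but its closed form was never published; litnet's definition
reproduces the documented range and monotonicity in association strength
and is fully deterministic given a corpus, but it will not numerically
match historical outputs, and rs values are comparable only within one
scoring run. Score files record their `scale_ref`, thresholds and corpus
fingerprint in the header for that reason.

Thresholds are strict inequalities: a pair passes at `lit_thresholds(30, 5)`
when $rs > 30$ **and** $lc > 5$. The defaults follow the conventions for
this kind of analysis: (30, 5) for building gene sets and gene–gene
networks, (35, 5) for extracting gene–disease association profiles. The
count floor removes pairs whose large lift rests on one or two abstracts;
the rs floor removes weak associations among well-studied concepts.

## Gene networks and topology statistics

The literature network has the input genes as nodes and an edge for every
gene pair passing the thresholds, weighted by rs with lc retained for
filtering. Isolated genes stay in the object so connected-versus-isolated
counts can be reported (`connectivity_report()`). Per-keyword annotations
(`annotate_nodes()`) store each gene's rs with a drug or disease term as a
vertex attribute, taken from one scoring run of the network's genes
against the keyword's whole category so the values share a scale.

`degree_analysis()` reports hubs (degree strictly above a threshold,
default 100) and a power-law fit. The default fit regresses the log
complementary CDF $\log P(D \ge d)$ on $\log d$ over observed degrees;
for $P(k) \propto k^{-\alpha}$ the CCDF slope estimates $-(\alpha - 1)$,
and the reported p-value is the two-sided t-test on that slope. This
regression is a pragmatic, widely used diagnostic rather than a rigorous
power-law test; a discrete maximum-likelihood alternative (igraph's
implementation of the Clauset–Shalizi–Newman estimator) is available via
`method = "mle"`. Whether to fit the raw histogram or the CCDF was an open
choice; the CCDF is used because it is monotone and far less noisy in the
tail at these network sizes.

Betweenness centrality is computed on the **unweighted** topology,
normalized by the number of node pairs: rs is a similarity, not a path
cost, and treating it as an edge length would invert its meaning. The
implementation is igraph's; tests verify it against brute-force
shortest-path enumeration by matrix powers on graphs up to 30 nodes.

## Keyword enrichment

For a query gene set of size $n$ drawn from a background of $N_{bg}$
genes (thesaurus genes mentioned in at least one document — genes absent
from the corpus cannot be drawn, so they are excluded from the urn), with
$K$ background genes linked to a keyword and $k$ of them in the query,
the p-value is the hypergeometric upper tail $P(X \ge k)$. "Linked" means
the gene–keyword pair passes the association thresholds. The
hypergeometric null is itself a design choice: the operation this mirrors
was described only as "keyword overrepresentation", and the
draw-without-replacement urn is the standard reading. Results are
filtered at raw $p < \alpha$ (default 0.05), matching how such tables are
conventionally reported, but Benjamini–Hochberg q-values over the whole
vocabulary are always emitted alongside so FDR control is available.

## Disease-profile clustering with multiscale bootstrap support

Disease profiles are the columns of the gene × disease rs matrix (zeros
where a pair fails the thresholds). Columns are compared by correlation
distance $d = 1 - r$ and clustered by complete linkage; constant columns
are rejected by name because their correlation is undefined. For
determinism, items enter the linkage in lexicographic label order, so
merge ties resolve by smallest member id. The `top_k_diseases()` helper
mirrors the usual practice of clustering only the diseases with the most
gene associations.

Cluster support resamples the **genes** (the observations each profile is
measured over) with replacement: at each scale $r \in \{0.5, 0.6, \ldots,
1.4\}$, $B$ resamples of $\mathrm{round}(r \cdot n)$ rows are drawn, the
tree is rebuilt, and $BP_r$ records the fraction of replicates containing
each reference cluster, with cluster identity defined as exact leaf-set
equality (partial-overlap matching was rejected for determinism). The
approximately unbiased value extrapolates across scales through the
probit fit

$$z_r = \Phi^{-1}(1 - BP_r) \approx v\sqrt{r} + c/\sqrt{r}, \qquad
AU = \big(1 - \Phi(v - c)\big) \times 100,$$

by weighted least squares with binomial weights
$B\,\phi(z_r)^2 / (BP_r(1-BP_r))$; BP is reported at $r = 1$.

Numerical handling of degenerate scales follows the practice of the
standard multiscale-bootstrap implementations: scales where $BP_r$ is
exactly 0 or 1 carry no gradient information and are excluded from the
fit, and a cluster degenerate at essentially every scale is reported
directly as $AU = 100$ (present in every replicate) or $AU = 0$ (never
observed, flagged). Extrapolating from boundary values that were clipped
into range would instead drag saturated clusters toward $AU \approx 50$,
which is why clipping was rejected. Two analytic anchors pin the fit
down: a cluster with $BP_r = 0.5$ at every scale has $v = c = 0$ and
$AU = 50$ exactly, and because the model has no constant term, *any* flat
bootstrap profile yields $v - c \approx 0$ and $AU$ near 50 — AU
deliberately withholds judgement when support shows no scale gradient.
In replicate trees, resampled columns that become constant are assigned
correlation 0 (distance 1) rather than aborting the replicate.

Resampling is seeded; identical seeds give identical support tables. The
dendrogram exports to Newick with branch lengths equal to merge-height
differences and node labels `AU/BP` in integer percent.

## The neighbor-weighted literature score

For gene $g$ and term $d$, let $g_1$ be the direct rs of $g$ with $d$,
and for each network neighbor $i$ let $g_i$ be the neighbor's rs with $d$
and $rg_i$ the rs of the edge between $g$ and the neighbor. Then

$$Ns = \frac{\sum_i rg_i \, g_i}{\sum_i rg_i}, \qquad
\mathrm{literature\_score}(g, d) = \frac{g_1 + Ns}{2}.$$

$Ns$ is the edge-weighted mean of the neighborhood's term scores, so the
literature score always lies between the direct score and the
neighborhood extremes, is invariant to rescaling all edge weights, and
only direct neighbors contribute (no recursion or diffusion). Two edge
cases were genuinely open:

* **Isolated genes.** The displayed average is undefined with no
  neighbors; litnet sets the score to $g_1$. Halving a lone direct score
  would penalize genes for missing neighborhood data, contradicting the
  score's purpose of *adding* contextual evidence.
* **Candidate selection mode.** Quadrant selection (`select_candidates()`,
  defaults high-side $> 25$, low-side $< 25$) is exposed on both the
  direct rs and the literature score, because the contrast between the
  two is the point: genes that look exclusively linked to a drug on
  direct scores can acquire the unwanted term through their neighbors,
  and the migration between modes identifies them.

## The synthetic corpus generator

Validation runs on synthetic corpora with planted, known structure,
because real literature corpora are neither redistributable nor equipped
with ground truth. The generative model: every document mentions every
concept independently with probability `background_rate`; each planted
pair $(a, b, q)$ additionally forces a joint mention with probability $q$
per document. Planted structure is built from such pairs: independent
gene–disease pairs, two disease blocks sharing gene partners, a hub gene
with twelve gene partners plus a four-gene clique, and a drug linked to a
ten-gene set. Mentions are injected as literal synonym strings in
template sentences, so the tagger is exercised rather than bypassed.

The closed-form expectations (`expected_pair_stats()`) follow from
inclusion–exclusion over the background and forced events; tests use them
to decide which planted pairs are strong enough to demand recovery at
given thresholds. Two model properties are worth knowing: a pair's lift
rises with its own excess $q$ only while $q$ is small relative to the
background rate (past that, forced events inflate both marginals and lift
falls back toward 1), and concepts appearing in many planted pairs have
inflated marginals that depress the lift of each individual pair — which
is why shared-block pairs sit at lower expected lift than independent
pairs under identical $q$.

The reference conditions, chosen once, are a 200-concept vocabulary (120
genes, 50 diseases, 30 drugs) over 2,000 documents at a 1% background
rate with planted excesses of 0.010–0.015; under the closed form the
independent planted pairs then have expected lift near 25 and expected
literature count near 20. The clustering stage is additionally studied in
isolation with directly simulated profile matrices (shared latent factor
per block, within-block correlation 0.9, between-block 0), which
separates clustering behavior from tagging and scoring noise. Validation
sizes: 1,000 random score instances for the neighbor score, 20 corpora
for exact count checks and for recovery/topology rates, 100 seeds for
enrichment ranking, 20 seeds at $B = 100$ for cluster support.

What the generator does **not** emulate: natural biomedical language
(synonym ambiguity in context, abbreviations, negation), publication-date
structure, realistic marginal heterogeneity across concepts, and
multi-concept sentence structure. Passing tests therefore demonstrate the
correctness of the counting, scoring and inference machinery under the
stated model — not tagging accuracy on real prose, which is bounded by
dictionary quality in any thesaurus-based system.

## Known limitations

* rs values are run-relative; scores from different corpora or different
  category runs are not directly comparable.
* The power-law "p-value" tests the CCDF regression slope, not the
  power-law hypothesis against alternatives.
* Hypergeometric enrichment inherits the usual independence assumption
  between genes, which literature co-mention data violates for famous
  gene families; q-values are provided but share the assumption.
* AU values rest on the probit extrapolation model; for clusters whose
  bootstrap profile is flat across scales, AU is uninformative by design
  (near 50) rather than equal to BP.
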