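---
title: "Mining MeSH co-occurrence semantic networks from MEDLINE corpora"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining MeSH co-occurrence semantic networks from MEDLINE corpora}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semnetmine)
library(igraph)
```

## The model

Every MEDLINE record is manually indexed with Medical Subject Headings
(MeSH): controlled-vocabulary descriptors, optionally refined by a
qualifier (subheading, attached with `/`) and optionally flagged — with a
printed asterisk — as a *major topic* of the article. A corpus of records
therefore induces a two-mode (bipartite) structure: articles on one side,
annotation concepts on the other.

`semnetmine` analyses the one-mode projections of that structure:

* the **concept projection** — the *semantic network* proper. Two concepts
  are linked whenever at least one article is annotated with both; the
  edge weight counts the co-annotating articles.
* the **article projection** — articles linked by the number of concepts
  they share; the more terms shared, the stronger the link.

Both projections satisfy an exact conservation law used throughout the
test suite: the sum of concept-projection edge weights equals
$\sum_a \binom{t_a}{2}$, where $t_a$ is the number of distinct concept
labels on article $a$ (and dually for the article projection). The
projections are computed as sparse matrix cross-products of the 0/1
incidence matrix; the tests verify them against an independent
brute-force enumeration of every article/label pair.

### Concepts are printed variants, not bare descriptors

A deliberate modelling choice, made once and applied everywhere: the
major-topic form (`*Health Equity`), the qualified forms
(`Health Equity/*organization & administration`) and the bare descriptor
(`Health Equity`) are *distinct* nodes. Indexers use the asterisk to mark
what an article is centrally about, so the flagged and unflagged forms
trace genuinely different threads of the literature, and their degrees
differ substantially in practice. `mesh_label(entities, "merged")` is
available to collapse all variants onto the bare descriptor when a
coarser vocabulary is wanted; merging is idempotent and many-to-one, and
every pipeline entry point accepts `label_mode = "merged"`.

Labels are compared verbatim and case-sensitively: MeSH is a controlled
vocabulary with canonical casing, so normalisation could only mask data
errors, never merge anything real. No validation against the official
MeSH thesaurus is attempted — annotations are taken as given.

## Corpus selection

`apply_selection_criteria()` implements the inclusion/exclusion rules as
a deterministic filter with an exact audit trail:

1. **duplicate** — a PMID already seen; the first occurrence is kept
   (order-stable, so re-running on the same input is the identity);
2. **no-mesh** — a record without any MeSH annotation cannot participate
   in a co-occurrence network;
3. **no-title** — records lacking a title are excluded;
4. **blocklist** — an optional, user-supplied PMID list standing in for
   manual relevance screening, which is not computable from the record.

A record failing several rules is logged once under the first matching
reason, in that fixed order, so `kept + excluded = input` always holds
exactly. Non-English records are retained; the `language` field is kept
on every record so callers can filter on it if they wish.

Country attribution takes the *first* affiliation string, splits it on
commas and scans the segments right to left (country names close an
affiliation), resolving the first match against a shipped gazetteer of
name variants to an ISO-3 code; unmatched records are counted under
`UNK`. One country per record is a deliberate simplification —
multi-country fractional counting is out of scope.

## Topology statistics

`compute_node_stats()` reports, per concept, the unweighted degree $k$
(number of adjacent concepts — co-occurrence multiplicity is reported
separately as *strength*), the rank $R$ in the degree ordering,
betweenness, closeness and the local clustering coefficient, plus global
counts, density, component count and the exact-integer degree histogram.

Conventions worth stating explicitly:

* **Rank tie-break.** Equal degrees are ordered by ascending label
  (byte order), making $R$ a bijection onto $1..|V|$ that is invariant
  under any permutation of the node list. This is a documented
  convention, not a claim about how any particular published ranking
  broke its ties.
* **Closeness on disconnected graphs** uses the Wasserman–Faust
  correction: within-component closeness scaled by the component's share
  of the graph; an isolated node scores 0.
* **Centralities are unweighted**: shortest paths count hops. The
  published degree values this package is designed to reproduce are
  adjacent-node counts (a tag present on every article in a 551-node
  network has $k = 550$), which only holds for unweighted degree.
* `core_periphery()` calls nodes *core* when their degree reaches the
  upper `quantile` tail of the empirical degree distribution (type-7
  quantile, R's default). The quantile must be strictly inside $(0,1)$.

## Thematic subnetworks

`extract_subnetwork()` builds the seed-plus-first-neighbour subnetworks
used to discuss specific themes: the node set is the seeds plus every
node within `radius` (default 1) of a seed, and the edge set is the full
**induced** subgraph — every parent edge between retained nodes, with
its weight, not merely the edges incident to a seed. Induced extraction
is the only reading consistent with the density of published
first-neighbour subnetworks, which are far denser than a star of
seed-incident edges could be. Because seeds such as `Culture` usually
have an asterisked twin (`*Culture`), `include_major_variants = TRUE`
pulls the twin in as an extra seed; both behaviours are exposed and
neither is claimed to be the published one.

## The synthetic corpus generator

Live bibliographic databases drift daily, so the package tests and the
acceptance analysis run entirely on synthetic corpora from
`generate_corpus()`. The generator emulates the statistical features the
pipeline actually depends on:

* a **near-universal check tag** (`Humans`), present with probability
  0.98 by default — in real human-health corpora the top tag covers
  roughly 99% of records and its degree is $|V|-1$ or just short of it;
* a **Zipf popularity law** over the remaining vocabulary (default
  exponent 1.2 over 300 descriptors): MeSH usage is heavy-tailed, and a
  skewed law is required to reproduce the published degree hierarchy
  (check tags ≫ demographic tags ≫ topical tags);
* a **zero-truncated Poisson** annotation count per record whose
  *truncated* mean equals `terms_per_record` (default 12, a typical
  MEDLINE indexing depth; the rate parameter is solved numerically);
* per-annotation major flags (0.3) and qualifiers (0.2, drawn from a
  small subheading vocabulary; when an annotation is major *and*
  qualified the asterisk is printed on the qualifier, the dominant form
  in practice);
* publication years uniform over 2014–2021 and affiliations ending in a
  country name drawn from a mix concentrated in the USA, Canada,
  Australia and the UK, mirroring where this literature is produced.

Defaults are fixed study conditions, not tuning knobs. Generation is
fully deterministic given `seed` (R's Mersenne-Twister stream, restored
on exit so callers' RNG state is untouched), and `corrupt =` injects
*exact* counts — `floor(rate × n)` duplicates, MeSH-stripped and
title-stripped records on disjoint sets — so exclusion accounting can be
checked against known ground truth rather than sampled rates.

What the generator does **not** emulate: semantic correlation between
descriptors (real MeSH terms co-occur by topic, not independently),
qualifier–descriptor compatibility rules, citation structure, abstracts,
or secular trends in publication volume. Passing tests therefore certify
the pipeline's graph-theoretic and accounting behaviour, not any claim
about real literature content.

## Numerical and format choices

* MEDLINE dialect: four-character space-padded tags followed by `"- "`;
  continuation lines indented ≥ 5 spaces are re-joined with single
  spaces. Writing wraps at 80 columns, breaking only at single spaces so
  the round-trip is byte-exact at any width; a value with no usable
  break point is emitted over-width rather than split mid-word.
* Years are the first four-digit token of the `DP` field (`"2015"`,
  `"2015 Mar-Apr"` all begin with the year); an unparseable date leaves
  the year absent rather than failing.
* Input is assumed UTF-8; undecodable bytes are replaced and logged as
  parse issues rather than aborting — robustness over strictness for
  mined text.
* No minimum edge weight is applied by default (`min_weight = 1`); all
  co-occurrences are reported, and thresholding is an explicit option.
* Pipeline artifacts are plain text (TSV edge lists, CSV tables, JSON
  global statistics, GraphML) with an MD5 manifest, so identical inputs
  yield hash-identical runs.

## Problem sizes

The test suite exercises the projection oracle on 200 random corpora of
up to 50 records over vocabularies of up to 40 descriptors, the rank and
subnetwork contracts on 100 random graphs of up to 30 nodes each, the
round-trip law on 100 written-and-reparsed corpora, and the statistical
recovery checks at n = 800–3000 records; the acceptance analysis runs
the full pipeline at the default 950 records. These sizes were chosen so
the whole suite completes in about a minute while every property is
exercised across hundreds of independent draws.

## Limitations

The pipeline inherits the assumptions of any MeSH-based co-word
analysis: only indexed, annotated literature is visible; concepts absent
from the thesaurus cannot appear; and indexing practice itself drifts
over time. Published node/edge counts from live database snapshots are
not reproducible targets — re-running the same query on a different day
yields a different corpus — which is exactly why the package ships a
generator rather than query scripts. Statistical backboning of
co-occurrence edges, community detection, weighted shortest-path
centralities and per-year network slicing are out of scope.

## A worked session

```{r toy}
corp <- toy_corpus()
net <- project_concepts(build_bipartite(corp))
report <- compute_node_stats(net)
report$nodes

subnetwork_summary(extract_subnetwork(net, "Health Equity"))
```
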