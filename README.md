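# semnetmine

Semantic-network mining of MEDLINE literature corpora in R.

Health-policy and bibliometrics researchers often need to know *what a
body of literature is actually about*: which indexing concepts dominate a
topic, how they interrelate, and which expected concepts are missing or
marginal. `semnetmine` answers this with MeSH co-word analysis. It parses
plain-text MEDLINE exports, curates the corpus with an exactly-accounted
exclusion log, and builds the **semantic network**: an undirected weighted
graph whose nodes are MeSH concept labels and whose edge weights count the
articles annotated with both endpoint concepts. Major-topic terms
(`*Health Equity`) and descriptor/qualifier combinations
(`Health Equity/*organization & administration`) are distinct concepts
from the bare descriptor, as they are in the index itself.

Formally, with incidence matrix $M \in \{0,1\}^{\text{articles} \times
\text{concepts}}$, the semantic network is the off-diagonal of $M^{T}M$
and the dual article-similarity network the off-diagonal of $MM^{T}$; the
weights obey $\sum_{e} w_e = \sum_a \binom{t_a}{2}$ with $t_a$ the number
of distinct labels on article $a$. Per-node reports give the unweighted
degree $k$, the rank $R$ in the degree ordering (rank 1 = most connected;
ties broken by label so ranking is order-independent), strength,
betweenness, closeness and clustering, plus Top-N listings,
degree-quantile core/periphery partitions, and seed-plus-first-neighbour
**induced** subnetworks for thematic analysis. A seeded synthetic-corpus
generator (Zipf descriptor popularity, near-universal `Humans` tag,
truncated-Poisson annotation counts, skewed country mix) makes every
stage testable offline.

## Worked example

The package ships a four-article toy corpus small enough to verify by
hand: articles annotated {Humans, Health Equity, Vulnerable Populations},
{Humans, Health Equity, Culture}, {Humans, Vulnerable Populations} and
{Humans, Culture, Trust}.

```r
library(semnetmine)

corp <- toy_corpus()
net  <- project_concepts(build_bipartite(corp))
write_edge_list(net)
#>          source                 target weight
#> 1       Culture          Health Equity      1
#> 2       Culture                 Humans      2
#> 3       Culture                  Trust      1
#> 4 Health Equity                 Humans      2
#> 5 Health Equity Vulnerable Populations      1
#> 6        Humans                  Trust      1
#> 7        Humans Vulnerable Populations      2
```

`Humans` co-occurs twice with `Culture` because two of the four articles
carry both tags; the seven weights sum to 10 = C(3,2)+C(3,2)+C(2,2)+C(3,2),
the per-article pair total. Topology and a thematic subnetwork:

```r
compute_node_stats(net)$nodes
#>                    label k R strength betweenness closeness clustering
#> 1                 Humans 4 1        7         2.0 1.0000000  0.5000000
#> 2                Culture 3 2        4         0.5 0.8000000  0.6666667
#> 3          Health Equity 3 3        4         0.5 0.8000000  0.6666667
#> 4                  Trust 2 4        2         0.0 0.6666667  1.0000000
#> 5 Vulnerable Populations 2 5        3         0.0 0.6666667  1.0000000

subnetwork_summary(extract_subnetwork(net, "Health Equity"))
#> nodes edges
#>     4     5
```

`Humans`, present on every article, is adjacent to all other concepts
(k = 4 = nodes − 1) and ranks first; `Culture` and `Health Equity` tie at
k = 3 and are ordered by label. The `Health Equity` ego subnetwork keeps
the seed, its three neighbours, and *all five* parent edges among them
(induced extraction), not just the three seed-incident ones.

The full staged pipeline — parse/generate, filter, build, stats, subnets,
tallies, with a hashed artifact manifest — is `run_pipeline()`, also
available from a shell via `inst/scripts/semnet-pipeline.R`:

```sh
Rscript inst/scripts/semnet-pipeline.R --simulate 950 --seed 7 \
  --out-dir out --seeds "Concept 001,Concept 002"
```

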