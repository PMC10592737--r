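# contactbn

Bayesian-network analysis of protein–protein interface contact fingerprints,
built for GPCR:G protein complexes but applicable to any interface whose
per-frame contacts can be expressed as binary variables.

Structural biologists studying receptor–transducer coupling face a gap
between what a static structure shows (a list of interface contacts) and
what dynamics reveal: contacts form and break *together*, and the pattern of
co-variation — not any single contact — carries the signature of coupling
selectivity. `contactbn` closes that gap:

1. **Contact fingerprinting** — detect typed interface contacts (salt
   bridge, hydrogen bond, van der Waals, pi-stack, cation-pi, with the
   standard geometric cutoffs) in multi-model PDB coordinates, or ingest
   precomputed binary fingerprint matrices (frames × contacts, TSV); filter
   contacts persisting in > 20 % of frames; label residues with generic
   numbers (Ballesteros–Weinstein / CGN) so complexes are comparable.
2. **Network learning** — learn a discrete Bayesian network over the contact
   variables by hill climbing with 50 random restarts under the BDeu
   marginal likelihood; report each edge's strength as the per-frame log
   marginal-likelihood ratio of the network with vs without the edge.
3. **Cooperativity** — rank contacts by node strength (sum of incident edge
   strengths), flag the top quartile, aggregate over structural regions,
   score G-protein regions by the mean strength of their unconserved
   cooperative contacts, and correlate with experimental coupling data
   (ΔlogEC50 of chimeric G proteins).
4. **Cross-complex comparison** — moralize the directed networks, extract
   the largest common subnetwork across complexes, and compare complexes by
   the Jensen–Shannon divergence of their empirical joint distributions over
   the shared subgraph.
5. **Allostery & robustness** — classify network edges as neighboring
   (≤ 10 Å Cα–Cα) or allosteric (> 10 Å), and validate models with 1000
   random topology perturbations and 1000 frame-resampling trials against a
   0.99 empirical confidence interval.
6. **Synthetic fixtures** — generate fingerprint matrices from planted DAGs
   (noisy-OR conditionals), with toy coordinates, regions and conservation
   flags, so the whole pipeline is testable without trajectory data.

## The statistic at the core

For binary contact variables $X_1,\dots,X_n$ over $N$ frames, a DAG $G$ is
scored by the decomposable BDeu log marginal likelihood (equivalent sample
size spread uniformly over parameter cells). The strength of edge
$u \to v$ is

$$w(u\to v) \;=\; \frac{1}{N}\Big[\log P\big(X_v \mid \mathrm{pa}(v)\big) -
\log P\big(X_v \mid \mathrm{pa}(v)\setminus\{u\}\big)\Big],$$

a per-observation Bayes-factor log-ratio, comparable across trajectories of
different length. A node's *cooperativity* is the sum of its incident edge
strengths.

## Worked example

```r
library(contactbn)

fx  <- make_interface_fixture(n_nodes = 20, n_frames = 5000, seed = 1)
net <- learn_structure(fx$fingerprints, restarts = 50, seed = 1)
net
#> <contact_bn> 20 nodes, 9 edges, score -54774.125 (-10.95482/frame)

tab <- rank_top_quartile(node_strengths(net), regions = fx$regions)
head(tab[, c("node", "receptor_id", "gprotein_id", "node_strength",
             "rank", "top_quartile")], 3)
#>           node receptor_id gprotein_id node_strength rank top_quartile
#> 1 1×48_G.X3.17        1×48     G.X3.17     1.8306004    1         TRUE
#> 2 3×43_G.X1.15        3×43     G.X1.15     0.3901490    2         TRUE
#> 3 1×41_G.X2.16        1×41     G.X2.16     0.3751665    3         TRUE

table(classify_edges(net, fx$ca_coords)$class)
#>  allosteric neighboring
#>           2           7

perturbation_test(net, fx$fingerprints, n = 1000, seed = 1)
#> <robustness_report> perturbation: 1000 trials, original score -54774.1248
#> fraction of trials below original: 1.0000
```

The top-ranked node `1×48_G.X3.17` is exactly the planted hub (`fx$hub`):
its five strong dependencies add up to the largest node strength. Edge
strengths are per-frame log likelihood ratios, so a deterministic binary
dependence approaches ln 2 ≈ 0.693. Edges spanning residues more than 10 Å
apart are the *allosteric* dependencies — co-variation that spatial
proximity cannot explain.

Console output above is from the exact commands shown (seed 1); your numbers
will match.

A thin CLI over the same functions ships in `inst/cli/contactbn.R`
(verbs: `simulate`, `contacts`, `fingerprint`, `learn`, `cooperativity`,
`compare`, `robustness`).

## Method vignette

`vignettes/cooperative-contact-networks.Rmd` documents the model and its
assumptions, every tunable parameter with units and defaults, what the
synthetic generator does and does not emulate, numerical edge cases, and
known limitations.
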