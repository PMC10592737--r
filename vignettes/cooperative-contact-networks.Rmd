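---
title: "Cooperative contact networks at protein-protein interfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cooperative contact networks at protein-protein interfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contactbn)
```

## The model

A protein-protein interface — the motivating case is a G-protein-coupled
receptor bound to a heterotrimeric G protein — is described here not as a
set of residues but as a set of *contacts*: each receptor-residue x
G-protein-residue interaction is one binary random variable, equal to 1 in a
frame of a molecular-dynamics trajectory when the pair satisfies at least one
of five geometric criteria (salt bridge, hydrogen bond, van der Waals,
pi-stacking, cation-pi). Stacking the per-frame indicators gives the
*fingerprint matrix* `X` with frames in rows and contact nodes in columns.
Residues are identified by generic numbers (Ballesteros-Weinstein for the
receptor, e.g. `3×50`; Common G-protein Numbering for the G alpha subunit,
e.g. `G.H5.24`), so a node label like `7×55_G.H5.24` means the same physical
interaction in every complex — the property that makes networks comparable
across receptors and G-protein subtypes.

Dependencies among contacts are modelled with a discrete Bayesian network:
a directed acyclic graph `G` over the contact variables, scored by the
Dirichlet-multinomial (BDeu) log marginal likelihood

$$\log P(X \mid G) \;=\; \sum_v \sum_{j=1}^{q_v}\left[
  \log\frac{\Gamma(\alpha_j)}{\Gamma(\alpha_j + N_{j})} +
  \sum_{k\in\{0,1\}} \log\frac{\Gamma(\alpha_{jk}+N_{jk})}{\Gamma(\alpha_{jk})}
\right],$$

where for node $v$ with $q_v = 2^{|\mathrm{pa}(v)|}$ parent configurations
the counts $N_{jk}$ tabulate the child's value $k$ under configuration $j$,
and the equivalent sample size is spread uniformly over cells
($\alpha_{jk} = \mathrm{ess}/(2 q_v)$). The score is decomposable and
score-equivalent, so edge *direction* within a Markov-equivalence class is
not identified from observational frames — which is why downstream
comparisons work on skeletons and moralized graphs.

Structure search is greedy hill climbing over single-edge add/delete/reverse
moves with random restarts (default 50: restart 0 starts from the empty
graph, the others from random DAGs with per-edge probability $2/(n-1)$).
Moves are enumerated in a fixed lexicographic order and ties go to the first
enumerated move, so the search is a pure function of (data, seed, restarts,
ess, max_parents).

The *strength* of an edge $u \to v$ is the log ratio of the marginal
likelihood of the network with and without the edge — by decomposability,
the child's family-score difference — divided by the number of frames. The
per-frame normalization puts strengths from trajectories of different length
on one scale. The *cooperativity* (node strength) of a contact is the sum of
the strengths of its incident edges regardless of direction; ranking nodes
and flagging the top quartile (`ceiling(0.25 N)`, label-ordered ties)
identifies the contacts whose presence co-varies most broadly across the
interface.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| salt bridge cutoff | 4.0 Å | anion-cation heavy-atom distance |
| H-bond cutoff / angle | 3.5 Å / 70° | donor-acceptor distance; deviation of D-H...A from linear |
| vdW tolerance | 0.5 Å | added to the Bondi radius sum |
| pi-stack cutoff / angle | 7.0 Å / 30° | centroid distance; inter-plane angle |
| cation-pi cutoff / angle | 6.0 Å / 60° | cation-centroid distance; ring-normal angle |
| persistence threshold | 0.20 | keep contacts present in > 20% of frames (strict) |
| restarts | 50 | hill-climbing random restarts |
| ess | 1.0 | BDeu equivalent sample size |
| max_parents | 5 | tractability cap on parent sets |
| allosteric cutoff | 10.0 Å | neighboring vs allosteric edge split |
| perturbations / resamples | 1000 / 1000 | robustness trial counts |
| CI level | 0.99 | empirical interval for the resampling test |
| quartile fraction | 0.25 | cooperative-node selection |

All of these live in `contactbn_config()` and can be overridden per call or
through a YAML file.

Two readings of the van der Waals criterion are supported. The default
treats two heavy atoms as in contact when their distance is below the sum of
their Bondi radii plus a 0.5 Å tolerance, the convention of standard MD
contact tooling; `vdw_gap_mode = TRUE` selects the literal rule "inter-atom
gap below 2 Å" instead, which is considerably more permissive. Since crystal
structures usually lack hydrogens, hydrogen-bond donors are typed from heavy
atoms and an idealized hydrogen is placed opposite the donor's bonded heavy
atoms for the angle test; explicit hydrogens are used when present, and a
donor whose antecedent atoms are missing falls back to the distance
criterion alone.

## Downstream comparisons

**Moralization.** Each learned DAG is converted to an undirected graph by
marrying every pair of co-parents and dropping edge directions; moral graphs
are deliberately unweighted. **Common subgraph**: across complexes, edges
whose node-label pair recurs in at least `min_support` moral graphs are
kept, and the largest connected component of the kept edges (by edge count;
ties by node count, then smallest label) is the shared backbone `G*`. The
connected-component reading is a design choice — a shared edge set need not
be connected — made because the object of interest is one coherent
interaction patch, not scattered coincidences. **Joint distributions**: over
`G*`'s node set the full empirical joint is tabulated per complex (the graph
contributes only the node set; probabilities come directly from the frames),
optionally with a Jeffreys-like pseudocount of 0.5 per state to keep
divergences finite when supports differ; pseudocount 0 gives raw
frequencies. Complexes are then compared by the Jensen-Shannon divergence in
natural-log units (bounded by ln 2 ≈ 0.693); a complex whose columns do not
cover `G*` is excluded from the matrix and reported. The logarithm base and
the smoothing are stated here because absolute divergence values depend on
both.

**Allosteric classification.** A network edge connects two contacts, i.e.
four residues. Its spatial extent is summarized from reference C-alpha
coordinates over the four cross residue pairs (identical residues excluded);
the default summary is the minimum, the most permissive "neighboring"
reading, with `mean` and `centroid` selectable. Edges within 10 Å (boundary
inclusive) are *neighboring*, the rest *allosteric* — the latter are the
dependencies that probability space sees but spatial proximity does not.

**Robustness.** Two protocols. The perturbation test applies small random
topology changes (default 2 add/remove moves, acyclicity preserved,
illegal draws resampled) 1000 times and reports the fraction of perturbed
topologies scoring strictly below the original on the same data. The
sensitivity test resamples frames with replacement 1000 times, rescores the
fixed topology per frame, and checks that the original per-frame score lies
inside the empirical 0.99 interval (type-1 quantiles of the trial scores).
Both are bit-reproducible given a seed. Frames are treated as independent
samples; MD frames are autocorrelated, so the resampling test's interval is,
if anything, optimistic about sampling variability (block resampling of
frames would be the remedy; plain frame resampling matches common usage).

## What the synthetic generator emulates

`make_interface_fixture()` builds one complex end to end: contact nodes
assigned to receptor x G-protein residue pairs; residues distributed
round-robin over the standard region inventories (TM1-7, H8, ICL1-3;
N-term, beta segments and loops, hns1, hgh4, core-other, alpha5-core,
alpha5-tip); C-alpha positions on a two-row lattice with 4 Å spacing so that
both neighboring and allosteric node pairs exist by construction; a planted
dependency DAG in which one *hub* node has five children and background
edges arrive with probability 0.08 (hub degree kept strictly maximal);
noisy-OR conditionals in which a child copies the OR of its parents and
flips with probability 0.1 — strong enough to be identifiable at a few
thousand frames without being deterministic; roots are Bernoulli(0.5); and
alternating G-protein residues flagged unconserved. Default problem sizes
for validation runs are 20 nodes and 5000 frames (3-node problems with 500
frames for exhaustive-search checks), sizes at which structure recovery is
reliable and a full validation cycle stays fast.

What the generator does *not* emulate: frame autocorrelation, non-stationary
contact formation, the heavy-tailed contact-frequency spectrum of real
interfaces, correlated typing noise between criteria, or physical protein
geometry (the lattice coordinates support distance classification only).
Passing tests on fixtures therefore demonstrate the statistical machinery —
score optimality, skeleton recovery, divergence separation, robustness — not
the geometric fidelity of contact detection on real structures, which is
exercised separately on analytically constructed coordinates.

## Numerical choices and degenerate inputs

- Family scores are memoized per (node, sorted parent set); cache hits are
  bit-identical to recomputation because the score is a pure function.
- Hill climbing accepts a move only if it improves the score by more than
  1e-9, guarding against float noise masquerading as improvement.
- Parent configurations never observed in the data contribute exactly zero
  to the score and are skipped.
- Constant fingerprint columns carry no dependency signal: they are kept as
  isolated, flagged nodes and never acquire edges; all-constant data is a
  degenerate-data error.
- The persistence filter is strict (`> 0.20`), so a contact at exactly the
  threshold frequency is dropped.
- Top-quartile size is `ceiling(q N)`, so even tiny networks flag at least
  one node; ties are broken by node label for reproducibility.
- Empirical joints refuse node sets whose state space exceeds `2^20`;
  KL terms with zero probability in the first argument contribute zero.
- An edge distance of exactly 10.0 Å classifies as neighboring.
- Region aggregation normalizes per G-protein region over that region's
  cooperative contacts (rows sum to 1); a second matrix normalized over all
  of the region's contacts is also returned, since either denominator is a
  defensible reading of "corrected on the number of total interactions".
- The alpha5-tip boundary (last 10 vs last 11 residues of the Galpha
  C-terminus) is genuinely ambiguous in the literature; region definitions
  are therefore *data* (a TSV), not code, and both presets can be shipped as
  files.

## A worked run

```{r example, eval = FALSE}
fx <- make_interface_fixture(n_nodes = 20, n_frames = 5000, seed = 1)
net <- learn_structure(fx$fingerprints, restarts = 50, seed = 1)
net

tab <- rank_top_quartile(node_strengths(net), regions = fx$regions)
head(tab, 5)

sel <- region_selectivity_scores(tab, fx$conserved)
mg <- moralize(net, "fixture")
cls <- classify_edges(net, fx$ca_coords)
table(cls$class)

perturbation_test(net, fx$fingerprints, n = 1000, seed = 1)
sensitivity_test(net, fx$fingerprints, n = 1000, seed = 2)
```

## Known limitations

- Frames are scored as independent observations (see above).
- Edge directions are not interpretable individually; only skeletons,
  moralized graphs and strengths are.
- Atom typing covers the twenty standard amino acids; ligands, ions and
  modified residues are ignored by the contact detector.
- Conservation flags and residue-numbering maps are user-supplied inputs;
  the package neither aligns sequences nor fetches numbering tables.
- The BDeu score stands in for proprietary scoring variants with the same
  marginal-likelihood-ratio edge semantics; the per-frame normalization
  provides the cross-network comparability, and the scoring function is
  isolated behind `family_score()` so alternatives can be plugged in.
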