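---
title: "Aligning protein interaction networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aligning protein interaction networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netaligner)
```

netaligner performs pairwise local alignment of protein–protein
interaction networks: given two interactomes (or a complex/pathway
query against an interactome), it finds subnetworks whose proteins are
homologous *and* whose interactions are conserved, scores them, and
attaches Monte-Carlo p-values. This vignette explains the underlying
probability models, the algorithmic choices, and what the synthetic
benchmark does and does not demonstrate.

## The probabilistic building blocks

### Interaction reliability

Every interaction carries a reliability in $[0,1]$. When input files
provide publication counts rather than precomputed reliabilities, we map
$n$ supporting publications to $r(n) = 1 - 2^{-n}$: each independent
publication halves the residual doubt, $r(0)=0$, and $r$ is monotone and
bounded below 1. This is a package convention — any precomputed
reliability column overrides it.

### Vertex probabilities from BLAST E-values

A vertex of the alignment graph is a pair of putative homologs, one
protein from each network. Its probability expresses sequence-level
confidence and is calibrated empirically-Bayes style: E-values observed
for accepted ortholog pairs (the homology model) and for all protein
pairs between the two proteomes (the null model) are binned by order of
magnitude, $b(E) = \lfloor \log_{10} E \rfloor$, with an extra bin below
all others for BLAST underflow ($E = 0$). The per-bin likelihood ratio
$LR(b) = f_{\mathrm{hom}}(b) / f_{\mathrm{null}}(b)$ uses add-one count
smoothing (finite samples leave null bins empty) and is then projected
onto the monotone non-increasing cone with the pool-adjacent-violators
algorithm (PAVA): a smaller E-value can never yield a smaller ratio.

The vertex probability is the *scaled* likelihood ratio
$p_v = t \cdot LR / LR_{\max}$ clamped to $[0,1]$, with $t = 1$ so that
the best pair gets probability exactly 1. A literal Bayes posterior
$LR\pi/(LR\pi + 1 - \pi)$ cannot reach 1 at any finite $LR$, so the
scaled form is the calibration that honours both anchor points used
throughout the package ($t=1$ for vertices, $t=0.9$ for interaction
conservation below). The scaling is invariant to multiplying all ratios
by a constant, and the full-Bayes alternative (prior
$\pi = t/((1-t)LR_{\max} + t)$, defined for $t<1$) is noted but not the
default.

Ortholog lists can be supplied, or derived from reciprocal BLAST
tabular output with `infer_reciprocal_orthologs()`: a pair is kept iff
each protein appears among the other's top-10 hits with
$E \le 10^{-10}$, in both directions; one-to-many and many-to-many
relations are retained.

### Evolutionary distances and conservation probabilities

Interacting proteins evolve at correlated rates, so the two homolog
pairs flanking a conserved interaction tend to show similar evolutionary
distances. Distances are estimated from fraction identity $q$ with the
Grishin model, which allows substitution rates to vary across sites and
residue types:

$$q = \frac{\ln(1 + 2d)}{2d}.$$

`grishin_distance()` iterates the contractive rearrangement
$d \leftarrow \ln(1+2d)/(2q)$ from the sites-only starting point
$d_0 = (1-q)/q$ until successive iterates differ by less than the
tolerance (default $10^{-3}$ substitutions/site, configurable; the
package's own validation drives it at $10^{-9}$), with a bisection
fallback on the residual for robustness near $q \to 1$. The direct
fixed-point form $d \leftarrow (e^{2dq}-1)/2$ diverges for moderate
$q$, which is why the logarithmic rearrangement is used.

The conservation model repeats the likelihood-ratio construction on
$\Delta d = |d_1 - d_2|$: a conservation sample (pairs flanking an
interaction observed in *both* networks — an observable quantity, no
ground truth required) against a null of random homolog-pair
combinations (default $10^6$ draws, down-scalable). $\Delta d$ is binned
at 0.1 substitutions/site — a fixed-width analogue of the
order-of-magnitude E-value binning, fine enough for smooth PAVA fits at
the default null size. The top bin is calibrated to probability 0.9, so
a predicted ("likely conserved") interaction is never more confident
than 0.9.

### Edge probabilities

Assuming mutual independence of reliabilities and conservation events,
an edge probability is the joint probability of everything it relies
on:

| edge type | probability |
|---|---|
| conserved | $r_q \cdot r_t$ |
| likely conserved (observed in query) | $r_q \cdot p_{\mathrm{cons}}(\Delta d)$ |
| gap (indirect in one network) | $r_{\mathrm{direct}} \cdot \prod_i r_{\mathrm{path},i}$ |
| mismatch (indirect in both) | $\prod_i r_{q,i} \cdot \prod_j r_{t,j}$ |

Naming convention: `likely_conserved_query`/`_target` name the network
where the interaction was *observed*; `gap_query`/`_target` name the
network that *contains* the gap (the indirect path).

## The alignment algorithm

1. **Vertices.** All homolog pairs with vertex probability at or above
   the vertex threshold. A protein may appear in many vertices; no
   one-to-one matching is imposed, which models duplication-driven
   one-to-many and many-to-many orthology without combinatorial
   explosion.
2. **Initial edges.** Conserved edges where both networks interact
   (self-interactions included — a homomultimer aligned to a
   heteromultimer is a legitimate conserved pattern); optionally
   likely-conserved edges where exactly one network interacts. Edges
   below the edge threshold are dropped.
3. **Seeds.** Connected components of the initial graph (depth-first
   search). Components need at least one edge: an isolated vertex
   carries no conserved interaction structure and is not a solution.
   Likely-conserved edges participate in seed formation.
4. **Extension.** Vertices of *different* seeds are connected by gap or
   mismatch edges when their proteins are linked indirectly by the best
   bounded path — the path of 2 up to `max_path_length` edges maximising
   the product of reliabilities (a modified Dijkstra view: shortest
   weighted path under $-\log r$ with a length cap). The default cap of
   3 edges reflects the small-world structure of interactomes: longer
   paths connect essentially everything. Within-seed pairs are never
   bridged — seeds are already connected conserved structure, and
   intra-seed shortcuts would mostly add false positives. Gap/mismatch
   paths may traverse any network protein, including proteins without
   homologs. Candidate pairs are pruned by unweighted hop distance
   before the bounded search; the pruning is exact, since no path of
   $\le k$ edges exists between proteins more than $k$ hops apart.
5. **Solutions.** Connected components of the extended graph. By
   construction no homolog pair occurs in two solutions (maximality),
   so overlapping complexes merge into one solution instead of needing
   post-hoc merging.

Ties anywhere (equal path products, equal scores) break on
lexicographic node sequences, making runs deterministic.

### Scoring and significance

A solution $G = (V, E)$ scores

$$S(G) = \alpha \sum_{v \in V} \log(1 + p_v) +
        (1-\alpha) \sum_{e \in E} \log(1 + p_e),$$

with $\alpha \in [0,1]$ (default 0.5) the vertex-to-edge balance.
Vertices and edges are transformed identically so $\alpha$ has its
literal meaning; the $+1$ keeps scores positive for ranking and affects
no ordering.

Significance uses a topology-preserving Monte-Carlo permutation test:
for each solution we build a background of `n_random_scores` (default
10,000) random scores by redrawing every vertex probability from the
pool of all vertex probabilities, and every edge from the reliability
(and conservation) pools according to its type and path lengths — same
topology, same edge types, no rewiring of the input networks and no
randomisation of homology relationships. The p-value is
$(1 + \#\{S_{\mathrm{rand}} \ge S_{\mathrm{obs}}\})/(1 + N)$; counting
ties as exceedances and adding one keeps it in $[1/(N+1), 1]$ and
conservative. Because backgrounds preserve size, large solutions are
not automatically significant.

## Benchmark evaluation rules

* Redundant complexes/pathways are clustered by single linkage on the
  Jaccard distance $1 - |A \cap B|/|A \cup B|$ at threshold 0.5
  (single linkage is the simplest scheme consistent with
  overlap-based clustering; Jaccard is the union-normalised overlap).
* A query/target set pair is *conserved* iff at least 2 and at least
  25% of each side's members have a homolog in the other side (both
  directions). Cluster-pair representatives minimise unmatched
  components, then maximise matched ones, then break ties
  lexicographically.
* A solution *covers* a target set iff its target-side proteins include
  at least 2 and at least 50% (complexes) or 1/3 (pathways) of the
  members.
* Set level: TP = distinct benchmark sets covered (a solution spanning
  two clustered complexes scores both), FP = solutions covering none,
  FN = sets uncovered. Protein level: distinct proteins in overlaps /
  unique to solutions / unique to covered sets, with each solution's
  overlap taken against its best-matching covered set (fewest unmatched
  proteins). Pathways add the same bookkeeping on target-side
  interactions. In query modes only the top-ranked significant solution
  is evaluated.
* With no significant solutions, precision is undefined; it is reported
  as 0 with an explicit `degenerate` flag.

Default parameter profiles are per task, chosen by grid search for the
highest average F-measure on the synthetic benchmark
(`calibrate_parameters()` exposes the driver). For whole-interactome
alignment the calibrated profile is strict (vertex 0.5, edge 0.6):
mean F plateaus for edge thresholds 0.6–0.7, and the lower end is kept
so likely-conserved edges (probability at most $0.9 \cdot r$) survive
filtering. Permissive thresholds let background gap/mismatch bridges
chain unrelated modules into one giant solution — the known failure
mode of whole-interactome comparison. Query modes (complex/pathway to
interactome) keep permissive thresholds (0.2/0.05) because the query
itself restricts the search space.

## The synthetic benchmark

`generate_synthetic()` creates paired networks with known ground truth:
planted conserved modules (default 20, sizes 3–8) mirrored in both
networks, Erdős–Rényi background (density 0.008, mean degree ≈ 2.4 at
300 proteins per side), 10% of planted edges rewired on one side, and a
homolog map with 20% decoy pairs. Defaults encode what the models
assume about real data:

* Planted modules are dense (spanning tree plus extra edges at
  probability 0.6) and well supported (publication counts
  $3 + \mathrm{Geom}(0.5)$ versus $1 + \mathrm{Geom}(0.6)$ for
  background): curated conserved complexes are densely connected and
  literature-rich, and this contrast is exactly what the score's edge
  term and the permutation test exploit.
* Homolog E-values are uniformly strong ($\log_{10} E$ uniform on
  $[-32, -28]$, reciprocal values correlated within a pair, optional
  exact-zero underflow spike), decoys weak ($[-8, -2]$), the all-pairs
  null log-normal around $10^{-2}$. Under scaled-likelihood-ratio
  calibration, vertex probabilities reproduce relative bin frequencies,
  so a flat band models "uniformly credible orthologs" while keeping
  decoys well below the vertex threshold.
* Identities are drawn per module around a module-level base value
  (s.d. 0.02), so planted conserved pairs have small $\Delta d$ while
  random pairs do not — the separation that conservation prediction
  requires.

What the generator does **not** emulate: scale-free degree
distributions (an Erdős–Rényi background is deliberate; the gap cap, not
the null topology, is what the method relies on), heavy-tailed homology
spectra with marginal hits, correlated experimental noise between
databases, and paralog inflation. Passing the planted-module tests
therefore demonstrates algorithmic correctness under the stated
statistical structure, not performance on any real interactome.

Problem sizes in the shipped tests are the package's validation
choices: the end-to-end study uses the default 300-protein networks
with 10,000-score backgrounds (9,999 in the recovery study so p-values
sit on a $10^{-4}$ grid); unit tests use 100–120-protein instances with
small backgrounds, since they probe contracts rather than power.

## Numerical choices and degenerate inputs

* E-value 0 (BLAST underflow) gets a dedicated lowest bin, preserving
  monotone ordering; lookups outside the fitted bin range clamp to the
  nearest end.
* Add-one smoothing on bin counts avoids division by zero in
  likelihood ratios.
* Duplicate interactions merge keeping the maximum support (union
  semantics across source databases); duplicate identity records keep
  the smallest distance (best alignment).
* Empty inputs: an empty interaction file is a valid empty network; an
  empty homolog set aligns to zero solutions; scoring an empty solution
  and fitting from empty samples are errors.
* Monte-Carlo p-values are reproducible under the run seed, and the
  aligner restores the caller's RNG state.

## Limitations

* The exact count-to-reliability mapping, posterior form, iteration
  tolerance and score constants of the original method are not
  recoverable from its description; the package documents its own
  choices above and anchors them to the two stated calibration points
  (top vertex pair = 1, top conservation bin = 0.9).
* Pairwise alignment only; multiple-network alignment is out of scope.
* One global gap-length cap is used for both networks.
* Identifier namespaces must already match (UniProt accessions in
  practice); no identifier mapping is performed.
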