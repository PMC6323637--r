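---
title: "Edge-based hypergraphs of multi-subject functional connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Edge-based hypergraphs of multi-subject functional connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Conventional functional-network analysis treats brain regions as nodes and
asks which regions cluster together. `edgehyper` inverts the unit of
analysis: the network *edge* (a functional connection between two regions)
becomes the object of interest, and the question becomes which edges
*co-vary in strength across individuals*.

Given a cohort of $S$ subjects with symmetric connectivity matrices over
$n$ regions, the package stacks them into an adjacency tensor
$A_{ijs}$ and treats each edge's weights over subjects as a vector of $S$
observations. For every pair of edges $m, n$ it computes the Pearson
correlation $H_{mn}$ of these vectors, storing them in the
$E \times E$ matrix $H$ (the *hypergraph*, with $E = n(n-1)/2$). Entries
whose two-sided $P$ value (t distribution, $S-2$ df) exceeds $\alpha =
0.05$ are zeroed to control false positives; surviving negative entries
are zeroed afterwards, with their prevalence recorded
(`fraction_negative`), so that community detection operates on a
nonnegative similarity matrix. Edges whose mean weight does not exceed
0.07 are excluded up front — near-constant weak edges contribute noise,
not covariance structure. Whether that filter should read per-subject
weights or a summary statistic is not uniquely determined; the
across-subject mean is the simplest reproducible choice and is
configurable.

*Hyperedges* — groups of co-varying edges — are communities of $H$ found
by maximizing Newman modularity

$$Q = \frac{1}{2w}\sum_{mn}\Big[H_{mn} - \gamma\,\frac{k_m k_n}{2w}\Big]\,
\delta(c_m, c_n)$$

with the Louvain algorithm (igraph backend, best of `n_restarts = 100`
random restarts, $\gamma = 1$).

### Two refinements the data forced

Two behaviours of this pipeline only become visible when it is run on
data with known ground truth, and both required a design response:

1. **Resolution limit.** Global modularity prefers to absorb a small,
   densely co-varying community into a much larger one once total graph
   weight is large, even when the two share only chance-level
   correlations. On synthetic cohorts this reliably swallowed the
   smallest planted group. `louvain_partition(refine = TRUE)` therefore
   re-partitions every community on its own induced subgraph, accepting a
   split whenever the *subgraph* modularity of the split is positive
   (the undivided community scores exactly 0), recursively. This keeps
   $\gamma$ at its default while recovering small structure — the
   standard hierarchical answer to the resolution limit.

2. **Halo contamination.** An edge whose weights are spuriously
   correlated with a community's shared latent signal (at, say,
   $r \approx 0.15$, just past the significance threshold) is correlated
   with *every* member of that community at once, so modularity attaches
   it and no link-counting rule can remove it. Genuine members are
   distinguishable only by weight (within-group correlations near
   $\beta^2/(\beta^2+\sigma^2)$, e.g. 0.94 at the default settings,
   versus $\sim$0.15 for the halo). `extract_hyperedges` therefore prunes
   each community to its cohesive core: the member with the weakest mean
   within-community correlation is removed while it falls below
   `min_within = 0.5` of the community's average member strength. The
   rule is scale-free (it adapts to each community's own strength) and
   leaves the partition itself untouched. It operationalizes the notion
   of a *significant* hyperedge, which is otherwise under-determined.

### Archetypes

Each hyperedge induces a binary node graph $B_r$ over the regions its
member edges touch. Classification is two-step: if the best bipartition
(maximum cut) leaves more than a fraction $1 - \tau$ of edges uncut
($b < \tau$, default $\tau = 0.9$), the hyperedge is a **cluster**;
otherwise the smaller part of the cut decides — fewer than 4 nodes makes
it a **star** with those nodes as its core, 4 or more a **bridge**. Max
cut is solved exactly by enumeration up to 20 nodes ($2^{19}$ splits) and
by spectral-initialized greedy local search with 50 restarts above that.
Ties in cut value break toward the more balanced partition, then the
lexicographically smallest; a single edge is a star with a one-node core.
The $\tau$-thresholded bipartivity is a deterministic stand-in for a
statistical bipartiteness test: a degree-preserving rewiring null was
rejected because stars cannot be rewired at all, which would misclassify
exactly the structures of interest.

Nodal **star scores** count how often a region serves as a star core;
**bridge** and **cluster scores** sum the region's degree over bridge and
cluster hyperedges. System summaries divide each system's share of the
total score by the number of regions in the system.

### Connectors

Stars (with well-defined cores of at most 3 regions) and clusters are the
*fundamental modules*. For each bridge side, the overlap with every
module is compared against a null in which the side is re-drawn uniformly
with its size preserved; that null overlap is hypergeometric, so the
package offers both a Monte-Carlo estimate (with add-one correction,
flooring $p$ at $1/(n_{null}+1)$) and the analytic tail. All
(bridge, side, module) $P$ values are corrected jointly by
Benjamini-Hochberg — the conservative reading of an ambiguous family — and
a bridge whose two sides both match modules at $q < Q = 0.05$ is typed
star–star, star–cluster, or cluster–cluster. Because the joint family
grows with the number of recovered modules while the Monte-Carlo floor is
fixed, `run_pipeline()` uses the analytic tail; with hundreds of modules
a floored $p$ of $10^{-4}$ can never survive the correction even when the
overlap is maximal. Whether a star module means its cores only or all
touched nodes is not uniquely determined; the full node set is the
default, cores-only is a flag.

Subtype enrichment compares assigned-bridge counts per subtype, normalized
by the number of possible module pairs of that kind, against replicates of
the same random-side null (two-sided, add-one corrected). Inside the
replicates the overlap tails are computed analytically — the limit of the
Monte-Carlo test — keeping the loop at $O(n_{null})$ rather than
$O(n_{null}^2)$. These counts are discrete, so the reported conservative
$p$ cannot be exactly uniform under the null; calibration tests instead
check the randomized probability-integral transform of the observed count
among the null counts, which is exactly uniform under exchangeability.

### Cohesion and development

Star cohesiveness is compared with predefined cognitive systems: the
distribution of pairwise cross-subject correlations among a module's
within-module edges versus the mean pairwise correlation of each star
centered in that module, via a one-sided Mann-Whitney rank-sum test
(stars greater), BH-corrected across modules. The two-sample test is not
uniquely determined by the taxonomy of the problem; the rank-sum was
chosen for distribution-freeness, with a permutation mean-difference
variant and a Storey-type FDR behind flags. Modules with few
within-module edge pairs remain testable but are flagged low-power.

Developmental effects: each hyperedge's per-subject mean strength is
regressed on age and in-scanner motion (OLS; overall $F$ with numerator
df 2, age-only $F$ by flag), and the partial correlation of strength with
age given motion is computed from the two motion-residualized variables.
Archetype classes are compared by one-way ANOVA on the partial
correlations, with pairwise post-hoc permutation tests (one-sided in the
direction of the larger observed class mean by default) and a BH-FDR mask
at $q \le 0.01$ over the per-hyperedge partial-correlation $P$ values.
Age enters linearly; motion is taken as a given covariate column.

## Wavelet coherence

When regional time series rather than connectomes are supplied,
per-subject connectivity is the band-averaged magnitude-squared wavelet
coherence (band 0.01–0.08 Hz by default): a continuous Morlet transform
($\omega_0 = 6$, dyadic scales at $dj = 1/12$), Grinsted-style smoothing
(time: Gaussian of width equal to the scale; scale: boxcar of
$\approx 0.6$ octaves, 7 bins), coherence as smoothed cross-spectrum
magnitude squared over the product of smoothed autospectra, averaged over
in-band scales outside the cone of influence (e-folding distance
$\sqrt{2}s$). These wavelet-family and smoothing parameters are toolbox
defaults, not uniquely determined choices. Users with their own
connectivity estimates can skip this module entirely — the hypergraph
construction applies to any symmetric nonnegative measure.

At 124 volumes and TR = 3 s the band contains few independent samples, so
smoothing induces a substantial bias floor for truly independent series
(measured around 0.3–0.4); `generate_coherent_pair()` provides
band-limited fixtures whose theoretical in-band coherence equals a target
in $[0,1]$ (construction $y = a x + \sqrt{1-a^2}\,\epsilon$ with
$a = \sqrt{\mathrm{target}}$ and matched in-band spectra), useful mainly
for monotonicity checks against that floor.

## The synthetic cohort generator

`generate_cohort()` draws, for each subject $s$ and each edge $e$ of a
planted group $g$,

$$w_{es} = \mathrm{clip}\big(\mu_e + \beta_g z_{gs} + \gamma_g \tilde a_s
  + \delta m_s + \varepsilon_{es},\; 0, 1\big)$$

with a group-exclusive standard-normal latent $z_{gs}$, standardized age
$\tilde a_s$, raw motion $m_s$, and noise
$\varepsilon_{es} \sim N(0, \sigma^2)$; unplanted edges receive
$\mu_e + \varepsilon_{es}$ only. Group-exclusive Gaussian latents keep the
ground truth block-diagonal and recovery unambiguous. Two same-group edges
correlate at $\beta^2/(\beta^2+\sigma^2)$ in expectation, which is also
the planted value every cohesion statistic should approach. Ages are
uniform on 8–22 years; motion is log-normal ($\mathrm{meanlog} = -1$,
$\mathrm{sdlog} = 0.5$), correlated with age through a Gaussian copula
($\rho = 0.3$) so the covariate adjustment is genuinely exercised;
$\delta = 0.05$ by default. Clipping to $[0,1]$ mirrors coherence's range;
at $\mu = 0.3$, $\sigma = 0.05$ it is rare for unplanted edges, and for
planted edges at $\beta = 0.2$ (roughly 7% of draws) it is shared through
the common latent and shifts within-group correlations by well under
0.01.

The default cohort (`default_cohort_spec()`) has 50 regions, 200
subjects, and four planted groups — a 13-node star $K_{1,12}$, a 9-node
star $K_{2,7}$, a 10-clique, and a $K_{9,9}$ bridge linking 9 of the
first star's regions to 9 of the clique's — with $\beta = 0.2$,
$\sigma = 0.05$, and an age effect $\gamma = 0.1$ on the cluster group
only, concentrating developmental signal in the cluster archetype. The
bridge side size is a power decision: at 50 regions, a side of $k$
regions overlapping an $M$-region module can reach a hypergeometric tail
of only $\binom{M}{k}/\binom{50}{k}$; $k = 9$ against the 13-region star
gives $\approx 3\times10^{-7}$, deep enough to survive the joint BH
family (tens of thousands of tests once background fragments register as
modules), whereas a side of 5 caps at $6\times10^{-5}$ and can never be
assigned, no matter how strong the planted covariance.

What the generator does *not* emulate: BOLD autocorrelation spectra,
hemodynamic variability, motion artifacts in the time series, cross-group
latent loadings, or any spatial embedding of regions. Passing tests
therefore demonstrate correct recovery of block-latent covariance
structure under Gaussian noise — not performance on real fMRI, where
edge-weight distributions are heavier-tailed and covariance is not
block-diagonal.

## Numerical and scale choices

* Hypergraph construction is blockwise (`block_size`) so the $E \times E$
  matrix never requires more than one block of standardized rows at a
  time beyond the output itself; desk-scale analyses use $E \le 2{,}000$.
* Test-suite and acceptance simulations use 20 cohort seeds for recovery,
  50 replicates for error-rate checks, 150–200 replicates for
  calibration KS checks, and 500–2,000 null draws inside Monte-Carlo
  loops; these sizes give Monte-Carlo standard errors comfortably inside
  the asserted tolerances.
* Monte-Carlo $P$ values carry the add-one correction; permutation
  post-hocs default to one-sided in the direction of the larger observed
  class mean; BH ties and greedy-move ties break deterministically
  (lowest index / lowest label).
* All randomized stages take explicit seeds; a pipeline re-run with the
  same configuration is byte-identical, and every output directory
  carries the resolved configuration with a content hash.

## Known limitations

* The cohesive-core rule assumes a community's genuine members are
  roughly homogeneous in strength; a community merging two blocks of very
  different strengths would lose the weaker block's periphery first.
* The bipartivity threshold $\tau = 0.9$ is a stand-in for a statistical
  bipartiteness test; graphs with bipartivity just under $\tau$ are
  labelled clusters regardless of size, so the star/bridge boundary is
  sharp but the cluster boundary is conventional.
* Joint BH across all (bridge, side, module) tests is conservative; a
  per-bridge family would assign more connectors at the same $Q$.
* At 264 regions the full pipeline is memory- and compute-intensive
  ($E = 34{,}716$; the hypergraph alone is $\sim$9.6 GB in doubles);
  blockwise construction makes it feasible, but the shipped simulations
  deliberately stay at desk scale.
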