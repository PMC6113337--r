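---
title: "Methods: low-rank decomposition, phase-transition scanning and community recovery in temporal networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: low-rank decomposition, phase-transition scanning and community recovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(netphase)
```

## The model

netphase analyses an ordered sequence of symmetric weighted adjacency
matrices $A(t)$, $t = 1,\dots,T$, under the assumption

$$A(t) = L(t) + S(t) + E(t),$$

where $L(t)$ is low-rank and captures the community structure, $S(t)$ is a
sparse perturbation (few entries, possibly large), and $E(t)$ is a dense
perturbation (many entries, small magnitude).  The community structure is
assumed piecewise constant in time: $L(t) = L_m$ on stable segments
separated by phase-transition epochs $[\tau_m^-, \tau_m^+]$ during which
communities merge, split, grow, appear or vanish.  Each snapshot is
decomposed independently by solving the convex relaxation

$$\min_{L,S,E}\ \|L\|_* + \gamma\|S\|_1 + \alpha\|E\|_F^2
  \quad\text{s.t.}\quad A = L + S + E$$

with an alternating splitting augmented Lagrangian method (ASALM, a
three-block ADMM): a closed-form ridge update for $E$, elementwise
soft-thresholding for $S$, singular value thresholding (SVT) for $L$, and a
multiplier ascent $\Lambda \leftarrow \Lambda + \beta(A - L - S - E)$.
Averaging the per-snapshot $L(t)$ within a stable segment then cancels
estimation noise, and the averaged $\bar L_m$ is clustered to recover the
segment's core communities.

## Tunable parameters

* `gamma` (sparsity weight): default $1/\sqrt{N}$, the standard robust-PCA
  choice.  Binary and other low-mean block data need care: the $\ell_1$
  term fits each block's *median*, which is 0 for Bernoulli$(p < 0.5)$
  edges, so the globally optimal split can leave the entire block structure
  in $S$ with $L = 0$.  Structured recovery requires the quadratic term to
  be the cheapest home for the Bernoulli fluctuations and the nuclear term
  for the block means; for within-density $p$ this works out to roughly
  $\alpha < 2\gamma$, $N_k\,(\gamma\,p - \alpha\,p(1-p)) > p$ and
  $\sigma_k > 1/(2\alpha)$ simultaneously.  In practice that means raising
  `gamma` above $1/\sqrt N$ (to $\approx 3/\sqrt N$) with a mid-low `alpha`
  for sparse binary block models, which is also what the reference's own
  published block-model settings do relative to its general-purpose rule.
* `beta` (augmented-Lagrangian penalty): fixed at $0.15 N^2 / \|A\|_1$
  (elementwise $\ell_1$ norm).  This makes the SVT threshold $1/\beta$ and
  the soft threshold $\gamma/\beta$; doubling $\beta$ halves both.
* `alpha` (dense-noise weight): selected by scanning an evenly spaced grid
  over $(0.5/\sqrt{N + \sqrt{8N}},\ 10/\sqrt{N + \sqrt{8N}})$ (default
  spacing 0.015), decomposing a handful of sampled snapshots (default 20)
  at each value, and choosing, inside the widest contiguous grid run where
  the recovered rank is constant for every sampled time, the value with
  minimal inconsistency $\|L_{\alpha_i} - L_{\alpha_{i+1}}\|_F /
  (\|L_{\alpha_i}\|_F + 1)$ to its neighbours; ties break toward larger
  $\alpha$.  The "+1" reading of the denominator mirrors the solver's
  stopping rule and guards division by zero; it is isolated in
  `inconsistency()` so the alternative reading can be flipped in one place.
* `eps` / `max_iter`: the solver stops when $(\|\Delta L\|_F^2 +
  \|\Delta S\|_F^2)/(\|L\|_F^2 + \|S\|_F^2 + 1) \le$ `eps` (default 1e-6,
  cap 500 sweeps).  The reference method leaves these unspecified; the
  defaults reach relative feasibility residuals below 1e-3 on all bundled
  generators.  Non-convergence is flagged on the result, never thrown: the
  scanning pipeline must tolerate occasional hard snapshots.

A structural consequence of the relaxation worth knowing: at the optimum the
dense component retains a spectral slice of magnitude $1/(2\alpha)$ per
recovered direction, so even noise-free rank-$r$ input is recovered only up
to a Frobenius gap $\approx \sqrt r/(2\alpha)$.  Exact-recovery checks
therefore use a large $\alpha$ (no dense noise to absorb); mid-range
$\alpha$ values are appropriate exactly when dense noise is present.

## Phase-transition scanning

The scan partitions $1..T$ into windows of length $\lfloor\sqrt T\rfloor$
(a shorter remainder window is kept, otherwise changes near $T$ would be
invisible), averages $L(t)$ within each window, and records the
*thresholded rank* — the number of singular values exceeding $h$ — for a
grid of thresholds.  The threshold is chosen once, at the coarsest level,
as the midpoint of the widest contiguous grid run on which the per-window
rank profile is unchanged, with two refinements beyond the plateau rule
itself:

* thresholds at which no window retains more than one direction are
  excluded — the thresholded rank is meant to count effective communities,
  and the "all windows read 1" plateau above the community spectrum is
  always wide and always uninformative;
* the default grid is 60 log-spaced values between 0.1 and $\sigma_1$ of
  the time-averaged $L$; coarser grids can fail to resolve the structural
  gap between community and noise singular values, letting accidental
  noise-floor gaps tie with it.

A window is flagged volatile when its thresholded rank differs from the
preceding window's; consecutive flags merge into a candidate region.  This
is the minimal formalization of "rank volatility" and reproduces the
reference behaviour, including the case where a transition leaves the rank
unchanged but alters membership: a window straddling the change averages
two different low-rank structures and its rank inflates transiently.  The
scan then zooms into each candidate region (one coarse window of margin on
each side) with the next smaller window length, by default
$(\lfloor\sqrt T\rfloor, \max(2, \lfloor T^{1/4}\rfloor), 2)$, reusing the
same $h$.  At the finest level, trailing flagged windows whose rank already
equals the post-change stable value are trimmed (they were flagged only for
differing from the mixed window before them), and the surviving ranges are
reported as closed 1-based epoch intervals; the stable segments are their
complement.  Because a window must straddle the change to be flagged, a
reported epoch can sit one snapshot to either side of the generative
switch; reports keep both the flagged windows and the refined interval.

## Community extraction and evaluation

For each stable segment the per-snapshot $L(t)$ are averaged and the
community count is set to $k =$ thresholded rank of $\bar L_m$ at the
selected $h$.  Clustering is standard normalized spectral clustering:
entries of $\bar L_m$ are clipped below at zero to form a similarity
(solver output can retain small negative entries), the symmetric-normalized
Laplacian embedding into the leading $k$ eigenvectors is row-normalized and
clustered by k-means with a fixed seed and 20 restarts.  Nodes whose
similarity row is entirely zero (absent from the data or fully
disconnected) receive the noise label $-1$ without entering the embedding.

Evaluation against planted truth matches predicted clusters to planted
communities by exact maximum-weight bipartite assignment.  A planted
community counts as *recovered* when its matched cluster reaches Jaccard
overlap $\ge 0.5$ (majority overlap, the weakest unambiguous rule; the
reference reports recovery counts without stating one), and matching to the
noise label never counts as recovery.  The *error rate* is the
misclassification restricted to nodes of recovered communities, averaged
over time when predictions are per-snapshot; `misclassification_rate()`
reports the all-node variant with noise treated as an ordinary class.

## Diagnostics

Three scalar diagnostics are implemented exactly as printed in their source
definitions: Newman-Girvan modularity $Q$ over all ordered pairs including
the diagonal; *relative polarization* $P_k$, the mean within-community-$k$
weight divided by the mean weight outside all communities (both means over
ordered pairs, again including diagonals — no exclusion is stated); and the
per-node *variation* $V_i$, a sample standard deviation of a node's
connection weights whose printed form mixes conventions (mean over $N$,
squared deviations over $N-1$).  `node_variation(consistent = TRUE)`
exposes the textbook version.

## Synthetic generators: the stated world

The generators reproduce the reference experimental designs, with planted
membership timelines and epochs returned as machine-readable truth.

* **Factor model**: per stable segment, $L_m = U_m U_m^T$ where members of
  community $k$ draw loadings $\mathrm{Unif}(r_{in}, 1)$ and everyone else
  (including designated outlier nodes) $\mathrm{Unif}(0, r_{out})$;
  defaults $r_{in} = 0.6$, $r_{out} = 0.4$, sparse density $p_s = 0.1$,
  dense amplitude $r = 0.1$.  Sparse noise is Bernoulli$(p_s)$ support
  times $\mathrm{Unif}(-1,1)$ values; dense noise $\mathrm{Unif}(-r, r)$;
  both are redrawn every snapshot while $L_m$ stays fixed.  Snapshots are
  projected onto $\Omega = \{0 \le X_{ij} \le 1,\ X = X^T\}$; the
  generators sample the upper triangle and mirror, so symmetrize-then-clip
  is the exact Euclidean projection.
* **SBM**: binary, within-community edges Bernoulli$(p_c)$, none between,
  categorical flip noise $P(\pm 1) = 0.05$ each; the block component is
  drawn once per stable segment (the model class posits a fixed $L_m$).
* **WSBM**: within weights $\mathrm{Unif}(1-ub, 1)$, others
  $\mathrm{Unif}(0, ub)$, so segment averages approach $0.7$ within and
  $0.3$ between at $ub = 0.6$; signal strength degrades as $ub \to 1$ and
  detection is expected to fail by $ub \ge 0.9$.

Presets: `"illustrative"` (N = 900 with 100 nodes joining, T = 200, four
segments of 11/11/7/12 communities, transitions at 30-31, 60-65, 130-135),
`"three-model"` (N = 1000, T = 30, 11/9/7 communities, changes at t = 10
and 20), `"wsbm-split"` (N = 500, T = 40, one community splitting), and
proportionally scaled desk variants `"illustrative-small"` (N = 300 + 33
joining, T = 60, transitions 9-10, 18-20, 39-41) and
`"three-model-small"` (N = 332).  Inside a multi-step transition the
reference leaves the interim structure undefined; here the affected nodes
migrate progressively (at step $s$ of $e$, the first
$\lceil s/e \cdot n_{changed}\rceil$ affected nodes in index order carry
the new segment's structure, and a pair of nodes takes the new weight once
both have migrated).  All randomness flows through named substreams derived
from one master seed, so scenarios are bit-reproducible and component draws
do not interact.

**Scale caveat.**  Proportional down-scaling preserves the factor-model
experiments qualitatively but *not* the SBM/WSBM noise regimes: community
singular values scale like $N_k$ while noise singular values scale like
$\sqrt N$, and the sparse-term boundary $\gamma N_k \approx 1$ tightens.
The block-model experiments are therefore validated at their original
N = 1000 size (fast here because the solver's SVT uses a randomized partial
eigendecomposition), while the factor-model illustrative design uses the
scaled replication.  A green test on synthetic data establishes that the
pipeline recovers structure its model class generated; it says nothing
about misspecified real data beyond the robustness the noise components
provide.

## Kuramoto simulator

Coupled phase oscillators $\dot\theta_i = \omega_i + \kappa \sum_j C_{ij}
\sin(\theta_j - \theta_i)$ on binary support graphs with exact per-node
degree design (within-community $14 N_k/16$ via complements of seeded
regular graphs, one cross-community edge via a seeded matching;
hierarchical variant with per-level degrees 15/3/1).  The reference wording
conflates "natural (initial) phase"; here $\omega_i \sim N(0,1)$ are
natural *frequencies* — that is the role the equation assigns them — and
initial phases are $\mathrm{Unif}(0, 2\pi)$ per replicate.  Integration is
forward Euler at the per-period step $\tau$, one snapshot per step;
similarity $A_{ij}(t) = \langle|\cos(\theta_i - \theta_j)|\rangle$ averaged
over replicates (40 in the reference setting).  Phases and frequencies
carry across period boundaries while the support switches.  During the
first period the oscillators are still synchronizing, so the low-rank
spectrum drifts within the period; the scan can flag an extra early
candidate there, consistent with the reference's own observation of
variability around the first merge epoch.

## Known limitations

* The joint total-variation-coupled formulation is out of scope; each
  snapshot is decomposed independently and temporal coupling enters only
  through averaging.
* The plateau rules for $\alpha$ and $h$ assume the sampled times and
  windows contain enough stable structure; sequences dominated by
  transients (or with fewer than two stable windows) raise selection
  errors rather than guessing.
* Change-point uncertainty is not quantified; epochs are reported as index
  intervals without p-values.
* Communities smaller than about $\sqrt N$ in binary data fall below the
  sparse/low-rank identifiability boundary at the default $\gamma$.
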