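# netphase

Core community structure recovery and phase-transition detection in
temporally evolving weighted networks.

## The problem

Given an ordered sequence of symmetric weighted adjacency matrices
$A(t)$, $t = 1,\dots,T$ — protein interaction screens across conditions,
correlation networks of asset returns, voting-similarity networks across
legislative sessions, synchronization patterns of coupled oscillators —
netphase answers three questions:

1. **What is the core community structure?**  Each snapshot is decomposed
   as $A(t) = L(t) + S(t) + E(t)$ into a low-rank community component, a
   sparse perturbation and a dense noise floor, by solving
   $\min \|L\|_* + \gamma\|S\|_1 + \alpha\|E\|_F^2$ subject to
   $A = L + S + E$ with a three-block augmented-Lagrangian ADMM (ASALM);
   the SVT step uses a randomized partial eigendecomposition, so snapshots
   with a thousand nodes decompose in about a second.
2. **When does it change?**  The *thresholded rank* (number of singular
   values above a threshold $h$) of window-averaged $L(t)$ is scanned over
   $\sqrt T$-length windows with recursive zoom-in; windows where the rank
   turns volatile mark phase-transition epochs $[\tau^-_m, \tau^+_m]$,
   including changes that leave the rank itself unchanged.
3. **Who belongs where?**  Within each stable segment the $L(t)$ are
   averaged and clustered by normalized spectral clustering with
   $k$ = thresholded rank of the average; nodes outside any community get
   the noise label −1.

Diagnostics include modularity $Q$, a *relative polarization* index $P_k$
(mean within-community weight over mean weight outside all communities)
and per-node connection *variation* $V_i$.  Seeded generators provide
factor-model, SBM and weighted-SBM temporal networks with planted
community timelines, and a Kuramoto oscillator simulator
($\dot\theta_i = \omega_i + \kappa\sum_j C_{ij}\sin(\theta_j-\theta_i)$)
emitting phase-similarity snapshots — so every pipeline stage can be
validated against known ground truth.

## Worked example

```r
library(netphase)

# a 332-node, 30-snapshot factor-model network: 11 communities, two planted
# changes (communities merge at t = 10 and t = 20)
sc  <- build_scenario("three-model-small", seed = 3)
res <- run_pipeline(sc$network, run_config(alpha = 0.16))
res
#> <transition_report: 2 epoch(s) [9-10, 19-20], h = 0.363, levels = 5,2>
#>   alpha = 0.16; per-segment community counts: 11, 9, 7

# score the recovered segment communities against the planted truth
ev <- evaluate_detection(res$segments[[1]]$labels, sc$truth$membership[1, ])
ev
#> <evaluation: recovery 1.000 (11 of 11), error rate 0>
```

The report says the community structure changed inside snapshots 9-10 and
19-20 (the planted transitions are between 9→10 and 19→20; a detected
epoch names the window that straddles the change), the stable segments
carry 11, 9 and 7 communities, and every planted community is recovered
with zero misclassification from the segment-averaged low-rank component.

Tuning-parameter selection, when you do not know `alpha`:

```r
mats <- lapply(pad_to_union(sc$network)$snapshots, `[[`, "matrix")
scan <- alpha_scan(mats, alphas = seq(0.04, 0.2, by = 0.015),
                   sample_times = c(3, 14, 25, 29))
select_alpha(scan)
#> [1] 0.16          # widest rank-consistent plateau, minimal inconsistency
```

A command-line pipeline mirrors the R API:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/netphase.R", package="netphase"))')" \
    simulate --model factor --preset three-model-small --seed 3 --out demo/
```

Subcommands: `simulate`, `decompose`, `tune-alpha`, `scan`, `communities`,
`metrics`, `run`.  Snapshots are read/written as per-time Matrix Market
files or a 4-column `t i j w` TSV edge list.

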