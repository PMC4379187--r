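---
title: "Group-sparse symmetric NMF for overlapping and hierarchical communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Group-sparse symmetric NMF for overlapping and hierarchical communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsnmf)
```

## The model

`gsnmf` detects communities in an undirected, nonnegatively weighted network
by fitting a generative factorization of its adjacency matrix. Each vertex
$i$ carries a nonnegative propensity $U_{ik}$ of participating in community
$k$; the expected weight of the link between $i$ and $j$ is
$\hat A_{ij} = \sum_k U_{ik} U_{jk}$, i.e. $\hat A = U U^\top$. Vertices
with large propensities in the same column are densely connected, so the
columns of $U$ *are* the communities, and a vertex with substantial weight
in several columns belongs to several communities at once — overlap is
native to the representation rather than bolted on.

Fitting minimizes, over $U \ge 0$,

$$
L(U) \;=\; \lVert A - U U^\top \rVert_F^2 \;+\; \lambda \, \lVert U \rVert_{2,1},
\qquad
\lVert U \rVert_{2,1} = \sum_{k} \lVert U_{\cdot k} \rVert_2 .
$$

The first term is the least-squares reconstruction error, which corresponds
to additive Gaussian noise on the observed weights. The second is the
$\ell_{2,1}$ *group-sparsity* penalty: the $\ell_1$ norm of the vector of
column norms. Just as the lasso zeroes individual coefficients, this mixed
norm zeroes whole columns. One therefore starts from a deliberately
generous number of columns $K_0$ and lets the penalty empty the surplus:
the surviving column count is the model's own estimate of the number of
communities. The weight $\lambda$ acts as a resolution parameter — small
values keep many fine communities, large values merge them into few coarse
ones, and scanning $\lambda$ walks through the network's hierarchy.

## Fitting: multiplicative updates with restarts

The gradient of $L$ is
$\nabla L = -4AU + 4UU^\top U + \lambda\, U_{\cdot k}/\lVert U_{\cdot k}\rVert_2$
(columnwise in the last term). Splitting it into positive and negative
parts and choosing the Oja-style step size $\eta_{ik} = U_{ik}/[\cdot]_+$
turns gradient descent into a multiplicative rule,

$$
U_{ik} \leftarrow U_{ik}\,
\frac{(4AU)_{ik}}
     {(4UU^\top U)_{ik} + \lambda U_{ik} / \lVert U_{\cdot k}\rVert_2},
$$

which preserves nonnegativity and leaves exact zeros fixed; its fixed
points satisfy the KKT complementary-slackness conditions of the
constrained problem ([kkt_residual()] checks this numerically on every
fit). Two numerical choices matter in practice:

* **Damping.** The plain ratio update oscillates with period 2 on dense
  matrices (it badly overshoots when $UU^\top$ is far from $A$).
  [snmf_fit()] therefore applies the averaged map
  $U \leftarrow U\,\big(\tfrac12 + \tfrac12 r\big)$ with $r$ the
  multiplicative ratio — the standard stabilization for symmetric
  factorizations. It has exactly the same fixed points, so the KKT
  argument is untouched; `damping = 1` restores the plain rule, and the
  exported [update_step()] applies the plain printed rule.
* **Floors.** Every denominator, including the column norm that the
  penalty itself drives to zero, is floored at `eps = 1e-10`, so emptied
  columns decay smoothly to zero instead of producing NaN.

The loss surface is non-convex, so each fit runs `n_restarts = 10`
independent initializations and keeps the lowest final loss. Entries start
i.i.d. Uniform(0, 1) scaled by $\sqrt{\overline{A}/K_0}$, which puts
$UU^\top$ at the magnitude of $A$; restarts cycle scale multipliers
$\{1, 1, 2, 4\}$ because at strong penalties an all-small start can cross
the regime where the penalty dominates and collapse every column before
any community forms. Iteration stops when the relative loss change drops
below `rel_tol` (default `1e-6`) or after `max_iter` (default 1000)
updates. One master seed spawns per-restart child seeds, so every result
is exactly reproducible.

## From the membership matrix to communities

```{r karate}
kar <- load_fixture("karate")
fit <- snmf_fit(kar$network, k_init = 17, lambda = 1.7, seed = 1)
glance(fit)
```

* **Automatic K.** [prune_communities()] drops columns whose norm falls
  below `1e-6` times the largest column norm (plus the same absolute
  floor, so a fully collapsed fit reports zero communities rather than
  counting vanishing columns). What survives is the selected number of
  communities.
* **Hard partition.** Row argmax, ties to the lowest column index.
* **Overlapping cover.** Each row is affinely rescaled so its minimum is 0
  and its maximum 1; a threshold $t$ then binarizes the rescaled matrix,
  every vertex keeping at least its argmax community. The threshold is
  chosen by sweeping $t \in \{0, 0.05, \dots, 0.95\}$ and maximizing an
  overlapping extension of Newman–Girvan modularity that divides each
  vertex pair's contribution by the product of their membership counts —
  the simplest extension that agrees exactly with plain modularity on
  disjoint partitions. Note one structural consequence of per-row
  rescaling: with exactly two surviving columns each row becomes $(1, 0)$,
  so a two-community cover can never overlap; overlap diagnostics at a
  two-community scale come from the entropy profile instead.
* **Entropy diagnostics.** Rows normalized to probabilities give each
  vertex an entropy $H_i = -\sum_k p_{ik}\log_2 p_{ik}$ (bits). Spikes
  flag vertices torn between communities:

```{r dolphins}
dol <- load_fixture("dolphins")
res <- detect_communities(dol$network, lambda = 1.7, k_init = 2,
                          n_restarts = 10, seed = 5, rel_tol = 1e-9,
                          max_iter = 8000)
head(dplyr::arrange(res$entropy, dplyr::desc(entropy)), 4)
```

On the dolphin social network at its natural two-group scale these four
most-uncertain animals are exactly the classic boundary individuals that
sit at the junction of the two groups.

## Choosing the resolution

[resolution_scan()] refits the model along a $\lambda$ grid and records
the reconstruction error, the (weighted) penalty $\lambda\lVert
U\rVert_{2,1}$, their ratio, and the surviving community count; each grid
point also receives a warm-start restart continued from its predecessor,
which stabilizes the sparse end of the path. As $\lambda$ grows the
penalty term shrinks, the error grows, and communities merge — the
distinct partitions along the path are the network's multi-scale
organization ([hierarchy_levels()] summarizes them).

[recommend_lambda()] implements a simple operating-point heuristic:
choose the $\lambda$ whose penalty-to-error ratio is closest to 0.5.
Empirically, on networks with clear structure this ratio regime selects
community counts close to the known ones (12 conferences for college
football; the planted 4 blocks of the synthetic benchmark), and the
resulting partitions score near the best modularity the model attains on
those networks. The ratio compares the two terms exactly as they enter
the objective ($\lambda$-weighted); `weighted = FALSE` compares the bare
norm instead. Where the ratio-0.5 point sits depends on the network's
size and density: for the small canonical networks it lies around
$\lambda \approx 7\!-\!13$, and the single-community collapse around
$\lambda \gtrsim 14$, so the function's default grid (0.1–4, matched to
fine-scale analyses) should be widened — e.g. `seq(2, 13, 1)` — whenever
the coarse end of the hierarchy or the recommendation itself is the goal.
The worked analyses in this package use exactly such grids, and the
scripts report the grids they use.

```{r football, eval = FALSE}
fb <- load_fixture("football")
prof <- resolution_scan(fb$network, k_init = 28, lambda_grid = seq(2, 13, 1),
                        n_restarts = 4, seed = 1, max_iter = 1200)
rec <- recommend_lambda(prof)
rec$row$n_communities            # 12 communities at the recommended lambda
modularity_q(fb$network, rec$row$partition[[1]])
```

## Synthetic benchmarks

Two seeded generators reproduce the standard validation conditions, and
are first-class, tested code:

* [planted_partition()] — 128 vertices in four blocks of 32, independent
  Bernoulli edges calibrated so every vertex expects degree 16, of which
  `z_out` cross block boundaries ($p_{in} = z_{in}/31$,
  $p_{out} = z_{out}/96$). Raising `z_out` blurs the planted structure;
  at `z_out = 2` the pipeline recovers the blocks exactly (NMI = 1).
* [hierarchical_benchmark()] — 512 vertices in 16 communities of 32
  nested in 4 supercommunities of 128, with expected link counts `k1`
  (within community, $p_1 = k_1/31$), `k2` (within supercommunity,
  $p_2 = k_2/96$) and `k3` (elsewhere, $p_3 = k_3/384$), defaults
  $k_1 = k_2 = 16$. Scanning $\lambda$ exposes both levels: around
  $\lambda \approx 34\!-\!42$ the sixteen fine communities survive, and
  around $\lambda \approx 90\!-\!120$ exactly the four supercommunities.

Degrees are expectations, not exact: edges are independent coin flips, as
the "expected degree" construction prescribes, so individual degrees
fluctuate binomially. The generators emulate homogeneous block structure
only — they have none of the heavy-tailed degree and community-size
heterogeneity of real networks (the LFR benchmarks cover that regime;
their files are consumable through [read_edge_list()] and
[read_communities()]). Tests passing on these generators therefore
demonstrate correctness of the model and optimizer under clean planted
structure, not performance on degree-heterogeneous data.

## Embedded networks

Four small canonical networks ship as plain-text edge lists with
ground-truth groupings: Zachary's karate club (34/78, 2 factions), the
Doubtful Sound dolphin network (62/159, 2 groups), American college
football (115/613, 12 conferences), and a political-books surrogate. The
karate and football fixtures are the published edge lists; the dolphins
fixture is a transcription of the published network that reproduces its
vertex/edge counts and degree statistics. The `polbooks` fixture is
explicitly a *synthetic* three-block stand-in matching the published
summary statistics (105 vertices, 441 edges, groups of 49/43/13) — the
original co-purchase edges are not redistributable here, and analyses of
it validate the pipeline's behaviour, not claims about the actual book
network.

## Numerical and design notes

* Ties are broken deterministically everywhere (argmax to the lowest
  column index; equal restart losses to the lowest restart index; equal
  cover quality to the smallest threshold; equal ratio distance to the
  smaller $\lambda$).
* Degenerate inputs are legal: an empty network fits to the zero matrix
  at zero loss; a fully pruned fit is a 0-community result; constant rows
  in the rescaling fall back to argmax-only membership (the affine map is
  0/0 there).
* NMI uses the sum normalization $2I/(H_1 + H_2)$, with the convention
  that two single-community partitions agree perfectly (value 1).
* `modularity_q()` includes the diagonal null-model terms, so a
  single-community partition scores exactly 0; weighted networks use
  weighted degrees throughout.
* The enrichment score takes any symmetric binary pair-similarity (matrix
  or function); it is the mean similarity of co-clustered pairs over the
  mean similarity of all pairs.

### Known limitations

* The objective is non-convex and multiplicative updates are local:
  reported structure depends on restarts, and at large $\lambda$ the
  all-zero matrix is a genuine attractor (and eventually the true
  optimum). The scale-laddered restarts and warm-start continuation
  mitigate but cannot eliminate this.
* The number of communities selected at a given $\lambda$ follows from
  the objective's own trade-off. It depends on network size and density,
  so $\lambda$ values do not transfer between networks of different
  scale; the ratio heuristic, not any fixed $\lambda$, is the portable
  operating point.
* Problem sizes in the test-suite analyses (grids of 3–12 $\lambda$
  values, 4–6 restarts, networks up to 512 vertices) are the package's
  validation choices; larger studies should scale `n_restarts` and the
  grid up.
* Dense matrix algebra throughout: networks beyond a few thousand
  vertices need a sparse reimplementation of the two matrix products.
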