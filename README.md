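# spreadRank

Identifying the nodes that would spread something — a disease, a rumour, a
failure — fastest and furthest is a core question in network epidemiology and
systems biology. Purely local scores (degree) ignore a node's position in the
network; purely path-based scores (betweenness, closeness) ignore how
well-connected its contacts are. **spreadRank** implements a DEMATEL-based
gravity model that combines both: pairwise *gravity* interactions feed the
DEMATEL (Decision-making Trial and Evaluation Laboratory) machinery, which
propagates influence along indirect chains, so a node is scored by the total
influence it exerts and receives across the whole network.

It is aimed at researchers benchmarking influential-spreader identification on
undirected contact networks, and ships everything needed for a self-contained
comparison study: the model itself, the six standard comparison centralities,
a susceptible–infected (SI) simulator for ground-truth spreading capacity,
Kendall rank-correlation evaluation, Pajek/edge-list I/O, seeded synthetic
network generators, and a command-line interface.

## The model

For an undirected simple graph with degrees `k_i` and geodesic (hop-count)
distances `d_ij`:

1. **Direct relation.** The influence of node *i* on node *j* is the gravity
   interaction `g_ij = k_i k_j / d_ij²` (zero on the diagonal and for
   unreachable pairs), collected in the direct-relation matrix **D**.
2. **Normalization.** `N = D / s` with the scalar
   `s = max(max row sum, max column sum)` of **D**.
3. **Total relation.** `T = N + N² + N³ + … = N (I − N)⁻¹`, so indirect
   influence along chains of any length is accumulated. When the spectral
   radius of `N` reaches 1 (regular structures), a truncated partial sum is
   used instead, with a warning.
4. **Importance.** `R_i = Σ_j T_ij` (influence exerted), `C_j = Σ_i T_ij`
   (influence received), and the node importance is `a = R + C`. On
   undirected input `T` is symmetric, so `R = C` and `a = 2R`.

Baselines, in the field's usual notation: degree `d_i`, betweenness
`b_i = Σ p_mn(i)/p_mn`, closeness `CC(i) = (n−1)/Σ_j d_ij`, eigenvector
`EC(i) = e_i` (Perron eigenvector), gravity `CG(i) = Σ_j k_i k_j / d_ij²`, and
eigenvector-weighted gravity `WG(i) = e_i · CG(i)`.

Rankings are validated against SI epidemics: every infected node infects each
susceptible neighbour with probability β per step; a node's *spreading
capacity* is the mean final number of infected nodes when seeding at it, and
agreement between a centrality and capacity is measured by Kendall's tau
(tie-corrected tau-b by default; the n(n−1)-denominator variant is available
as `variant = "paper"`).

## Worked example

```r
library(spreadRank)

g <- readPajek(system.file("extdata", "synthetic_net.net", package = "spreadRank"))
g
#> SpreaderGraph with 6 nodes and 5 edges
#>   labels: hub, l1, l2, mid, tail1, tail2

res <- rankDematel(g)
res$relations
#> RelationMatrices: n = 6 | scale s = 13.83333 | method = closed_form | converged = TRUE
print(scoreTable(res$importance), digits = 4)
#>    node          method score rank
#> 1   hub dematel-gravity 5.643    1
#> 2   mid dematel-gravity 5.338    2
#> 3 tail1 dematel-gravity 3.558    3
#> 4    l1 dematel-gravity 2.101    4
#> 5    l2 dematel-gravity 2.101    5
#> 6 tail2 dematel-gravity 1.290    6
```

`hub` (degree 3) ranks first, but `mid` (degree 2) comes a close second: it
bridges the hub to the tail, so it exerts and receives a lot of *indirect*
influence — precisely what the total-relation matrix adds on top of plain
gravity. The two symmetric leaves `l1`, `l2` tie exactly.

Checking against simulated spreading:

```r
cap <- spreadingCapacity(g, config = siConfig(beta = 0.3, steps = 5, runs = 200, seed = 7))
round(cap, 2)
#>   hub    l1    l2   mid tail1 tail2
#>  4.18  2.96  2.94  4.18  3.54  2.54
kendallTau(scores(res$importance)[names(cap)], cap)
#> Kendall tau (tau_b) = 0.9660918  [concordant 14, discordant 0, n = 6]
```

The importance ranking and the simulated spreading capacities agree almost
perfectly (no discordant pairs).

The same pipeline from a shell, via the bundled script
(`inst/scripts/spreadrank`):

```sh
spreadrank generate --model ba --n 200 --m-attach 2 --seed 7 --output net.edges
spreadrank rank --input net.edges --method dematel-gravity,gravity --output scores.tsv
spreadrank evaluate --input net.edges --methods dc,gravity,dematel-gravity \
    --beta-grid 0.05:0.55:0.05 --steps 20 --runs 100 --seed 7 --output tau.tsv
```

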