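# blsentropy

Contour-based shape descriptors built on **branch length similarity (BLS)
entropy**, for quantifying how self-similar a 2D silhouette is and for
comparing groups of silhouettes (e.g. gesture classes, organism outlines)
by their entropy profiles.

## The science

Take a shape boundary traced as an ordered sequence of `N` nodes. Make each
node in turn the hub of a *star network* joining it to all other boundary
nodes; with branch lengths `L_1..L_n` (`n = N - 1`) and branch
probabilities `p_j = L_j / Σ L_k`, the BLS entropy of that network is the
normalised Shannon entropy

    S = − Σ_j p_j log(p_j) / log(n)  ∈ (0, 1],

which equals 1 exactly when all branches are equal and is independent of
the logarithm base. Reading `S` for every node counterclockwise around the
boundary gives the **entropy profile**, which depends only on distance
ratios — it is invariant under translation, rotation and uniform scaling.

The **self-similarity Γ** of a (min–max normalised) profile of length `L`
is computed from sliding windows: split the profile into `K = L/W`
consecutive windows of size `W` (default 20), fit an ordinary
least-squares slope `w` to each, and call two windows *similar* when their
slopes agree in sign and `min(|w1|,|w2|)/max(|w1|,|w2|) ≥ c` (default
`c = 0.8`). Repeating this for cyclic window offsets `j·φ`
(`j = 0..θ`, `θ = LCM(W,φ)/φ − 1`, lag `φ` default 20) yields the
similar-window count matrix `M`; each row gives the percentage
`γ_j = 2 h_j / (K(K−1)) · 100` of similar unordered window pairs, with
`h_j = Σ_k (M_jk − 1)/2`, and

    Γ = max_j γ_j  ∈ [0, 100] %.

For groups of shapes, `Q` is the maximal Pearson correlation between two
profiles over all cyclic shifts, and the group statistic
`Z = BLS(mean_j Q_j) / 10 ∈ (0, 0.1]` treats each member's mean within-group
`Q` as a branch length: `Z = 0.1` exactly for perfectly homogeneous groups.
Groups separate in the `(Γ, Z)` plane; a nearest-centroid rule in that
plane classifies held-out shapes.

## Worked example

```r
library(blsentropy)

sq <- make_regular_polygon(4, 250)               # square, 996 nodes
pr <- entropy_profile(resample_contour(sq, 1000))
pr
#> <bls_profile: 1000 nodes, closed; raw range [0.978527, 0.981112]>

self_similarity(pr, gamma_params())              # W = 20, lag = 20, c = 0.8
#> <gamma_result: Gamma = 10.86% (K = 50 windows, theta = 0)>
#>   gamma by offset: 10.86

contour_gamma(make_regular_polygon(5, 200))$gamma   # pentagon
#> [1] 16.32653
contour_gamma(make_random_polygon(15, seed = 1))$gamma
#> [1] 6.040816

groups <- make_shape_groups(n_groups = 3, n_members = 5,
                            nodes_total = 400, seed = 2)
profs  <- lapply(groups, function(g) lapply(g, entropy_profile))
group_features(profs)
#>   group_id n gamma_mean gamma_sd          Z
#> 1      g01 5   7.052632 1.025978 0.09999999
#> 2      g02 5   7.157895 0.288275 0.09999999
#> 3      g03 5   4.210526 1.052632 0.09999993
nearest_centroid_loo(profs)$accuracy
#> [1] 1
```

The raw profile of a near-symmetric shape is nearly constant (range above:
0.9785–0.9811); the structure lives in the normalised profile. The regular
pentagon scores higher Γ than an irregular random 15-gon because its
profile repeats five identical lobes whose windowed slopes keep matching
under cyclic offsets. In the group table, `Z ≈ 0.1` says members of each
template-plus-noise group correlate almost equally with one another, and
leave-one-out nearest-centroid classification in `(Γ, Z)` recovers every
member's group.

## Command line

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "blsentropy.R", package = "blsentropy"))') \
    synth --kind triangle --counts 100,120,120 --out tri.csv
# subcommands: synth | profile | gamma | batch | z | classify
```

Masks are PNG, ASCII PGM/PBM or 0/1 CSV; contours and profiles are plain
CSV; features and Γ reports are JSON. A JSON config file (`--config`) can
supply any flag.

## Package layout

- `R/contour.R`, `R/generators.R`, `R/trace.R` — contour container,
  synthetic shape generators, Moore-neighbour boundary tracing, mask and
  CSV I/O
- `R/entropy.R` — BLS entropy and entropy profiles
- `R/selfsim.R` — windowed slopes, similarity criterion, count matrix, Γ
- `R/groups.R` — cyclic correlation `Q`, group statistic `Z`, `(Γ, Z)`
  features, nearest-centroid classification
- `R/cli.R`, `inst/cli/blsentropy.R` — batch orchestration and CLI
- `vignettes/self-similarity.Rmd` — methods notes: model, parameters,
  numerical choices, limitations
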