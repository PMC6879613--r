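# cdinet — Communities of Dynamical Influence for directed networks

`cdinet` identifies the vertices that can lead a networked system to
rapid consensus, and the communities that form under their influence,
from the geometry of a graph's dominant left eigenvectors. It is aimed
at people studying collective behaviour on directed networks — flocking
models, voxel-wise brain connectomes, engineered multi-agent systems —
who need influence-aware community structure rather than edge-density
clusters.

## The method

For a weighted digraph with adjacency matrix `A` (`a_ij > 0` iff edge
`i -> j`), outdegree matrix `D` and Laplacian `L = D − A`, consensus to
a target `u` under a globally bounded input perturbation evolves as

    dx/dt = −L x + C (u·1 − x),   C = diag(c),  Σ c_i = 1,  c_i ≥ 0,

and converges at rate `|Re λ₁(−(L + C))|`. The left eigenvectors of `L`
(`v L = λ v`) order the network by dynamical influence: `v_L1` (at
`λ₁ = 0`) scores each vertex's pull on the collective state, and the
next eigenvectors split the network into basins of influence.

**Communities of Dynamical Influence (CDI)** places each vertex at its
coordinates in the first `m` left eigenvectors. Vertices with no
outgoing edge towards a point farther from the origin are *leaders*;
every other vertex joins a leader reachable along a strictly
radius-increasing path (scalar products resolve multiple claims). A
staged perturbation optimiser then validates the leaders by maximising
`|λ₁(−(L + C))|` over allocations built from community-masked `v_L1`
vectors (powers `η` concentrate them, weights `r` mix them). A
community-overlap statistic (*mean number of matching communities*)
compares voxel-embedded graphs, and recursive spectral bisection is
included as a baseline.

## Worked example

```r
library(cdinet)

g  <- generateKNNR(100, 10, seed = 7)   # 100 vertices, k = 10
cs <- detectCDI(g, m = 3)               # 3 input eigenvectors
cs
#> CommunitySet: 3 communities over 100 vertices
#>   leaders (by influence): 33, 53, 43
#>   sizes: 66, 33, 1

res <- optimisePerturbation(g, cs)
res
#> PerturbationResult: rate 0.0338325 using 1 community vector(s)
#>   baseline (plain vL1) rate: 0.0197002
#>   stages accepted: 2

tr <- simulateConsensus(g, res@allocation, u = 1,
                        horizon = 5 / res@rate, steps = 300)
empiricalDecayRate(tr)                  # matches the analytic rate
#> [1] 0.03383245
```

The detected communities partition the vertices under the most
influential leaders; the optimised allocation reaches consensus ~1.7x
faster than the plain `v_L1` baseline, and the simulated trajectory
decays at exactly the analytic rate.

A shell entry point mirrors the main pipelines:

```sh
inst/cli/cdinet generate --family knnr --n 100 --k 10 --seed 7 --out g.tsv
inst/cli/cdinet cdi --graph g.tsv --m 3 --out communities.csv
inst/cli/cdinet optimise --graph g.tsv --m 3 --out perturbation.csv
```

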