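# emfi — divide-and-conquer solver for large weighted p-median problems

`emfi` places `p` facilities among `n` demand points so that the
demand-weighted sum of distances from every destination to its nearest open
facility,

> Z = Σᵢ wᵢ · d(i, nearest open facility),

is minimised — the discrete p-median location-allocation model used, for
example, to site ad-hoc dispensing clinics over census block groups in
public-health emergency planning. Exact mixed-integer solutions and even the
standard fast-interchange (vertex-substitution) heuristic stop scaling at a
few thousand demand points, so `emfi` decomposes the problem along the
spatial structure of demand:

1. fit bivariate Gaussian mixtures (EM, `c = 2..cmax`) to the demand-point
   coordinates and keep the minimum-BIC labelling;
2. keep only subregions that are **dense** (demand per convex-hull area above
   the region's) and **spatially concentrated** (quadrat χ² test against the
   binomial expectation, dof = n_sub), dissolving the rest into their nearest
   dense neighbour;
3. apportion facilities to the surviving subregions proportionally to
   demand, solve each subproblem independently (exact branch-and-bound when
   small, fast interchange otherwise, optionally in parallel);
4. union the facilities and reassign all destinations globally
   (*reassignment*), then optionally refine with a warm-started global fast
   interchange (*improvement*) or with iterative distance-based
   re-decomposition (k-means over the current facilities, k chosen by the
   Davies–Bouldin index, k → k−1 until the cost stalls).

A synthetic instance generator (clustered / centered / homogeneous demand
surfaces built from ~N(1500, 400)-sized aggregations of atomic demand units,
`p = n/4`) makes every stage testable end to end.

## Worked example

```r
library(emfi)

cfg  <- synthetic_config("clustered", total_demand = 120000,
                         n_gen_clusters = 4, seed = 7)
inst <- generate_instance(cfg)
inst
#> p-median instance: n = 80 destinations, p = 20, 80 candidate sites
#> total demand = 120000

res <- run_em_fi(inst, emfi_config(seed = 1, improve_mode = "global_fi"))
res
#> EM-FI result (em_fi:global_fi): Z = 387184
#> k = 5 mixture components -> q = 4 subproblems; 2.75s

best <- min(fi_restarts(inst, 30, seed = 1))
relative_cost(res$solution$objective, best)
#> [1] 100.5668
```

The report says the mixture sweep found `k = 5` components, four survived
the merge step (`q = 4`, matching the four generator blobs), and the final
objective sits 0.57% above the best of 30 random-restart fast-interchange
runs.

There is also a thin command-line wrapper:

```sh
Rscript inst/cli/emfi generate --out inst.csv --layout clustered --seed 4
Rscript inst/cli/emfi solve --input inst.csv --p 100 --method emfi \
    --improve global-fi --seed 1 --out solution
Rscript inst/cli/emfi evaluate --input inst.csv --facilities solution_facilities.csv
```

`solve` writes `solution_facilities.csv`, `solution_assignment.csv` and
`solution_summary.json`; `--geojson` additionally emits facility points and
convex-hull service areas for GIS viewers.

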