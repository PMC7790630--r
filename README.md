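# dietweb

Weighted directed food webs from predator diet records.

`dietweb` turns tabular predator-diet observations — stomach, stomach-flushing
and scat studies reporting **fraction of occurrence** (proportion of sampled
stomachs containing a prey category) and **fraction of diet by weight**
(gravimetric proportion of stomach-content mass) — into *cumulative*,
region-specific weighted directed food webs, and quantifies their structure.
It was written for circumpolar Southern Ocean diet syntheses (four
longitude-bounded sectors south of 40°S) but every scheme — months retained,
latitude cut-off, sector boundaries, group memberships — is configuration,
not code.

The pipeline:

1. **records** — read/validate/write the canonical record CSV (one row per
   predator–prey observation with study id, location, month, both diet
   metrics); longitudes normalized to [−180, 180).
2. **refinement** — summer-only (retain Nov–Mar), Southern-Ocean-only
   (latitude ≤ −40°, plus explicit manual exclusion lists), and
   taxon-quality filters; every drop attributed and reported.
3. **sectors** — half-open longitude intervals `[west, east)` with dateline
   wraparound (default: Atlantic 55°W–55°E, Indian 55°E–145°E, West Pacific
   145°E–115°W, East Pacific 115°W–55°W).
4. **webs** — aggregate taxa into trophic groups (fine ≈50-group and coarse
   15-group schemes supplied as tables), then build one edge per distinct
   (prey group → predator group) pair, weighted by the record-level mean of
   the chosen metric. Fine webs drop links lacking occurrence data; coarse
   webs keep them flagged `weight_missing`.
5. **metrics** — for a web with S groups and L links: connectance
   C = L/S² (self-links counted possible), link density LD = L/S, and for
   each mid-trophic group (zooplankton through demersal fish) the weighted
   out-degree strength Σ_out w — the total predation pressure on that group
   across predator groups — under both diet metrics.
6. **sampling bias** — source-randomized species-accumulation curves
   (sampling unit = source study, without replacement), their exact
   hypergeometric expectation E[count at x] = Σ_g [1 − C(n−n_g, x)/C(n, x)],
   and a least-squares negative-exponential fit S(x) = S_max (1 − e^{−kx}).
7. **synthetic data** — a stomach-level simulator (binomial occurrence,
   Dirichlet-style weight splits, per-metric missingness) generating
   datasets with known regional dominance structure.

## Worked example

```r
library(dietweb)

cfg     <- default_synthetic_config(seed = 1)   # four-sector synthetic world
records <- simulate_dataset(cfg)
scheme  <- synthetic_group_scheme(cfg)
refined <- apply_refinement(records)$records
grouped <- map_taxa(refined, scheme)$records
sectors <- split_by_sector(grouped)

web <- build_web(sectors[["Atlantic"]], metric = "occurrence",
                 require_metric = TRUE)
network_summary(web)
#> S = 7 groups, L = 10 links, C = 0.2041, LD = 1.4286
strength_table(web, scheme)[, 1:4]
#>                  group out_degree out_strength_occurrence out_strength_diet
#> 1      antarctic_krill          2               1.5468692         0.9100186
#> 2           myctophids          2               0.7292230         0.2155480
#> 3          cephalopods          2               0.6775780         0.3866926
#> 4 antarctic_silverfish          2               0.4938716         0.1666931
#> 5            amphipods          2               0.3689124         0.2164265
```

The krill analog tops the mid-trophic out-degree strength ranking in this
krill-dominated sector: two predator groups eat it, with occurrence-weighted
strength 1.55 (out of a possible 2.0), well clear of the alternatives. The
sampling-effort diagnostic on the pooled dataset:

```r
acc <- accumulation_curve(grouped, n_perm = 1000, seed = 1)
fit_negative_exponential(acc)
#> S(x) = S_max (1 - exp(-k x)): S_max = 5.9923, k = 1.7517, rss = 0.0202
```

The fitted asymptote (≈6 prey groups) matches the simulated richness, and
the large rate k says coverage saturates within a handful of source studies
— additional studies would add few new prey groups.

`run_pipeline(pipeline_config(...))` chains all stages and writes, per
sector and for the pooled dataset: refined records, rejection/refinement
reports, fine and coarse edge lists (CSV + GraphML), a network summary
table, mid-trophic strength tables, and accumulation curves, all
deterministically sorted so identical inputs give byte-identical outputs.
A command-line wrapper lives at `inst/scripts/run_pipeline.R`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

simulates the default synthetic world under the given seed, runs the full
pipeline (refinement → sector webs → metrics → strengths → accumulation),
prints the per-sector summary table, and writes the target JSON to `--out`.

## Vignette

`vignettes/sector-food-webs.Rmd` documents the model and its assumptions,
the tunable parameters and their defaults, what the synthetic generator
does and does not emulate, and the numerical choices (fit initialization,
tie-breaking, degenerate inputs).
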