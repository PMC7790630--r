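---
title: "Building sector-specific food webs from diet records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building sector-specific food webs from diet records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietweb)
```

## The problem

Diet studies of marine predators — lethal stomach sampling, stomach
flushing, scat analysis — accumulate as heterogeneous tables: one study
reports what fraction of sampled stomachs of predator *i* contained prey
*j* ("fraction of occurrence"), another reports what fraction of the total
stomach-content mass prey *j* contributed ("fraction of diet by weight"),
and many report only one of the two. Pooled across decades and regions,
such records support a *cumulative* food web: a directed graph recording
which trophic groups can interact within a region over ecological time,
with edge weights summarizing the average importance of each interaction.
Cumulative webs deliberately ignore fluxes at an instant; they are the
standard object for comparing food-web *structure* across regions.

`dietweb` implements that construction end to end, with the Southern Ocean
as the motivating system: records south of 40°S in the austral summer,
partitioned into the four major oceanic sectors by longitude, aggregated to
trophic groups at two resolutions, and summarized by network statistics.

## The model

**Records.** One row per predator–prey dietary observation:
study (`source_id`), reported predator and prey taxa, location (decimal
degrees; longitude kept on [−180, 180), east positive), collection month,
the two diet metrics as proportions in [0, 1], and the sampling method.
Metrics are stored internally as proportions; percentages exist only at
I/O (`percent_mode`) and in reporting columns, which avoids double-scaling
bugs.

**Refinement.** Three pure predicates, so their order is immaterial and
drops can be attributed to the first rule violated:

* *season*: retain months {11, 12, 1, 2, 3}. Records with unknown month are
  dropped by default (`drop_missing_month = TRUE`) because their season
  cannot be certified; set it to `FALSE` to keep them.
* *region*: retain latitude ≤ `latitude_max` (default −40°). Manual
  judgements — e.g. coastal samples from temperate landmasses whose
  predators do not forage in the study region — cannot be recomputed from a
  record, so they are carried as an explicit `excluded_records` list.
* *taxa*: drop records touching `excluded_taxa` (nonliving items, names too
  coarse to place such as "Fish"), together with the links they carried.

**Sectors.** Half-open longitude intervals `[west, east)` proceeding
eastward, validated to tile the circle exactly once; an interval whose
eastern bound lies numerically west of its western bound wraps the
dateline. Half-open boundaries are a convention the data do not dictate;
any consistent choice preserves the partition property, and ours puts a
record exactly on a boundary into the eastern sector.

**Webs.** After mapping taxa to groups (unmapped taxa are dropped and
reported), each distinct (prey group, predator group) pair with at least
one record becomes one edge, directed prey → predator. The edge weight
under a metric is the *unweighted arithmetic mean over records* that report
it. Two alternatives were considered and rejected as defaults: averaging
study-level means (would need a study key more reliable than the data
provide) and sample-size weighting (stomach counts are rarely reported);
the record-level mean is the simplest faithful estimator, and the
coarse-web builder exposes `pool_records = FALSE` for the
average-of-averages variant. Fine (sector) webs are built with
`require_metric = TRUE` on occurrence: links with no occurrence value
anywhere are omitted. Coarse functional-group webs keep such links but flag
them `weight_missing` — the interaction is known to occur even if its
gravimetric contribution is unreported. Self-loops are ordinary edges: a
group (e.g. cephalopods) can prey on itself, and the connectance
denominator counts them possible.

**Statistics.** For a web with S nodes (groups on ≥ 1 retained edge — a
web never contains isolated groups by construction) and L edges:
connectance C = L/S², link density LD = L/S. The out-degree of a group is
the number of predator groups consuming it; its out-degree *strength* under
a metric is the sum of outgoing edge weights, i.e. the weighted total of
predation pressure upon it. Strength tables cover the mid-trophic groups
(zooplankton through demersal fish, per the group scheme's flags), the
layer that channels energy from producers to top predators; comparing which
group tops that ranking across regions is the package's central scientific
output. Sorting ties are broken alphabetically for determinism. Note that
C and LD are reported as computed from S and L; they need not be mutually
consistent with any rounded published pair, and the summary table always
carries S so readers can recompute both.

**Sampling-effort diagnostics.** Are regional differences an artifact of
effort? The species-accumulation curve answers by resampling *source
studies* (not records) without replacement: for a random ordering of the n
sources, count cumulative distinct prey groups after x sources, and average
over `n_perm` orderings. Without-replacement sampling admits an exact
expectation — a group found in n_g of n sources is absent from a random
x-subset with hypergeometric probability C(n−n_g, x)/C(n, x), so

E[count at x] = Σ_g [1 − C(n−n_g, x)/C(n, x)]

— which the package also computes (`accumulation_expectation()`) and the
tests use as the oracle for the Monte-Carlo curve. The mean curve is then
fit by least squares to the negative exponential S(x) = S_max (1 − e^{−kx});
a rapidly saturating curve (large k, asymptote near the observed total)
indicates additional studies would reveal few new prey groups. The
parameterization and fitting procedure follow the accumulation-curve
literature; they are this package's documented choice, with the fit always
on the mean curve rather than per-permutation.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `retained_months` | {11, 12, 1, 2, 3} | month | austral summer; winter sampling is too sparse to compare |
| `latitude_max` | −40 | degrees | conventional northern limit of the study region |
| `drop_missing_month` | TRUE | — | unknown season cannot be certified summer |
| sector bounds | −55/55/145/−115 | degrees | the four major ocean basins |
| `require_metric` | TRUE (fine webs) | — | occurrence is the robust, near-universal metric; links without it are unquantifiable |
| `n_perm` | 200 (pipeline) | orderings | Monte-Carlo error ≪ between-region differences at this size; raise for publication figures |
| fit start | S_max₀ = max(count), k₀ = 1 | — | documented deterministic initialization |

## The synthetic world

The generator emulates the *estimator*, not the ocean. A simulated study
picks one predator and examines n stomachs (uniform in `stomach_range`);
each prey occurs in each stomach independently with configured probability
p, so `fraction_occurrence = occurrences/n` reproduces the binomial
sampling noise of the real estimator. Diet-by-weight fractions are a
Dirichlet-style split (gamma shares with shape ∝ concentration × p) over
the prey that occurred, and each metric is independently censored at a
configured missingness rate, mimicking the database's partial reporting.
Studies carry one summer location and month inside their sector, so the
default world passes refinement untouched.

The default four-sector configuration states the qualitative contrast the
pipeline must resolve: a krill-dominated Atlantic (krill occurrence 0.8
across five predators, alternatives ≤ 0.3) and East Pacific, an Indian
sector led by the other-krill analog, and a silverfish-dominated West
Pacific (silverfish 0.85, krill 0.05). Scales (5–8 sources per sector,
20–60 stomachs per study) are small-study values chosen once to keep test
runtimes in seconds while leaving the dominance signal well above sampling
noise.

What the generator does **not** emulate: real taxonomy and its reporting
inconsistencies, spatial clustering of studies, correlated prey occurrence
within stomachs, multi-predator studies, seasonal or interannual trends,
and digestion-rate biases (gelatinous prey underrepresentation). A green
structure-recovery test therefore establishes that the pipeline correctly
propagates a regional dominance signal from stomach-level sampling to the
strength ranking — not that any real ocean has that structure.

## Numerical choices and degenerate inputs

* Edge means use only non-missing values; a pair with no value under a
  metric has weight `NA`, which strength sums treat as 0 while counting it
  in a coverage note (`n_missing`).
* The hypergeometric expectation is computed on the log scale
  (`lchoose`) so large source counts cannot overflow; impossible absences
  (x > n − n_g) come out exactly 0 via `exp(-Inf)`.
* The negative-exponential fit tries `nls` first; on failure (singular
  gradients, e.g. flat curves) it falls back to Nelder–Mead on
  log-parameters. Fits are *flagged*, never silently returned, when the
  optimizer did not converge or exp(−k) < 1e−8 (the rate has run to the
  boundary: the curve is flat within the model class and S_max is just the
  plateau).
* An empty record set builds an empty web (not an error); an empty web has
  no summary (error, since C and LD are undefined); an empty sector in the
  pipeline yields a `"no data"` summary row rather than a crash.
* All written tables are sorted (edges by prey then predator, strengths by
  rank then name) so identical configuration and inputs give byte-identical
  output trees; the run log records a hash of the scientific settings only,
  not input/output paths.
* Seeds fully determine the simulator and the accumulation permutations;
  both restore the caller's RNG state.

## Limitations

Diet composition alone cannot quantify energy *flux*, only the structure
and relative weighting of pathways. The record-level mean weights studies
by how many records they report, which overweights prolific studies; the
alternatives are exposed but no weighting is defensible without per-study
sample sizes. Strength rankings on webs built from few sources are
sensitive to single studies — that is precisely what the accumulation
diagnostic is for, and results from sectors whose curves have not begun to
saturate should be read as provisional.
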