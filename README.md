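# dietspec

Individual diet specialization analysis for provisioning predators.

Within a population of generalist predators, individuals often differ
consistently in what they hunt: some females of a spider-hunting mud-dauber
wasp provision their nest cells exclusively with one spider genus while
nest-mates a metre away take prey from six families. `dietspec` quantifies
this *individual specialization* from long-format prey records — one row per
prey item with its individual (nest) ID, nest-cell ID (one discrete foraging
bout), taxonomic family, genus, ecological guild and size measurements — and
is aimed at behavioural ecologists working with provisioned-nest or
gut-content style diet data.

## What it computes

For individual diet proportions `p_ij` and population diet `q_j`:

* **PS_i** = `1 − 0.5 · Σ_j |p_ij − q_j|`, each individual's overlap with
  the population diet (0 = extreme specialist, 1 = generalist), and
  **IS** = mean PS_i, with a multinomial Monte Carlo null (each individual
  redraws its n_i items from `q`) and one-tailed `(r+1)/(R+1)` p-value.
* **C_ws**, the clustering index of the diet-overlap network
  (`w_ij = 1 − 0.5 · Σ_k |p_ik − p_jk|`): ≈ 0 means no modularity
  (generalists, or specialists nested within generalists), < 0 discrete
  specialist groups, > 0 idiosyncratic specialists; two-tailed Monte Carlo
  null.
* **NODF**, nestedness based on overlap and decreasing fill (0–100) on the
  binary individual × resource matrix, tested against the
  marginal-probability null model (cell probability = average of row and
  column fill proportions).
* **WIC/TNW**, the exact decomposition of total niche width on a continuous
  prey trait into within- and between-individual components
  (TNW = WIC + BIC), with a permutation null; values near 0 indicate strong
  size specialization.

Supporting modules: field-protocol filtering (drop cells with < 5 intact
prey, sample up to 3 cells per female, exclusion flags for damaged
specimens), a one-way ANOVA and paired t-test, a synthetic-population
generator with controllable specialization / nestedness / modularity /
temporal drift / size structure, and a pipeline with single-bout,
temporal-consistency and single-resource-subset analyses plus a thin CLI
(`inst/cli/dietspec.R`, verbs `simulate` / `run` / `temporal` / `subset`).

## Worked example

```r
library(dietspec)

rec <- generate_population(synthetic_config(seed = 42))  # 30 nests, 935 items
report <- run_single_cell_analysis(rec, analysis_config(replicates = 999,
                                                        seed = 1))
report
```

```
Diet (PSi / IS):
  level psi_min psi_max    is     p
 family   0.515   0.900 0.798 0.001
  genus   0.515   0.900 0.798 0.001
  guild   0.610   0.951 0.861 0.001

Network clustering (Cws):
  level      cws     p
 family -0.01094 0.004
  genus -0.01094 0.004
  guild -0.00608 0.011

Nestedness (NODF):
  level nodf nodf_null     p
 family 65.1      45.7 0.002
  genus 65.1      46.4 0.002
  guild 57.8      50.5 0.138

Niche width (WIC/TNW):
        measure   wic    bic  tnw ratio     p
    body_length 4.184 1.2968 5.48 0.763 0.001
 carapace_width 0.262 0.0682 0.33 0.794 0.001
```

Read: the population is significantly specialized at every classification
level (IS ≈ 0.80 with PS_i spanning 0.52–0.90; p = 0.001 is the floor at
999 replicates), the overlap network shows essentially no modularity
(C_ws ≈ 0) while family-level diets are significantly nested (NODF 65.1 vs
null mean 45.7) — the signature of specialists whose diets are subsets of
generalists' — and individuals also specialize on prey size (WIC/TNW ≈ 0.76,
i.e. 24% of the population's size-niche width lies between individuals).

Temporal consistency on the same population:

```r
run_temporal_analysis(rec, analysis_config(replicates = 999, seed = 1))
#>  level  n mean_single mean_pooled mean_diff     t df       p
#> family 10       0.701       0.764   -0.0626 -2.71  9 0.02415
```

Single-bout PS_i values are compared with three-bout pooled values per
individual by a paired t-test; consistent foragers show no difference or
higher single-bout values.

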