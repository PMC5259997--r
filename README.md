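# bufcomp

Street-network buffer comparison for built-environment exposure assessment.

## The problem

Studies linking the built environment to physical activity first have to decide
what a participant's "neighborhood" is. A common choice is a **network
buffer**: the area reachable within a fixed walking distance (typically 1 km)
of the home along the street network. GIS platforms offer several ways to turn
the reached streets into a polygon, and the choice is not innocent — the
polygon's area can differ by tens of percent between methods, which feeds
directly into every density-type measure computed inside it:

* **sausage** buffer — sweep a disk of radius *t* (the *trim distance*, 25 or
  75 m here) along every reached street segment and dissolve the result. Fully
  reproducible in any GIS.
* **detailed-trimmed** buffer — a service-area polygon wrapped around the
  reached streets and trimmed back to roughly the trim distance; fills slivers
  between nearby parallel streets.
* **detailed** buffer — the untrimmed service-area polygon; wraps whole city
  blocks, so it is the largest of the three.

`bufcomp` implements all three operators on planar street networks, computes
eleven standard built-environment measures (BEMs) inside each buffer — net
residential density, intersection count/density, transit stop count/density,
private recreation count/density, park count/total area, land-use-mix entropy,
and a walkability index (sum of z-scores of residential density, land-use mix
and intersection density) — and then asks the two questions that matter for
study design:

1. **Do the BEM values differ between buffer methods?** (paired *t* tests and
   mean squared error on participant-matched BEM vectors)
2. **Do the BEMs' associations with physical-activity outcomes differ?**
   (linear mixed models `outcome ~ z(BEM) + covariates + (1 | cluster)`;
   standardized coefficients compared by the z test
   `z = (b1 - b2) / sqrt(se1^2 + se2^2)`; tabulation of pairs that differ in
   significance at alpha = 0.05)

Because the original cohort data behind such studies are proprietary, the
package ships a seeded **synthetic-city generator** (pruned street grid,
land-use parcels, transit/recreation points, parks, and a participant cohort
with SES-by-walkability strata, spatially contiguous recruitment clusters and
five self-reported activity outcomes), so the whole pipeline runs and is
tested end-to-end on data it can regenerate from a seed.

The detailed and detailed-trimmed polygon generators of commercial GIS
software are proprietary; `bufcomp` implements documented surrogates by
morphological closing of the sausage polygon (see the methods vignette in
`vignettes/buffer-methods.Rmd`). Buffer geometry is computed on a fine
metric grid from the exact Euclidean distance field of the reached segments,
with vector MultiPolygon outlines traced for export.

## Worked example

```r
library(bufcomp)

city <- generate_city(city_config(), n = 50, n_clusters = 10, seed = 7)
net <- filter_walkable(city$net)
print(net)
#> <street_network> 169 nodes, 278 edges (278 walkable), total 27.8 km

home <- c(city$participants$x[1], city$participants$y[1])
loc <- snap_to_network(home, net)
reach <- reachable_subnetwork(net, loc, cutoff = 1000)
print(reach)
#> <reached_subnetwork> cutoff 1000 m, 244 segments, 23576.2 m reached

bufs <- network_buffers(reach, trim = 25, resolution = 2, participant_id = 1)
for (b in bufs) print(b)
#> <buffer_polygon> method=sausage trim=25 m area=0.9808 km^2 (grid 905x905 @ 2 m)
#> <buffer_polygon> method=detailed_trimmed trim=25 m area=1.2903 km^2 (grid 905x905 @ 2 m)
#> <buffer_polygon> method=detailed trim=25 m area=1.3639 km^2 (grid 905x905 @ 2 m)
```

The same participant's streets produce a 39% larger neighborhood under the
detailed method than under the sausage method — the buffers are nested, so
counts can only grow, while densities shrink with the extra area:

```r
bem <- compute_bem_table(city$participants, net, city$parcels, city$points,
                        city$parks, trims = 25, resolution = 3)
bem[bem$participant_id == 1, c("method", "res_density", "intersection_density",
                               "transit_count", "land_use_mix", "walk_index")]
#>            method res_density intersection_density transit_count land_use_mix walk_index
#>           sausage    14846.62              127.766            18        0.782     -0.387
#>  detailed_trimmed    14846.62               94.456            18        0.782     -0.551
#>          detailed    14829.78               89.181            18        0.782     -0.824
```

Method differences in the *values* are massive, yet the *associations* with an
outcome barely move:

```r
s <- bem[bem$method == "sausage", ]
d <- bem[bem$method == "detailed", ]
d <- d[match(s$participant_id, d$participant_id), ]
paired_ttest(s$intersection_density, d$intersection_density)
#> intersection density, sausage vs detailed: t = 95.0, p = 3.21e-57

f1 <- fit_association(city$participants$walk_transport_days, s$intersection_density,
                      cluster = city$participants$cluster_id, method = "sausage")
f2 <- fit_association(city$participants$walk_transport_days, d$intersection_density,
                      cluster = city$participants$cluster_id, method = "detailed")
compare_coefficients(f1, f2)
#> b1 = -0.44 (se 0.27), b2 = -0.59 (se 0.27)
#> coefficient difference: z = 0.39, p = 0.70, status = only_method_2
```

At this small n = 50 the two coefficients are statistically indistinguishable
(z test p = 0.70) even though one of them happens to cross the alpha = 0.05
line and the other does not — exactly the kind of fragile
"differing-significance" pair the agreement tables count.

## Full pipeline

`run_pipeline()` chains every stage — snap, reach, three buffers, BEM table,
paired BEM tests, mixed-model fits per stratum, coefficient z tests, agreement
tables — and writes tidy CSVs plus a JSON manifest whose config hash, row
counts and outputs are byte-identical across reruns with the same seed:

```r
run_pipeline(system.file("extdata", "demo_config.yaml", package = "bufcomp"))
```

A thin command-line driver wraps the same functions:

```sh
Rscript inst/cli/bufcomp.R synth --n 200 --seed 7 --out city/
Rscript inst/cli/bufcomp.R run --config inst/extdata/demo_config.yaml
```

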