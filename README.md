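# marrowmap

Quantitative 3D mapping of disseminated tumour cells (DTCs) in the
bone-marrow vascular niche.

When breast-cancer cells seed the bone marrow they do not land at random:
imaging studies find them pressed against the vasculature, and in particular
against **type H capillaries** — the CD31^hi^Endomucin^hi^ vessel subtype of
the metaphysis that connects arterioles to sinusoids. Quantifying that
preference from multi-channel 3D microscopy requires a chain of
image-analysis steps that are usually performed interactively in commercial
software. `marrowmap` implements the whole chain as scripted, tested R:

1. **Vessel phenotyping** — classify voxels into arterial
   (CD31^hi^EMCN^–^), type H (CD31^hi^EMCN^hi^) and type L sinusoid
   (CD31^lo^EMCN^lo^) classes from the joint CD31/EMCN intensity
   distribution (automatic three-class Otsu gates, or manual thresholds),
   then extract per-vessel 26-connected components.
2. **Spot detection** — anisotropy-corrected difference-of-Gaussian blob
   detection of 10 µm DTCs in the tumour-reporter channel.
3. **Spatial niche statistics** — exact anisotropic Euclidean distance
   transforms; per-spot distances to bone and each vessel subtype; the
   fraction of spots within 10 µm of each structure; a random-spot null
   model placed uniformly over the admissible marrow (excluding vessels,
   lumens and bone, and only on volumes containing all vessel subtypes);
   two-sided Kolmogorov–Smirnov comparisons of distance distributions and
   unpaired t tests on per-volume means.
4. **Vessel morphometry** — 3D topological-thinning skeletons, vessel
   length, surface area over length, endothelial sprout counts per 100 µm,
   lumen cross-section areas, and intralesional vessel volume fraction.
5. **Synthetic marrow generator** — a hierarchical arteriole → type H →
   type L capsule-geometry phantom with bone, sprouts, rendered
   CD31/EMCN/nuclear/tumour channels and DTCs placed with configurable
   spatial preference, plus exhaustive ground truth. Every measurement
   stage is validated against it.

The key summary statistic is the proximity fraction

    P(structure, t) = #{spots with d(spot, structure) <= t} / #spots,

with `d` the Euclidean distance (µm) from the spot centre to the nearest
structure voxel and `t = 10 µm` by default, compared between observed DTCs
and the random-spot null model.

## Worked example

```r
library(marrowmap)

# a synthetic marrow volume: 256 x 256 x 64 voxels at (1, 1, 2) um,
# 500 DTCs placed with the default perivascular/type-H preference
ds <- generate_dataset(synthetic_config(seed = 42))

# gate vessels and detect spots
gates <- derive_gates(ds$volume)
map   <- classify_voxels(ds$volume, gates)
spots <- detect_spots(ds$volume)

# distances to the gated vasculature and the null model
masks  <- class_map_masks(map)
fields <- list(vessel_any = distance_field(masks$vessel_any))
dtc    <- measure_spot_distances(spots, fields)
rand   <- generate_random_spots(ds$truth$masks, 5000, seed = 1)
null   <- measure_spot_distances(rand, fields)

proximity_fraction(dplyr::bind_rows(dtc, null), "vessel_any", 10)
#> # A tibble: 2 x 8
#>   kind   structure  threshold_um n_volumes n_spots fraction   sem per_volume
#>   <chr>  <chr>             <dbl>     <int>   <int>    <dbl> <dbl> <list>
#> 1 dtc    vessel_any           10         1     500    0.656    NA <tibble>
#> 2 random vessel_any           10         1    5000    0.134    NA <tibble>

tidy(ks_two_sample(dtc$dist_vessel_any, null$dist_vessel_any))
#> # A tibble: 1 x 5
#>   statistic   p.value    n1    n2 method
#>       <dbl>     <dbl> <int> <int> <chr>
#> 1     0.524 2.23e-308   500  5000 two-sided two-sample Kolmogorov-Smirnov ...
```

65.6% of the placed DTCs sit within 10 µm of a vessel versus 13.4% of
random spots — the generator's configured perivascular preference,
recovered by the blind pipeline, with the KS test rejecting equality of the
two distance distributions.

The full pipeline (simulate → classify → spots → distances → nullmodel →
stats → morphometry) can also be driven from a JSON configuration:

```r
run_pipeline(list(simulate = list(dims = c(128, 128, 32))), "out/", seed = 1)
```

or from the shell via the thin CLI wrapper:

```sh
Rscript inst/cli/marrowmap all --config config.json --out out/ --seed 1
```

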