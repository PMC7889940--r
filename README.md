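# benthoshare

Species sharing and community-structure analysis for multi-habitat benthic
macrofaunal surveys.

## What it is for

Coastal surveys frequently sample several habitat types — e.g. an artificial
breakwater wall and natural habitats such as an eelgrass bed, an intertidal
flat, and a subtidal bottom — at several sampling times, with replicated
sites per habitat. benthoshare answers two kinds of questions about such
data:

1. **Species sharing.** Per sampling time, every observed species is
   classified by habitat occupancy: *common* (all H habitats), *endemic*
   (exactly one), or *shifting* (2..H−1 habitats, further split into
   k-habitat users by exact habitat combination). Habitat pairs are compared
   by shared richness and the Jaccard similarity
   `J = S_ab / (S_a + S_b − S_ab)`.
2. **Community inference.** Square-root Bray–Curtis (`Σ|x−y| / Σ(x+y)`) and
   binary Jaccard dissimilarities, NMDS ordination minimizing Kruskal's
   stress-1 (accepted when stress < 0.2), two-way PERMANOVA
   (habitat, time, habitat × time; sequential sums of squares on the
   Gower-centered inner-product matrix; pseudo-F = MS(term)/MS(residual);
   permutation p-values), and pairwise post-hoc PERMANOVAs corrected with
   the Benjamini–Hochberg false discovery rate.

Between the two sits a dominance step: each community's abundant species are
selected by its **effective number of species** (inverse Simpson,
`e = 1/Σp²`), keeping the top `⌈e⌉` abundance ranks plus all species tied at
the cut-off, and aggregating the selection into functional groups (primary
feeding types, common life forms) for functional-composition inference.

A synthetic multi-habitat community generator (lognormal abundances, Poisson
detection, known ground-truth categories) makes the whole pipeline testable
without any field data.

## Worked example

```r
library(benthoshare)

cfg <- synthetic_config(seed = 42)        # 4 habitats x 2 times x 5 sites
ds  <- generate_community(cfg)

sets <- habitat_species_sets(ds$table, ds$meta, "T1")
head(sharing_summary(sets), 4)
#>   habitat category count  pct
#> 1      H1   common     8  7.8
#> 2      H1  endemic    35 34.3
#> 3      H1 shifting    59 57.8
#> 4      H1    total   102 41.1
```

Of the 102 species observed in habitat H1 at time T1, 8 (7.8%) occur in all
four habitats, 35 (34.3%) only in H1, and 59 (57.8%) in an intermediate
number of habitats; H1 holds 41.1% of the species observed at T1. The three
category counts always sum to the habitat's richness (the package asserts
this partition identity on every run).

```r
d   <- bray_curtis(ds$table)              # sqrt-transformed by default
nmds(d, seed = 1)
#> NMDS: 40 points in 2 dims, stress-1 = 0.0498 (accepted, < 0.2; best of 20 starts)

permanova(d, ds$meta, c("habitat", "time"), n_perm = 999, seed = 1)
#> PERMANOVA (sequential SS, 999 permutations, seed 1)
#>            term df     SS     MS        F     R2     p
#>         habitat  3 7.3762 2.4587 444.6457 0.9740 0.001
#>            time  1 0.0025 0.0025   0.4456 0.0003 0.716
#>  habitat x time  3 0.0177 0.0059   1.0698 0.0023 0.384
#>       Residuals 32 0.1769 0.0055       NA 0.0234    NA
#>           Total 39 7.5734     NA       NA 1.0000    NA
```

The ordination is trustworthy (stress 0.05 < 0.2). Habitat explains 97% of
the dissimilarity variation (R² = 0.974) at the smallest attainable p-value
(1/(999+1) = 0.001), as expected for a generator whose endemic pools differ
by construction; time and the interaction explain essentially nothing here.

```r
rep <- selection_coverage_report(select_abundant_all(ds$table), ds$meta)
mean(rep$coverage)
#> [1] 0.824
```

The effective-number selection covers 82% of total abundance on average
across the 40 site communities.

The full chain (reading CSVs, pooling replicates, integrating strata,
classification, dominance, functional composition, ordination, tests, and a
JSON manifest) runs via `run_all(run_config(...))`, or from a shell via
`inst/scripts/benthoshare-cli.R` with subcommands `validate`, `simulate`,
`classify`, `dominance`, `functional`, `dissim`, `nmds`, `permanova`, and
`run-all`.

## Documentation

The methods vignette (`vignettes/habitat-sharing-methods.Rmd`) describes the
model and procedure choices in detail: the per-time classification
semantics, the inverse-Simpson dominance rule and its tie handling, the
majorization NMDS, sequential-SS PERMANOVA, the synthetic generator's
assumptions, and known limitations.
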