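Package: clonalarch
Title: Clone Discrimination, Clonal Diversity and Spatial Clonal
    Architecture from Microsatellite Genotypes
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing the clonal structure of plant populations
    sampled on regular grids and genotyped at co-dominant microsatellite
    (SSR) loci. Collapses samples into multilocus genotypes (MLGs), assesses
    marker resolution with genotype accumulation curves, computes the
    clonal-identity probabilities Pgen and Psex (Parks & Werth), and clusters
    MLGs into multilocus lineages (genets) with a pairwise-distance threshold
    chosen by a gap-based cutoff predictor. Provides per-quadrat clonal
    diversity indices (clonal richness R, Simpson evenness V, Pareto index),
    spatial genet architecture (convex hulls, hull-overlap counts with
    jackknife confidence intervals, clonal identity by distance, stem
    density), two-group and all-pairs comparisons, and a spatially explicit
    simulator of stoloniferous clonal populations with known ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
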