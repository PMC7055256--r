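Package: heteropools
Title: Stochastic Simulation of Heterotic Pool Formation and Reciprocal
    Recurrent Selection in Self-Pollinating Crops
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates hybrid breeding programs in a self-pollinating, doubled
    haploid capable crop under the dominance model of heterosis. Founder
    genomes are drawn from a neutral coalescent model, a quantitative trait is
    built from biallelic quantitative trait nucleotides (QTN) with additive
    effects and incomplete dominance, and the founder set is split into two
    heterotic pools either at random, by SNP genetic distance (PCA), or by a
    genetic algorithm that maximises mean between-pool F1 hybrid performance
    in a full diallel. The package then runs reciprocal recurrent selection on
    true general combining ability over many cycles against a per se selection
    control, and reports trajectories of inbred and hybrid true genetic value
    means and variances together with SNP-diversity (PC1) divergence of the
    pools.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    ggplot2,
    yaml
Config/testthat/edition: 3
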