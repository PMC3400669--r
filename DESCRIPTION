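Package: snpmeta
Title: Meta-Analysis of Case-Control Genetic Association Studies
Version: 1.0.0
Authors@R: person("Analysis", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Pools case-control genotype data for a biallelic SNP across
    studies under four genetic models (two codominant contrasts, dominant,
    recessive). Provides Hardy-Weinberg equilibrium QC of control arms,
    Mantel-Haenszel fixed-effects and DerSimonian-Laird random-effects
    pooling with Cochran's Q driven model selection, subgroup analysis by
    ethnicity and control source, Egger and Begg publication-bias tests,
    funnel-plot data export, leave-one-out sensitivity analysis, a
    multinomial study simulator with known truth, and a command-line
    pipeline. Ships the seven-study EGF +61G/A glioma dataset as a worked
    fixture.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    optparse
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
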