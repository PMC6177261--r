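Package: ancbind
Title: Ancestral Protein Reconstruction and Evolution of DNA-Binding Specificity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying how transcription-factor DNA-binding function
    evolves, built around three quantitative workflows: maximum-likelihood
    ancestral sequence reconstruction of protein domains under the LG
    substitution model with discrete-gamma rate variation (marginal
    posteriors, AltAll robustness variants, diagnostic-substitution
    accounting); protein-binding-microarray specificity analysis (rank-based
    k-mer E-scores, specificity correlations, Manhattan-distance clustering,
    position-specific binding-energy model regression and energy logos); and
    equilibrium and kinetic binding-model fitting (quadratic titration
    isotherms, 1:1 surface-plasmon-resonance association kinetics, residence
    times and preference comparisons). Synthetic-data generators for all
    input kinds make the full pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
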