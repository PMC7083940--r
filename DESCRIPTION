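Package: chromarch
Title: Bacterial Chromosome Architecture from Hi-C Contact Maps and
    Single-Molecule Localization Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for bacterial chromosome organization built
    around two data streams. For chromosome conformation capture (3C/Hi-C):
    classification of restriction-fragment read pairs into informative and
    non-informative (self-circle, uncut) events, binning into contact
    matrices, sequential component normalization (SCN), log2 ratio maps,
    stratum-adjusted correlation (SCC) map comparison with hierarchical
    strain grouping, directional-index domain-boundary detection on
    correlation matrices, and quantification of the replichore-cohesion
    secondary diagonal anchored at a parS-like locus. For photoactivated
    localization microscopy (PALM/SMLM): photon and PSF-width event
    filtering, blink grouping across frames, cell-mask assignment, OPTICS
    reachability ordering, nested macro-/subcluster extraction by
    reachability thresholds, per-cell cluster statistics and rank-based
    condition comparison. A parametric generator produces ground-truthed
    synthetic contact pairs (circular genome, power-law distance decay,
    chromatin interaction domains, arm-cohesion band, ori cross signal) and
    localization tables (nested Gaussian clusters, blinking, background),
    so every stage is testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    ape
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
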