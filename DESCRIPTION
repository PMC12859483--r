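Package: nucploidy
Title: Nuclear Ploidy Inference from Segmented Fluorescence Images
Version: 0.1.0
Authors@R: person("nucploidy", "developers", role = c("aut", "cre"),
    email = "nucploidy@example.org")
Description: Infers per-nucleus ploidy classes from object-level feature
    tables exported by image segmentation tools. Nuclear intensity and
    size features are log2-scaled and modelled as Gaussian mixtures fitted
    by expectation-maximization; component counts and covariance families
    are selected by AIC/BIC; classification uncertainty is quantified from
    posterior probabilities; and segmentation label images are recolored
    into spatial ploidy maps. Includes record-level quality filters,
    internal-standard (haploid reference) normalization with QC gates, a
    two-sample Cramer-von Mises comparison against flow-cytometry
    distributions, and a synthetic-data generator with doubling-cluster
    ground truth.
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
    jsonlite,
    yaml,
    png,
    digest
Suggests:
    rhdf5,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
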