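Package: agequant
Title: Quantitative Analysis Pipelines for Cellular Ageing Assays
Version: 0.1.0
Authors@R:
    person("agequant", "developers", email = "agequant@example.org",
           role = c("aut", "cre"))
Description: Statistical pipelines for the quantitative assays used in
    microbial chronological-ageing studies: Poisson maximum-likelihood
    estimation of colony-forming units from serial-dilution plating and
    relative-viability lifespan curves; parametric growth-curve fitting
    (logistic, Gompertz, Richards) with lag, rate and capacity comparison
    by ANOVA with Tukey or Dunnett-style post-hoc tests; synthetic genetic
    array (SGA) colony-size filtering, spatial normalization and genetic
    interaction scoring; polysome-profile quantification (region
    segmentation, AUC integration, polysome:monosome ratio, ribosome
    content) and per-fraction qPCR mRNA distributions; presence-filtered
    moderated-t enrichment calling for RNA-pulldown proteomics; and
    delta-delta-Ct relative quantification. Seeded generators simulate
    every input type with recorded ground truth so each stage is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
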