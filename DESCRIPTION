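Package: aortadissect
Title: Multi-Modal Characterization of Acute Aortic Dissection Tissue
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for ex vivo characterization of acute aortic
    dissection tissue by ambient mass spectrometry (REIMS/iKnife), quantitative
    histology and non-parametric statistics. Provides burn-event detection and
    pseudo-Gaussian total-ion-current processing of per-scan spectra, weighted
    RGB stain indices for collagen and elastin quantification on VVG and
    Picrosirius Red sections, PLS-DA classification of tissue types with VIP
    feature refinement and repeated split evaluation, Ward hierarchical
    clustering with multiscale-bootstrap approximately-unbiased cluster
    support, and Kruskal-Wallis/Dunn/Mann-Whitney testing. A synthetic-data
    generator emulates the three tissue regions (false lumen, dissection flap,
    true lumen) and latent false-lumen sub-structure with known ground truth so
    the whole workflow is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    EBImage,
    png,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    pROC,
    withr
Config/testthat/edition: 3
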