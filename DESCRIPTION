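Package: embryolin
Title: Lineage and X-Chromosome Dosage Dynamics in Preimplantation
    Single-Cell Transcriptomes
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Staged analysis of single-cell RNA-seq data from preimplantation
    embryos: quality control and sex classification, spike-in-calibrated
    selection of highly variable genes, principal-curve pseudo-time,
    hierarchical lineage classification (trophectoderm vs inner cell mass,
    epiblast vs primitive endoderm, polar vs mural trophectoderm),
    Stouffer-combined lineage-specific gene rankings, diffusion-map
    segregation scoring, X-chromosome dosage-compensation statistics, and
    allele-resolved classification of biallelic versus monoallelic
    expression that distinguishes chromosome-wide expression dampening from
    conventional X inactivation. Includes an allele-resolved synthetic-data
    generator with ground truth so that every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    cluster,
    e1071,
    Rtsne,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    vcfR,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
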