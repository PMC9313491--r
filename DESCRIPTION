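Package: pvnscreen
Title: Ligand-Receptor Prioritization for Perivascular-Niche Tumor Models from scRNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies candidate ligand-receptor interactions between glioma
    stem cells and their perivascular-niche neighbours (endothelial cells and
    astrocytes) from monoculture versus triculture single-cell RNA-seq count
    matrices. Implements quality control, log-normalization, highly variable
    gene selection, shared-nearest-neighbor modularity clustering, marker-based
    cell-type annotation, expression-based chromosome-arm copy-number scoring,
    Wilcoxon rank-sum differential expression with Benjamini-Hochberg FDR
    control, and a four-stage receptor prioritization cascade (receptor
    universe intersection, secreted-ligand expression filter, hypergeometric
    pathway enrichment, fold-change ranking) with eigengene summarization and
    per-patient receptor evidence tiering. A negative-binomial simulator
    generates monoculture/triculture experiments with planted cell types,
    arm-level copy-number events and ligand-receptor effects so the whole
    pipeline can be validated against known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    irlba,
    jsonlite,
    stats,
    utils,
    methods
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
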