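Package: ctDNAsig
Title: Copy-Number Signature Scoring and Subtyping from Shallow-WGS cfDNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computes multi-feature DNA copy-number signature scores (such as
    the RB-LOH proliferation signature) from shallow whole-genome sequencing
    of plasma cell-free DNA. Reads ichorCNA and generic SEG segmentation
    output, maps segments to gene-level values, averages genes into a fixed
    canonical segment scheme, applies tumor-fraction/ploidy adjustment, and
    scores samples against published signature weight tables. Provides
    consensus clustering with a nearest-centroid subtype classifier,
    SAM-style permutation differential tests, survival and clinical
    association statistics, and a synthetic cfDNA cohort generator for
    end-to-end validation (dilution series, coverage downsampling, signature
    ablation).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
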