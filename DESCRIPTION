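Package: qmpguilds
Title: Quantitative Microbiome Profiling, Compositional-Artifact Detection,
    and Co-Abundance Guilds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantitative microbiome profiling (QMP) of murine
    gut communities: 16S rRNA gene copy-number correction of genus-level
    read tables, scaling by flow-cytometry total cell counts to absolute
    abundances per gram and per intestinal compartment, rarefaction and
    alpha/beta diversity with PERMANOVA, paired absolute/relative log2
    fold-change reports that flag compositional artifacts, Spearman/Ward
    co-abundance guild clustering with silhouette-based cluster-number
    selection, stable-isotope (13C threonine) mucus-secretion flux and
    qPCR delta-delta-Ct expression analysis, and an assumption-gated
    two-way ANOVA workflow. Includes a synthetic-study generator with
    known ground truth emulating a fiber-deprivation diet experiment, so
    the full pipeline is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    ape,
    cluster,
    car,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
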