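Package: daeprobe
Title: Gene-Set Inference from Transcriptome Compendia with Denoising
    Autoencoder Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains ensembles of tied-weight denoising autoencoders of
    arbitrary depth on bacterial expression compendia (logTPM matrices),
    probes every bottleneck node through the decoder to obtain per-gene
    response signatures, and associates nodes with curated gene sets
    (KEGG pathways, GO processes, regulons, operons) via hypergeometric
    enrichment with ensemble-wide error control and preranked GSEA.
    Includes the gene-set response statistic phi linking gene sets to
    experimental conditions, discovery of condition-specific nodes and
    de novo gene sets, a per-gene permutation control, and a synthetic
    compendium generator with planted co-regulated modules for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    fgsea,
    optparse,
    yaml
Config/testthat/edition: 3
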