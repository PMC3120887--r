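Package: mirseqpipe
Title: Indexed Small RNA-Seq Workflow for Brain-Region miRNA Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of indexed small RNA sequencing
    experiments for microRNA expression profiling, with a matched
    microarray arm. Provides a synthetic-data generator for 36-nt indexed
    reads (mature miRNA insert flanked by a 6-nt index and a 3' adapter),
    a demultiplex/trim/filter preprocessing cascade with per-stage read
    accounting, mismatch-tolerant alignment to a mature miRNA reference,
    negative-binomial exact-test differential expression with common
    dispersion, empirical-Bayes moderated-t for array signals, weighted
    ordered-list rank similarity with a permutation null, a consensus
    miRNA target-prediction filter based on a Poisson multiple-binding-site
    statistic, and seed-family / genomic-cluster annotation of results.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    limma,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
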