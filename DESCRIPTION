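Package: bettapop
Title: Population-Genomic Toolkit for Domestication Analyses in Betta Fish
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable implementations of the population-genomic analyses used to
    study the domestication of Siamese fighting fish (Betta splendens):
    quartet site-pattern statistics (Patterson's D, f4, windowed fdM) with
    robust segmentation and introgression-tract calling; neighbor-joining
    trees with block bootstrap and tract-level ancestry assignment;
    haplotype-homozygosity selection scans (H, G12/G2-G1, Tajima's D) with an
    LD-clumped permutation test for group differences; unfolded site-frequency
    spectra and composite-likelihood inference of a single instantaneous
    bottleneck; genotype quality filtering with trio Mendelian-error ROC
    curves and coverage-based region masks; sex-determination penetrance
    statistics; and HSV-based color phenotyping. A coalescent-backed
    synthetic-data generator produces panels, pedigrees, and planted signals
    so every stage can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    ape,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
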