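Package: meiomap
Title: Recombination Landscapes and Bin Maps for Doubled-Haploid Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of meiotic recombination in doubled-haploid (DH)
    populations genotyped with SNP arrays. Provides genotype quality control,
    recombination-bin segmentation, crossover calling, sliding-window cM/Mb
    landscapes with hot-region detection, crossover-to-gene context analysis,
    homoeologous-segment detection for allopolyploid genomes, Kosambi bin-map
    construction, and Haley-Knott interval mapping of quantitative trait loci.
    Includes a seeded meiosis simulator (gamma-renewal crossover interference,
    configurable genotyping noise) that generates populations with known ground
    truth for validating every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
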