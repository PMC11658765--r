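Package: exoload
Title: Pest and Microbe Load Phenotypes from Non-Target Sequencing Reads
Version: 0.1.0
Authors@R: person("exoload", "maintainers", email = "maintainers@exoload.org",
    role = c("aut", "cre"))
Description: Turns the reads that do not map to a host reference genome
    ("exogenous reads") into quantitative pest and microbe load phenotypes
    and analyses them genetically and epigenetically. Provides read-pair
    classification into target / ambiguous / exogenous classes with an
    ambiguous-read blacklist for variant calling, competitive pseudo-reference
    species assignment, depth-corrected load normalisation, REML kinship
    heritability, linear mixed model genome-wide and epigenome-wide
    association, a priori candidate enrichment with a genome-rotation
    permutation null, a simplified group-contrast caller for differentially
    methylated regions, and a synthetic-data module that generates complete
    toy datasets (genomes, alignments, genotypes, loads, methylation) with
    recorded ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
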