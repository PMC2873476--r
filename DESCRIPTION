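Package: amplihap
Title: Haplotyping and Copy-Number Estimation from Deep Amplicon Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for simultaneous haplotyping and copy-number (CN)
    estimation of multicopy loci (such as the human beta-defensin cluster at
    8p23.1) from deep amplicon sequencing reads. Reads are assigned to
    amplicon references by semi-global alignment, alleles are extracted at
    multisite variation (MSV) positions to yield per-read haplotype calls
    (HCs), low-fraction calls are filtered as PCR-chimera and sequencing
    artifacts, minimal copy numbers are inferred from integer-ratio fitting
    of HC counts, per-amplicon estimates are harmonized across a sample, and
    directional partial haplotypes are collapsed into complete amplicon
    haplotypes by a minimum-support transportation matching. A pyrosequencing
    style read simulator with PCR template-switch chimeras, homopolymer
    indels, directional skew and read truncation makes the whole pipeline
    testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    methods,
    stats,
    utils,
    yaml
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
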