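Package: mapas
Title: Nucleotide-Resolution RNA-Binding-Site Discovery from Cross-Link-Induced Deletions
Version: 0.1.0
Authors@R:
    person("CRAC", "Tools", email = "crac-tools@example.org", role = c("aut", "cre"))
Description: Calls RNA-binding-protein binding sites from CRAC/CLIP read
    alignments at nucleotide resolution using cross-link-induced deletions.
    Candidate cross-link positions are localized from replicate deletion
    pileups, penalized against a control library, assigned empirical
    coverage and deletion p-values combined by Fisher's method, and scored
    with a 7-nt seed positional weight matrix whose significance threshold
    is the 95th percentile of the exhaustive heptamer score distribution.
    Downstream utilities annotate sites to transcript regions and biotypes,
    compute affinity-weighted sequence logos, per-RNA interaction weights,
    transcript metaprofiles, polyadenylation-site usage, polysome-profiling
    translation-efficiency statistics with target-set enrichment, and
    calibration-curve molecule stoichiometry. A deterministic synthetic-data
    generator produces aligned reads, annotation, expression and count
    matrices with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
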