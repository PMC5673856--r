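Package: haplodelim
Title: Gene-Tree Species-Delimitation Statistics for Haplogroups
Version: 0.1.0
Authors@R: person("haplodelim", "maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Tests a putative taxonomy against a single-locus gene tree.
    Given a support-annotated rooted phylogeny, a tip-to-haplogroup
    assignment table, and a DNA alignment, computes per-haplogroup
    species-delimitation statistics (Intra, Inter, Intra/Inter, P ID strict
    and liberal with Monte-Carlo confidence intervals, Av MRCA-tips),
    monophyly assessments, grouped uncorrected-p and Kimura 2-parameter
    distance matrices with pairwise deletion, GTR-corrected distances and
    substitution-saturation profiles. Includes a multispecies-coalescent
    simulator with transition-biased sequence evolution for generating
    benchmark datasets with known species boundaries, and a command-line
    pipeline producing plain-text reports.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
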