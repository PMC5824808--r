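Package: cryptclock
Title: Clonal Evolution of Barrett's Esophagus at Crypt and Biopsy Resolution
Version: 0.1.0
Authors@R:
    person("Crypt", "Clock Developers", email = "cryptclock@example.org",
           role = c("aut", "cre"))
Description: Tools to reconstruct the somatic evolution of Barrett's esophagus
    segments from allele-specific copy-number profiles of single crypts and
    whole-biopsy epithelium. Allele-specific segment boundaries are turned into
    binary breakpoint markers, maximum-parsimony phylogenies and patristic
    diversity statistics are computed per patient, and a Bayesian model with a
    per-allele-copy birth-death copy-number clock, a constant-size coalescent
    tree prior and an optional random local clock estimates somatic
    copy-number alteration rates, segment onset ages, effective population
    sizes and branch-local rate shifts. Genome-doubling calls, spatial
    gradient statistics relative to the gastro-esophageal junction and
    PCA-based clonal maps complete the pipeline. A ground-truthed synthetic
    cohort generator makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn
Config/testthat/edition: 3
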