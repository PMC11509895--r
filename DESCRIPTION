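Package: pbflex
Title: Protein Blocks Flexibility Analysis of Conformational Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Comparative conformational-flexibility analysis of protein
    structural ensembles, designed for nanobody (VHH) disulfide-bridge
    studies but applicable to any multi-model ensemble.  Assigns each
    residue of every frame to one of the 16 Protein Blocks (a structural
    alphabet over backbone phi/psi dihedrals), computes the per-position
    equivalent number of states Neq, the between-system profile distances
    Delta-PB and Delta-Neq, and the coordinate-space measures RMSD and
    RMSF (Kabsch superposition on C-alpha atoms).  Includes in-silico
    cysteine truncation mutants (Cys to Ala/Gly), CDR/framework region
    annotation, logo-ready frequency matrices, and a synthetic-ensemble
    generator with known conformer statistics for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
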