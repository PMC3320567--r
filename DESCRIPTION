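Package: mdcontacts
Title: Interaction Fingerprinting of Protein-Peptide Molecular Dynamics Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tidy analysis of molecular-dynamics trajectories of SH2
    domain/phosphopeptide complexes. Reads multi-model PDB files (one MODEL
    per frame) or plain per-frame coordinate tables, detects hydrogen bonds,
    salt bridges and hydrophobic contacts per frame with geometric cutoffs,
    aggregates atomic events into residue-pair occupancies, applies an
    occupancy-based stability filter, classifies interactions as
    main-chain/side-chain/hydrophobic-only, maps phosphopeptide residues to
    pY-relative interface regions, and renders interaction tables and region
    summaries. Includes a synthetic-trajectory generator with planted,
    schedule-controlled contacts for ground-truth validation, and small
    quantification helpers for reporter-assay and immunoblot data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    bio3d,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
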