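Package: hintmd
Title: Hydropathic Interaction Scoring and Trajectory Flexibility Analysis
    for Point-Mutated Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: In-silico single-point mutagenesis of protein structures by
    deterministic side-chain truncation, intramolecular hydropathic
    (HINT-style, logP-based) interaction scoring with semi-essential
    hydrogen augmentation and Shrake-Rupley solvent accessibility, and
    molecular-dynamics trajectory observables (RMSD, per-residue RMSF,
    radius of gyration, SASA time series, helix-barrel interface distance,
    essential-dynamics PCA).  Wild-type versus mutant flexibility
    differencing with conformational-epitope annotation, a synthetic
    structure/trajectory generator with known ground truth, and a pipeline
    driver.  Developed around the lipocalin allergen Mus m 1 (mouse major
    urinary protein) and its stability mutants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
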