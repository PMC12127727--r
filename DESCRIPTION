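Package: oligofinger
Title: Contact-Fingerprint Analysis of Homo-Oligomer Assembly Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for inferring the architecture of self-assembling protein
    homo-oligomers from multi-chain conformational ensembles. Frames are
    encoded as chain-permutation-invariant binary inter-chain contact
    fingerprints, reduced by principal component analysis (ccPCA) and
    clustered into structural states; the dominant state is summarised as a
    contact-persistence network, classified into interface classes with
    multiplicities, and checked for assembly order and point-group-like
    chain-permutation symmetry. Forward models of chemical-crosslinking band
    ladders and size-exclusion-chromatography stoichiometric factors connect
    the structural model to its wet-lab readouts. A coarse-grained generator
    of synthetic tetramer assembly ensembles, built around the BCL11B ZF0
    zinc-finger domain (residues 54-82), makes the whole pipeline testable
    without external trajectory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    cluster,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
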