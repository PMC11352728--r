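Package: chiralcat
Title: DFT-Derived Descriptors and Domain-Transfer Benchmarking for
    Chiral Rhodium Hydrogenation Catalysts
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Automated featurization of chiral-ligand rhodium precatalysts
    ([Rh(L)(NBD)]+ complexes) and their olefin substrates for machine
    learning on asymmetric hydrogenation outcomes.  Builds bonding graphs
    from XYZ geometries, partitions complexes into metal, ligand and
    auxiliary diene, and computes steric (percent buried volume, exact
    cone angle, sterimol), geometric (bite angle, donor distances, diene
    dihedral) and electronic (HOMO-LUMO gap, NBO charges, lone-pair
    occupancies ingested from sidecar files) descriptors into a fixed
    34-feature catalyst schema plus an 18-feature olefin steric
    fingerprint.  Ships a random-forest harness for in-domain,
    partially and fully out-of-domain reaction-outcome prediction
    (conversion classification, enantioselectivity regression via the
    Gibbs ee-to-ddG transform), alternative ligand encodings (circular
    fingerprints, one-hot, random-vector controls), PCA chemical-space
    maps, and a synthetic-data module that emulates a 192-ligand by
    5-substrate high-throughput screen with realistic correlation
    structure so the whole pipeline is testable without quantum-chemistry
    runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
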