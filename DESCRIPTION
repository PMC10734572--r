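Package: rgmine
Title: Resistance-Gene-Guided Mining of Biosynthetic Gene Clusters from
    Gene Coordinate Tables
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects candidate self-resistant secondary-metabolite
    biosynthetic gene clusters in annotated fungal genomes by joining a
    table of putative resistance-gene homologs against a table of core
    biosynthetic backbone genes (NRPS, PKS, terpene synthase/cyclase,
    DMATS). A pair is reported when both genes lie on the same scaffold
    of the same genome, their interval centers are within a user-chosen
    cutoff, the genes do not overlap, the resistance gene is not
    oversized, and (by default) the genome carries at least two
    resistance-gene copies. Includes a literal all-pairs reference
    implementation kept as a testing oracle, a seeded synthetic
    genome-annotation generator with construction-time ground truth,
    distance histograms, cutoff sweeps, per-genome summaries, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'gene-tables.R'
    'mine.R'
    'fixtures.R'
    'reports.R'
    'cli.R'
    'rgmine-package.R'
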