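Package: OrthoQuery
Title: Query Protein Ortholog Groups, Percent Identity Heatmaps and
    Neighbor-Joining Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A self-contained workflow for exploring putative protein
    orthologs across many species. Given a directory of proteome FASTA
    files and an ortholog-group table (parsed from a SonicParanoid-style
    flat file, or inferred at small scale by a built-in reciprocal-best-hit
    stage), OrthoQuery locates the group(s) containing one or more query
    proteins, aligns the group members with a progressive profile
    aligner, computes a percent identity matrix, builds a midpoint-rooted
    neighbor-joining tree, and writes tabular, FASTA, Newick and heatmap
    artifacts. No external alignment or orthology binaries are required.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    Biostrings,
    S4Vectors,
    ape,
    igraph,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    pheatmap,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'seqio.R'
    'align.R'
    'phylo.R'
    'groups.R'
    'fixtures.R'
    'infer.R'
    'pipeline.R'
    'report.R'
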