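Package: chromoglyph
Title: Annotated Chromosome Ideograms from Tab-Delimited Genomic Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Renders chromosome ideograms annotated with genomic data supplied
    in a single tab-delimited file: phenotype glyphs connected by lines to
    base-pair positions, transverse line and region plots (GWAS, PheWAS, array
    coverage, CNV-style inputs), ancestry shapes, zoomed single-chromosome
    views, and cytogenetic-band shading. Glyphs are placed by one of three
    one-dimensional non-overlap spacing algorithms and colored by one of five
    categorical palette methods. Output is PNG (with physical-resolution
    metadata, up to 1200 DPI) or SVG, from the R API or a command-line script.
    Includes a seeded synthetic study generator for fully offline examples and
    tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grid,
    grDevices,
    stats,
    png
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
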