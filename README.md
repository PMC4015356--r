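# chromoglyph

Annotated chromosome ideograms from a single tab-delimited file.

Results that live at genomic coordinates — GWAS and PheWAS associations,
genotyping-array coverage, imputation density, copy-number variant calls —
are easiest to survey drawn across a karyogram. chromoglyph renders such
data as chromosomal ideograms: transverse lines or filled regions mark
base-pair positions and regions on each chromosome body, colored glyphs
connected by leader lines identify the phenotype associated with each
locus, distinct shapes mark up to three ancestry groups, short text notes
annotate loci, and an optional cytogenetic-band layer shades G-bands in
greys, heterochromatin in dark blue, and ribosomal stalks in light blue.
Output is PNG (300 DPI, or 1200 DPI publication-ready) or SVG.

## The input format

One tab-delimited file with a header. Recognized columns (case-insensitive):

| column | required | meaning |
|---|---|---|
| `CHR` | yes | chromosome (1–22, X, Y; `chr` prefix accepted) |
| `POS` | yes | 1-based base-pair position, or region start |
| `END` | no | region end (draws a filled band instead of a line) |
| `PHENOTYPE` | no | phenotype label, drawn as a colored glyph |
| `NOTE` / `ANNOTATION` | no | text shown beside the chromosome (10 chars max) |
| `ETHNICITY` / `ANCESTRY` | no | up to three groups get distinct shapes |
| `GROUP` | no | phenotypes sharing a group share a color gradient |
| `POSCOLOR` | no | transverse-line color code, integer 0–7 |

## The core layout problem

Glyphs anchored at nearby loci collide. Placement is 1-D non-overlapping
label layout along each chromosome track: given anchor coordinates
*a₁ ≤ … ≤ aₙ* and glyph diameter *d*, find *y₁ ≤ … ≤ yₙ* with
*yᵢ₊₁ − yᵢ ≥ d*. Three algorithms are provided:

* **standard** — greedy minimum push-down sweep (default);
* **equal** — *yᵢ = i·extent/(n+1)*, genomic order kept;
* **proximity** — the exact minimizer of Σ(yᵢ − aᵢ)², computed by
  iterative cluster merging (pool-adjacent-violators in gap-transformed
  coordinates).

Phenotype colors come from one of five methods (fixed 10-color list,
even-hue generator at 360/n° separation, seeded draw from the 216 web-safe
colors, seeded uniform random, or per-group gradients), all deterministic
under one seed (default 7).

## Worked example

```r
library(chromoglyph)

genome <- builtin_genome()
#> <genome_assembly> 24 chromosomes, 307 cytogenetic bands

spec <- synthetic_study_spec(n_records = 64,
  phenotype_labels = c("rheumatoid arthritis", "Crohns disease",
                       "blood pressure", "Alzheimers disease",
                       "breast cancer", "pancreatic cancer",
                       "colorectal cancer", "prostate cancer"),
  seed = 7)
tsv <- generate_synthetic_input(spec, genome)
cat(head(tsv, 3), sep = "\n")
#> CHR	POS	PHENOTYPE
#> 10	32823392	rheumatoid arthritis
#> 19	43841409	Crohns disease

parsed <- parse_input(tsv)
#> <parsed_input> 64 records, columns: CHR, PHENOTYPE, POS

img <- render_ideogram(parsed, genome,
                       plot_config(title = "GWAS catalog style plot",
                                   outline_circle = TRUE),
                       file = "gwas_style.png")
img
#> <rendered_image> png, 1600 x 1064 px, 300 DPI, 127171 bytes
```

The 24 chromosome tracks are drawn in two rows on one shared
pixels-per-base-pair scale; each of the 64 records contributes one
transverse line and one outlined glyph colored by the fixed list palette
(8 phenotypes ≤ 10, so the list method is chosen automatically); the legend
across the bottom has 8 entries in first-appearance order.

The same pipeline runs from the shell via the bundled script
(`inst/scripts/chromoglyph`):

```sh
chromoglyph -i input.tsv -o plot.png -t "My study" -O -z   # 1200 DPI PNG
chromoglyph -i input.tsv -o region.svg -f svg -Z 6:25000000-35000000
chromoglyph -h                                             # full flag list
```

Exit status is 0 on success, 1 on data errors (with the offending line
number), 2 on usage errors.

## Notes on the bundled genome

Chromosome lengths are the exact GRCh37/hg19 reference lengths. The
band-level layout is a generated schematic (the bundled file is named
`cytoBand_hg19_synthetic.txt` to make that unmistakable): centromere
positions, heterochromatin blocks, and acrocentric stalk regions are
placed per the reference karyotype, but individual Giemsa band boundaries
are synthetic. Any real UCSC-format cytoBand file can be used instead via
`read_cytoband()` and `build_genome()`.
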