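---
title: "Rendering annotated chromosome ideograms with chromoglyph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rendering annotated chromosome ideograms with chromoglyph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromoglyph)
```

## The problem

A chromosomal ideogram — an idealized drawing of each chromosome with its
centromere and banding pattern — is a natural canvas for any result that
lives at a genomic coordinate: genome-wide association hits across many
phenotypes, phenome-wide associations at single loci, genotyping-array
coverage, imputation density, or copy-number variant calls. chromoglyph
renders such data from a single tab-delimited file: transverse lines or
filled regions mark positions on the chromosome body, colored glyphs
connected by leader lines identify the phenotype at each locus, shapes
distinguish up to three ancestry groups, and short text notes annotate
individual loci. Output is PNG (with physical-resolution metadata, 300 or
1200 DPI) or SVG.

## Coordinate model

Internally the genome model follows the UCSC convention: cytogenetic band
intervals are 0-based and half-open, which is what a cytoBand file encodes.
User-facing positions in the annotation file are 1-based and inclusive, the
convention biologists use for point positions, and are converted on ingest.
The vertical pixel map is affine per chromosome track: base 1 (or the zoom
start) maps to the track top, the chromosome length (or zoom end) to the
track bottom, and all chromosomes of a whole-genome plot share one
pixels-per-base-pair scale so lengths are visually comparable.

The bundled human genome uses the exact GRCh37/hg19 reference chromosome
lengths. Its band-level layout is a generated schematic rather than the UCSC
database dump (the file is named `cytoBand_hg19_synthetic.txt` to make this
unmistakable): centromeres sit at the reference centromere positions, the
large heterochromatin blocks (1q12, 9q12, 16q11.2, distal Yq, and the
acrocentric p-arms of 13, 14, 15, 21, and 22) are marked `gvar`, the five
ribosomal-RNA stalk regions sit on those same acrocentric p-arms, and the
remaining arm territory alternates R-bands (`gneg`, drawn white) with
G-bands (`gpos25`–`gpos100`, drawn in greys of increasing darkness).
Heterochromatin is drawn dark blue and stalks light blue. Any real
UCSC-format cytoBand file can be substituted via `read_cytoband()` +
`build_genome()`; non-canonical contigs (chrM, random/alt) are skipped
because real dumps contain them.

## Glyph spacing

Glyphs anchored at exactly the same mapped pixel form a *run* and fan
horizontally into lanes. Three algorithms place runs vertically, and all
three preserve genomic order:

* **standard** (default): a greedy top-to-bottom sweep pushes each run down
  the minimum needed to clear the previous run by one glyph diameter; if the
  last run would leave the track, a second bottom-up pass pushes runs back
  up. This is cheap and leaves isolated glyphs exactly at their loci.
* **equal**: the n runs are placed at intervals of extent/(n+1) from the
  track top, ignoring anchors except for their order.
* **proximity**: the order-preserving placement with pairwise gaps of at
  least one diameter that minimizes total squared displacement from the
  anchors. It is computed by iterative cluster merging — neighbors closer
  than the gap merge into a cluster centered on the mean of member anchors
  and spread at minimum separation, to a fixed point — which in the
  gap-transformed coordinate `z_i = y_i - (i-1)d` is exactly the
  pool-adjacent-violators solution of an isotonic regression, so the result
  is the true quadratic-program optimum (the test suite checks this against
  an exhaustive active-set enumeration on small instances). Unlike the other
  two methods, co-located glyphs are not fanned into lanes here: they split
  symmetrically around their shared anchor, which is what minimizes
  displacement.

When a track cannot hold all runs at the required separation — more than
(extent/diameter + 1) runs — standard and proximity fall back to equal
spacing with a warning rather than failing: a plotting tool should always
produce a plot. Text notes occupy spacing slots exactly like glyphs, so
annotations never collide with circles.

## Color and shape assignment

Five methods map phenotypes (in first-appearance order, which also fixes the
legend order) to colors:

* **list** — the first n of a fixed, documented 10-color palette chosen for
  colorblind-aware separation (`LIST_PALETTE`); limited to ten phenotypes,
  and asking for more is an explicit error pointing at the generator method.
* **generator** — hues evenly spaced at 360/n degrees at fixed saturation
  0.78 and value 0.90, the maximum achievable minimum hue separation.
* **web** — a seeded shuffle of the 216 web-safe colors (all channels
  multiples of 51), taken without replacement so the mapping stays
  injective up to n = 216.
* **random** — seeded independent uniform RGB draws, with no separation
  guarantee.
* **group** — each GROUP value receives a base hue from the generator
  palette over the number of groups; members of a group share that hue with
  strictly increasing lightness, so related phenotypes read as a gradient.

One seed (default 7) feeds all stochastic choices; list, generator, and
group ignore it entirely, so only web and random respond to `-r`.

Ancestry groups map to shapes circle, square, triangle in first-appearance
order; every group beyond the third renders as a circle, so at most three
distinct shapes ever appear. Transverse-line colors come from the fixed
POSCOLOR table (0 black through 7 magenta); the 0–7 bound is enforced at
parse time.

## Rendering choices

The scene is built as a plain data frame of drawing primitives before any
device is touched, which makes every visual rule unit-testable by counting
commands. The PNG backend replays the scene through grid on the cairo
device; the SVG backend serializes the same primitives directly to SVG 1.1
text. Both are byte-deterministic for fixed inputs and seed.

Numerical constants: default 300 DPI with high-res at 1200 (geometry is
computed in 300-DPI-nominal pixels and scaled, so layout is
resolution-independent); transverse lines are 1.6 px wide, halved by the
thin-lines flag; the transparent-lines flag sets line alpha to 0.4, so two
stacked marks composite to 0.64 coverage and dense regions read darker;
chromosome outlines are 1.4 px, doubled by the thick-boundary flag; glyph
diameter is proportional to the chromosome bar width (14 px in whole-genome
plots, 30 px in single-chromosome views), halved by small-circle; big-font
scales legend text by 1.45 and deliberately leaves glyphs unchanged.
Chromosome arms are drawn as rounded capsules meeting at a centromere
waist. Region marks (rows with END) layer in input-file order, so later
rows plot on top — useful when overlaying two CNV callsets in two colors.

Degenerate inputs: an empty record set renders bare ideograms; records
outside a zoom span are dropped with a warning rather than an error; invalid
rows (bad coordinates, unknown chromosomes, POSCOLOR out of range) are fatal
with the line number, because silently dropping data from a figure misleads.
Line plots (no PHENOTYPE column) simply omit glyphs and legend; the
chrom-only flag filters the plot to chromosomes that carry data, in either
mode.

## The synthetic study generator

`generate_synthetic_input()` emulates the three input shapes the tool is
designed around: GWAS-catalog-style phenotype points (uniform positions,
phenotypes round-robin so every label appears), dense line sets as produced
by array-coverage summaries, and CNV-style region rows (END spans up to 5%
of a chromosome). Optional columns add ancestries (round-robin), short
notes, groups, and POSCOLOR codes. Everything is seeded and reproducible,
and every generated file re-parses with zero warnings — a property the test
suite enforces.

What the generator does not emulate: the strong clustering of real
association hits (e.g. the MHC), linkage-disequilibrium structure, realistic
phenotype frequency imbalance, or biologically placed region boundaries.
Tests passing on generated data therefore demonstrate the plotting
machinery — parsing, layout, spacing optimality, color rules, determinism —
not any biological claim about real datasets.

## Problem sizes and verification

The test suite exercises spacing on roughly a thousand random instances
(up to 45 runs per 600 px track), verifies proximity spacing against an
exhaustive quadratic-program oracle on instances of up to 8 slots, and
renders whole-genome plots of 64 records across 8 phenotypes; these sizes
keep the full suite under a minute while covering every code path at the
scale real plots use. `scripts/acceptance.R` recomputes the interface
constants (216 web-safe colors, 10-character notes, POSCOLOR 0–7, three
ancestry shapes, seed 7, 300/1200 DPI, 24 tracks, 8 legend entries) and the
spacing/determinism properties from a fresh run of the installed package.

## Known limitations

Only the bundled hg19-style assembly, user-supplied UCSC-format cytoBand
files, and synthetic genomes are supported; there is no liftover and no
other built-in assembly. Glyphs render on one side of each chromosome only.
Output formats are PNG and SVG; there is no PDF or interactive output.
Label overlap between the note column and neighboring chromosome tracks is
possible for extremely dense annotation, since notes shift vertically but
never horizontally.
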