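scene_for <- function(lines, config = plot_config(), genome = tiny_genome()) {
  build_scene(parse_input(lines), genome, config)
}

count_el <- function(scene, el) sum(scene$commands$element == el)

test_that("stain classes map to the documented fills", {
  expect_equal(stain_fill("gneg"), "#FFFFFF")
  greys <- grDevices::col2rgb(stain_fill(c("gpos25", "gpos50",
                                           "gpos75", "gpos100")))["red", ]
  expect_true(all(diff(greys) < 0))  # strictly darker with intensity
  expect_equal(stain_fill("acen"), stain_fill("gvar"))  # heterochromatin
  acen <- grDevices::col2rgb(stain_fill("acen"))[, 1]
  expect_gt(acen["blue"], acen["red"])   # dark blue
  stalk <- grDevices::col2rgb(stain_fill("stalk"))[, 1]
  expect_gt(stalk["blue"], 200)          # light blue
  expect_gt(sum(stalk), sum(acen))
  expect_error(stain_fill("pink"), class = "cg_data_error")
})

test_that("every record yields exactly one transverse mark", {
  sc <- scene_for(c("CHR\tPOS\tEND",
                    "1\t100\t", "1\t5000\t", "2\t100\t200", "3\t42\t"))
  expect_equal(count_el(sc, "mark_line"), 3L)
  expect_equal(count_el(sc, "mark_region"), 1L)
  # region rectangle spans the mapped coordinates
  reg <- sc$commands[sc$commands$element == "mark_region", ]
  geom <- sc$geometry
  y0 <- bp_to_y(100, "2", geom); y1 <- bp_to_y(200, "2", geom)
  expect_equal(reg$y, (y0 + y1) / 2, tolerance = 1e-6)
})

test_that("each phenotype record yields one glyph and one connector", {
  sc <- scene_for(c("CHR\tPOS\tPHENOTYPE", "1\t100\ta", "1\t200\tb",
                    "2\t100\t"))
  expect_equal(count_el(sc, "glyph"), 2L)     # bare-position row: no glyph
  expect_equal(count_el(sc, "connector"), 2L)
  expect_equal(count_el(sc, "mark_line"), 3L) # but still a mark
})

test_that("transparent and thin line flags change alpha and width only", {
  lines <- c("CHR\tPOS", "1\t100", "1\t100")
  base <- scene_for(lines)$commands
  trans <- scene_for(lines, plot_config(trans_lines = TRUE))$commands
  thin <- scene_for(lines, plot_config(thin_lines = TRUE))$commands
  b <- base[base$element == "mark_line", ]
  tr <- trans[trans$element == "mark_line", ]
  th <- thin[thin$element == "mark_line", ]
  expect_equal(unique(b$alpha), 1)
  expect_equal(unique(tr$alpha), 0.4)
  expect_equal(unique(th$lwd), unique(b$lwd) / 2)
  # two stacked 0.4 marks composite to 1 - 0.6^2 = 0.64 effective coverage
  expect_equal(1 - (1 - 0.4)^2, 0.64)
  expect_equal(nrow(tr), 2L)
})

test_that("glyph styling flags control outline and size", {
  lines <- c("CHR\tPOS\tPHENOTYPE", "1\t100\ta")
  plain <- scene_for(lines)$commands
  outl <- scene_for(lines, plot_config(outline_circle = TRUE))$commands
  small <- scene_for(lines, plot_config(small_circle = TRUE))$commands
  g0 <- plain[plain$element == "glyph", ]
  g1 <- outl[outl$element == "glyph", ]
  g2 <- small[small$element == "glyph", ]
  expect_true(is.na(g0$col))
  expect_equal(g1$col, "#000000")
  expect_equal(g2$w, g0$w / 2)
})

test_that("ancestry drives the glyph shape with circle overflow", {
  lines <- c("CHR\tPOS\tPHENOTYPE\tETHNICITY",
             "1\t100\ta\tEUR", "1\t5000\ta\tAFR", "2\t100\ta\tEAS",
             "2\t5000\ta\tAMR")
  sc <- scene_for(lines)
  glyphs <- sc$commands[sc$commands$element == "glyph", ]
  expect_setequal(glyphs$type, c("circle", "square", "triangle"))
  expect_equal(sum(glyphs$type == "circle"), 2L)  # EUR + overflow AMR
})

test_that("annotations appear only under the annotation flag, truncated", {
  lines <- c("CHR\tPOS\tNOTE", "1\t100\timmunoregion")
  off <- scene_for(lines)
  on <- scene_for(lines, plot_config(include_annotation = TRUE))
  expect_equal(count_el(off, "note"), 0L)
  expect_equal(count_el(on, "note"), 1L)
  note <- on$commands[on$commands$element == "note", ]
  expect_equal(note$label, "immunoregi")
  expect_equal(nchar(note$label), 10L)
})

test_that("band shading is gated by the chromatin flag", {
  lines <- c("CHR\tPOS", "1\t100")
  off <- scene_for(lines)
  on <- scene_for(lines, plot_config(shade_chromatin = TRUE))
  expect_equal(count_el(off, "band"), 0L)
  expect_gt(count_el(on, "band"), 0L)
  bands_1 <- on$commands[on$commands$element == "band", ]
  expect_true(all(bands_1$fill %in% unname(
    c(stain_fill(chromoglyph::STAINS)))))
})

test_that("thick boundary doubles the chromosome outline stroke", {
  lines <- c("CHR\tPOS", "1\t100")
  base <- scene_for(lines)$commands
  thick <- scene_for(lines, plot_config(thick_boundary = TRUE))$commands
  w0 <- unique(base[base$element == "chrom_outline", "lwd"])
  w1 <- unique(thick[thick$element == "chrom_outline", "lwd"])
  expect_equal(w1, 2 * w0)
})

test_that("the legend lists each phenotype once, in first-appearance order", {
  lines <- c("CHR\tPOS\tPHENOTYPE",
             sprintf("%d\t%d\t%s", rep(1:4, 2), seq(100, 800, 100),
                     rep(c("flu", "gout"), 4)))
  sc <- scene_for(lines)
  expect_equal(count_el(sc, "legend_swatch"), 2L)
  labels <- sc$commands[sc$commands$element == "legend_label", "label"]
  expect_equal(labels, c("flu", "gout"))
  # line-plot input: no phenotypes, no legend
  sc0 <- scene_for(c("CHR\tPOS", "1\t100"))
  expect_equal(count_el(sc0, "legend_swatch"), 0L)
})

test_that("big font enlarges legend labels only", {
  lines <- c("CHR\tPOS\tPHENOTYPE", "1\t100\ta")
  base <- scene_for(lines)$commands
  big <- scene_for(lines, plot_config(big_font = TRUE))$commands
  f0 <- base[base$element == "legend_label", "fontpx"]
  f1 <- big[big$element == "legend_label", "fontpx"]
  expect_gt(f1, f0)
  g0 <- base[base$element == "glyph", "w"]
  g1 <- big[big$element == "glyph", "w"]
  expect_equal(g0, g1)
})

test_that("records outside a zoom region are dropped with a warning", {
  g <- synthetic_genome(2, 10000, seed = 2)
  sc <- build_scene(parse_input(c("CHR\tPOS\tPHENOTYPE",
                                  "1\t2500\ta", "1\t9000\tb", "2\t100\tc")),
                    g, plot_config(zoom = parse_zoom("1:2000-3000")))
  expect_equal(count_el(sc, "glyph"), 1L)
  expect_match(sc$warnings, "dropped", all = FALSE)
})

test_that("all drawing commands stay within the canvas", {
  g <- tiny_genome()
  spec <- synthetic_study_spec(80, letters[1:6], region_fraction = 0.2,
                               note_fraction = 0.2, seed = 5)
  sc <- build_scene(parse_input(generate_synthetic_input(spec, g)), g,
                    plot_config(title = "bounds", include_annotation = TRUE))
  cmd <- sc$commands
  xs <- c(cmd$x, cmd$xend)
  ys <- c(cmd$y, cmd$yend)
  expect_true(all(xs[!is.na(xs)] >= 0 & xs[!is.na(xs)] <= sc$geometry$width))
  expect_true(all(ys[!is.na(ys)] >= 0 & ys[!is.na(ys)] <= sc$geometry$height))
})

test_that("PNG output decodes with declared dimensions and DPI metadata", {
  g <- tiny_genome()
  p <- parse_input(c("CHR\tPOS\tPHENOTYPE", "1\t100\ta"))
  img <- render_ideogram(p, g, plot_config())
  info <- attr(png::readPNG(img$payload, info = TRUE), "info")
  expect_equal(info$dim, c(img$width_px, img$height_px))
  expect_equal(info$dpi[1], 300, tolerance = 0.01)
  expect_equal(img$dpi, 300)

  hi <- render_ideogram(p, g, plot_config(high_res = TRUE))
  info_hi <- attr(png::readPNG(hi$payload, info = TRUE), "info")
  expect_equal(info_hi$dpi[1], 1200, tolerance = 0.01)
  expect_equal(info_hi$dim, 4 * info$dim)
})

test_that("SVG output is well-formed XML with one element per command", {
  skip_if_not_installed("xml2")
  g <- tiny_genome()
  p <- parse_input(c("CHR\tPOS\tPHENOTYPE\tNOTE", "1\t100\ta\t<&MHC>"))
  img <- render_ideogram(p, g, plot_config(out_format = "svg",
                                           include_annotation = TRUE,
                                           title = "t"))
  doc <- xml2::read_xml(rawToChar(img$payload))
  expect_equal(xml2::xml_name(doc), "svg")
  n_children <- length(xml2::xml_children(doc))
  expect_equal(n_children, nrow(img$scene$commands))
})

test_that("rendering is byte-deterministic for fixed inputs", {
  g <- tiny_genome()
  spec <- synthetic_study_spec(30, letters[1:4], seed = 9)
  p <- parse_input(generate_synthetic_input(spec, g))
  cfg <- plot_config(title = "det", color_method = "web", seed = 7)
  expect_identical(render_ideogram(p, g, cfg)$payload,
                   render_ideogram(p, g, cfg)$payload)
  cfg_svg <- plot_config(out_format = "svg", color_method = "random")
  expect_identical(render_ideogram(p, g, cfg_svg)$payload,
                   render_ideogram(p, g, cfg_svg)$payload)
})

test_that("an empty record set still renders bare ideograms", {
  g <- tiny_genome()
  p <- parse_input("CHR\tPOS")
  img <- render_ideogram(p, g, plot_config())
  expect_s3_class(img, "rendered_image")
  expect_equal(count_el(img$scene, "glyph"), 0L)
  expect_gt(count_el(img$scene, "chrom_outline"), 0L)
})

test_that("unsupported output formats are rejected up front", {
  expect_error(plot_config(out_format = "pdf"), class = "cg_usage_error")
})
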