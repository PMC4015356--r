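# Image backends: replay a scene on the cairo PNG device via 'grid', or
# serialize it to SVG 1.1 text. Both consume the same drawing-command data
# frame, so a scene renders identically (up to rasterization) in either
# format, and both are byte-deterministic for a fixed scene.

px_alpha <- function(col, alpha) {
  ifelse(is.na(col), NA,
         grDevices::adjustcolor(col, alpha.f = ifelse(is.na(alpha), 1, alpha)))
}

triangle_pts <- function(x, y, d) {
  r <- d / 2
  list(x = c(x, x - r * sqrt(3) / 2, x + r * sqrt(3) / 2),
       y = c(y - r, y + r / 2, y + r / 2))
}

draw_scene_grid <- function(commands, width, height) {
  grid::grid.newpage()
  vp <- grid::viewport(x = 0, y = 0, just = c("left", "bottom"),
                       width = 1, height = 1,
                       xscale = c(0, width), yscale = c(height, 0))
  grid::pushViewport(vp)
  nat <- function(v) grid::unit(v, "native")
  for (i in seq_len(nrow(commands))) {
    cm <- commands[i, ]
    fill <- px_alpha(cm$fill, cm$alpha)
    col <- px_alpha(cm$col, cm$alpha)
    gp <- grid::gpar(
      fill = if (is.na(fill)) NA else fill,
      col = if (is.na(col)) NA else col,
      lwd = if (is.na(cm$lwd)) 1 else cm$lwd,
      # fontpx is in 300-DPI-nominal canvas px; 1 px = 72/300 pt
      fontsize = (if (is.na(cm$fontpx)) NOTE_PX else cm$fontpx) * 72 / 300
    )
    switch(cm$type,
      rect = grid::grid.rect(x = nat(cm$x), y = nat(cm$y),
                             width = nat(cm$w), height = nat(cm$h), gp = gp),
      square = grid::grid.rect(x = nat(cm$x), y = nat(cm$y),
                               width = nat(cm$w), height = nat(cm$h), gp = gp),
      roundrect = grid::grid.roundrect(
        x = nat(cm$x), y = nat(cm$y), width = nat(cm$w), height = nat(cm$h),
        r = grid::unit(cm$rr / 300, "in"), gp = gp),
      segment = grid::grid.segments(x0 = nat(cm$x), y0 = nat(cm$y),
                                    x1 = nat(cm$xend), y1 = nat(cm$yend),
                                    gp = gp),
      circle = grid::grid.circle(x = nat(cm$x), y = nat(cm$y),
                                 r = nat(cm$w / 2), gp = gp),
      triangle = {
        p <- triangle_pts(cm$x, cm$y, cm$w)
        grid::grid.polygon(x = nat(p$x), y = nat(p$y), gp = gp)
      },
      text = grid::grid.text(
        cm$label, x = nat(cm$x), y = nat(cm$y),
        just = if (cm$hjust == "left") c("left", "centre") else "centre",
        gp = gp)
    )
  }
  grid::popViewport()
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

svg_num <- function(v) formatC(v, format = "fg", digits = 8)

svg_style <- function(fill, alpha, col, lwd) {
  parts <- character()
  parts <- c(parts, if (is.na(fill)) 'fill="none"' else
    sprintf('fill="%s"', tolower(fill)))
  if (!is.na(fill) && !is.na(alpha) && alpha < 1) {
    parts <- c(parts, sprintf('fill-opacity="%s"', svg_num(alpha)))
  }
  if (!is.na(col)) {
    parts <- c(parts, sprintf('stroke="%s"', tolower(col)),
               sprintf('stroke-width="%s"', svg_num(if (is.na(lwd)) 1 else lwd)))
    if (!is.na(alpha) && alpha < 1) {
      parts <- c(parts, sprintf('stroke-opacity="%s"', svg_num(alpha)))
    }
  }
  paste(parts, collapse = " ")
}

scene_to_svg <- function(commands, width, height) {
  out <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" version="1.1" ',
                   'width="%d" height="%d" viewBox="0 0 %d %d">'),
            width, height, width, height)
  )
  for (i in seq_len(nrow(commands))) {
    cm <- commands[i, ]
    style <- svg_style(cm$fill, cm$alpha, cm$col, cm$lwd)
    el <- switch(cm$type,
      rect = ,
      square = sprintf('<rect x="%s" y="%s" width="%s" height="%s" %s/>',
                       svg_num(cm$x - cm$w / 2), svg_num(cm$y - cm$h / 2),
                       svg_num(cm$w), svg_num(cm$h), style),
      roundrect = sprintf(
        '<rect x="%s" y="%s" width="%s" height="%s" rx="%s" %s/>',
        svg_num(cm$x - cm$w / 2), svg_num(cm$y - cm$h / 2),
        svg_num(cm$w), svg_num(cm$h), svg_num(cm$rr), style),
      segment = sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s" %s/>',
                        svg_num(cm$x), svg_num(cm$y), svg_num(cm$xend),
                        svg_num(cm$yend),
                        svg_style(NA, cm$alpha, cm$col, cm$lwd)),
      circle = sprintf('<circle cx="%s" cy="%s" r="%s" %s/>',
                       svg_num(cm$x), svg_num(cm$y), svg_num(cm$w / 2), style),
      triangle = {
        p <- triangle_pts(cm$x, cm$y, cm$w)
        sprintf('<polygon points="%s" %s/>',
                paste(sprintf("%s,%s", svg_num(p$x), svg_num(p$y)),
                      collapse = " "), style)
      },
      text = sprintf(
        paste0('<text x="%s" y="%s" font-family="sans-serif" ',
               'font-size="%s" text-anchor="%s" ',
               'dominant-baseline="middle" fill="%s">%s</text>'),
        svg_num(cm$x), svg_num(cm$y),
        svg_num(if (is.na(cm$fontpx)) NOTE_PX else cm$fontpx),
        if (cm$hjust == "left") "start" else "middle",
        if (is.na(cm$col)) "#000000" else tolower(cm$col),
        xml_escape(cm$label))
    )
    out <- c(out, el)
  }
  paste(c(out, "</svg>"), collapse = "\n")
}

#' Render an annotated ideogram to PNG or SVG
#'
#' Composes layout, color and shape assignment, transverse marks, glyphs,
#' annotations, legend, and title into an image. PNG output carries physical
#' resolution (pHYs) metadata: 300 DPI by default, 1200 DPI with
#' `high_res`. Rendering is a pure function of (records, genome, config):
#' repeated calls give byte-identical payloads.
#'
#' @param parsed A `parsed_input` (see [parse_input()]) or record data frame.
#' @param genome A `genome_assembly` (see [builtin_genome()]).
#' @param config A `plot_config` (see [plot_config()]).
#' @param file Optional output path; the payload is written there when given.
#' @return A `rendered_image`: list with `payload` (raw), `width_px`,
#'   `height_px`, `dpi`, `format`, `scene`, `warnings`.
#' @export
#' @examples
#' genome <- synthetic_genome(4, 1e6, seed = 1)
#' tsv <- generate_synthetic_input(
#'   synthetic_study_spec(n_records = 20, phenotype_labels = c("A", "B")),
#'   genome)
#' img <- render_ideogram(parse_input(tsv), genome, plot_config())
#' img$dpi
render_ideogram <- function(parsed, genome, config = plot_config(),
                            file = NULL) {
  scene <- build_scene(parsed, genome, config)
  geom <- scene$geometry
  if (config$out_format == "png") {
    s <- config$dpi / DEFAULT_DPI
    tmp <- tempfile(fileext = ".png")
    on.exit(unlink(tmp), add = TRUE)
    grDevices::png(tmp, width = round(geom$width * s),
                   height = round(geom$height * s),
                   res = config$dpi, type = "cairo", bg = "white")
    ok <- FALSE
    tryCatch({
      draw_scene_grid(scene$commands, geom$width, geom$height)
      ok <- TRUE
    }, finally = grDevices::dev.off())
    if (!ok) config_error("PNG rendering failed")
    payload <- readBin(tmp, "raw", file.info(tmp)$size)
    decoded <- png::readPNG(payload, info = TRUE)
    width_px <- dim(decoded)[2]; height_px <- dim(decoded)[1]
  } else {
    txt <- scene_to_svg(scene$commands, geom$width, geom$height)
    payload <- charToRaw(enc2utf8(txt))
    width_px <- geom$width; height_px <- geom$height
  }
  if (!is.null(file)) writeBin(payload, file)
  img <- list(payload = payload, width_px = width_px, height_px = height_px,
              dpi = config$dpi, format = config$out_format,
              scene = scene, warnings = scene$warnings)
  class(img) <- "rendered_image"
  img
}

#' @export
print.rendered_image <- function(x, ...) {
  cat(sprintf("<rendered_image> %s, %d x %d px, %d DPI, %d bytes\n",
              x$format, x$width_px, x$height_px, x$dpi, length(x$payload)))
  invisible(x)
}
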