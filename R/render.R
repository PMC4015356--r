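# Ideogram rendering.
#
# build_scene() turns records + genome + config into a plain data frame of
# drawing commands (one primitive per row), so every visual rule is testable
# without decoding an image. render_ideogram() replays the scene on the cairo
# PNG device (through 'grid') or serializes it directly to SVG 1.1.
#
# Numerical constants the plots depend on:
#   default DPI 300, high-res (-z) 1200;
#   transverse line width 1.6 px, halved by -n; alpha 1, 0.4 under -T;
#   chromosome boundary stroke 1.4 px, doubled by -B;
#   legend/label font sizes scaled 1.45x by -F.

DEFAULT_DPI <- 300
HIGH_RES_DPI <- 1200
MARK_LWD <- 1.6
MARK_ALPHA_TRANS <- 0.4
OUTLINE_LWD <- 1.4
BIG_FONT_SCALE <- 1.45

# text sizes, in 300-DPI-nominal canvas pixels
TITLE_PX <- 54
CHROM_LABEL_PX <- 28
NOTE_PX <- 22
LEGEND_PX <- 26

# legend grid: column width follows the longest label so entries never
# collide; used by both the height estimate and the scene builder
legend_grid <- function(labels, width, big_font = FALSE) {
  fontpx <- if (big_font) LEGEND_PX * BIG_FONT_SCALE else LEGEND_PX
  entry_w <- 46 + 0.52 * fontpx * max(nchar(labels), 1L)
  per_row <- max(1L, floor((width - 2 * MARGIN) / entry_w))
  list(fontpx = fontpx, entry_w = entry_w, per_row = per_row,
       n_rows = ceiling(length(labels) / per_row))
}

STAIN_FILLS <- c(
  gneg = "#FFFFFF",
  gpos25 = "#C9C9C9", gpos50 = "#969696", gpos75 = "#5F5F5F",
  gpos100 = "#2B2B2B",
  acen = "#1F3B8C", gvar = "#1F3B8C",   # condensed heterochromatin: dark blue
  stalk = "#9FC5E8"                     # ribosomal stalks: light blue
)

#' Fill color for a Giemsa stain class
#'
#' R-bands (`gneg`) are white; G-bands (`gpos25`..`gpos100`) are greys of
#' strictly increasing darkness; centromeric and variable heterochromatin
#' (`acen`, `gvar`) are dark blue; ribosomal stalks are light blue.
#'
#' @param stain Character vector of stain names (see [STAINS]).
#' @return Hex fill colors.
#' @export
stain_fill <- function(stain) {
  bad <- setdiff(unique(stain), names(STAIN_FILLS))
  if (length(bad)) data_error("unknown stain: %s", paste(bad, collapse = ", "))
  unname(STAIN_FILLS[stain])
}

#' Build a validated plot configuration
#'
#' Collects every rendering option into one validated object. Defaults:
#' standard spacing, automatic color method (`list` for up to ten phenotypes,
#' `generator` beyond), PNG at 300 DPI, seed 7, all style flags off.
#'
#' @param title Plot title ("" for none).
#' @param out_format `"png"` or `"svg"`.
#' @param spacing `"standard"`, `"equal"`, or `"proximity"`.
#' @param color_method `"auto"` or one of `"list"`, `"generator"`, `"web"`,
#'   `"random"`, `"group"`.
#' @param high_res Render PNG at 1200 DPI instead of 300.
#' @param chrom_only Plot only chromosomes carrying at least one record.
#' @param small_circle Halve the glyph diameter.
#' @param outline_circle Stroke a black outline around each glyph.
#' @param zoom Optional `zoom_region` (see [parse_zoom()]) or spec string.
#' @param include_annotation Draw NOTE text beside the chromosomes.
#' @param trans_lines Draw transverse lines at 0.4 alpha so dense regions
#'   composite darker.
#' @param thin_lines Halve the transverse line width.
#' @param thick_boundary Double the chromosome outline stroke width.
#' @param big_font Enlarge phenotype legend labels.
#' @param shade_chromatin Shade cytogenetic bands / heterochromatin.
#' @param seed Integer seed for the stochastic color methods (default 7).
#' @return A `plot_config` list.
#' @export
plot_config <- function(title = "", out_format = c("png", "svg"),
                        spacing = c("standard", "equal", "proximity"),
                        color_method = "auto", high_res = FALSE,
                        chrom_only = FALSE, small_circle = FALSE,
                        outline_circle = FALSE, zoom = NULL,
                        include_annotation = FALSE, trans_lines = FALSE,
                        thin_lines = FALSE, thick_boundary = FALSE,
                        big_font = FALSE, shade_chromatin = FALSE,
                        seed = 7L) {
  out_format <- tolower(out_format)
  if (!out_format[1] %in% c("png", "svg")) {
    usage_error("unsupported output format '%s' (png or svg)", out_format[1])
  }
  spacing <- match.arg(spacing)
  if (!color_method %in% c("auto", "list", "generator", "web", "random",
                           "group")) {
    usage_error("unknown color method '%s'", color_method)
  }
  if (is.character(zoom)) zoom <- parse_zoom(zoom)
  seed <- as.integer(seed)
  if (is.na(seed)) usage_error("seed must be an integer")
  cfg <- list(
    title = title, out_format = out_format[1], spacing = spacing,
    color_method = color_method, high_res = isTRUE(high_res),
    chrom_only = isTRUE(chrom_only), small_circle = isTRUE(small_circle),
    outline_circle = isTRUE(outline_circle), zoom = zoom,
    include_annotation = isTRUE(include_annotation),
    trans_lines = isTRUE(trans_lines), thin_lines = isTRUE(thin_lines),
    thick_boundary = isTRUE(thick_boundary), big_font = isTRUE(big_font),
    shade_chromatin = isTRUE(shade_chromatin), seed = seed
  )
  cfg$dpi <- if (cfg$high_res) HIGH_RES_DPI else DEFAULT_DPI
  class(cfg) <- "plot_config"
  cfg
}

scene_row <- function(element, type, x = NA, y = NA, xend = NA, yend = NA,
                      w = NA, h = NA, rr = NA, fill = NA, alpha = 1,
                      col = NA, lwd = NA, fontpx = NA, label = NA,
                      hjust = "center") {
  data.frame(element = element, type = type, x = x, y = y, xend = xend,
             yend = yend, w = w, h = h, rr = rr, fill = fill, alpha = alpha,
             col = col, lwd = lwd, fontpx = fontpx, label = label,
             hjust = hjust, stringsAsFactors = FALSE)
}

# Chromosome outline: two rounded-rectangle arms meeting in a centromere
# waist. Bands are emitted under the outline only when shade_chromatin is on.
chromosome_scene <- function(track, chrom_def, bands, config) {
  lwd <- if (config$thick_boundary) 2 * OUTLINE_LWD else OUTLINE_LWD
  y_of <- function(bp) {
    span <- max(1, track$end_bp - track$start_bp)
    track$y_top + (pmin(pmax(bp, track$start_bp), track$end_bp) -
                     track$start_bp) / span * (track$y_bottom - track$y_top)
  }
  cen_mid_bp <- (chrom_def$centromere_start_bp + chrom_def$centromere_end_bp) / 2
  rows <- list()
  if (config$shade_chromatin && nrow(bands) > 0L) {
    vis <- bands[bands$end_bp >= track$start_bp &
                   bands$start_bp <= track$end_bp, , drop = FALSE]
    if (nrow(vis) > 0L) {
      # band starts are 0-based; +1 converts to the 1-based track span
      y0 <- y_of(vis$start_bp + 1)
      y1 <- y_of(vis$end_bp)
      rows[[length(rows) + 1L]] <- scene_row(
        element = "band", type = "rect",
        x = track$x + track$chrom_w / 2, y = (y0 + y1) / 2,
        w = track$chrom_w, h = pmax(0.5, y1 - y0),
        fill = stain_fill(vis$stain), alpha = 1
      )
    }
  }
  arm <- function(bp0, bp1) {
    y0 <- y_of(pmax(bp0, track$start_bp)); y1 <- y_of(pmin(bp1, track$end_bp))
    if (y1 - y0 < 1) return(NULL)
    scene_row(element = "chrom_outline", type = "roundrect",
              x = track$x + track$chrom_w / 2, y = (y0 + y1) / 2,
              w = track$chrom_w, h = y1 - y0,
              rr = min(track$chrom_w * 0.45, (y1 - y0) / 2),
              fill = NA, col = "#000000", lwd = lwd)
  }
  in_span <- function(bp) bp >= track$start_bp && bp <= track$end_bp
  if (in_span(cen_mid_bp)) {
    rows[[length(rows) + 1L]] <- arm(track$start_bp, cen_mid_bp)
    rows[[length(rows) + 1L]] <- arm(cen_mid_bp, track$end_bp)
  } else {
    rows[[length(rows) + 1L]] <- arm(track$start_bp, track$end_bp)
  }
  label <- if (track$end_bp - track$start_bp <
               chrom_def$length_bp - 1) {
    sprintf("%s:%.0f-%.0f", track$chrom, track$start_bp, track$end_bp)
  } else {
    track$chrom
  }
  rows[[length(rows) + 1L]] <- scene_row(
    element = "chrom_label", type = "text",
    x = track$x + track$chrom_w / 2, y = track$y_bottom + 22,
    fontpx = CHROM_LABEL_PX, col = "#000000", label = label
  )
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

glyph_scene_row <- function(shape, x, y, d, fill, outline) {
  col <- if (outline) "#000000" else NA
  scene_row(element = "glyph", type = shape, x = x, y = y, w = d, h = d,
            fill = fill, col = col, lwd = if (outline) 1.1 else NA)
}

#' Build the drawing-command scene for a plot
#'
#' Pure function from (parsed input, genome, config) to a data frame of
#' drawing primitives plus the supporting objects. Records falling outside a
#' zoom span are dropped with a warning.
#'
#' @param parsed A `parsed_input` (or a bare record data frame).
#' @param genome A `genome_assembly`.
#' @param config A `plot_config`.
#' @return A `scene` list: `commands` (data frame), `geometry`, `colors`
#'   (`color_assignment` or NULL), `shapes` (`shape_assignment`),
#'   `warnings`.
#' @export
build_scene <- function(parsed, genome, config = plot_config()) {
  records <- if (inherits(parsed, "parsed_input")) parsed$records else parsed
  records <- validate_against_genome(records, genome)
  warnings <- character()

  geometry <- layout_chromosomes(genome, config, records)
  on_canvas <- records$chrom %in% geometry$tracks$chrom
  if (!is.null(config$zoom)) {
    t <- geometry$tracks[1, ]
    in_span <- records$chrom == t$chrom &
      records$pos_bp >= t$start_bp & records$pos_bp <= t$end_bp
    dropped <- sum(!in_span)
    if (dropped > 0) {
      warnings <- c(warnings, sprintf(
        "%d record(s) outside zoom region %s:%.0f-%.0f were dropped",
        dropped, t$chrom, t$start_bp, t$end_bp))
    }
    records <- records[in_span, , drop = FALSE]
  } else {
    records <- records[on_canvas, , drop = FALSE]
  }

  phenos <- records$phenotype[!is.na(records$phenotype)]
  colors <- NULL
  if (length(phenos) > 0) {
    method <- config$color_method
    if (method == "auto") {
      method <- if (length(unique(phenos)) <= 10L) "list" else "generator"
    }
    groups <- NULL
    if (method == "group") {
      gr <- records[!is.na(records$phenotype) & !is.na(records$group), ,
                    drop = FALSE]
      groups <- stats::setNames(gr$group, gr$phenotype)
      groups <- groups[!duplicated(names(groups))]
    }
    colors <- assign_colors(phenos, method, seed = config$seed,
                            groups = groups)
  }
  shapes <- assign_shapes(records$ancestry)

  cmds <- list()
  if (nzchar(config$title)) {
    cmds[[length(cmds) + 1L]] <- scene_row(
      element = "title", type = "text", x = geometry$width / 2, y = MARGIN,
      fontpx = TITLE_PX, col = "#000000", label = config$title)
  }

  mark_lwd <- if (config$thin_lines) MARK_LWD / 2 else MARK_LWD
  mark_alpha <- if (config$trans_lines) MARK_ALPHA_TRANS else 1

  for (i in seq_len(nrow(geometry$tracks))) {
    track <- geometry$tracks[i, ]
    chrom_def <- genome$chromosomes[genome$chromosomes$name == track$chrom, ]
    bands <- genome$bands[genome$bands$chrom == track$chrom, , drop = FALSE]
    cmds[[length(cmds) + 1L]] <- chromosome_scene(track, chrom_def, bands,
                                                  config)
    rec <- records[records$chrom == track$chrom, , drop = FALSE]
    if (nrow(rec) == 0L) next

    # transverse marks: one line per point record, one filled band per region
    y <- bp_to_y(rec$pos_bp, track$chrom, geometry)
    mark_col <- poscolor_lookup(ifelse(is.na(rec$poscolor), 0L, rec$poscolor))
    is_region <- !is.na(rec$end_bp)
    if (any(!is_region)) {
      cmds[[length(cmds) + 1L]] <- scene_row(
        element = "mark_line", type = "segment",
        x = track$x, y = y[!is_region],
        xend = track$x + track$chrom_w, yend = y[!is_region],
        col = mark_col[!is_region], alpha = mark_alpha, lwd = mark_lwd)
    }
    if (any(is_region)) {
      yend <- bp_to_y(pmin(rec$end_bp[is_region],
                           track$end_bp), track$chrom, geometry)
      y0 <- y[is_region]
      cmds[[length(cmds) + 1L]] <- scene_row(
        element = "mark_region", type = "rect",
        x = track$x + track$chrom_w / 2, y = (y0 + yend) / 2,
        w = track$chrom_w, h = pmax(1, yend - y0),
        fill = mark_col[is_region], alpha = mark_alpha)
    }

    # glyph + note slots share the spacing pass ("annotation is spaced too")
    slot_idx <- which(!is.na(rec$phenotype) |
                        (config$include_annotation & !is.na(rec$note)))
    if (length(slot_idx) > 0L) {
      d <- geometry$glyph_d
      slots <- data.frame(rec_i = slot_idx, anchor_y = y[slot_idx])
      slots <- slots[order(slots$anchor_y), , drop = FALSE]
      spaced <- space_slots(slots, c(track$y_top, track$y_bottom), d,
                            config$spacing)
      if (isTRUE(attr(spaced, "fallback"))) {
        warnings <- c(warnings,
                      sprintf("chromosome %s: glyphs exceed track capacity",
                              track$chrom))
      }
      gx0 <- track$x + track$chrom_w + d * 0.9
      for (k in seq_len(nrow(spaced))) {
        r <- rec[spaced$rec_i[k], ]
        gy <- spaced$placed_y[k]
        gx <- gx0 + spaced$lane[k] * d
        has_glyph <- !is.na(r$phenotype)
        if (has_glyph) {
          cmds[[length(cmds) + 1L]] <- scene_row(
            element = "connector", type = "segment",
            x = track$x + track$chrom_w, y = spaced$anchor_y[k],
            xend = gx - d / 2, yend = gy,
            col = "#5A5A5A", lwd = 0.8)
          shape <- if (!is.na(r$ancestry) && r$ancestry %in%
                         names(shapes$mapping)) {
            shapes$mapping[[r$ancestry]]
          } else "circle"
          cmds[[length(cmds) + 1L]] <- glyph_scene_row(
            shape, gx, gy, d, unname(colors$mapping[[r$phenotype]]),
            config$outline_circle)
        }
        if (config$include_annotation && !is.na(r$note)) {
          nx <- gx + (if (has_glyph) d else 0)
          cmds[[length(cmds) + 1L]] <- scene_row(
            element = "note", type = "text", x = nx, y = gy,
            fontpx = NOTE_PX, col = "#000000",
            label = truncate_note(r$note), hjust = "left")
        }
      }
    }
  }

  # legend: phenotype swatches in rows across the bottom; ancestry shape key
  if (!is.null(colors)) {
    lg <- legend_grid(colors$legend_order, geometry$width, config$big_font)
    for (j in seq_along(colors$legend_order)) {
      row_i <- (j - 1) %/% lg$per_row
      col_i <- (j - 1) %% lg$per_row
      lx <- MARGIN + col_i * lg$entry_w
      ly <- geometry$legend_y + row_i * LEGEND_ROW_H + LEGEND_ROW_H / 2
      lab <- colors$legend_order[j]
      cmds[[length(cmds) + 1L]] <- scene_row(
        element = "legend_swatch", type = "circle", x = lx + 11, y = ly,
        w = 22, h = 22, fill = unname(colors$mapping[[lab]]),
        col = if (config$outline_circle) "#000000" else NA,
        lwd = if (config$outline_circle) 1.1 else NA)
      cmds[[length(cmds) + 1L]] <- scene_row(
        element = "legend_label", type = "text", x = lx + 30, y = ly,
        fontpx = lg$fontpx, col = "#000000", label = lab, hjust = "left")
    }
    if (length(shapes$mapping) > 0L) {
      ly <- geometry$legend_y + lg$n_rows * LEGEND_ROW_H + LEGEND_ROW_H / 2
      lx <- MARGIN
      for (a in names(shapes$mapping)) {
        cmds[[length(cmds) + 1L]] <- scene_row(
          element = "legend_shape", type = shapes$mapping[[a]],
          x = lx + 11, y = ly, w = 20, h = 20, fill = "#FFFFFF",
          col = "#000000", lwd = 1.1)
        cmds[[length(cmds) + 1L]] <- scene_row(
          element = "legend_shape_label", type = "text", x = lx + 30, y = ly,
          fontpx = lg$fontpx, col = "#000000", label = a, hjust = "left")
        lx <- lx + 46 + 0.52 * lg$fontpx * max(nchar(a), 4L)
      }
    }
  }

  commands <- do.call(rbind, cmds)
  if (is.null(commands)) commands <- scene_row(character(0), character(0))[0, ]
  rownames(commands) <- NULL
  scene <- list(commands = commands, geometry = geometry, colors = colors,
                shapes = shapes, warnings = warnings)
  class(scene) <- "ideogram_scene"
  scene
}
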