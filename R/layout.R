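# Canvas layout and glyph spacing.
#
# Geometry is computed in a 300-DPI-nominal pixel coordinate system with the
# origin at the top-left (y grows downward). Rendering at other resolutions
# scales the whole canvas, so layout never depends on the output DPI.
#
# Glyph spacing works on "runs": all glyphs anchored at exactly the same
# mapped coordinate form one run, fanned into consecutive horizontal lanes
# (lane 0 next to the chromosome). The three spacing algorithms move whole
# runs vertically, never reorder them, and fall back to equal spacing with a
# warning when the track cannot hold all runs at the required separation.

# -- canvas constants (300-DPI-nominal px) ------------------------------------
GENOME_CANVAS_W <- 1600
SINGLE_CANVAS_W <- 820
ROW_TRACK_H <- 360        # vertical extent of the longest chromosome in a row
ROW_LABEL_H <- 46
SINGLE_TRACK_H <- 880
MARGIN <- 48
TITLE_H <- 64
CHROM_W_GENOME <- 18
CHROM_W_SINGLE <- 44
GLYPH_D_GENOME <- 14
GLYPH_D_SINGLE <- 30
LEGEND_ROW_H <- 46

#' Parse a zoom specification
#'
#' Accepts a bare chromosome (`"7"`) for a whole-chromosome view or
#' `"7:10000-20000"` for a region; a hyphen or an en-dash may separate the
#' range endpoints. Positions are 1-based inclusive.
#'
#' @param spec Character scalar.
#' @return A `zoom_region`: list with `chrom` and `start_bp`/`end_bp`
#'   (`NA` when the whole chromosome is requested).
#' @export
parse_zoom <- function(spec) {
  if (!is.character(spec) || length(spec) != 1L || !nzchar(trimws(spec))) {
    usage_error("empty zoom specification")
  }
  spec <- trimws(spec)
  spec <- gsub("–|−", "-", spec)   # en-dash / minus -> hyphen
  if (!grepl(":", spec, fixed = TRUE)) {
    chrom <- normalize_chrom(spec)
    if (!chrom %in% CHROMOSOMES) {
      usage_error("zoom: unknown chromosome '%s'", spec)
    }
    z <- list(chrom = chrom, start_bp = NA_real_, end_bp = NA_real_)
  } else {
    m <- regmatches(spec, regexec("^([^:]+):([0-9]+)-([0-9]+)$", spec))[[1]]
    if (length(m) != 4L) usage_error("malformed zoom specification '%s'", spec)
    chrom <- normalize_chrom(m[2])
    if (!chrom %in% CHROMOSOMES) {
      usage_error("zoom: unknown chromosome '%s'", m[2])
    }
    start_bp <- as.numeric(m[3]); end_bp <- as.numeric(m[4])
    if (start_bp >= end_bp) {
      usage_error("zoom: start (%s) must be below end (%s)", m[3], m[4])
    }
    z <- list(chrom = chrom, start_bp = start_bp, end_bp = end_bp)
  }
  class(z) <- "zoom_region"
  z
}

#' Compute the canvas geometry for a plot
#'
#' Whole-genome mode lays chromosome tracks out in two rows (1-12 above,
#' 13-22 plus X and Y below), all sharing one pixels-per-base-pair scale set
#' by the longest chromosome. A zoom renders a single enlarged track. With
#' `chrom_only`, only chromosomes carrying at least one record are kept.
#'
#' @param genome A `genome_assembly`.
#' @param config A `plot_config` (see [plot_config()]).
#' @param records Optional record data frame, needed for `chrom_only`
#'   filtering and legend sizing.
#' @return A `canvas_geometry`: list with `width`, `height`, `glyph_d`,
#'   `tracks` (data frame: `chrom`, `x` (left edge of the chromosome bar),
#'   `chrom_w`, `y_top`, `y_bottom`, `start_bp`, `end_bp`, `px_per_bp`),
#'   `legend_y`, `mode`.
#' @export
layout_chromosomes <- function(genome, config, records = NULL) {
  zoom <- config$zoom
  title_h <- if (nzchar(config$title)) TITLE_H else 24
  phenos <- if (!is.null(records)) {
    unique(records$phenotype[!is.na(records$phenotype)])
  } else character()
  has_anc <- !is.null(records) && any(!is.na(records$ancestry))

  if (!is.null(zoom)) {
    i <- match(zoom$chrom, genome$chromosomes$name)
    if (is.na(i)) usage_error("zoom chromosome %s is not in the genome", zoom$chrom)
    len <- genome$chromosomes$length_bp[i]
    start_bp <- if (is.na(zoom$start_bp)) 1 else max(1, zoom$start_bp)
    end_bp <- if (is.na(zoom$end_bp)) len else min(len, zoom$end_bp)
    glyph_d <- if (config$small_circle) GLYPH_D_SINGLE / 2 else GLYPH_D_SINGLE
    y_top <- MARGIN + title_h
    tracks <- data.frame(
      chrom = zoom$chrom, x = 170, chrom_w = CHROM_W_SINGLE,
      y_top = y_top, y_bottom = y_top + SINGLE_TRACK_H,
      start_bp = start_bp, end_bp = end_bp,
      px_per_bp = SINGLE_TRACK_H / max(1, end_bp - start_bp),
      stringsAsFactors = FALSE
    )
    width <- SINGLE_CANVAS_W
    legend_y <- y_top + SINGLE_TRACK_H + ROW_LABEL_H
    mode <- "zoom"
  } else {
    chroms <- genome$chromosomes
    if (config$chrom_only) {
      if (is.null(records)) data_error("chrom_only requires records")
      chroms <- chroms[chroms$name %in% unique(records$chrom), , drop = FALSE]
      if (nrow(chroms) == 0L) data_error("no chromosome carries any record")
    }
    glyph_d <- if (config$small_circle) GLYPH_D_GENOME / 2 else GLYPH_D_GENOME
    split_at <- match("13", chroms$name)
    if (nrow(chroms) <= 12L || is.na(split_at)) {
      row_of <- rep(1L, nrow(chroms))
    } else {
      row_of <- ifelse(seq_len(nrow(chroms)) < split_at, 1L, 2L)
    }
    n_rows <- max(row_of)
    n_cols <- max(table(row_of))
    width <- GENOME_CANVAS_W
    cell_w <- (width - 2 * MARGIN) / max(n_cols, 1)
    px_per_bp <- ROW_TRACK_H / max(chroms$length_bp)
    tracks_l <- vector("list", nrow(chroms))
    for (r in seq_len(n_rows)) {
      idx <- which(row_of == r)
      row_top <- MARGIN + title_h + (r - 1) * (ROW_TRACK_H + ROW_LABEL_H)
      for (j in seq_along(idx)) {
        i <- idx[j]
        tracks_l[[i]] <- data.frame(
          chrom = chroms$name[i],
          x = MARGIN + (j - 1) * cell_w + cell_w * 0.12,
          chrom_w = CHROM_W_GENOME,
          y_top = row_top,
          y_bottom = row_top + chroms$length_bp[i] * px_per_bp,
          start_bp = 1, end_bp = chroms$length_bp[i],
          px_per_bp = px_per_bp,
          stringsAsFactors = FALSE
        )
      }
    }
    tracks <- do.call(rbind, tracks_l)
    legend_y <- MARGIN + title_h + n_rows * (ROW_TRACK_H + ROW_LABEL_H)
    mode <- if (config$chrom_only) "chrom_only" else "genome"
  }

  legend_h <- 0
  if (length(phenos) > 0) {
    legend_h <- legend_grid(phenos, width, config$big_font)$n_rows *
      LEGEND_ROW_H
  }
  if (has_anc) legend_h <- legend_h + LEGEND_ROW_H
  geom <- list(
    width = width,
    height = ceiling(legend_y + legend_h + MARGIN),
    glyph_d = glyph_d,
    tracks = tracks,
    legend_y = legend_y,
    mode = mode
  )
  class(geom) <- "canvas_geometry"
  geom
}

#' Map a base-pair position to a canvas y coordinate
#'
#' Affine and strictly increasing: the first base of the track span maps to
#' the track top, the last to the track bottom. Positions outside a zoomed
#' span return `NA` so callers can drop those records with a warning.
#'
#' @param pos_bp Numeric vector of 1-based positions.
#' @param chrom Chromosome label of the track.
#' @param geometry A `canvas_geometry`.
#' @return Numeric y pixel coordinates (`NA` where out of span).
#' @export
bp_to_y <- function(pos_bp, chrom, geometry) {
  t <- geometry$tracks[geometry$tracks$chrom == chrom, , drop = FALSE]
  if (nrow(t) == 0L) return(rep(NA_real_, length(pos_bp)))
  span <- max(1, t$end_bp - t$start_bp)
  y <- t$y_top + (pos_bp - t$start_bp) / span * (t$y_bottom - t$y_top)
  y[pos_bp < t$start_bp | pos_bp > t$end_bp] <- NA_real_
  y
}

# Group sorted slots into runs of identical anchors; returns run index and
# lane (0-based position within the run).
slot_runs <- function(anchor_y) {
  if (length(anchor_y) == 0L) {
    return(list(run = integer(), lane = integer()))
  }
  run <- cumsum(c(TRUE, diff(anchor_y) != 0))
  lane <- stats::ave(anchor_y, run, FUN = seq_along) - 1
  list(run = run, lane = as.integer(lane))
}

finish_slots <- function(slots, run, lane, run_y, fallback = FALSE) {
  slots$placed_y <- run_y[run]
  slots$lane <- lane
  attr(slots, "fallback") <- fallback
  slots
}

#' Equal-interval glyph spacing
#'
#' Places the n runs at equal intervals spanning the track (interval
#' extent/(n+1) from the track top), preserving genomic order.
#'
#' @param slots Data frame with at least `anchor_y`, sorted increasing.
#' @param track_extent Numeric `c(top, bottom)` of the usable track, px.
#' @param glyph_d Glyph diameter in px (unused; kept for a uniform signature).
#' @return `slots` with `placed_y` and `lane` columns added.
#' @export
space_equal <- function(slots, track_extent, glyph_d = NULL) {
  stopifnot(!is.unsorted(slots$anchor_y))
  g <- slot_runs(slots$anchor_y)
  n <- max(g$run, 0L)
  if (n == 0L) return(finish_slots(slots, g$run, g$lane, numeric()))
  step <- (track_extent[2] - track_extent[1]) / (n + 1)
  run_y <- track_extent[1] + step * seq_len(n)
  finish_slots(slots, g$run, g$lane, run_y)
}

#' Standard (greedy minimum-push) glyph spacing
#'
#' The default method. Runs are swept top to bottom, each pushed down the
#' minimum amount needed to stay at least one glyph diameter below the run
#' before it; a final pass pushes runs back up if the last run would leave
#' the track. Falls back to [space_equal()] with a warning when the runs
#' cannot fit at that separation.
#'
#' @inheritParams space_equal
#' @return `slots` with `placed_y` and `lane` columns added.
#' @export
space_standard <- function(slots, track_extent, glyph_d) {
  stopifnot(!is.unsorted(slots$anchor_y))
  g <- slot_runs(slots$anchor_y)
  n <- max(g$run, 0L)
  if (n == 0L) return(finish_slots(slots, g$run, g$lane, numeric()))
  anchors <- slots$anchor_y[!duplicated(g$run)]
  if (n * glyph_d > (track_extent[2] - track_extent[1]) + glyph_d) {
    warning("standard spacing: track capacity exceeded; using equal spacing",
            call. = FALSE)
    return(space_equal(slots, track_extent, glyph_d))
  }
  run_y <- anchors
  for (i in seq_len(n)[-1]) {
    run_y[i] <- max(run_y[i], run_y[i - 1] + glyph_d)
  }
  if (run_y[n] > track_extent[2]) {           # bottom-overflow pass
    run_y[n] <- track_extent[2]
    for (i in rev(seq_len(n - 1))) {
      run_y[i] <- min(run_y[i], run_y[i + 1] - glyph_d)
    }
  }
  finish_slots(slots, g$run, g$lane, run_y)
}

#' Proximity (least-displacement) glyph spacing
#'
#' Order-preserving placement with pairwise run gaps of at least one glyph
#' diameter that minimizes the total squared displacement from the anchors.
#' Implemented by iterative cluster merging: any two neighboring slots (or
#' clusters) closer than the required gap merge into one cluster centered on
#' the mean of its member anchors and spread at minimum separation, repeated
#' to a fixed point; the result is clamped to the track. Falls back to
#' [space_equal()] with a warning when capacity is exceeded.
#'
#' Unlike [space_standard()], co-located slots are not fanned into lanes:
#' every slot is its own unit (all in lane 0), so glyphs sharing an anchor
#' split symmetrically around it.
#'
#' @inheritParams space_equal
#' @return `slots` with `placed_y` and `lane` columns added.
#' @export
space_proximity <- function(slots, track_extent, glyph_d) {
  stopifnot(!is.unsorted(slots$anchor_y))
  n <- nrow(slots)
  if (n == 0L) return(finish_slots(slots, integer(), integer(), numeric()))
  anchors <- slots$anchor_y
  lo <- track_extent[1]
  hi <- track_extent[2] - (n - 1) * glyph_d
  if (hi < lo) {
    warning("proximity spacing: track capacity exceeded; using equal spacing",
            call. = FALSE)
    return(space_equal(slots, track_extent, glyph_d))
  }
  # Work in gap-transformed coordinates z_i = y_i - (i-1)*d, where the gap
  # constraints become plain monotonicity. Clusters are (sum, count, value).
  z <- anchors - (seq_len(n) - 1) * glyph_d
  cs <- z          # cluster sums
  cn <- rep(1L, n) # cluster sizes
  m <- 0L
  for (i in seq_len(n)) {
    m <- m + 1L
    cs[m] <- z[i]; cn[m] <- 1L
    while (m > 1L && cs[m] / cn[m] <= cs[m - 1L] / cn[m - 1L]) {
      cs[m - 1L] <- cs[m - 1L] + cs[m]
      cn[m - 1L] <- cn[m - 1L] + cn[m]
      m <- m - 1L
    }
  }
  fitted <- rep(cs[seq_len(m)] / cn[seq_len(m)], cn[seq_len(m)])
  fitted <- pmin(pmax(fitted, lo), hi)   # uniform box in z-space stays exact
  placed <- fitted + (seq_len(n) - 1) * glyph_d
  finish_slots(slots, seq_len(n), rep(0L, n), placed)
}

#' Dispatch to a spacing method by name
#'
#' @param method `"standard"`, `"equal"`, or `"proximity"`.
#' @inheritParams space_equal
#' @param glyph_d Glyph diameter in px.
#' @return `slots` with `placed_y` and `lane` columns added.
#' @export
space_slots <- function(slots, track_extent, glyph_d,
                        method = c("standard", "equal", "proximity")) {
  method <- match.arg(method)
  switch(method,
         standard = space_standard(slots, track_extent, glyph_d),
         equal = space_equal(slots, track_extent, glyph_d),
         proximity = space_proximity(slots, track_extent, glyph_d))
}
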