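# Categorical color and shape assignment.
#
# Colors are plain "#RRGGBB" hex strings throughout; transparency is carried
# separately by the renderer so the same assignment serves opaque glyphs and
# translucent transverse lines.

#' The fixed 10-color list palette
#'
#' A documented constant of well-separated, colorblind-aware categorical
#' colors used by the `list` color method, which is intended for studies with
#' ten or fewer phenotypes.
#'
#' @format Character vector of 10 hex colors.
#' @export
LIST_PALETTE <- c(
  "#E69F00", "#56B4E9", "#009E73", "#F0E442", "#0072B2",
  "#D55E00", "#CC79A7", "#999999", "#882255", "#117733"
)

# Hue spacing constants for the generator method: even hue steps at fixed
# saturation/value give the maximum pairwise hue separation of 360/n degrees.
GENERATOR_S <- 0.78
GENERATOR_V <- 0.90

#' Transverse-line color codes
#'
#' The fixed POSCOLOR code table: 0 black (the default line color), 1 red,
#' 2 blue, 3 green, 4 orange, 5 purple, 6 brown, 7 magenta.
#'
#' @format Named character vector (names "0".."7") of hex colors.
#' @export
POSCOLOR_TABLE <- c(
  `0` = "#000000", `1` = "#D62728", `2` = "#1F77B4", `3` = "#2CA02C",
  `4` = "#FF7F0E", `5` = "#9467BD", `6` = "#8C564B", `7` = "#E377C2"
)

#' First n colors of the fixed list palette
#'
#' @param n Number of colors, between 1 and 10.
#' @return Character vector of `n` hex colors, seed-independent.
#' @export
list_palette <- function(n) {
  stopifnot(n >= 1)
  if (n > length(LIST_PALETTE)) {
    data_error(paste0("the list color method supports at most 10 phenotypes ",
                      "(%d requested); use the generator method"), n)
  }
  LIST_PALETTE[seq_len(n)]
}

#' Maximum-separation generated palette
#'
#' `n` colors with hues evenly spaced at 360/n degree intervals (fixed
#' saturation and value), so the minimum pairwise hue distance is exactly
#' 360/n degrees. Deterministic and seed-independent.
#'
#' @param n Number of colors (>= 1).
#' @return Character vector of `n` distinct hex colors.
#' @export
generator_palette <- function(n) {
  stopifnot(n >= 1)
  grDevices::hsv(h = (seq_len(n) - 1) / n, s = GENERATOR_S, v = GENERATOR_V)
}

#' The 216 web-safe colors
#'
#' Every color whose red, green, and blue channels are multiples of 51
#' (0, 51, 102, 153, 204, 255), in lattice order.
#'
#' @return Character vector of 216 hex colors.
#' @export
web_safe_palette <- function() {
  lev <- c(0L, 51L, 102L, 153L, 204L, 255L)
  g <- expand.grid(b = lev, g = lev, r = lev)
  grDevices::rgb(g$r, g$g, g$b, maxColorValue = 255)
}

#' Assign colors to phenotypes
#'
#' Maps each distinct phenotype to a color by one of five methods:
#' \describe{
#'   \item{list}{first-n of the fixed [LIST_PALETTE] (at most 10 phenotypes).}
#'   \item{generator}{evenly hue-spaced colors from [generator_palette()].}
#'   \item{web}{a seeded shuffle of the 216 web-safe colors, taken without
#'     replacement.}
#'   \item{random}{seeded independent uniform RGB draws, with no regard for
#'     color proximity.}
#'   \item{group}{each group gets a base hue from
#'     [generator_palette()] over the number of groups; its members get that
#'     hue in a strictly increasing lightness gradient.}
#' }
#' Identical inputs and seed always give identical assignments; `list`,
#' `generator`, and `group` ignore the seed entirely.
#'
#' @param phenotypes Character vector of phenotype labels in first-appearance
#'   order (duplicates allowed; the first appearance fixes legend order).
#' @param method One of `"list"`, `"generator"`, `"web"`, `"random"`,
#'   `"group"`.
#' @param seed Integer RNG seed (default 7).
#' @param groups For `method = "group"`, a named character vector mapping
#'   every phenotype label to its group label.
#' @return A `color_assignment`: list with `method`, `mapping` (named hex
#'   vector, one entry per distinct phenotype), `legend_order`.
#' @export
assign_colors <- function(phenotypes, method = c("list", "generator", "web",
                                                 "random", "group"),
                          seed = 7L, groups = NULL) {
  method <- match.arg(method)
  legend_order <- unique(phenotypes)
  n <- length(legend_order)
  stopifnot(n >= 1)
  cols <- switch(method,
    list = list_palette(n),
    generator = generator_palette(n),
    web = with_rng_seed(seed, sample(web_safe_palette())[seq_len(n)]),
    random = with_rng_seed(seed, {
      m <- matrix(floor(stats::runif(3 * n, 0, 256)), ncol = 3)
      m[m > 255] <- 255
      grDevices::rgb(m[, 1], m[, 2], m[, 3], maxColorValue = 255)
    }),
    group = {
      if (is.null(groups) || !all(legend_order %in% names(groups))) {
        missing <- if (is.null(groups)) legend_order else
          setdiff(legend_order, names(groups))
        data_error("group color method: no group for phenotype(s) %s",
                   paste(missing, collapse = ", "))
      }
      grp <- unname(groups[legend_order])
      grp_order <- unique(grp)
      hues <- (match(grp, grp_order) - 1) / length(grp_order)
      out <- character(n)
      for (g in grp_order) {
        idx <- which(grp == g)
        k <- length(idx)
        v <- if (k == 1) GENERATOR_V else seq(0.45, 0.95, length.out = k)
        out[idx] <- grDevices::hsv(h = hues[idx][1], s = GENERATOR_S, v = v)
      }
      out
    }
  )
  res <- list(method = method,
              mapping = stats::setNames(cols, legend_order),
              legend_order = legend_order)
  class(res) <- "color_assignment"
  res
}

#' Assign shapes to ancestry groups
#'
#' The first three ancestry groups (in first-appearance order) get the three
#' distinct shapes circle, square, triangle; every group beyond the third
#' falls back to a circle. Records with no ancestry render as circles.
#'
#' @param ancestries Character vector of ancestry labels in first-appearance
#'   order (duplicates allowed); may be empty.
#' @return A `shape_assignment`: list with `mapping` (named character vector
#'   label -> shape) and `overflow_shape` (`"circle"`).
#' @export
assign_shapes <- function(ancestries = character()) {
  shapes <- c("circle", "square", "triangle")
  labels <- unique(ancestries[!is.na(ancestries)])
  assigned <- rep("circle", length(labels))
  first3 <- seq_len(min(3L, length(labels)))
  assigned[first3] <- shapes[first3]
  mapping <- stats::setNames(assigned, labels)
  res <- list(mapping = mapping, overflow_shape = "circle")
  class(res) <- "shape_assignment"
  res
}

#' Look up a transverse-line color code
#'
#' @param code Integer vector of POSCOLOR codes, each in 0-7.
#' @return Hex colors from [POSCOLOR_TABLE].
#' @export
poscolor_lookup <- function(code) {
  if (any(is.na(code)) || any(code < 0 | code > 7) ||
      any(code != floor(code))) {
    data_error("POSCOLOR code must be an integer 0-7")
  }
  unname(POSCOLOR_TABLE[as.character(as.integer(code))])
}
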