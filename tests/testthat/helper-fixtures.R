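# Shared fixtures, built in code.

tiny_genome <- function() synthetic_genome(4, 1e6, seed = 11)

# a valid hand-written band set for one chromosome
toy_bands <- function() {
  parse_cytoband(c(
    "chr1\t0\t100\tp12\tgneg",
    "chr1\t100\t200\tp11\tacen",
    "chr1\t200\t300\tq11\tacen",
    "chr1\t300\t500\tq12\tgpos50"
  ))
}

make_slots <- function(anchors) {
  data.frame(anchor_y = sort(anchors))
}

# Independent brute-force quadratic-program oracle for least-displacement
# spacing: minimize sum (x_i - a_i)^2 subject to x_{i+1} - x_i >= d.
# Enumerates every subset of adjacent gap constraints forced tight; each
# candidate places maximal tight blocks at the mean of their anchors; the
# optimum must be among the feasible candidates.
oracle_proximity <- function(anchors, d) {
  n <- length(anchors)
  if (n == 1L) return(anchors)
  best <- NULL
  best_obj <- Inf
  for (mask in 0:(2^(n - 1) - 1)) {
    tight <- bitwAnd(mask, 2^(0:(n - 2))) > 0
    blk <- cumsum(c(1L, as.integer(!tight)))
    x <- numeric(n)
    for (b in unique(blk)) {
      idx <- which(blk == b)
      off <- (seq_along(idx) - 1) * d
      x[idx] <- mean(anchors[idx] - off) + off
    }
    if (all(diff(x) >= d - 1e-9)) {
      obj <- sum((x - anchors)^2)
      if (obj < best_obj) {
        best_obj <- obj
        best <- x
      }
    }
  }
  best
}

# HSL lightness of a hex color, in [0, 1]
lightness_of <- function(hex) {
  m <- grDevices::col2rgb(hex) / 255
  (apply(m, 2, max) + apply(m, 2, min)) / 2
}

hue_of <- function(hex) {
  grDevices::rgb2hsv(grDevices::col2rgb(hex))["h", ] * 360
}

eight_phenotypes <- c(
  "rheumatoid arthritis", "Crohn's disease", "blood pressure",
  "Alzheimer's disease", "breast cancer", "pancreatic cancer",
  "colorectal cancer", "prostate cancer"
)
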