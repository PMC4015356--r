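test_that("zoom specifications parse per the documented forms", {
  z <- parse_zoom("7")
  expect_equal(z$chrom, "7")
  expect_true(is.na(z$start_bp) && is.na(z$end_bp))

  z <- parse_zoom("7:10000-20000")
  expect_equal(z$chrom, "7")
  expect_equal(z$start_bp, 10000)
  expect_equal(z$end_bp, 20000)

  # en-dash works as the range separator too
  expect_equal(parse_zoom("7:10000–20000"), z)
  expect_equal(parse_zoom("chrX"), parse_zoom("X"))

  expect_error(parse_zoom("7:20000-10000"), class = "cg_usage_error")
  expect_error(parse_zoom("zz"), class = "cg_usage_error")
  expect_error(parse_zoom("7:10-"), class = "cg_usage_error")
  expect_error(parse_zoom(""), class = "cg_usage_error")
})

test_that("bp_to_y is affine, monotone, and exact at the track ends", {
  g <- synthetic_genome(2, 1000, seed = 5)
  geom <- layout_chromosomes(g, plot_config())
  t <- geom$tracks[geom$tracks$chrom == "1", ]
  expect_equal(bp_to_y(1, "1", geom), t$y_top)
  expect_equal(bp_to_y(1000, "1", geom), t$y_bottom)
  mid <- bp_to_y(500, "1", geom)
  expect_equal(mid, (t$y_top + t$y_bottom) / 2, tolerance = 0.5)
  ys <- bp_to_y(c(1, 250, 500, 750, 1000), "1", geom)
  expect_true(all(diff(ys) > 0))
})

test_that("bp_to_y returns NA outside a zoom span", {
  g <- synthetic_genome(1, 10000, seed = 5)
  geom <- layout_chromosomes(g, plot_config(zoom = parse_zoom("1:2000-3000")))
  expect_true(is.na(bp_to_y(1500, "1", geom)))
  expect_false(is.na(bp_to_y(2500, "1", geom)))
  t <- geom$tracks[1, ]
  expect_equal(bp_to_y(2000, "1", geom), t$y_top)
  expect_equal(bp_to_y(3000, "1", geom), t$y_bottom)
})

test_that("standard spacing pushes runs down minimally and fans co-located slots", {
  ext <- c(0, 1000)
  s <- space_standard(make_slots(c(100, 200)), ext, 10)
  expect_equal(s$placed_y, c(100, 200))   # no conflict, no movement

  s <- space_standard(make_slots(c(300, 300)), ext, 10)
  expect_equal(s$placed_y, c(300, 300))   # one run, two lanes
  expect_equal(s$lane, c(0L, 1L))

  s <- space_standard(make_slots(c(50, 52, 54)), ext, 10)
  expect_equal(s$placed_y, c(50, 60, 70))
  expect_equal(s$lane, c(0L, 0L, 0L))
})

test_that("standard spacing pushes back up at the track bottom", {
  s <- space_standard(make_slots(c(95, 96, 100)), c(0, 100), 10)
  expect_equal(s$placed_y, c(80, 90, 100))
})

test_that("equal spacing places runs at extent/(n+1) intervals", {
  s <- space_equal(make_slots(50), c(0, 100))
  expect_equal(s$placed_y, 50)
  s <- space_equal(make_slots(c(10, 11, 90)), c(0, 100))
  expect_equal(s$placed_y, c(25, 50, 75))
  s <- space_equal(make_slots(sort(runif(7, 0, 100))), c(0, 100))
  expect_true(all(abs(diff(diff(s$placed_y))) < 1))
})

test_that("proximity spacing solves the least-displacement problem", {
  ext <- c(0, 1000)
  s <- space_proximity(make_slots(c(100, 300, 600)), ext, 10)
  expect_equal(s$placed_y, c(100, 300, 600))   # feasible anchors untouched

  s <- space_proximity(make_slots(c(400, 400)), ext, 10)
  expect_equal(s$placed_y, c(395, 405))        # symmetric split on the mean

  s <- space_proximity(make_slots(c(10, 12, 14, 90)), c(0, 100), 10)
  expect_equal(s$placed_y, c(2, 12, 22, 90))
})

test_that("proximity spacing matches the brute-force QP oracle", {
  set.seed(42)
  for (trial in 1:300) {
    n <- sample(2:8, 1)
    anchors <- sort(round(runif(n, 0, 200), 1))
    if (trial %% 3 == 0) {  # force duplicate anchors regularly
      anchors[2] <- anchors[1]
      anchors <- sort(anchors)
    }
    d <- sample(c(5, 10, 20), 1)
    got <- space_proximity(make_slots(anchors), c(-1e4, 1e4), d)$placed_y
    want <- oracle_proximity(anchors, d)
    expect_true(all(diff(got) >= d - 1e-9))
    expect_equal(sum((got - anchors)^2), sum((want - anchors)^2),
                 tolerance = 1e-6)
  }
})

test_that("all spacing methods preserve genomic order and avoid overlap", {
  set.seed(99)
  ext <- c(0, 500)
  d <- 10
  for (trial in 1:120) {
    n <- sample(1:40, 1)   # n*d <= extent: capacity always sufficient
    anchors <- sort(round(runif(n, 0, 500)))
    slots <- make_slots(anchors)
    for (m in c("standard", "equal", "proximity")) {
      s <- space_slots(slots, ext, d, m)
      expect_true(all(diff(s$placed_y) >= -1e-9))  # order preserved
      lane0 <- s$placed_y[s$lane == 0L]
      expect_true(all(diff(lane0) >= d - 1e-6))
      expect_true(all(s$placed_y >= ext[1] - 1e-9 &
                        s$placed_y <= ext[2] + 1e-9))
    }
  }
})

test_that("over-capacity inputs fall back to equal spacing with a warning", {
  anchors <- sort(runif(30, 0, 100))
  for (m in c("standard", "proximity")) {
    expect_warning(s <- space_slots(make_slots(anchors), c(0, 100), 10, m),
                   "equal")
    expect_equal(s$placed_y,
                 suppressWarnings(
                   space_equal(make_slots(anchors), c(0, 100))$placed_y))
  }
})

test_that("whole-genome layout arranges 24 tracks on a shared scale", {
  geom <- layout_chromosomes(builtin_genome(), plot_config())
  expect_equal(nrow(geom$tracks), 24L)
  expect_length(unique(geom$tracks$px_per_bp), 1L)
  expect_true(all(geom$tracks$y_bottom <= geom$height))
  expect_true(all(geom$tracks$x >= 0 & geom$tracks$x <= geom$width))
  # two rows: 1-12 share a top edge above 13-Y
  expect_length(unique(geom$tracks$y_top[1:12]), 1L)
  expect_length(unique(geom$tracks$y_top[13:24]), 1L)
  expect_lt(geom$tracks$y_top[1], geom$tracks$y_top[13])
})

test_that("zoom and chrom-only modes reduce the track set", {
  g <- builtin_genome()
  geom <- layout_chromosomes(g, plot_config(zoom = parse_zoom("7")))
  expect_equal(nrow(geom$tracks), 1L)
  expect_equal(geom$tracks$chrom, "7")

  rec <- parse_input(c("CHR\tPOS", "1\t100", "6\t200"))$records
  geom <- layout_chromosomes(g, plot_config(chrom_only = TRUE), rec)
  expect_equal(sort(geom$tracks$chrom), c("1", "6"))

  expect_error(
    layout_chromosomes(synthetic_genome(2, 1000, seed = 1),
                       plot_config(zoom = parse_zoom("7"))),
    class = "cg_usage_error")
})

test_that("layout is deterministic for identical inputs", {
  g <- builtin_genome()
  rec <- parse_input(c("CHR\tPOS\tPHENOTYPE", "1\t100\ta"))$records
  expect_identical(layout_chromosomes(g, plot_config(), rec),
                   layout_chromosomes(g, plot_config(), rec))
})
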