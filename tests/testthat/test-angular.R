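# angular segmentation and binning: worked examples, wraparound, and the
# conservation / nesting / equivariance / discretization property suites

test_that("bin membership uses half-open intervals with wraparound", {
  s90 <- bin_scheme(90)
  expect_identical(bin_index(c(0, 44.99, 45, 135, 359), s90),
                   c(1L, 1L, 2L, 3L, 1L))
  s10 <- bin_scheme(10)
  # [355, 5) belongs to the 0-degree bin
  expect_identical(bin_index(c(359, 355, 354.99, 5), s10),
                   c(1L, 1L, 36L, 2L))
  expect_error(bin_scheme(60), "one of")
})

test_that("segments from control points follow the delta-weight formula", {
  arc <- make_beam(c(0, 90, 180), c(0, 0.5, 1), rot = "CW",
                   beam_type = "DYNAMIC", mu = 100)
  segs <- beam_to_segments(arc, fraction_weight = 1)
  expect_equal(segs$mu, c(50, 50))
  expect_equal(segs$start_deg, c(0, 90))
  expect_equal(segs$span_deg, c(90, 90))
  expect_identical(segs$direction, c("CW", "CW"))

  static <- make_static_beam(0, 200)
  ss <- beam_to_segments(static)
  expect_identical(ss$direction, "POINT")
  expect_equal(ss$mu, 200)
  expect_equal(ss$start_deg, 0)

  # wrap through 0: 350 -> 10 clockwise is a 20-degree travel
  wrap <- make_beam(c(350, 10), c(0, 1), rot = "CW", beam_type = "DYNAMIC",
                    mu = 60)
  ws <- beam_to_segments(wrap)
  expect_equal(ws$start_deg, 350)
  expect_equal(ws$span_deg, 20)
  expect_equal(sum(ws$mu), 60)

  # fraction weight scales MU linearly
  expect_equal(sum(beam_to_segments(arc, fraction_weight = 10)$mu), 1000)

  expect_error(beam_to_segments(make_beam(c(0, 90), c(0, 1), rot = "NONE",
                                          beam_type = "DYNAMIC")),
               class = "uf_validation")
  expect_error(beam_to_segments(make_beam(c(0, 90), c(0.5, 0.2), rot = "CW",
                                          beam_type = "DYNAMIC")),
               class = "uf_validation")
})

test_that("binning matches the worked example and analytic arc splits", {
  s90 <- bin_scheme(90)
  h <- bin_segments(angular_segments(c(0, 90), c(0, 0), c("POINT", "POINT"),
                                     c(200, 300)), s90)
  expect_equal(h$mu_per_bin, c(200, 300, 0, 0))

  # 0 -> 180 CW arc overlaps the 0/90/180 bins by 45/90/45 degrees
  h2 <- bin_segments(angular_segments(0, 180, "CW", 100), s90)
  expect_equal(h2$mu_per_bin, c(25, 50, 25, 0))

  # wraparound arc entirely inside the 0-degree bin
  h3 <- bin_segments(angular_segments(350, 20, "CW", 60), s90)
  expect_equal(h3$mu_per_bin, c(60, 0, 0, 0))

  # point at 359 in the 10-degree scheme lands in the 0-degree bin
  h4 <- bin_segments(angular_segments(359, 0, "POINT", 50), bin_scheme(10))
  expect_equal(h4$mu_per_bin[1], 50)
  expect_equal(sum(h4$mu_per_bin), 50)

  # full laps spread uniformly
  h5 <- bin_segments(angular_segments(123.4, 720, "CC", 80), s90)
  expect_equal(h5$mu_per_bin, rep(20, 4))
})

test_that("MU is conserved to 1e-9 relative over 1000 random beams", {
  set.seed(31)
  total_in <- 0; scheme <- bin_scheme(45)
  acc <- numeric(8)
  for (i in 1:1000) {
    beam <- random_beam()
    h <- bin_segments(beam_to_segments(beam), scheme)
    expect_equal(sum(h$mu_per_bin), beam$beam_meterset_mu,
                 tolerance = 1e-9)
    total_in <- total_in + beam$beam_meterset_mu
    acc <- acc + h$mu_per_bin
  }
  expect_equal(sum(acc), total_in, tolerance = 1e-9)
})

test_that("analytic binning matches the 1e5-sub-step oracle", {
  # geometry on a grid whose bin boundaries coincide with sub-step edges,
  # where the midpoint oracle is exact: agreement to 1e-6 relative
  set.seed(32)
  for (w in c(90, 45, 30, 10)) {
    scheme <- bin_scheme(w)
    segs <- angular_segments(
      start_deg = sample(0:359, 6),
      span_deg = c(0, 100, 250, 125, 200, 500),
      direction = c("POINT", "CW", "CC", "CW", "CC", "CW"),
      mu = stats::runif(6, 10, 300))
    h <- bin_segments(segs, scheme)
    o <- oracle_bin(segs, scheme, nsub = 1e5)
    expect_equal(h$mu_per_bin, o, tolerance = 1e-6)
  }
  # arbitrary real-valued geometry: agreement within the oracle's own
  # discretization error bound (half a sub-step of MU per bin boundary)
  segs <- random_segments(20)
  scheme <- bin_scheme(10)
  h <- bin_segments(segs, scheme)
  o <- oracle_bin(segs, scheme, nsub = 1e5)
  bound <- sum(segs$mu) / 1e5 * (360 / 10)
  expect_true(max(abs(h$mu_per_bin - o)) <= bound)
})

test_that("fine histograms nest exactly into coarser aligned schemes", {
  set.seed(33)
  segs <- random_segments(50)
  h10 <- bin_segments(segs, bin_scheme(10))
  h30 <- bin_segments(segs, bin_scheme(30))
  h90 <- bin_segments(segs, bin_scheme(90))
  expect_equal(rebin_histogram(h10, bin_scheme(30))$mu_per_bin,
               h30$mu_per_bin, tolerance = 1e-12)
  expect_equal(rebin_histogram(h30, bin_scheme(90))$mu_per_bin,
               h90$mu_per_bin, tolerance = 1e-12)
  expect_equal(rebin_histogram(h10, bin_scheme(90))$mu_per_bin,
               h90$mu_per_bin, tolerance = 1e-12)
  # 45 does not nest with 10 or 30
  expect_error(rebin_histogram(h10, bin_scheme(45)), "nest")
})

test_that("rotating all angles by one bin width permutes the bins", {
  set.seed(34)
  for (w in c(90, 45, 30, 10)) {
    scheme <- bin_scheme(w)
    segs <- random_segments(30)
    shifted <- segs
    shifted$start_deg <- (segs$start_deg + w) %% 360
    h <- bin_segments(segs, scheme)
    hs <- bin_segments(shifted, scheme)
    n <- length(h$mu_per_bin)
    expect_equal(hs$mu_per_bin, h$mu_per_bin[c(n, seq_len(n - 1))],
                 tolerance = 1e-9)
  }
})

test_that("merging histograms equals binning the concatenated segments", {
  set.seed(35)
  scheme <- bin_scheme(30)
  for (rep in 1:100) {
    parts <- lapply(1:3, function(i) random_segments(sample(1:5, 1)))
    hs <- lapply(parts, bin_segments, scheme = scheme)
    merged <- merge_histograms(hs)
    direct <- bin_segments(do.call(rbind, parts), scheme)
    expect_equal(merged$mu_per_bin, direct$mu_per_bin, tolerance = 1e-12)
  }
  empty <- merge_histograms(list(), scheme = scheme)
  expect_equal(empty$mu_per_bin, numeric(12))
  expect_error(merge_histograms(list(bin_segments(random_segments(2),
                                                  bin_scheme(90)),
                                     bin_segments(random_segments(2),
                                                  bin_scheme(45)))),
               "schemes")
})
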