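# use-factor percentages, stratified aggregation, rendering

test_that("use factors are MU fractions on the percent scale", {
  h <- bin_segments(angular_segments(c(0, 90), c(0, 0), c("POINT", "POINT"),
                                     c(200, 300)), bin_scheme(90))
  expect_equal(use_factors(h), c(40, 60, 0, 0))
  h1 <- bin_segments(angular_segments(0, 0, "POINT", 123), bin_scheme(90))
  expect_equal(use_factors(h1), c(100, 0, 0, 0))
  u <- use_factors(bin_segments(angular_segments(0, 360, "CW", 99),
                                bin_scheme(45)))
  expect_equal(u, rep(12.5, 8))
  empty <- merge_histograms(list(), scheme = bin_scheme(90))
  expect_error(use_factors(empty), class = "uf_empty")
})

test_that("aggregation pools MU and fills the marginal strata", {
  p1 <- make_plan(list(make_static_beam(0, 100)), site = "breast")
  p2 <- make_plan(list(
    make_beam(c(90, 90), c(0, 1), rot = "NONE", beam_type = "DYNAMIC",
              mu = 100)), site = "pelvis")
  # in p2 the dynamic fixed-gantry beam is IMRT; all MU at 90
  tab <- aggregate_use_factors(list(p1, p2), bin_scheme(90))
  expect_equal(unname(usefactor_row(tab, "3D-CRT", "breast")),
               c(100, 0, 0, 0))
  expect_equal(unname(usefactor_row(tab, "IMRT", "pelvis")),
               c(0, 100, 0, 0))
  expect_equal(unname(usefactor_row(tab, "ALL", "ALL")), c(50, 50, 0, 0))
  expect_equal(unname(usefactor_row(tab, "3D-CRT", "ALL")), c(100, 0, 0, 0))
  expect_equal(unname(usefactor_row(tab, "ALL", "pelvis")), c(0, 100, 0, 0))
  # zero-MU strata are absent
  expect_error(usefactor_row(tab, "VMAT", "ALL"), "no stratum")
})

test_that("duplicating a cohort leaves the percentages unchanged", {
  set.seed(41)
  plans <- lapply(1:5, function(i)
    make_plan(list(random_beam()), fractions = sample(1:30, 1)))
  t1 <- aggregate_use_factors(plans, bin_scheme(45))
  t2 <- aggregate_use_factors(c(plans, plans), bin_scheme(45))
  expect_equal(usefactor_row(t2), usefactor_row(t1), tolerance = 1e-12)
})

test_that("fraction weighting matters only across unequal fraction counts", {
  pA <- make_plan(list(make_static_beam(0, 100)), fractions = 30L)
  pB <- make_plan(list(make_static_beam(90, 100)), fractions = 1L)
  w <- aggregate_use_factors(list(pA, pB), bin_scheme(90),
                             weight_fractions = TRUE)
  u <- aggregate_use_factors(list(pA, pB), bin_scheme(90),
                             weight_fractions = FALSE)
  expect_equal(unname(usefactor_row(w))[1:2], c(3000, 100) / 3100 * 100)
  expect_equal(unname(usefactor_row(u))[1:2], c(50, 50))
  # equal fraction counts: global constant cancels
  pC <- make_plan(list(make_static_beam(90, 100)), fractions = 30L)
  w2 <- aggregate_use_factors(list(pA, pC), bin_scheme(90))
  u2 <- aggregate_use_factors(list(pA, pC), bin_scheme(90),
                              weight_fractions = FALSE)
  expect_equal(usefactor_row(w2), usefactor_row(u2), tolerance = 1e-12)
})

test_that("rows sum to 100 and MU-weighted technique rows give the ALL row", {
  set.seed(42)
  plans <- lapply(1:20, function(i)
    make_plan(list(random_beam()), fractions = sample(1:30, 1),
              site = sample(c("breast", "pelvis", "chest"), 1)))
  tab <- aggregate_use_factors(plans, bin_scheme(30))
  expect_true(all(abs(rowSums(tab$pct) - 100) < 1e-6))
  tech <- tab$strata$technique != "ALL" & tab$strata$site == "ALL"
  wts <- tab$strata$mu_total[tech]
  blended <- colSums(tab$pct[tech, , drop = FALSE] * wts) / sum(wts)
  expect_equal(unname(blended), unname(usefactor_row(tab)),
               tolerance = 1e-9)
})

test_that("rendering rounds half-up and orders bins from 0 degrees", {
  h <- bin_segments(
    angular_segments(c(0, 90, 180), c(0, 0, 0), rep("POINT", 3),
                     c(1, 1, 1)), bin_scheme(90))
  p <- make_plan(list(make_static_beam(0, 1, beam_number = 1L),
                      make_static_beam(90, 1, beam_number = 2L),
                      make_static_beam(180, 1, beam_number = 3L)))
  tab <- aggregate_use_factors(list(p), bin_scheme(90))
  r <- render_usefactor_table(tab, decimals = 1)
  all_row <- r[r$technique == "ALL" & r$site == "ALL", ]
  expect_identical(unname(unlist(all_row[c("0", "90", "180", "270")])),
                   c("33.3", "33.3", "33.3", "0.0"))
  # half-up at the .5 boundary, where round() would go to even
  expect_equal(usefactor:::round_half_up(0.25, 1), 0.3)
  expect_equal(usefactor:::round_half_up(40.05, 1), 40.1)
  expect_equal(usefactor:::round_half_up(-0.25, 1), -0.3)
})

test_that("CSV and JSON writers round-trip the table", {
  d <- withr::local_tempdir()
  p <- make_plan(list(make_static_beam(0, 200, 1L),
                      make_static_beam(90, 300, 2L)))
  tab <- aggregate_use_factors(list(p), bin_scheme(90))
  csv <- file.path(d, "t.csv")
  write_usefactor_csv(tab, csv)
  back <- read_usefactor_csv(csv)
  expect_equal(back$pct, tab$pct, ignore_attr = TRUE)
  expect_equal(back$strata$mu_total, tab$strata$mu_total)
  js <- file.path(d, "t.json")
  write_usefactor_json(tab, js)
  j <- jsonlite::fromJSON(js)
  expect_equal(j$width_deg, 90)
  expect_equal(
    unlist(j$strata$use_factor_pct[j$strata$technique == "ALL" &
                                     j$strata$site == "ALL", ]),
    c(`0` = 40, `90` = 60, `180` = 0, `270` = 0))
})
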