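# DICOM encoding layer: generator round-trips and conformance against an
# independent DICOM implementation (pydicom)

test_that("generated plans round-trip through the reader exactly", {
  set.seed(11)
  d <- withr::local_tempdir()
  specs <- list(
    synthetic_plan_spec("3D-CRT",
                        list(synthetic_beam(0, mu = 200),
                             synthetic_beam(90, mu = 300)),
                        fractions = 5, site = "breast"),
    synthetic_plan_spec("IMRT",
                        list(synthetic_beam(200, mu = 123.456,
                                            n_control_points = 12)),
                        fractions = 25),
    synthetic_plan_spec("VMAT",
                        list(synthetic_beam(181, 179, mu = 333.3,
                                            direction = "CW",
                                            n_control_points = 40)),
                        fractions = 30, include_setup = TRUE)
  )
  for (i in seq_along(specs)) {
    f <- generate_plan(specs[[i]], file.path(d, sprintf("p%d.dcm", i)),
                       seed = 100 + i)
    plan <- read_rtplan(f$path)
    spec <- specs[[i]]
    n_expected <- length(spec$beams) + spec$include_setup
    expect_length(plan$beams, n_expected)
    expect_identical(plan$number_of_fractions_planned, spec$fractions)
    for (j in seq_along(spec$beams)) {
      b <- plan$beams[[j]]
      expect_equal(b$beam_meterset_mu, spec$beams[[j]]$mu, tolerance = 1e-9)
      expect_true(b$beam_dose_present)
      cp <- b$control_points
      expect_equal(nrow(cp), spec$beams[[j]]$n_control_points)
      expect_true(all(diff(cp$cumulative_meterset_weight) >= 0))
      expect_equal(cp$cumulative_meterset_weight[nrow(cp)], 1,
                   tolerance = 1e-9)
      expect_true(all(cp$gantry_angle_deg >= 0 & cp$gantry_angle_deg < 360))
    }
  }
})

test_that("pydicom parses generated files to the same values", {
  d <- withr::local_tempdir()
  spec <- synthetic_plan_spec("VMAT",
    list(synthetic_beam(350, 10, mu = 60, direction = "CW",
                        n_control_points = 6)),
    fractions = 3, include_setup = TRUE)
  f <- generate_plan(spec, file.path(d, "p.dcm"), seed = 9)
  py <- file.path(d, "dump.py")
  writeLines(c(
    "import json, sys, pydicom",
    "ds = pydicom.dcmread(sys.argv[1])",
    "b = ds.BeamSequence[0]",
    "rb = ds.FractionGroupSequence[0].ReferencedBeamSequence",
    "print(json.dumps({",
    " 'sop': str(ds.SOPClassUID),",
    " 'fractions': int(ds.FractionGroupSequence[0].NumberOfFractionsPlanned),",
    " 'metersets': [float(r.BeamMeterset) for r in rb],",
    " 'dose_present': [hasattr(r, 'BeamDose') for r in rb],",
    " 'beam_type': str(b.BeamType),",
    " 'angles': [float(c.GantryAngle) for c in b.ControlPointSequence],",
    " 'weights': [float(c.CumulativeMetersetWeight) for c in b.ControlPointSequence]}))"
  ), py)
  out <- system2("python", c(py, f$path), stdout = TRUE)
  got <- jsonlite::fromJSON(paste(out, collapse = ""))
  plan <- read_rtplan(f$path)
  cp <- plan$beams[[1]]$control_points
  expect_identical(got$sop, "1.2.840.10008.5.1.4.1.1.481.5")
  expect_identical(got$fractions, 3L)
  expect_equal(got$metersets, c(60, 1))
  expect_identical(got$dose_present, c(TRUE, FALSE))
  expect_identical(got$beam_type, "DYNAMIC")
  expect_equal(got$angles, cp$gantry_angle_deg, tolerance = 1e-9)
  expect_equal(got$weights, cp$cumulative_meterset_weight, tolerance = 1e-9)
})

test_that("implicit VR little endian files are readable", {
  d <- withr::local_tempdir()
  spec <- synthetic_plan_spec("3D-CRT", list(synthetic_beam(270, mu = 80)),
                              fractions = 2)
  f <- generate_plan(spec, file.path(d, "p.dcm"), seed = 3)
  py <- file.path(d, "conv.py")
  writeLines(c(
    "import sys, pydicom",
    "from pydicom.uid import ImplicitVRLittleEndian",
    "ds = pydicom.dcmread(sys.argv[1])",
    "ds.file_meta.TransferSyntaxUID = ImplicitVRLittleEndian",
    "ds.save_as(sys.argv[2], implicit_vr=True, little_endian=True,",
    "           enforce_file_format=True)"), py)
  implicit <- file.path(d, "implicit.dcm")
  system2("python", c(py, f$path, implicit))
  p1 <- read_rtplan(f$path); p2 <- read_rtplan(implicit)
  expect_equal(p2$beams[[1]]$beam_meterset_mu, 80)
  expect_equal(p2$beams[[1]]$control_points$gantry_angle_deg,
               p1$beams[[1]]$control_points$gantry_angle_deg)
  expect_identical(p2$number_of_fractions_planned, 2L)
})

test_that("non-DICOM and wrong-SOP files raise the typed error", {
  d <- withr::local_tempdir()
  txt <- file.path(d, "notdicom.txt")
  writeLines("just text", txt)
  expect_error(read_rtplan(txt), class = "uf_not_rtplan")
  expect_error(read_rtplan(file.path(d, "absent.dcm")), "not found")
})
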