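Package: usefactor
Title: Gantry-Angle Use Factors from DICOM-RT Plan Files
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes radiotherapy vault shielding use factors directly from
    DICOM RT Plan files. Parses beams, fraction groups and control-point
    sequences, distributes each treatment beam's monitor units (MU) over
    gantry angle, bins them into configurable angular interval schemes
    (90, 45, 30 or 10 degrees), stratifies results by treatment technique
    (3D-CRT, IMRT, VMAT) and treatment site, and compares the resulting
    use factors against the reference values published in NCRP 151 and
    related shielding reports. Includes a synthetic RT Plan generator with
    known ground-truth angular MU distributions and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
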