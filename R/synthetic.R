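# Synthetic RT Plan generation.
#
# Emits conformant DICOM Part 10 RT Plan files with known ground-truth
# angular MU distributions, so the whole pipeline can be exercised without
# clinical data. Arcs deliver uniform MU per degree (matching the binning
# model) but are written with irregular control-point spacing, so the
# reader and apportionment code see unequal weight increments. Cohorts
# emulate a mixed radiotherapy caseload: a technique mix over 3D-CRT /
# IMRT / VMAT, a treatment-site mix, and per-plan fraction counts.

#' Describe one synthetic beam
#'
#' @param gantry_start_deg start (or only) gantry angle in degrees.
#' @param gantry_stop_deg arc stop angle; `NA` for static/fixed-gantry
#'   beams.
#' @param direction `"CW"` or `"CC"` for arcs, `"NONE"` otherwise.
#' @param mu beam meterset in MU (per fraction), > 0.
#' @param n_control_points number of control points (>= 2).
#' @return list of class `synthetic_beam`.
#' @export
synthetic_beam <- function(gantry_start_deg, gantry_stop_deg = NA, mu = 100,
                           direction = if (is.na(gantry_stop_deg)) "NONE" else "CW",
                           n_control_points = if (is.na(gantry_stop_deg)) 2L else 20L) {
  if (mu <= 0) stop("mu must be positive")
  if (n_control_points < 2) stop("n_control_points must be >= 2")
  if (!is.na(gantry_stop_deg) && !(direction %in% c("CW", "CC"))) {
    stop("arc beams need direction CW or CC")
  }
  structure(list(gantry_start_deg = normalize_angle(gantry_start_deg),
                 gantry_stop_deg = if (is.na(gantry_stop_deg)) NA_real_ else
                   normalize_angle(gantry_stop_deg),
                 direction = direction, mu = mu,
                 n_control_points = as.integer(n_control_points)),
            class = "synthetic_beam")
}

#' Describe one synthetic plan
#'
#' @param technique `"3D-CRT"`, `"IMRT"` or `"VMAT"`; checked against the
#'   beams (arcs require VMAT, fixed-gantry beams forbid it).
#' @param beams list of [synthetic_beam()] descriptions.
#' @param fractions planned fraction count (positive integer).
#' @param site treatment site label.
#' @param patient_key anonymized patient identifier.
#' @param label plan label.
#' @param include_setup also emit a setup field (referenced in the fraction
#'   group without a beam dose entry, so it must be excluded by the
#'   treatment-beam rule).
#' @return list of class `synthetic_plan_spec`.
#' @export
synthetic_plan_spec <- function(technique, beams, fractions = 1L,
                                site = "other", patient_key = "ANON",
                                label = "synthetic", include_setup = FALSE) {
  if (!(technique %in% TECHNIQUES)) {
    stop("technique must be one of ", paste(TECHNIQUES, collapse = ", "))
  }
  if (fractions < 1) stop("fractions must be a positive integer")
  if (!length(beams)) stop("at least one beam required")
  for (b in beams) {
    arc <- !is.na(b$gantry_stop_deg)
    if (arc && technique != "VMAT") {
      stop("arc beams (gantry_stop_deg set) require technique VMAT")
    }
    if (!arc && technique == "VMAT") {
      stop("VMAT beams need gantry_stop_deg")
    }
  }
  structure(list(technique = technique, beams = beams,
                 fractions = as.integer(fractions), site = site,
                 patient_key = patient_key, label = label,
                 include_setup = isTRUE(include_setup)),
            class = "synthetic_plan_spec")
}

# travel span of an arc beam spec in degrees; full 360 when start == stop
.arc_span <- function(b) {
  s <- if (b$direction == "CW") {
    (b$gantry_stop_deg - b$gantry_start_deg) %% 360
  } else {
    (b$gantry_start_deg - b$gantry_stop_deg) %% 360
  }
  if (s == 0) 360 else s
}

# control-point table for one synthetic beam: irregular angular spacing,
# weights proportional to angular progress (uniform MU per degree)
.synth_cp <- function(b, rng_jitter = TRUE) {
  n <- b$n_control_points
  if (is.na(b$gantry_stop_deg)) {
    ang <- rep(b$gantry_start_deg, n)
    w <- if (n == 2L) c(0, 1) else {
      # fixed-gantry dynamic beams get irregular positive weight steps
      wi <- cumsum(c(0, stats::runif(n - 1L, 0.2, 1)))
      wi / wi[n]
    }
    rot <- rep("NONE", n)
  } else {
    span <- .arc_span(b)
    prog <- if (rng_jitter && n > 2L) {
      g <- stats::runif(n - 1L, 0.2, 1)
      cumsum(c(0, g)) / sum(g)
    } else {
      seq(0, 1, length.out = n)
    }
    sgn <- if (b$direction == "CW") 1 else -1
    ang <- normalize_angle(b$gantry_start_deg + sgn * prog * span)
    w <- prog
    rot <- rep(b$direction, n)
  }
  data.frame(index = seq_len(n) - 1L, gantry_angle_deg = ang,
             rotation_direction = rot, cumulative_meterset_weight = w)
}

.beam_item_bytes <- function(beam_number, beam_type, cp, name) {
  cp_items <- lapply(seq_len(nrow(cp)), function(i) c(
    dcm_element(0x300A, 0x0112, "IS", cp$index[i]),
    dcm_element(0x300A, 0x011E, "DS", cp$gantry_angle_deg[i]),
    dcm_element(0x300A, 0x011F, "CS", cp$rotation_direction[i]),
    dcm_element(0x300A, 0x0134, "DS", cp$cumulative_meterset_weight[i])
  ))
  c(
    dcm_element(0x300A, 0x00C0, "IS", beam_number),
    dcm_element(0x300A, 0x00C2, "LO", name),
    dcm_element(0x300A, 0x00C4, "CS", beam_type),
    dcm_element(0x300A, 0x00C6, "CS", "PHOTON"),
    dcm_element(0x300A, 0x00CE, "CS",
                if (grepl("setup", name)) "SETUP" else "TREATMENT"),
    dcm_element(0x300A, 0x010E, "DS",
                cp$cumulative_meterset_weight[nrow(cp)]),
    dcm_element(0x300A, 0x0110, "IS", nrow(cp)),
    dcm_sequence(0x300A, 0x0111, cp_items)
  )
}

#' Generate a DICOM RT Plan file from a synthetic spec
#'
#' Writes an explicit-VR-little-endian RT Plan instance and returns the
#' analytic ground-truth angular MU distribution implied by the spec under
#' the uniform-MU-per-degree arc model.
#'
#' @param spec a [synthetic_plan_spec()].
#' @param path output file path.
#' @param seed optional integer; fixes the control-point jitter so the file
#'   is reproducible.
#' @return list with `path`, `spec` and `ground_truth`, a function
#'   `(scheme, weight_fractions = TRUE)` returning the exact
#'   `mu_histogram` the file should produce.
#' @export
generate_plan <- function(spec, path, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  uid <- dcm_make_uid(paste0(spec$label, "|", spec$patient_key, "|",
                             basename(path)))
  beams_bytes <- list(); ref_items <- list()
  bn <- 0L
  for (b in spec$beams) {
    bn <- bn + 1L
    cp <- .synth_cp(b)
    btype <- if (is.na(b$gantry_stop_deg) && b$n_control_points == 2L)
      "STATIC" else "DYNAMIC"
    beams_bytes[[bn]] <- .beam_item_bytes(bn, btype, cp,
                                          sprintf("beam%02d", bn))
    ref_items[[bn]] <- c(
      dcm_element(0x300A, 0x0084, "DS", 2.0),
      dcm_element(0x300A, 0x0086, "DS", b$mu),
      dcm_element(0x300C, 0x0006, "IS", bn)
    )
  }
  if (spec$include_setup) {
    bn <- bn + 1L
    cp <- data.frame(index = 0:1, gantry_angle_deg = 0,
                     rotation_direction = "NONE",
                     cumulative_meterset_weight = c(0, 1))
    beams_bytes[[bn]] <- .beam_item_bytes(bn, "STATIC", cp, "setup")
    # referenced without a BeamDose entry: must fail the treatment-beam rule
    ref_items[[bn]] <- c(
      dcm_element(0x300A, 0x0086, "DS", 1.0),
      dcm_element(0x300C, 0x0006, "IS", bn)
    )
  }
  fg_item <- c(
    dcm_element(0x300A, 0x0071, "IS", 1L),
    dcm_element(0x300A, 0x0078, "IS", spec$fractions),
    dcm_element(0x300A, 0x0080, "IS", bn),
    dcm_sequence(0x300C, 0x0004, ref_items)
  )
  dataset <- c(
    dcm_element(0x0008, 0x0016, "UI", UID_RTPLAN_STORAGE),
    dcm_element(0x0008, 0x0018, "UI", uid),
    dcm_element(0x0008, 0x0060, "CS", "RTPLAN"),
    dcm_element(0x0010, 0x0020, "LO", spec$patient_key),
    dcm_element(0x300A, 0x0002, "SH", substr(spec$label, 1, 16)),
    dcm_sequence(0x300A, 0x0070, list(fg_item)),
    dcm_sequence(0x300A, 0x00B0, beams_bytes)
  )
  dcm_write_file(path, dataset, UID_RTPLAN_STORAGE, uid)
  spec_local <- spec
  gt <- function(scheme, weight_fractions = TRUE) {
    ground_truth_histogram(spec_local, scheme, weight_fractions)
  }
  list(path = path, spec = spec, plan_uid = uid, ground_truth = gt)
}

#' Analytic ground-truth histogram of a synthetic plan spec
#'
#' Computed directly from the beam descriptions (point deposits for fixed
#' beams, uniform MU per degree over the arc for rotating beams), without
#' going through control points or DICOM encoding.
#'
#' @param spec a [synthetic_plan_spec()].
#' @param scheme a [bin_scheme()].
#' @param weight_fractions multiply by the planned fraction count.
#' @return `mu_histogram`.
#' @export
ground_truth_histogram <- function(spec, scheme, weight_fractions = TRUE) {
  fw <- if (weight_fractions) spec$fractions else 1
  segs <- do.call(rbind, lapply(spec$beams, function(b) {
    if (is.na(b$gantry_stop_deg)) {
      angular_segments(b$gantry_start_deg, 0, "POINT", b$mu * fw)
    } else {
      angular_segments(b$gantry_start_deg, .arc_span(b), b$direction,
                       b$mu * fw)
    }
  }))
  bin_segments(segs, scheme)
}

# one random plan spec per technique, emulating typical field arrangements
.random_plan_spec <- function(technique, site, label, patient_key) {
  fractions <- sample(c(1L, 5L, 10L, 15L, 25L, 30L), 1L)
  beams <- switch(technique,
    "3D-CRT" = {
      nb <- sample(2:4, 1L)
      lapply(seq_len(nb), function(i) {
        synthetic_beam(sample(seq(0, 355, by = 5), 1L),
                       mu = stats::runif(1, 50, 150))
      })
    },
    "IMRT" = {
      nb <- sample(5:9, 1L)
      lapply(seq_len(nb), function(i) {
        synthetic_beam(sample(seq(0, 355, by = 5), 1L),
                       mu = stats::runif(1, 80, 250),
                       n_control_points = sample(10:40, 1L))
      })
    },
    "VMAT" = {
      nb <- sample(1:2, 1L)
      lapply(seq_len(nb), function(i) {
        full <- stats::runif(1) < 0.5
        if (full) {
          s <- sample(seq(0, 355, by = 5), 1L)
          synthetic_beam(s, s, mu = stats::runif(1, 150, 450),
                         direction = sample(c("CW", "CC"), 1L),
                         n_control_points = sample(30:90, 1L))
        } else {
          s <- sample(seq(0, 355, by = 5), 1L)
          span <- stats::runif(1, 60, 350)
          dir <- sample(c("CW", "CC"), 1L)
          e <- if (dir == "CW") s + span else s - span
          synthetic_beam(s, e, mu = stats::runif(1, 150, 450),
                         direction = dir,
                         n_control_points = sample(30:90, 1L))
        }
      })
    },
    stop("unknown technique ", technique))
  synthetic_plan_spec(technique, beams, fractions = fractions, site = site,
                      patient_key = patient_key, label = label,
                      include_setup = stats::runif(1) < 0.3)
}

#' Generate a synthetic cohort of RT Plan files
#'
#' Draws plans from a technique mix and a site mix, writes one DICOM RT
#' Plan file per plan under `dir`, and returns the analytic ground-truth
#' use factors per stratum (computed directly from the specs, not from the
#' files). Random streams are seeded per plan as `seed + plan index`, so
#' any single plan can be regenerated in isolation and the cohort is fully
#' reproducible.
#'
#' @param mix named numeric vector of technique proportions (names among
#'   `"3D-CRT"`, `"IMRT"`, `"VMAT"`); must sum to 1.
#' @param n_plans number of plans (> 0).
#' @param dir output directory (created if needed).
#' @param site_mix named proportions over the site vocabulary; must sum
#'   to 1.
#' @param seed integer cohort seed.
#' @param write_ground_truth also write `ground_truth.json` beside the
#'   cohort.
#' @return list with `dir`, `files`, `specs`, `site_map` (path of the
#'   emitted `site_map.csv`, since treatment site is not a DICOM RT Plan
#'   attribute) and `ground_truth` (exact per-stratum use factors per
#'   supported scheme width).
#' @export
generate_cohort <- function(mix, n_plans, dir,
                            site_mix = c(other = 1), seed = 1L,
                            write_ground_truth = TRUE) {
  if (n_plans <= 0) stop("n_plans must be positive")
  mix <- unlist(mix); site_mix <- unlist(site_mix)
  if (abs(sum(mix) - 1) > 1e-9) {
    stop("mix proportions must sum to 1 (got ", sum(mix), ")")
  }
  if (abs(sum(site_mix) - 1) > 1e-9) {
    stop("site_mix proportions must sum to 1 (got ", sum(site_mix), ")")
  }
  if (!all(names(mix) %in% TECHNIQUES)) {
    stop("mix names must be among ", paste(TECHNIQUES, collapse = ", "))
  }
  if (!all(names(site_mix) %in% SITE_VOCABULARY)) {
    stop("site_mix names must be in the site vocabulary")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  techs <- sample(names(mix), n_plans, replace = TRUE, prob = mix)
  sites <- sample(names(site_mix), n_plans, replace = TRUE, prob = site_mix)
  specs <- vector("list", n_plans); files <- character(n_plans)
  for (i in seq_len(n_plans)) {
    set.seed(seed + i)
    spec <- .random_plan_spec(techs[i], sites[i],
                              label = sprintf("syn%04d", i),
                              patient_key = sprintf("PT%04d", i))
    out <- generate_plan(spec, file.path(dir, sprintf("plan%04d.dcm", i)))
    specs[[i]] <- spec; files[i] <- out$path
  }
  gt <- cohort_ground_truth(specs)
  # treatment site is not a DICOM RT Plan attribute; ship the mapping the
  # pipeline expects as a site-map CSV next to the cohort
  site_map_path <- file.path(dir, "site_map.csv")
  utils::write.csv(
    data.frame(patient_key = vapply(specs, `[[`, "", "patient_key"),
               site = vapply(specs, `[[`, "", "site")),
    site_map_path, row.names = FALSE, quote = FALSE)
  if (write_ground_truth) {
    jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(dir = dir, files = files, specs = specs, ground_truth = gt,
       site_map = site_map_path)
}

#' Exact stratified use factors implied by a list of synthetic specs
#'
#' @param specs list of [synthetic_plan_spec()] objects.
#' @param widths bin widths to tabulate (default all four).
#' @param weight_fractions multiply by planned fraction counts.
#' @return named list (one element per width) of lists keyed
#'   `"technique|site"` (with `"ALL"` margins) holding `use_factor_pct`
#'   and `mu_total`.
#' @export
cohort_ground_truth <- function(specs, widths = c(90, 45, 30, 10),
                                weight_fractions = TRUE) {
  out <- list()
  for (w in widths) {
    scheme <- bin_scheme(w)
    acc <- list()
    for (spec in specs) {
      h <- ground_truth_histogram(spec, scheme, weight_fractions)
      for (key in c(paste0(spec$technique, "|", spec$site),
                    paste0(spec$technique, "|ALL"),
                    paste0("ALL|", spec$site), "ALL|ALL")) {
        acc[[key]] <- if (is.null(acc[[key]])) h$mu_per_bin else
          acc[[key]] + h$mu_per_bin
      }
    }
    out[[as.character(w)]] <- lapply(acc, function(mu) {
      list(mu_total = sum(mu),
           use_factor_pct = as.numeric(mu / sum(mu) * 100))
    })
  }
  out
}

#' Read a cohort spec YAML
#'
#' Fields: `mix` (named technique proportions), `n_plans`, `site_mix`
#' (optional), `seed` (optional, default 1).
#'
#' @param path YAML file.
#' @return validated argument list for [generate_cohort()].
#' @export
read_cohort_spec <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$mix)) stop("cohort spec: missing field 'mix'")
  mix <- unlist(y$mix)
  if (abs(sum(mix) - 1) > 1e-9) {
    stop("cohort spec: 'mix' proportions must sum to 1 (got ", sum(mix), ")")
  }
  if (is.null(y$n_plans) || y$n_plans <= 0) {
    stop("cohort spec: 'n_plans' must be a positive integer")
  }
  list(mix = mix, n_plans = as.integer(y$n_plans),
       site_mix = if (is.null(y$site_mix)) c(other = 1) else
         unlist(y$site_mix),
       seed = if (is.null(y$seed)) 1L else as.integer(y$seed))
}
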