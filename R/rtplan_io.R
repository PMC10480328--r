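# Reading DICOM RT Plan files into validated in-memory records.
#
# A plan is represented as a list of class "rtplan": metadata plus a list of
# "beam_record" objects. Beam geometry comes from the Beam Sequence
# (300A,00B0); the per-beam meterset in MU and the presence of a beam dose
# come from the Fraction Group Sequence's Referenced Beam Sequence
# (300C,0004), joined on the referenced beam number — that is where DICOM
# stores per-beam MU. Gantry angles follow IEC 61217 (0 deg = beam pointing
# down from above, increasing clockwise seen from the couch) and are
# normalized to [0, 360); 360 maps to 0.

SITE_VOCABULARY <- c("breast", "H&N", "abdomen", "chest", "pelvis", "spine",
                     "extremity", "other")

normalize_angle <- function(a) {
  a <- a %% 360
  a[a == 360] <- 0
  a
}

new_beam_record <- function(beam_number, beam_type, radiation_type,
                            beam_meterset_mu, beam_dose_present,
                            final_cumulative_meterset_weight, control_points,
                            delivery_type = NA_character_,
                            beam_name = NA_character_) {
  structure(list(
    beam_number = as.integer(beam_number),
    beam_type = beam_type,
    radiation_type = radiation_type,
    beam_meterset_mu = beam_meterset_mu,
    beam_dose_present = isTRUE(beam_dose_present),
    final_cumulative_meterset_weight = final_cumulative_meterset_weight,
    control_points = control_points,
    delivery_type = delivery_type,
    beam_name = beam_name
  ), class = "beam_record")
}

new_rtplan <- function(plan_uid, plan_label, patient_key,
                       number_of_fractions_planned, beams,
                       site = NA_character_, source_path = NA_character_) {
  nums <- vapply(beams, function(b) b$beam_number, integer(1))
  if (anyDuplicated(nums)) {
    stop_validation(sprintf("duplicate beam number(s) in plan %s: %s",
                            plan_uid,
                            paste(nums[duplicated(nums)], collapse = ", ")))
  }
  structure(list(
    plan_uid = plan_uid,
    plan_label = plan_label,
    patient_key = patient_key,
    number_of_fractions_planned = as.integer(number_of_fractions_planned),
    beams = beams,
    site = site,
    source_path = source_path
  ), class = "rtplan")
}

.cp_table <- function(cp_items) {
  n <- length(cp_items)
  idx <- integer(n); ang <- numeric(n); rot <- character(n); w <- numeric(n)
  last_ang <- NA_real_; last_rot <- "NONE"
  for (i in seq_len(n)) {
    it <- cp_items[[i]]
    idx[i] <- dcm_get(it, "300A0112", i - 1L)[1]
    a <- dcm_get(it, "300A011E")
    # gantry angle / rotation direction may be encoded only when they change
    if (!is.null(a)) last_ang <- a[1]
    r <- dcm_get(it, "300A011F")
    if (!is.null(r) && nzchar(r[1])) last_rot <- r[1]
    ang[i] <- last_ang
    rot[i] <- last_rot
    w[i] <- dcm_get(it, "300A0134", NA_real_)[1]
  }
  data.frame(index = idx,
             gantry_angle_deg = normalize_angle(ang),
             rotation_direction = rot,
             cumulative_meterset_weight = w)
}

#' Read a DICOM RT Plan file
#'
#' Parses a DICOM Part 10 RT Plan instance into an `rtplan` record. Beams
#' are joined to their fraction-group referenced-beam entries by beam number
#' to resolve the per-beam meterset (MU) and whether a beam dose value is
#' present; beams never referenced by a fraction group (e.g. setup fields)
#' carry no meterset and are not treatment beams.
#'
#' @param path path to a DICOM RT Plan file (implicit or explicit VR little
#'   endian).
#' @return an object of class `rtplan` with elements `plan_uid`,
#'   `plan_label`, `patient_key`, `number_of_fractions_planned`, `beams`
#'   (list of `beam_record`) and `site` (`NA` until assigned).
#' @examples
#' spec <- synthetic_plan_spec("3D-CRT",
#'   beams = list(synthetic_beam(0, mu = 200)), fractions = 1)
#' f <- generate_plan(spec, tempfile(fileext = ".dcm"))
#' plan <- read_rtplan(f$path)
#' plan$beams[[1]]$beam_meterset_mu
#' @export
read_rtplan <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- dcm_read_file(path)
  sop <- dcm_get(d$dataset, "00080016",
                 dcm_get(d$meta, "00020002", ""))
  if (!identical(sop, UID_RTPLAN_STORAGE)) {
    stop_not_rtplan(path, paste0("SOP class ", sop))
  }
  ds <- d$dataset

  # fraction groups: meterset and beam-dose presence per referenced beam
  fg_items <- dcm_get(ds, "300A0070", list())
  n_fractions <- 1L
  ref <- new.env(parent = emptyenv())
  if (length(fg_items)) {
    nf <- dcm_get(fg_items[[1]], "300A0078")
    if (!is.null(nf) && is.finite(nf[1]) && nf[1] >= 1) n_fractions <- nf[1]
    for (fg in fg_items) {
      for (rb in dcm_get(fg, "300C0004", list())) {
        bn <- dcm_get(rb, "300C0006")
        if (is.null(bn)) next
        key <- as.character(bn[1])
        prev <- if (exists(key, envir = ref)) get(key, envir = ref) else
          list(meterset = NA_real_, dose_present = FALSE)
        ms <- dcm_get(rb, "300A0086")
        if (!is.null(ms)) {
          prev$meterset <- sum(c(if (is.finite(prev$meterset)) prev$meterset,
                                 ms[1]))
        }
        prev$dose_present <- prev$dose_present || dcm_has(rb, "300A0084")
        assign(key, prev, envir = ref)
      }
    }
  }

  beam_items <- dcm_get(ds, "300A00B0", list())
  beams <- vector("list", length(beam_items))
  seen <- character(0)
  for (i in seq_along(beam_items)) {
    bi <- beam_items[[i]]
    bn <- dcm_get(bi, "300A00C0", NA_integer_)[1]
    key <- as.character(bn)
    seen <- c(seen, key)
    entry <- if (exists(key, envir = ref)) get(key, envir = ref) else
      list(meterset = NA_real_, dose_present = FALSE)
    cps <- .cp_table(dcm_get(bi, "300A0111", list()))
    beams[[i]] <- new_beam_record(
      beam_number = bn,
      beam_type = dcm_get(bi, "300A00C4", "STATIC")[1],
      radiation_type = dcm_get(bi, "300A00C6", "PHOTON")[1],
      beam_meterset_mu = entry$meterset,
      beam_dose_present = entry$dose_present,
      final_cumulative_meterset_weight = dcm_get(bi, "300A010E", NA_real_)[1],
      control_points = cps,
      delivery_type = dcm_get(bi, "300A00CE", NA_character_)[1],
      beam_name = dcm_get(bi, "300A00C2", NA_character_)[1]
    )
  }
  missing_refs <- setdiff(ls(envir = ref), seen)
  if (length(missing_refs)) {
    stop_validation(sprintf(
      "fraction group references beam number(s) %s absent from the beam sequence",
      paste(sort(as.integer(missing_refs)), collapse = ", ")))
  }

  new_rtplan(
    plan_uid = dcm_get(ds, "00080018", basename(path)),
    plan_label = dcm_get(ds, "300A0002", ""),
    patient_key = dcm_get(ds, "00100020", ""),
    number_of_fractions_planned = n_fractions,
    beams = beams,
    source_path = path
  )
}

#' Is a beam a treatment beam?
#'
#' A beam contributes MU to the use factor only if its fraction-group entry
#' carries a beam dose value and a positive meterset. Setup and imaging
#' fields fail this test. When a `TreatmentDeliveryType` label is present and
#' disagrees, a message is emitted but the dose/meterset rule decides.
#'
#' @param beam a `beam_record`.
#' @return `TRUE` or `FALSE`.
#' @export
is_treatment_beam <- function(beam) {
  ok <- isTRUE(beam$beam_dose_present) &&
    is.finite(beam$beam_meterset_mu) && beam$beam_meterset_mu > 0
  dt <- beam$delivery_type
  if (!is.na(dt) && nzchar(dt)) {
    label_says <- identical(dt, "TREATMENT")
    if (label_says != ok) {
      message(sprintf(
        "beam %d: delivery type '%s' disagrees with dose/meterset rule (%s)",
        beam$beam_number, dt, if (ok) "treatment" else "non-treatment"))
    }
  }
  ok
}

#' Validate a parsed RT plan
#'
#' Collects structural findings that would make MU apportionment ambiguous
#' or wrong: non-monotone cumulative meterset weights, a `NONE` rotation
#' direction across control points whose gantry angle changes (the traveled
#' path, hence the binning, would be ambiguous), a dose-bearing beam with no
#' meterset, a final cumulative weight that disagrees with the last control
#' point, and a STATIC beam whose gantry angle varies.
#'
#' @param plan an `rtplan`.
#' @return a data frame with columns `beam_number`, `severity`
#'   (`"error"`/`"warning"`), `code`, `message`; zero rows if clean.
#' @export
validate_plan <- function(plan) {
  out <- list()
  add <- function(bn, severity, code, msg) {
    out[[length(out) + 1L]] <<- data.frame(
      beam_number = bn, severity = severity, code = code, message = msg)
  }
  for (b in plan$beams) {
    cp <- b$control_points
    if (isTRUE(b$beam_dose_present) && !is.finite(b$beam_meterset_mu)) {
      add(b$beam_number, "warning", "missing_meterset",
          "beam dose present but no meterset value")
    }
    if (nrow(cp) < 2) next
    w <- cp$cumulative_meterset_weight
    if (any(diff(w) < 0)) {
      add(b$beam_number, "error", "nonmonotone_weight",
          "cumulative meterset weight decreases between control points")
    }
    ang <- cp$gantry_angle_deg
    moving <- which(abs(diff(ang)) > 1e-9)
    if (length(moving)) {
      dirs <- cp$rotation_direction[moving]
      if (any(dirs == "NONE")) {
        add(b$beam_number, "error", "ambiguous_rotation",
            "gantry angle changes but rotation direction is NONE")
      }
    }
    if (identical(b$beam_type, "STATIC") && length(moving)) {
      add(b$beam_number, "warning", "static_gantry_varies",
          "STATIC beam with varying gantry angle")
    }
    fin <- b$final_cumulative_meterset_weight
    if (is.finite(fin) && fin > 0) {
      if (abs(w[length(w)] - fin) > 1e-6 * fin) {
        add(b$beam_number, "warning", "final_weight_mismatch",
            "last cumulative weight differs from final cumulative meterset weight")
      }
    }
  }
  if (!length(out)) {
    data.frame(beam_number = integer(0), severity = character(0),
               code = character(0), message = character(0))
  } else {
    do.call(rbind, out)
  }
}

#' Read all RT plans under a directory
#'
#' Scans a directory tree for DICOM RT Plan instances. Files that are not
#' DICOM or not RT plans are skipped with a warning; plans whose validation
#' reports errors are skipped too (use [validate_plan()] directly to
#' inspect). Plans with zero treatment beams are kept but contribute nothing
#' downstream.
#'
#' @param dir directory to scan.
#' @param site_map optional data frame from [read_site_map()]; matched plans
#'   get their `site` assigned, unmatched plans get `"other"`.
#' @param recursive scan subdirectories (default `TRUE`).
#' @return list of `rtplan` objects, with attributes `n_skipped` and
#'   `skipped` (paths).
#' @export
read_rtplan_dir <- function(dir, site_map = NULL, recursive = TRUE) {
  if (!dir.exists(dir)) stop("directory not found: ", dir)
  files <- list.files(dir, recursive = recursive, full.names = TRUE)
  plans <- list(); skipped <- character(0)
  for (f in files) {
    p <- tryCatch(read_rtplan(f), error = function(e) e)
    if (inherits(p, "error")) {
      warning(sprintf("skipping %s: %s", f, conditionMessage(p)),
              call. = FALSE)
      skipped <- c(skipped, f)
      next
    }
    v <- validate_plan(p)
    if (any(v$severity == "error")) {
      warning(sprintf("skipping %s: %s", f,
                      paste(unique(v$message[v$severity == "error"]),
                            collapse = "; ")), call. = FALSE)
      skipped <- c(skipped, f)
      next
    }
    plans[[length(plans) + 1L]] <- p
  }
  if (!is.null(site_map)) plans <- lapply(plans, assign_site, site_map = site_map)
  attr(plans, "n_skipped") <- length(skipped)
  attr(plans, "skipped") <- skipped
  plans
}

#' Read a plan-to-site mapping table
#'
#' The mapping is a CSV with header `plan_uid,site` or `patient_key,site`.
#' Sites outside the controlled vocabulary (breast, H&N, abdomen, chest,
#' pelvis, spine, extremity, other) are coerced to `"other"` with a warning.
#'
#' @param path CSV path.
#' @return data frame with columns `key_field`, `key`, `site`.
#' @export
read_site_map <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  key_field <- intersect(c("plan_uid", "patient_key"), names(df))
  if (!length(key_field) || !("site" %in% names(df))) {
    stop("site map must have columns 'plan_uid,site' or 'patient_key,site'")
  }
  key_field <- key_field[1]
  site <- df$site
  bad <- !(site %in% SITE_VOCABULARY)
  if (any(bad)) {
    warning("site(s) outside vocabulary mapped to 'other': ",
            paste(unique(site[bad]), collapse = ", "), call. = FALSE)
    site[bad] <- "other"
  }
  data.frame(key_field = key_field, key = as.character(df[[key_field]]),
             site = site)
}

assign_site <- function(plan, site_map) {
  key <- plan[[site_map$key_field[1]]]
  hit <- match(key, site_map$key)
  plan$site <- if (is.na(hit)) "other" else site_map$site[hit]
  plan
}

#' @export
print.rtplan <- function(x, ...) {
  cat(sprintf("<rtplan> %s  label='%s'  fractions=%d  beams=%d (%d treatment)\n",
              x$plan_uid, x$plan_label, x$number_of_fractions_planned,
              length(x$beams),
              sum(vapply(x$beams, function(b)
                suppressMessages(is_treatment_beam(b)), logical(1)))))
  invisible(x)
}

#' @export
print.beam_record <- function(x, ...) {
  cat(sprintf("<beam_record> #%d %s %s  MU=%s  control points=%d\n",
              x$beam_number, x$beam_type, x$radiation_type,
              format(x$beam_meterset_mu), nrow(x$control_points)))
  invisible(x)
}
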