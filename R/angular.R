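# Angular MU apportionment.
#
# Each treatment beam becomes a set of MU-weighted angular segments: one
# POINT segment per static dwell, one moving segment per consecutive
# control-point pair of an arc. MU within a moving segment is spread
# uniformly per degree of gantry travel (simultaneous linear interpolation
# of angle and cumulative meterset weight). Segments are then binned into a
# scheme of equal angular intervals centered on 0, width, 2*width, ...
# degrees; each bin covers the half-open arc
# [center - width/2, center + width/2), so the 90-degree bin at 90 covers
# [45, 135). Moving segments are split analytically at bin boundaries;
# travel of 360 degrees or more is decomposed into full laps (which deposit
# uniformly) plus a remainder.

#' Angular bin scheme
#'
#' @param width_deg interval width in degrees; one of 90, 45, 30, 10.
#' @return object of class `bin_scheme` with `width_deg` and `centers`
#'   (0, width, ..., 360 - width).
#' @export
bin_scheme <- function(width_deg) {
  if (!(width_deg %in% c(90, 45, 30, 10))) {
    stop("width_deg must be one of 90, 45, 30, 10")
  }
  structure(list(width_deg = width_deg,
                 centers = seq(0, 360 - width_deg, by = width_deg)),
            class = "bin_scheme")
}

n_bins <- function(scheme) length(scheme$centers)

same_scheme <- function(a, b) isTRUE(all.equal(a$width_deg, b$width_deg))

#' Bin membership of an angle
#'
#' @param angle_deg angle(s) in degrees (any real; reduced mod 360).
#' @param scheme a [bin_scheme()].
#' @return 1-based bin index; bin `k` is centered at `(k-1) * width`.
#' @export
bin_index <- function(angle_deg, scheme) {
  w <- scheme$width_deg
  as.integer(floor(((angle_deg + w / 2) %% 360) / w)) + 1L
}

new_mu_histogram <- function(scheme, mu_per_bin) {
  stopifnot(length(mu_per_bin) == n_bins(scheme), all(mu_per_bin >= -1e-12))
  structure(list(scheme = scheme, mu_per_bin = as.numeric(mu_per_bin)),
            class = "mu_histogram")
}

#' Angular segments
#'
#' Builds the segment table consumed by [bin_segments()]. `direction` is
#' `"CW"` (gantry angle increasing), `"CC"` (decreasing) or `"POINT"`
#' (no travel; `span_deg` must be 0).
#'
#' @param start_deg start angle in degrees `[0, 360)`.
#' @param span_deg non-negative travel in degrees.
#' @param direction `"CW"`, `"CC"` or `"POINT"`.
#' @param mu MU carried by each segment.
#' @return data frame with those four columns.
#' @export
angular_segments <- function(start_deg, span_deg, direction, mu) {
  df <- data.frame(start_deg = normalize_angle(start_deg),
                   span_deg = span_deg, direction = direction, mu = mu)
  if (any(df$span_deg < 0) || any(df$mu < 0)) {
    stop("span_deg and mu must be non-negative")
  }
  if (any((df$direction == "POINT") != (df$span_deg == 0))) {
    stop("direction POINT iff span_deg == 0")
  }
  df
}

#' Convert a treatment beam into MU-weighted angular segments
#'
#' For each consecutive control-point pair the segment carries
#' `beam_meterset_mu * fraction_weight * dw / final_cumulative_meterset_weight`
#' MU, where `dw` is the cumulative-weight increment. Geometry follows the
#' gantry from the first angle to the second along the recorded rotation
#' direction, unwrapping through 0 when crossed; equal angles give a POINT
#' segment.
#'
#' @param beam a `beam_record` for which [is_treatment_beam()] is `TRUE`.
#' @param fraction_weight multiplier on the beam meterset; pass the planned
#'   fraction count to get course-total MU, or 1 for a single fraction.
#' @return segment data frame (see [angular_segments()]); total `mu` equals
#'   `beam_meterset_mu * fraction_weight`.
#' @export
beam_to_segments <- function(beam, fraction_weight = 1) {
  stopifnot(fraction_weight > 0)
  cp <- beam$control_points
  if (nrow(cp) < 2) {
    stop_validation(sprintf("beam %d has fewer than 2 control points",
                            beam$beam_number))
  }
  w <- cp$cumulative_meterset_weight
  if (any(diff(w) < 0)) {
    stop_validation(sprintf(
      "beam %d: cumulative meterset weight decreases", beam$beam_number))
  }
  fin <- w[length(w)]
  if (!is.finite(fin) || fin <= 0) {
    stop_validation(sprintf("beam %d: non-positive final cumulative weight",
                            beam$beam_number))
  }
  total_mu <- beam$beam_meterset_mu * fraction_weight
  n <- nrow(cp)
  start <- numeric(n - 1L); span <- numeric(n - 1L)
  dirn <- character(n - 1L); mu <- numeric(n - 1L)
  for (i in seq_len(n - 1L)) {
    a0 <- cp$gantry_angle_deg[i]; a1 <- cp$gantry_angle_deg[i + 1L]
    dw <- w[i + 1L] - w[i]
    mu[i] <- total_mu * dw / fin
    start[i] <- a0
    if (abs(a1 - a0) < 1e-12) {
      span[i] <- 0; dirn[i] <- "POINT"
    } else {
      dr <- cp$rotation_direction[i]
      if (dr == "NONE") dr <- cp$rotation_direction[i + 1L]
      if (dr == "CW") {
        span[i] <- (a1 - a0) %% 360; dirn[i] <- "CW"
      } else if (dr == "CC") {
        span[i] <- (a0 - a1) %% 360; dirn[i] <- "CC"
      } else {
        stop_validation(sprintf(
          "beam %d: gantry moves %g to %g with rotation direction NONE",
          beam$beam_number, a0, a1))
      }
    }
  }
  keep <- mu > 0 | span > 0
  angular_segments(start[keep], span[keep], dirn[keep], mu[keep])
}

# exact overlap of the oriented interval [a, a + rem] (rem < 360) with each
# bin, as degrees of travel per bin
.interval_bin_lengths <- function(a, rem, scheme) {
  w <- scheme$width_deg
  out <- numeric(n_bins(scheme))
  if (rem <= 0) return(out)
  b <- a + rem
  # boundary positions m*w - w/2 strictly inside (a, b)
  m_lo <- ceiling((a + w / 2) / w); m_hi <- floor((b + w / 2) / w)
  cuts <- if (m_lo > m_hi) numeric(0) else seq(m_lo, m_hi) * w - w / 2
  cuts <- cuts[cuts > a & cuts < b]
  pts <- c(a, cuts, b)
  for (j in seq_len(length(pts) - 1L)) {
    k <- bin_index((pts[j] + pts[j + 1L]) / 2, scheme)
    out[k] <- out[k] + (pts[j + 1L] - pts[j])
  }
  out
}

#' Bin angular segments into an MU histogram
#'
#' POINT segments deposit all their MU in the bin containing their angle;
#' moving segments deposit MU proportional to the angular overlap of the
#' traveled path with each bin (uniform MU per degree within a segment).
#' Total MU is conserved.
#'
#' @param segments data frame from [angular_segments()] /
#'   [beam_to_segments()].
#' @param scheme a [bin_scheme()].
#' @return `mu_histogram`.
#' @export
bin_segments <- function(segments, scheme) {
  mu_per_bin <- numeric(n_bins(scheme))
  w <- scheme$width_deg
  for (i in seq_len(nrow(segments))) {
    mu <- segments$mu[i]
    span <- segments$span_deg[i]
    if (segments$direction[i] == "POINT" || span == 0) {
      k <- bin_index(segments$start_deg[i], scheme)
      mu_per_bin[k] <- mu_per_bin[k] + mu
      next
    }
    if (mu == 0) next
    mu_per_deg <- mu / span
    laps <- floor(span / 360)
    rem <- span - 360 * laps
    if (laps > 0) {
      # each full lap spreads uniformly: width degrees of travel per bin
      mu_per_bin <- mu_per_bin + mu_per_deg * w * laps
    }
    if (rem > 0) {
      a <- segments$start_deg[i]
      # orient so the interval always runs in increasing coordinate
      lo <- if (segments$direction[i] == "CW") a else a - rem
      mu_per_bin <- mu_per_bin +
        mu_per_deg * .interval_bin_lengths(lo, rem, scheme)
    }
  }
  new_mu_histogram(scheme, mu_per_bin)
}

#' Merge MU histograms
#'
#' Elementwise sum of histograms sharing one scheme.
#'
#' @param hists list of `mu_histogram` objects (may be empty).
#' @param scheme required when `hists` is empty; otherwise taken from the
#'   first histogram and checked against the rest.
#' @return `mu_histogram`.
#' @export
merge_histograms <- function(hists, scheme = NULL) {
  if (!length(hists)) {
    if (is.null(scheme)) stop("scheme required to merge an empty list")
    return(new_mu_histogram(scheme, numeric(n_bins(scheme))))
  }
  scheme <- hists[[1]]$scheme
  acc <- numeric(n_bins(scheme))
  for (h in hists) {
    if (!same_scheme(h$scheme, scheme)) {
      stop("cannot merge histograms with different bin schemes")
    }
    acc <- acc + h$mu_per_bin
  }
  new_mu_histogram(scheme, acc)
}

#' Re-bin a fine histogram onto a coarser nesting scheme
#'
#' Valid when the coarse width is a multiple of the fine width with aligned
#' edges (10 -> 30 -> 90; 45 does not nest with 10 or 30).
#'
#' @param hist `mu_histogram` on the fine scheme.
#' @param coarse target [bin_scheme()].
#' @return `mu_histogram` on `coarse`.
#' @export
rebin_histogram <- function(hist, coarse) {
  wf <- hist$scheme$width_deg; wc <- coarse$width_deg
  if (wc %% wf != 0) {
    stop(sprintf("%d-degree bins do not nest inside %d-degree bins", wf, wc))
  }
  idx <- bin_index(hist$scheme$centers, coarse)
  acc <- numeric(n_bins(coarse))
  for (i in seq_along(idx)) acc[idx[i]] <- acc[idx[i]] + hist$mu_per_bin[i]
  new_mu_histogram(coarse, acc)
}

#' @export
print.mu_histogram <- function(x, ...) {
  cat(sprintf("<mu_histogram> %d-degree bins, total MU %.6g\n",
              x$scheme$width_deg, sum(x$mu_per_bin)))
  print(stats::setNames(x$mu_per_bin, paste0(x$scheme$centers, "°")))
  invisible(x)
}

#' @export
print.bin_scheme <- function(x, ...) {
  cat(sprintf("<bin_scheme> width %d deg, %d bins centered at %s\n",
              x$width_deg, n_bins(x),
              paste0(x$centers, collapse = ", ")))
  invisible(x)
}
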