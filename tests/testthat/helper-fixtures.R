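# in-memory record builders and the brute-force discretization oracle

make_cp <- function(angles, weights, rot = "NONE") {
  data.frame(index = seq_along(angles) - 1L,
             gantry_angle_deg = angles,
             rotation_direction = rep(rot, length.out = length(angles)),
             cumulative_meterset_weight = weights)
}

make_beam <- function(angles, weights = NULL, rot = "NONE", mu = 100,
                      beam_type = NULL, beam_number = 1L,
                      dose_present = TRUE) {
  if (is.null(weights)) weights <- seq(0, 1, length.out = length(angles))
  if (is.null(beam_type)) {
    beam_type <- if (length(unique(angles)) == 1L && length(angles) == 2L)
      "STATIC" else "DYNAMIC"
  }
  usefactor:::new_beam_record(
    beam_number = beam_number, beam_type = beam_type,
    radiation_type = "PHOTON", beam_meterset_mu = mu,
    beam_dose_present = dose_present,
    final_cumulative_meterset_weight = weights[length(weights)],
    control_points = make_cp(angles, weights, rot))
}

make_static_beam <- function(angle, mu, beam_number = 1L) {
  make_beam(c(angle, angle), c(0, 1), rot = "NONE", mu = mu,
            beam_type = "STATIC", beam_number = beam_number)
}

make_plan <- function(beams, fractions = 1L, site = NA_character_,
                      uid = paste0("uid-", paste(sample(letters, 8,
                                                        replace = TRUE),
                                                 collapse = ""))) {
  usefactor:::new_rtplan(plan_uid = uid, plan_label = "test",
                         patient_key = "PT",
                         number_of_fractions_planned = fractions,
                         beams = beams, site = site)
}

# independent oracle: split each moving segment into nsub equal sub-steps and
# deposit each sub-step's MU in the bin of its midpoint
oracle_bin <- function(segments, scheme, nsub = 1e5) {
  mu <- numeric(length(scheme$centers))
  for (i in seq_len(nrow(segments))) {
    if (segments$direction[i] == "POINT" || segments$span_deg[i] == 0) {
      k <- bin_index(segments$start_deg[i], scheme)
      mu[k] <- mu[k] + segments$mu[i]
      next
    }
    sgn <- if (segments$direction[i] == "CW") 1 else -1
    mids <- segments$start_deg[i] +
      sgn * (seq_len(nsub) - 0.5) / nsub * segments$span_deg[i]
    k <- bin_index(mids, scheme)
    mu <- mu + segments$mu[i] / nsub *
      tabulate(k, nbins = length(scheme$centers))
  }
  mu
}

# random segment sets for property tests
random_segments <- function(n, grid = NULL) {
  start <- if (is.null(grid)) stats::runif(n, 0, 360) else
    sample(grid, n, replace = TRUE)
  moving <- stats::runif(n) < 0.7
  span <- ifelse(moving, stats::runif(n, 0, 359), 0)
  dirn <- ifelse(moving, sample(c("CW", "CC"), n, replace = TRUE), "POINT")
  angular_segments(start, span, dirn, stats::runif(n, 1, 500))
}

# random in-memory treatment beam (static, fixed-gantry dynamic, or arc)
random_beam <- function(beam_number = 1L) {
  kind <- sample(c("static", "imrt", "vmat"), 1L)
  mu <- stats::runif(1, 10, 500)
  if (kind == "static") return(make_static_beam(stats::runif(1, 0, 360), mu))
  n <- sample(3:30, 1L)
  w <- cumsum(c(0, stats::runif(n - 1L)))
  w <- w / w[n]
  if (kind == "imrt") {
    a <- stats::runif(1, 0, 360)
    make_beam(rep(a, n), w, rot = "NONE", mu = mu, beam_type = "DYNAMIC",
              beam_number = beam_number)
  } else {
    start <- stats::runif(1, 0, 360)
    span <- stats::runif(1, 20, 360)
    dir <- sample(c("CW", "CC"), 1L)
    sgn <- if (dir == "CW") 1 else -1
    ang <- (start + sgn * seq(0, 1, length.out = n) * span) %% 360
    make_beam(ang, w, rot = dir, mu = mu, beam_type = "DYNAMIC",
              beam_number = beam_number)
  }
}
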