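# Use-factor tables.
#
# The use factor of an angular bin is the fraction of total MU delivered
# while the gantry pointed into that bin. Aggregation across patients is
# MU-pooled: all contributing beams are merged into one histogram per
# stratum and the percentages are taken from the pooled totals. Pooling —
# rather than averaging per-patient percentages — matches the workload
# interpretation: a barrier cares about total MU, so a 10-fraction
# high-MU course counts for more than a single palliative field.

#' Use factors of an MU histogram
#'
#' @param hist `mu_histogram` with positive total MU.
#' @return numeric vector of percentages, one per bin, summing to 100.
#' @export
use_factors <- function(hist) {
  tot <- sum(hist$mu_per_bin)
  if (tot <= 0) stop_empty("use factor undefined: histogram has zero MU")
  hist$mu_per_bin / tot * 100
}

.stratum_key <- function(technique, site) paste(technique, site, sep = "\r")

#' Aggregate plans into a stratified use-factor table
#'
#' Every treatment beam contributes its MU histogram to four strata: its
#' own (technique, site) cell, the two marginals (technique, ALL) and
#' (ALL, site), and the grand total (ALL, ALL). Beams are stratified
#' individually, so a plan mixing static and arc beams feeds each beam to
#' its own technique row. Strata that received no MU are omitted.
#'
#' @param plans list of `rtplan` objects (e.g. from [read_rtplan_dir()]).
#' @param scheme a [bin_scheme()].
#' @param weight_fractions multiply each beam's meterset by the plan's
#'   planned fraction count (default `TRUE`), so totals reflect the full
#'   course; `FALSE` weights every plan by a single fraction. A global
#'   constant weight cancels out of the percentages, so this only changes
#'   results when plans differ in fraction count.
#' @return object of class `usefactor_table`: list with `scheme`,
#'   `strata` (data frame of technique, site, n_plans, n_beams, mu_total),
#'   `mu` (matrix, strata x bins) and `pct` (same shape, rows sum to 100).
#' @export
aggregate_use_factors <- function(plans, scheme, weight_fractions = TRUE) {
  if (!length(plans)) stop_empty("no plans to aggregate")
  acc <- new.env(parent = emptyenv())
  bump <- function(tech, site, hist, plan_uid) {
    key <- .stratum_key(tech, site)
    cur <- if (exists(key, envir = acc)) get(key, envir = acc) else
      list(technique = tech, site = site, mu = numeric(n_bins(scheme)),
           n_beams = 0L, plan_uids = character(0))
    cur$mu <- cur$mu + hist$mu_per_bin
    cur$n_beams <- cur$n_beams + 1L
    cur$plan_uids <- union(cur$plan_uids, plan_uid)
    assign(key, cur, envir = acc)
  }
  any_beam <- FALSE
  for (p in plans) {
    fw <- if (weight_fractions) p$number_of_fractions_planned else 1
    site <- if (is.na(p$site) || !nzchar(p$site)) "other" else p$site
    for (b in p$beams) {
      if (!suppressMessages(is_treatment_beam(b))) next
      any_beam <- TRUE
      tech <- classify_beam(b)
      h <- bin_segments(beam_to_segments(b, fraction_weight = fw), scheme)
      bump(tech, site, h, p$plan_uid)
      bump(tech, "ALL", h, p$plan_uid)
      bump("ALL", site, h, p$plan_uid)
      bump("ALL", "ALL", h, p$plan_uid)
    }
  }
  if (!any_beam) stop_empty("no treatment beams in any plan")
  cells <- lapply(ls(envir = acc), get, envir = acc)
  keep <- vapply(cells, function(c) sum(c$mu) > 0, logical(1))
  cells <- cells[keep]
  tech_order <- c(TECHNIQUES, "MIXED", "ALL")
  site_order <- c(setdiff(SITE_VOCABULARY, "other"), "other", "ALL")
  o <- order(match(vapply(cells, `[[`, "", "technique"), tech_order),
             match(vapply(cells, `[[`, "", "site"), site_order))
  cells <- cells[o]
  mu <- do.call(rbind, lapply(cells, `[[`, "mu"))
  colnames(mu) <- paste0(scheme$centers)
  strata <- data.frame(
    technique = vapply(cells, `[[`, "", "technique"),
    site = vapply(cells, `[[`, "", "site"),
    n_plans = vapply(cells, function(c) length(c$plan_uids), integer(1)),
    n_beams = vapply(cells, `[[`, 0L, "n_beams"),
    mu_total = rowSums(mu)
  )
  pct <- sweep(mu, 1, rowSums(mu), "/") * 100
  structure(list(scheme = scheme, strata = strata, mu = mu, pct = pct),
            class = "usefactor_table")
}

#' Extract one stratum's use-factor row
#'
#' @param table a `usefactor_table`.
#' @param technique,site stratum labels (`"ALL"` for the margins).
#' @return numeric percentage vector named by bin center.
#' @export
usefactor_row <- function(table, technique = "ALL", site = "ALL") {
  i <- which(table$strata$technique == technique & table$strata$site == site)
  if (!length(i)) {
    stop(sprintf("no stratum (%s, %s) in table", technique, site))
  }
  stats::setNames(table$pct[i, ], colnames(table$pct))
}

# round half up, the convention of the published tables (base round() is
# round-half-even)
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Render a use-factor table for display
#'
#' Percentages are rounded half-up to `decimals` places; rows are ordered
#' technique then site, columns by bin center ascending from 0 degrees.
#'
#' @param table a `usefactor_table`.
#' @param decimals digits after the decimal point (default 1).
#' @return data frame of formatted strings plus the stratum columns.
#' @export
render_usefactor_table <- function(table, decimals = 1) {
  pct <- round_half_up(table$pct, decimals)
  out <- cbind(table$strata[, c("technique", "site", "n_plans", "n_beams")],
               mu_total = round_half_up(table$strata$mu_total, decimals))
  fmt <- sprintf("%%.%df", decimals)
  for (j in seq_len(ncol(pct))) out[[colnames(pct)[j]]] <- sprintf(fmt, pct[, j])
  out
}

#' @export
print.usefactor_table <- function(x, decimals = 1, ...) {
  cat(sprintf("<usefactor_table> %d-degree bins, %d strata, %.6g MU total\n",
              x$scheme$width_deg, nrow(x$strata),
              max(x$strata$mu_total)))
  print(render_usefactor_table(x, decimals), row.names = FALSE)
  invisible(x)
}

#' Write a use-factor table to CSV
#'
#' One row per stratum; bin columns are named by center angle in degrees.
#'
#' @param table a `usefactor_table`.
#' @param path output path.
#' @export
write_usefactor_csv <- function(table, path) {
  df <- cbind(table$strata,
              width_deg = table$scheme$width_deg,
              as.data.frame(table$pct, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a use-factor table to JSON
#'
#' @param table a `usefactor_table`.
#' @param path output path.
#' @export
write_usefactor_json <- function(table, path) {
  rows <- lapply(seq_len(nrow(table$strata)), function(i) {
    list(technique = table$strata$technique[i],
         site = table$strata$site[i],
         n_plans = table$strata$n_plans[i],
         n_beams = table$strata$n_beams[i],
         mu_total = table$strata$mu_total[i],
         use_factor_pct = stats::setNames(as.list(table$pct[i, ]),
                                          colnames(table$pct)))
  })
  jsonlite::write_json(
    list(width_deg = table$scheme$width_deg,
         bin_centers_deg = table$scheme$centers, strata = rows),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read back a use-factor table written by [write_usefactor_csv()]
#'
#' @param path CSV path.
#' @return `usefactor_table`.
#' @export
read_usefactor_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  scheme <- bin_scheme(df$width_deg[1])
  bin_cols <- as.character(scheme$centers)
  pct <- as.matrix(df[, bin_cols, drop = FALSE])
  mu <- sweep(pct / 100, 1, df$mu_total, "*")
  structure(list(scheme = scheme,
                 strata = df[, c("technique", "site", "n_plans", "n_beams",
                                 "mu_total")],
                 mu = mu, pct = pct),
            class = "usefactor_table")
}
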