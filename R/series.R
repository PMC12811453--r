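#' A longitudinal series of visits for one eye
#'
#' Bundles the dated visits of one eye with its baseline ring polygon and
#' the four baseline-frozen loci selections. Visit 0 is baseline; only
#' follow-up-mode visits enter longitudinal computation, and visits must be
#' strictly time-ordered.
#'
#' @param eye_id Identifier.
#' @param visits List of `sensitivity_field`, baseline first.
#' @param years Numeric vector of elapsed years per visit (baseline 0).
#' @param grid The `test_grid`.
#' @param ring Baseline `ring_polygon` in degrees, or `NULL` when no ring
#'   is available (HRS then unavailable).
#' @param selections Optional named list of `loci_selection` (`MMS`, `ESS`,
#'   `mFTP`, `HRS`); computed from the baseline visit when omitted.
#' @return Object of class `eye_series`.
#' @export
eye_series <- function(eye_id, visits, years, grid, ring = NULL,
                       selections = NULL) {
  stopifnot(length(visits) == length(years), length(visits) >= 1L)
  if (any(diff(years) <= 0)) {
    stop("visits must be strictly time-ordered.", call. = FALSE)
  }
  if (years[1] != 0) stop("visit 0 is baseline: years[1] must be 0.", call. = FALSE)
  keep <- vapply(visits, function(f) isTRUE(f$followup_mode), logical(1))
  keep[1] <- TRUE                       # baseline anchors the series
  visits <- visits[keep]; years <- years[keep]
  if (is.null(selections)) {
    baseline <- visits[[1]]
    selections <- list(MMS = select_mms(baseline, grid),
                       ESS = select_ess(baseline, grid),
                       mFTP = select_mftp(rank_ftp(baseline, grid)))
    selections$HRS <- if (!is.null(ring)) select_hrs(baseline, grid, ring)
  }
  structure(list(eye_id = eye_id, visits = visits, years = years,
                 grid = grid, ring = ring, selections = selections),
            class = "eye_series")
}

#' Longitudinal eligibility of an eye
#'
#' An eye is eligible for longitudinal analysis when its follow-up span is
#' at least 2 years and it has at least 3 follow-up tests.
#'
#' @param series An `eye_series`.
#' @param min_years Minimum follow-up span (default 2).
#' @param min_visits Minimum number of tests (default 3).
#' @return List with `eligible` flag and a character vector of `reasons`
#'   for failure (empty when eligible).
#' @export
check_eligibility <- function(series, min_years = 2, min_visits = 3) {
  span <- max(series$years)
  n <- length(series$visits)
  reasons <- character(0)
  if (span < min_years) {
    reasons <- c(reasons, sprintf("follow-up span %.2f y < %g y", span, min_years))
  }
  if (n < min_visits) {
    reasons <- c(reasons, sprintf("%d tests < %d required", n, min_visits))
  }
  list(eligible = length(reasons) == 0L, reasons = reasons)
}

# Visit indices entering a window. Trend windows at 0.5/1/1.5/2 years take
# every visit up to window + 0.1 y; "all" takes everything.
.window_years <- function(window) {
  switch(window,
         "0.5y" = 0.5, "1y" = 1, "1.5y" = 1.5, "2y" = 2, "all" = Inf,
         stop("unknown window '", window, "'", call. = FALSE))
}

.trend_window_idx <- function(years, window, tol = 0.1) {
  w <- .window_years(window)
  if (is.infinite(w)) seq_along(years) else which(years <= w + tol)
}

#' Trend-based progression: OLS slope of a metric over time
#'
#' Ordinary least-squares regression of the per-visit metric mean against
#' elapsed years; the slope estimates the progression rate in dB/year.
#' With `censor_scotoma = TRUE`, once a locus has read -1 dB at two
#' consecutive visits it is dropped from that visit onward (the per-visit
#' mean is recomputed over the surviving loci), mitigating the floor
#' effect.
#'
#' @param series An `eye_series`.
#' @param metric One of `"MMS"`, `"ESS"`, `"mFTP"`, `"HRS"`.
#' @param window `"0.5y"`, `"1y"`, `"1.5y"`, `"2y"` or `"all"`. Subwindows
#'   include every visit up to the window plus a 0.1-year tolerance.
#' @param censor_scotoma Apply the scotoma-termination rule (default
#'   `FALSE`, matching rates reported without it).
#' @return List of class `trend_result`: `metric`, `window`, `slope`
#'   (dB/year, `NA` when fewer than 2 usable time points), `intercept`,
#'   `n_visits`, `follow_up` (years).
#' @export
trend <- function(series, metric, window = "all", censor_scotoma = FALSE) {
  sel <- series$selections[[metric]]
  if (is.null(sel)) stop("no ", metric, " selection for eye ", series$eye_id,
                         call. = FALSE)
  idx <- .trend_window_idx(series$years, window)
  yrs <- series$years[idx]
  if (!censor_scotoma) {
    vals <- vapply(series$visits[idx],
                   function(f) evaluate_selection(sel, f), numeric(1))
  } else {
    ids <- sel$locus_ids[sel$trend_eligible]
    mat <- vapply(series$visits[idx], function(f) f$values[ids],
                  numeric(length(ids)))
    mat <- matrix(mat, nrow = length(ids))
    alive <- .alive_before_scotoma(mat)
    vals <- vapply(seq_along(idx), function(j) {
      use <- alive[, j]
      if (!any(use)) NA_real_ else mean(mat[use, j])
    }, numeric(1))
  }
  use <- is.finite(vals)
  out <- list(metric = metric, window = window,
              slope = NA_real_, intercept = NA_real_,
              n_visits = sum(use), follow_up = if (any(use)) max(yrs[use]) else 0)
  if (sum(use) >= 2L) {
    fit <- stats::lm.fit(cbind(1, yrs[use]), vals[use])
    out$intercept <- unname(fit$coefficients[1])
    out$slope <- unname(fit$coefficients[2])
  }
  structure(out, class = "trend_result")
}

# loci x visits matrix of -1 flags -> TRUE while the locus is still usable:
# a locus dies at its second consecutive -1 reading and stays dead.
.alive_before_scotoma <- function(mat) {
  scot <- mat == -1
  alive <- matrix(TRUE, nrow(mat), ncol(mat))
  if (ncol(mat) >= 2) {
    for (j in 2:ncol(mat)) {
      alive[, j] <- alive[, j - 1] & !(scot[, j] & scot[, j - 1])
    }
  }
  alive
}

#' Event-based progression: mean change over prespecified loci
#'
#' Implements the clinically-meaningful-change criterion for
#' microperimetry: a mean decline of at least 7 dB across at least 5
#' prespecified loci, each with a baseline sensitivity of at least 8 dB.
#' The target visit is the last visit for `window = "all"`, or the visit
#' nearest 2.0 years (within +/- 0.5 y) for `window = "2y"`.
#'
#' @param series An `eye_series`.
#' @param metric Metric name.
#' @param window `"2y"` or `"all"`.
#' @param event_threshold_db Mean-change threshold; the event fires when
#'   `mean_change <= event_threshold_db` (default -7, boundary inclusive).
#' @param min_loci Minimum number of event-eligible loci (default 5).
#' @return List of class `event_result`: `metric`, `window`, `n_loci`,
#'   `mean_change` (dB, target minus baseline averaged over eligible
#'   loci), `event` (flag), `mean_rate` (dB/year = mean_change / elapsed
#'   years of the target visit), `eligible`, and `reason` when ineligible.
#' @export
event <- function(series, metric, window = "all",
                  event_threshold_db = -7, min_loci = 5) {
  sel <- series$selections[[metric]]
  out <- structure(list(metric = metric, window = window,
                        n_loci = 0L, mean_change = NA_real_,
                        event = NA, mean_rate = NA_real_,
                        eligible = FALSE, reason = NULL),
                   class = "event_result")
  if (is.null(sel)) { out$reason <- "no selection"; return(out) }
  ids <- sel$eligible_event_ids
  out$n_loci <- length(ids)
  if (length(ids) < min_loci) {
    out$reason <- sprintf("%d event-eligible loci < %d", length(ids), min_loci)
    return(out)
  }
  yrs <- series$years
  if (window == "all") {
    tgt <- length(yrs)
  } else if (window == "2y") {
    cand <- which(abs(yrs - 2) <= 0.5 & yrs > 0)
    if (!length(cand)) { out$reason <- "no visit within 2 +/- 0.5 years"; return(out) }
    tgt <- cand[which.min(abs(yrs[cand] - 2))]
  } else {
    stop("event window must be '2y' or 'all'.", call. = FALSE)
  }
  base <- series$visits[[1]]$values[ids]
  final <- series$visits[[tgt]]$values[ids]
  out$eligible <- TRUE
  out$mean_change <- mean(final - base)
  out$event <- out$mean_change <= event_threshold_db
  out$mean_rate <- out$mean_change / yrs[tgt]
  out$follow_up <- yrs[tgt]
  out
}

#' Floor-effect diagnostics: proportion of loci reaching scotoma
#'
#' A locus has "reached scotoma" when it reads -1 dB at two consecutive
#' visits within the observation window. Returns the fraction of the
#' metric's loci that did.
#'
#' @param series An `eye_series`.
#' @param metric Metric name.
#' @param window Observation window (as in [trend()]).
#' @return Proportion in `[0, 1]`; `NA` for an empty selection.
#' @export
floor_diagnostics <- function(series, metric, window = "all") {
  sel <- series$selections[[metric]]
  if (is.null(sel) || !length(sel$locus_ids)) return(NA_real_)
  ids <- sel$locus_ids
  idx <- .trend_window_idx(series$years, window)
  mat <- vapply(series$visits[idx], function(f) f$values[ids] == -1L,
                logical(length(ids)))
  mat <- matrix(mat, nrow = length(ids))
  reached <- apply(mat, 1, function(r) {
    length(r) >= 2 && any(r[-1] & r[-length(r)])
  })
  mean(reached)
}

#' Full per-eye progression summary
#'
#' Runs trend, event and floor diagnostics for every metric and window and
#' returns one tidy row per eye x metric x window.
#'
#' @param series An `eye_series`.
#' @param windows Character vector of windows (default `c("2y", "all")`).
#' @param metrics Metrics to analyse.
#' @param censor_scotoma Passed to [trend()].
#' @param event_threshold_db,min_loci Passed to [event()].
#' @return Data frame: `eye_id`, `metric`, `window`, `slope`, `n_visits`,
#'   `follow_up_years`, `n_event_loci`, `mean_change`, `event`,
#'   `mean_rate`, `prop_floor`.
#' @export
progression_summary <- function(series, windows = c("2y", "all"),
                                metrics = c("MMS", "ESS", "mFTP", "HRS"),
                                censor_scotoma = FALSE,
                                event_threshold_db = -7, min_loci = 5) {
  rows <- list()
  for (w in windows) for (m in metrics) {
    tr <- trend(series, m, w, censor_scotoma = censor_scotoma)
    ev <- if (w %in% c("2y", "all")) {
      event(series, m, w, event_threshold_db = event_threshold_db,
            min_loci = min_loci)
    } else NULL
    rows[[length(rows) + 1L]] <- data.frame(
      eye_id = series$eye_id, metric = m, window = w,
      slope = tr$slope, n_visits = tr$n_visits,
      follow_up_years = tr$follow_up,
      n_event_loci = if (is.null(ev)) NA_integer_ else ev$n_loci,
      mean_change = if (is.null(ev)) NA_real_ else ev$mean_change,
      event = if (is.null(ev)) NA else ev$event,
      mean_rate = if (is.null(ev)) NA_real_ else ev$mean_rate,
      prop_floor = floor_diagnostics(series, m, w))
  }
  do.call(rbind, rows)
}
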