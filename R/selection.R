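#' A single visit's sensitivity field
#'
#' One integer threshold per grid locus, in dB attenuation: 0 (brightest)
#' to 36 (dimmest), with -1 coding "not seen at the brightest stimulus"
#' (absolute scotoma).
#'
#' @param values Integer vector of thresholds, one per locus, in
#'   `grid$loci` order; each in `{-1, 0, ..., 36}`.
#' @param grid The `test_grid` the values refer to.
#' @param visit_date Calendar date of the visit (`Date` or coercible).
#' @param followup_mode Whether the test was recorded in follow-up mode
#'   (tracking the baseline retinal landmarks); only follow-up tests enter
#'   longitudinal analysis.
#' @return Object of class `sensitivity_field`.
#' @export
sensitivity_field <- function(values, grid, visit_date = NA,
                              followup_mode = TRUE) {
  values <- as.vector(values)
  if (length(values) != nrow(grid$loci)) {
    stop("expected one value per locus (", nrow(grid$loci), "), got ",
         length(values), ".", call. = FALSE)
  }
  if (any(!is.finite(values)) || any(values != round(values))) {
    stop("thresholds must be integers.", call. = FALSE)
  }
  if (any(values < -1 | values > 36)) {
    stop("thresholds must lie in {-1, 0..36} dB.", call. = FALSE)
  }
  structure(list(values = as.integer(values),
                 visit_date = if (inherits(visit_date, "Date")) visit_date
                              else suppressWarnings(as.Date(visit_date)),
                 followup_mode = isTRUE(followup_mode)),
            class = "sensitivity_field")
}

.field_values <- function(field) {
  if (inherits(field, "sensitivity_field")) field$values else as.integer(field)
}

.new_selection <- function(metric, locus_ids, baseline, provenance = NULL,
                           trend_eligible = NULL, flags = character(0)) {
  locus_ids <- as.integer(locus_ids)
  if (is.null(trend_eligible)) trend_eligible <- rep(TRUE, length(locus_ids))
  eligible_event <- locus_ids[baseline[locus_ids] >= 8]
  structure(list(metric = metric,
                 locus_ids = locus_ids,
                 trend_eligible = trend_eligible,
                 eligible_event_ids = eligible_event,
                 provenance = provenance,
                 flags = flags),
            class = "loci_selection")
}

#' Mean macular sensitivity (MMS) selection
#'
#' MMS averages all 68 loci of the grid, scotomatous (-1 dB) loci included.
#' All loci are selected; loci with a baseline of at least 8 dB are
#' additionally event-eligible.
#'
#' @param field Baseline `sensitivity_field`.
#' @param grid A `test_grid`.
#' @return A `loci_selection` with `metric = "MMS"`.
#' @export
select_mms <- function(field, grid) {
  v <- .field_values(field)
  .new_selection("MMS", grid$loci$id, v,
                 provenance = rep("all-loci", nrow(grid$loci)))
}

#' Edge-of-scotoma sensitivity (ESS) selection
#'
#' Selects the seeing edge of the scotoma: every non-scotomatous locus with
#' at least one scotomatous (-1 dB) neighbour at baseline. Scotomatous loci
#' themselves are excluded (their mean would be uninformative; the edge
#' literature measures the seeing side). If the baseline has no -1 locus
#' the selection is empty and carries a `"no-scotoma"` flag.
#'
#' @inheritParams select_mms
#' @return A `loci_selection` with `metric = "ESS"`.
#' @export
select_ess <- function(field, grid) {
  v <- .field_values(field)
  scot <- grid$loci$id[v == -1L]
  if (!length(scot)) {
    return(.new_selection("ESS", integer(0), v, flags = "no-scotoma"))
  }
  ids <- grid$loci$id[vapply(grid$loci$id, function(i) {
    v[i] != -1L && any(grid$adjacency[[as.character(i)]] %in% scot)
  }, logical(1))]
  .new_selection("ESS", ids, v,
                 provenance = rep("adjacent-to-scotoma", length(ids)))
}

#' Rank loci by proportion of adjacent loci 7 dB lower (FTP ranking)
#'
#' For each locus with a baseline of at least 8 dB, computes the proportion
#' of its adjacent loci whose baseline is at least 7 dB lower. A -1 dB
#' neighbour participates arithmetically (e.g. 8 - (-1) = 9 >= 7 counts as
#' a drop), matching computation on raw exports where -1 is the stored
#' number. Loci below 8 dB, and loci with no neighbours under a custom
#' scheme, are absent from the ranking.
#'
#' @inheritParams select_mms
#' @param drop_db Drop threshold in dB (default 7).
#' @param min_baseline_db Baseline eligibility threshold in dB (default 8).
#' @param peripheral_only If `TRUE`, only neighbours at strictly higher
#'   eccentricity than the locus are counted (both numerator and
#'   denominator); default `FALSE`.
#' @return Data frame of class `ftp_ranking`: `id`, `baseline_db`,
#'   `n_neighbors`, `n_drop`, `proportion`.
#' @export
rank_ftp <- function(field, grid, drop_db = 7, min_baseline_db = 8,
                     peripheral_only = FALSE) {
  v <- .field_values(field)
  cand <- grid$loci$id[v >= min_baseline_db]
  ecc <- grid$loci$eccentricity
  rows <- lapply(cand, function(i) {
    nb <- grid$adjacency[[as.character(i)]]
    if (peripheral_only) nb <- nb[ecc[nb] > ecc[i]]
    if (!length(nb)) return(NULL)       # denominator 0: unrankable
    ndrop <- sum(v[nb] <= v[i] - drop_db)
    data.frame(id = i, baseline_db = v[i], n_neighbors = length(nb),
               n_drop = ndrop, proportion = ndrop / length(nb))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(id = integer(0), baseline_db = integer(0),
                      n_neighbors = integer(0), n_drop = integer(0),
                      proportion = numeric(0))
  }
  class(out) <- c("ftp_ranking", "data.frame")
  out
}

#' Modified functional-transition-point (mFTP) selection
#'
#' Takes every ranked locus whose proportion of 7-dB-lower neighbours is
#' 100%. If fewer than `min_loci` qualify, whole tiers at the next-highest
#' strictly positive proportion are added until at least `min_loci` loci
#' are selected (tied tiers are included in full, so the selection may
#' exceed `min_loci`). Zero-proportion loci carry no transition-zone signal
#' and are never selected; an eye that cannot reach `min_loci` is returned
#' as-is with an `"ineligible-for-event"` flag.
#'
#' @param ranking An `ftp_ranking` from [rank_ftp()].
#' @param min_loci Minimum selection size before tier expansion stops
#'   (default 5).
#' @return A `loci_selection` with `metric = "mFTP"`; provenance records
#'   each locus's proportion.
#' @export
select_mftp <- function(ranking, min_loci = 5) {
  pos <- ranking[ranking$proportion > 0, , drop = FALSE]
  sel <- pos[pos$proportion == 1, , drop = FALSE]
  remaining <- pos[pos$proportion < 1, , drop = FALSE]
  while (nrow(sel) < min_loci && nrow(remaining) > 0) {
    top <- max(remaining$proportion)
    tier <- remaining[remaining$proportion == top, , drop = FALSE]
    sel <- rbind(sel, tier)
    remaining <- remaining[remaining$proportion < top, , drop = FALSE]
  }
  baseline <- integer(max(ranking$id, 1))
  baseline[ranking$id] <- ranking$baseline_db
  flags <- if (nrow(sel) < min_loci) "ineligible-for-event" else character(0)
  sel <- sel[order(sel$id), , drop = FALSE]
  .new_selection("mFTP", sel$id, baseline,
                 provenance = sprintf("proportion=%.3f", sel$proportion),
                 flags = flags)
}

#' Hyperautofluorescent-ring sensitivity (HRS) selection
#'
#' Selects every locus whose 2 x 2 degree tessellation square is transected
#' by the registered ring boundary. Loci that are scotomatous (-1 dB) at
#' baseline remain in the selection for event bookkeeping but are excluded
#' from trend analysis. A ring lying wholly outside the grid yields an
#' empty selection flagged `"no-hrs-loci"`.
#'
#' @inheritParams select_mms
#' @param ring A `ring_polygon` in degrees.
#' @return A `loci_selection` with `metric = "HRS"`.
#' @export
select_hrs <- function(field, grid, ring) {
  v <- .field_values(field)
  hit <- transects_grid(grid, ring)
  ids <- grid$loci$id[hit]
  if (!length(ids)) {
    return(.new_selection("HRS", integer(0), v, flags = "no-hrs-loci"))
  }
  .new_selection("HRS", ids, v,
                 provenance = rep("ring-transects-square", length(ids)),
                 trend_eligible = v[ids] != -1L)
}

#' Mean sensitivity of a selection on a visit
#'
#' Arithmetic mean of the visit's thresholds over the selection's
#' trend-eligible loci. For MMS, ESS and mFTP the -1 dB code enters the
#' mean arithmetically; for HRS, loci scotomatous at baseline were already
#' excluded from trend eligibility at selection time.
#'
#' @param selection A `loci_selection`.
#' @param field A `sensitivity_field` (any visit).
#' @return Mean in dB, or `NA_real_` when the effective locus set is empty
#'   (never a silent 0).
#' @export
evaluate_selection <- function(selection, field) {
  ids <- selection$locus_ids[selection$trend_eligible]
  if (!length(ids)) return(NA_real_)
  mean(.field_values(field)[ids])
}

#' @export
print.loci_selection <- function(x, ...) {
  cat(x$metric, " selection: ", length(x$locus_ids), " loci (",
      length(x$eligible_event_ids), " event-eligible)",
      if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ", "), "]"),
      "\n", sep = "")
  invisible(x)
}
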