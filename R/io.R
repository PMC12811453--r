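#' Study configuration with the standard thresholds
#'
#' All analysis thresholds live here as data, defaulted to the standard
#' values: a 7 dB drop defines a transition-zone neighbour, 8 dB is the
#' baseline eligibility for ranked/event loci, an event is a mean change
#' of -7 dB or worse across at least 5 prespecified loci. Everything is
#' overridable.
#'
#' @param eccentricity_cut Grid radial cut, degrees.
#' @param adjacency_scheme Locus adjacency scheme.
#' @param af_fov,af_res,maia_fov,maia_res Image specs (degrees, pixels).
#' @param windows Analysis windows.
#' @param drop_db mFTP neighbour-drop threshold, dB.
#' @param min_baseline_db Event/ranking baseline eligibility, dB.
#' @param event_threshold_db Event mean-change threshold, dB.
#' @param min_event_loci Minimum prespecified loci for the event analysis.
#' @param censor_scotoma Scotoma-termination rule for trend slopes.
#' @param mirror_od Mirror x for right eyes at load time.
#' @return List of class `study_config`.
#' @export
study_config <- function(eccentricity_cut = 9.2,
                         adjacency_scheme = "chebyshev8",
                         af_fov = 30, af_res = 768,
                         maia_fov = 36, maia_res = 1024,
                         windows = c("2y", "all"),
                         drop_db = 7, min_baseline_db = 8,
                         event_threshold_db = -7, min_event_loci = 5,
                         censor_scotoma = FALSE, mirror_od = FALSE) {
  structure(as.list(environment()), class = "study_config")
}

#' Read / write a study configuration as YAML
#' @param config A `study_config`.
#' @param path File path.
#' @return `read_config` returns a `study_config`; writers return the path
#'   invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(study_config, vals[names(vals) %in% names(formals(study_config))])
}

#' Write one visit as a headered CSV
#'
#' Columns: `locus_id`, `x_deg`, `y_deg`, `threshold_db`, `visit_date`,
#' `followup_mode`, `eye_id`, `laterality`; one row per locus.
#'
#' @param field A `sensitivity_field`.
#' @param grid The `test_grid`.
#' @param path Output path.
#' @param eye_id,laterality Identification columns.
#' @export
write_visit <- function(field, grid, path, eye_id = "eye", laterality = "OS") {
  d <- data.frame(locus_id = grid$loci$id,
                  x_deg = grid$loci$x, y_deg = grid$loci$y,
                  threshold_db = field$values,
                  visit_date = as.character(field$visit_date),
                  followup_mode = as.integer(field$followup_mode),
                  eye_id = eye_id, laterality = laterality)
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Load and validate a visit CSV
#'
#' Validates the file against the constructed grid: exactly one row per
#' locus, integer thresholds in `{-1, 0..36}`, and positions matching the
#' grid to 1e-6 degrees. Errors name the offending locus ids or file
#' lines. When `mirror` is `TRUE`, x is negated before matching (used for
#' right eyes recorded in retinal coordinates).
#'
#' @param path Visit CSV path.
#' @param grid The `test_grid`.
#' @param mirror Negate x before matching against the grid.
#' @return A `sensitivity_field`.
#' @export
load_visit <- function(path, grid, mirror = FALSE) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("locus_id", "x_deg", "y_deg", "threshold_db")
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    stop(path, ": missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (mirror) d$x_deg <- -d$x_deg
  if (anyDuplicated(d$locus_id)) {
    dup <- unique(d$locus_id[duplicated(d$locus_id)])
    stop(path, ": duplicate locus ids: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  absent <- setdiff(grid$loci$id, d$locus_id)
  if (length(absent)) {
    stop(path, ": missing loci: ", paste(absent, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(d$locus_id, grid$loci$id)
  if (length(extra)) {
    stop(path, ": unknown locus ids: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.finite(d$threshold_db) |
                 d$threshold_db != round(d$threshold_db) |
                 d$threshold_db < -1 | d$threshold_db > 36)
  if (length(bad)) {
    stop(path, ": thresholds outside {-1, 0..36} at line(s) ",
         paste(bad + 1L, collapse = ", "), call. = FALSE)  # +1 for header
  }
  d <- d[match(grid$loci$id, d$locus_id), , drop = FALSE]
  off <- abs(d$x_deg - grid$loci$x) > 1e-6 | abs(d$y_deg - grid$loci$y) > 1e-6
  if (any(off)) {
    stop(path, ": locus positions disagree with the grid for ids ",
         paste(d$locus_id[off], collapse = ", "), call. = FALSE)
  }
  sensitivity_field(d$threshold_db, grid,
                    visit_date = if ("visit_date" %in% names(d)) d$visit_date[1] else NA,
                    followup_mode = if ("followup_mode" %in% names(d))
                      d$followup_mode[1] == 1 else TRUE)
}

#' Read / write ring vertices and landmark pairs as CSV
#'
#' Rings are two-column CSVs (`x`, `y`; pixels or degrees depending on the
#' stage); landmarks are four-column CSVs (`src_x`, `src_y`, `dst_x`,
#' `dst_y`).
#'
#' @param path CSV path.
#' @param vertices Two-column matrix.
#' @param src,dst Two-column matrices of corresponding points.
#' @return Readers return matrices (a list `src`/`dst` for landmarks);
#'   writers return the path invisibly.
#' @export
write_ring_csv <- function(vertices, path) {
  utils::write.csv(data.frame(x = vertices[, 1], y = vertices[, 2]),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ring_csv
#' @export
read_ring_csv <- function(path) {
  d <- utils::read.csv(path)
  as.matrix(d[, c("x", "y")])
}

#' @rdname write_ring_csv
#' @export
write_landmarks_csv <- function(src, dst, path) {
  utils::write.csv(data.frame(src_x = src[, 1], src_y = src[, 2],
                              dst_x = dst[, 1], dst_y = dst[, 2]),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ring_csv
#' @export
read_landmarks_csv <- function(path) {
  d <- utils::read.csv(path)
  list(src = as.matrix(d[, c("src_x", "src_y")]),
       dst = as.matrix(d[, c("dst_x", "dst_y")]))
}

#' Serialize baseline selections as CSV
#'
#' One row per metric x locus: `metric`, `locus_id`, `x_deg`, `y_deg`,
#' `baseline_db`, `provenance`, `trend_eligible`, `event_eligible`.
#'
#' @param selections Named list of `loci_selection`.
#' @param baseline Baseline `sensitivity_field`.
#' @param grid The `test_grid`.
#' @param path Output path (omit to just get the data frame).
#' @return The data frame, invisibly when written.
#' @export
write_selections_csv <- function(selections, baseline, grid, path = NULL) {
  rows <- lapply(selections, function(s) {
    if (is.null(s) || !length(s$locus_ids)) return(NULL)
    data.frame(metric = s$metric, locus_id = s$locus_ids,
               x_deg = grid$loci$x[s$locus_ids],
               y_deg = grid$loci$y[s$locus_ids],
               baseline_db = baseline$values[s$locus_ids],
               provenance = s$provenance %||% "",
               trend_eligible = s$trend_eligible,
               event_eligible = s$locus_ids %in% s$eligible_event_ids)
  })
  d <- do.call(rbind, rows)
  if (!is.null(path)) {
    utils::write.csv(d, path, row.names = FALSE)
    return(invisible(d))
  }
  d
}

#' Write a synthetic cohort to a directory of plain-text files
#'
#' Per eye: visit CSVs (`<eye>_visit<k>.csv`), the ring in AF pixels and in
#' degrees, and the landmark pairs; plus a `cohort.json` manifest with the
#' visit years, ages and ground-truth parameters.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  grid <- cohort$eyes[[1]]$grid
  manifest <- list(config = unclass(cohort$config),
                   eyes = list())
  for (es in cohort$eyes) {
    for (k in seq_along(es$visits)) {
      write_visit(es$visits[[k]], grid,
                  file.path(dir, sprintf("%s_visit%02d.csv", es$eye_id, k)),
                  eye_id = es$eye_id)
    }
    write_ring_csv(es$ring_af_px, file.path(dir, paste0(es$eye_id, "_ring_af_px.csv")))
    write_ring_csv(es$ring$vertices, file.path(dir, paste0(es$eye_id, "_ring_deg.csv")))
    write_landmarks_csv(es$landmarks$src, es$landmarks$dst,
                        file.path(dir, paste0(es$eye_id, "_landmarks.csv")))
    manifest$eyes[[es$eye_id]] <- list(years = es$years, age = es$age,
                                       r0 = es$r0, n_visits = length(es$visits))
  }
  jsonlite::write_json(manifest, file.path(dir, "cohort.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a cohort directory back into eye series
#'
#' Re-runs the registration stage from the stored AF-pixel rings and
#' landmarks, so a round-tripped cohort exercises the same pipeline as a
#' freshly generated one.
#'
#' @param dir Directory written by [write_cohort()].
#' @param config A `study_config`.
#' @return List of `eye_series`.
#' @export
load_cohort <- function(dir, config = study_config()) {
  manifest <- jsonlite::read_json(file.path(dir, "cohort.json"),
                                  simplifyVector = TRUE)
  if (!length(manifest$eyes)) stop("no eyes found in ", dir, call. = FALSE)
  grid <- build_grid(config$eccentricity_cut, config$adjacency_scheme)
  maia <- image_spec(config$maia_fov, config$maia_res)
  lapply(names(manifest$eyes), function(id) {
    info <- manifest$eyes[[id]]
    visits <- lapply(seq_len(info$n_visits), function(k) {
      load_visit(file.path(dir, sprintf("%s_visit%02d.csv", id, k)), grid)
    })
    lm <- read_landmarks_csv(file.path(dir, paste0(id, "_landmarks.csv")))
    ring_px <- read_ring_csv(file.path(dir, paste0(id, "_ring_af_px.csv")))
    t_fit <- fit_similarity(lm$src, lm$dst)
    ring <- ring_to_degrees(ring_px, t_fit, maia = maia)
    es <- eye_series(eye_id = id, visits = visits, years = info$years,
                     grid = grid, ring = ring)
    es$age <- info$age
    es
  })
}

#' Run the full analysis pipeline over a cohort
#'
#' Executes register -> select -> progress -> compare: per-eye baseline
#' selections (already frozen inside each `eye_series`), per-eye trend and
#' event analyses over the configured windows, and cohort-level
#' repeated-measures ANOVA of the slopes per window. Ineligible eyes are
#' reported, not analysed.
#'
#' @param cohort A `synthetic_cohort`, a list of `eye_series`, or a
#'   directory path written by [write_cohort()].
#' @param config A [study_config()].
#' @return List of class `results_bundle`:
#'   \describe{
#'     \item{results}{data frame, one row per eye x metric x window (see
#'       [progression_summary()]).}
#'     \item{anova}{named list per window: `rm_anova_result` on the slope
#'       matrix.}
#'     \item{eligibility}{data frame of per-eye eligibility and reasons.}
#'     \item{config}{the thresholds used.}
#'   }
#' @export
run_pipeline <- function(cohort, config = study_config()) {
  eyes <- if (is.character(cohort)) load_cohort(cohort, config)
          else if (inherits(cohort, "synthetic_cohort")) cohort$eyes
          else cohort
  if (!length(eyes)) stop("no eyes to analyse.", call. = FALSE)
  elig <- do.call(rbind, lapply(eyes, function(es) {
    ok <- check_eligibility(es)
    data.frame(eye_id = es$eye_id, eligible = ok$eligible,
               reasons = paste(ok$reasons, collapse = "; "))
  }))
  usable <- eyes[elig$eligible]
  if (!length(usable)) stop("stage progress: no eligible eyes.", call. = FALSE)
  results <- do.call(rbind, lapply(usable, function(es) {
    tryCatch(
      progression_summary(es, windows = config$windows,
                          censor_scotoma = config$censor_scotoma,
                          event_threshold_db = config$event_threshold_db,
                          min_loci = config$min_event_loci),
      error = function(e) stop("stage progress failed for eye ", es$eye_id,
                               ": ", conditionMessage(e), call. = FALSE))
  }))
  anovas <- lapply(stats::setNames(config$windows, config$windows), function(w) {
    sub <- results[results$window == w, c("eye_id", "metric", "slope")]
    m <- stats::reshape(sub, idvar = "eye_id", timevar = "metric",
                        direction = "wide")
    mat <- as.matrix(m[, -1, drop = FALSE])
    colnames(mat) <- sub("^slope\\.", "", colnames(mat))
    if (sum(stats::complete.cases(mat)) >= 2) {
      rm_anova(mat, pairwise_always = TRUE)
    }
  })
  structure(list(results = results, anova = anovas, eligibility = elig,
                 config = config),
            class = "results_bundle")
}

#' @export
print.results_bundle <- function(x, ...) {
  cat("results bundle: ", length(unique(x$results$eye_id)), " eyes x ",
      length(unique(x$results$metric)), " metrics x ",
      length(unique(x$results$window)), " windows\n", sep = "")
  invisible(x)
}
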