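#' Configuration for the synthetic longitudinal cohort
#'
#' The generator emulates a retinal-degeneration cohort with a
#' hill-of-vision that collapses outward-in: each eye has a
#' hyperautofluorescent ring of baseline radius `R0` (drawn uniformly per
#' eye) marking the transition zone between preserved and degenerate
#' retina, the ring contracts at `contraction` degrees/year, and retinal
#' sensitivity follows a logistic profile across the transition of width
#' `transition_width`. Test-retest noise is heteroscedastic: its standard
#' deviation grows with the local spatial gradient of the sensitivity
#' surface, encoding the higher variability observed at the border of deep
#' scotoma than over normal retina. Simulated thresholds are rounded to
#' integer dB and floor-censored at -1 (ceiling 36).
#'
#' @param n_eyes Number of eyes (default 30).
#' @param visit_interval Years between visits (default 0.5).
#' @param n_visits Number of visits (default 9: baseline plus 4 years of
#'   6-monthly follow-up).
#' @param s_max Plateau sensitivity, dB (default 24).
#' @param floor_level Pre-censoring floor of the sensitivity surface, dB
#'   (default -5; values rounding below 0 are exported as -1).
#' @param r0_range Per-eye uniform draw bounds for the baseline ring
#'   radius, degrees (default `c(3, 8)`).
#' @param contraction Ring contraction rate, degrees/year (default 0.25).
#' @param transition_width Logistic transition width, degrees (default 1.5).
#' @param sigma0 Baseline test-retest noise SD, dB (default 1).
#' @param sigma1 Edge noise gain, dB per (dB/degree) of local spatial
#'   gradient (default 0.5).
#' @param ring_offset Ring radius minus the half-sensitivity radius,
#'   degrees (default 0: the ring sits on the transition midpoint).
#' @param axis_ratio Ring ellipse axis ratio (default 1, a circle).
#' @param age_range Per-eye uniform draw bounds for baseline age, years.
#' @param seed Integer seed; the cohort is deterministic given the seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_eyes = 30, visit_interval = 0.5, n_visits = 9,
                       s_max = 24, floor_level = -5, r0_range = c(3, 8),
                       contraction = 0.25, transition_width = 1.5,
                       sigma0 = 1, sigma1 = 0.5, ring_offset = 0,
                       axis_ratio = 1, age_range = c(18, 60), seed = 1) {
  stopifnot(n_eyes >= 1, visit_interval > 0, n_visits >= 1,
            s_max > floor_level, all(r0_range > 0), contraction >= 0,
            transition_width > 0, sigma0 >= 0, sigma1 >= 0, axis_ratio > 0)
  if ((n_visits - 1) * visit_interval < 2) {
    warning("follow-up span below 2 years: no eye will be trend-eligible.")
  }
  structure(as.list(environment()), class = "sim_config")
}

#' Noiseless sensitivity surface of the disease model
#'
#' `s(r, t) = floor + (s_max - floor) * logistic((R(t) - r) / w)` with
#' `R(t) = R0 - contraction * t`: a plateau inside the ring, the floor
#' outside, and a logistic transition of width `w` centred on the ring.
#'
#' @param r Eccentricity in degrees (vectorised).
#' @param t Elapsed years.
#' @param r0 Baseline ring radius, degrees.
#' @param config A `sim_config`.
#' @return Sensitivity in dB (continuous, pre-noise, pre-censoring).
#' @export
true_sensitivity <- function(r, t, r0, config) {
  R <- r0 - config$contraction * t
  config$floor_level + (config$s_max - config$floor_level) *
    stats::plogis((R - r) / config$transition_width)
}

# spatial gradient ds/dr (dB/degree), used for the heteroscedastic noise
.true_gradient <- function(r, t, r0, config) {
  R <- r0 - config$contraction * t
  z <- (R - r) / config$transition_width
  l <- stats::plogis(z)
  -(config$s_max - config$floor_level) * l * (1 - l) / config$transition_width
}

#' Generate a synthetic longitudinal cohort
#'
#' Simulates `n_eyes` eyes. For each eye: a baseline ring radius is drawn,
#' every visit samples the noiseless surface at each grid locus, adds
#' Gaussian noise whose SD is `sigma0 + sigma1 * |ds/dr|`, rounds to
#' integer dB, and censors to the export range (below 0 becomes -1, above
#' 36 becomes 36). The baseline ring is emitted both in degrees and as an
#' autofluorescence-pixel trace together with four landmark pairs related
#' by a per-eye random similarity transform between the AF (30 deg /
#' 768 px) and MAIA (36 deg / 1024 px) pixel frames, so the registration
#' stage can be exercised end to end. Baseline selections are computed by
#' running the actual pipeline: landmarks -> similarity fit -> ring in
#' degrees -> transection -> selections.
#'
#' @param config A [sim_config()].
#' @return List of class `synthetic_cohort` with elements
#'   \describe{
#'     \item{eyes}{list of `eye_series`, each with extra fields
#'       `ring_af_px`, `landmarks` (src/dst matrices), `age`, `r0`.}
#'     \item{truth}{list of class `ground_truth`: per-eye `r0`, the
#'       config, and closed-form rate functions (see [truth_rates()]).}
#'     \item{config}{the config used.}
#'   }
#' @export
generate_cohort <- function(config = sim_config()) {
  set.seed(config$seed)
  grid <- build_grid()
  af <- image_spec(30, 768); maia <- image_spec(36, 1024)
  maia_c <- c(maia$resolution / 2, maia$resolution / 2)
  yrs <- (seq_len(config$n_visits) - 1) * config$visit_interval
  base_scale <- af$degrees_per_pixel / maia$degrees_per_pixel
  eyes <- vector("list", config$n_eyes)
  r0s <- stats::runif(config$n_eyes, config$r0_range[1], config$r0_range[2])
  ages <- stats::runif(config$n_eyes, config$age_range[1], config$age_range[2])
  base_date <- as.Date("2020-01-06")
  for (e in seq_len(config$n_eyes)) {
    r0 <- r0s[e]
    r <- grid$loci$eccentricity
    visits <- lapply(yrs, function(t) {
      mu <- true_sensitivity(r, t, r0, config)
      sd <- config$sigma0 + config$sigma1 * abs(.true_gradient(r, t, r0, config))
      v <- round(mu + stats::rnorm(length(r), 0, sd))
      v[v < 0] <- -1
      v[v > 36] <- 36
      sensitivity_field(v, grid, visit_date = base_date + round(365.25 * t),
                        followup_mode = TRUE)
    })
    # baseline ring in degrees, then pushed out to AF pixels through a
    # per-eye random similarity (AF px -> MAIA px)
    ring_deg <- polygonize_ring(radius = r0 + config$ring_offset,
                                axis_ratio = config$axis_ratio)
    true_t <- structure(list(
      scale = base_scale * stats::runif(1, 0.9, 1.1),
      rotation = stats::runif(1, -0.1, 0.1),
      translation = c(0, 0), rmse = 0, n = 0L), class = "similarity_transform")
    # anchor the translation so that the AF image centre maps near the
    # MAIA grid centre
    af_c <- c(af$resolution / 2, af$resolution / 2)
    true_t$translation <- maia_c - apply_similarity(true_t, rbind(af_c))[1, ]
    ring_maia_px <- sweep(cbind(ring_deg$vertices[, 1],
                                -ring_deg$vertices[, 2]) / maia$degrees_per_pixel,
                          2, maia_c, "+")
    ring_af_px <- apply_similarity(true_t, ring_maia_px, inverse = TRUE)
    lm_src <- rbind(c(100, 100), c(668, 100), c(668, 668), c(100, 668))
    lm_dst <- apply_similarity(true_t, lm_src)
    # run the actual registration stage to recover the ring in degrees
    t_fit <- fit_similarity(lm_src, lm_dst)
    ring_fit <- ring_to_degrees(ring_af_px, t_fit, maia = maia,
                                grid_center_px = maia_c)
    es <- eye_series(eye_id = sprintf("eye%02d", e), visits = visits,
                     years = yrs, grid = grid, ring = ring_fit)
    es$ring_af_px <- ring_af_px
    es$landmarks <- list(src = lm_src, dst = lm_dst)
    es$age <- ages[e]
    es$r0 <- r0
    eyes[[e]] <- es
  }
  truth <- structure(list(r0 = r0s, config = config), class = "ground_truth")
  structure(list(eyes = eyes, truth = truth, config = config),
            class = "synthetic_cohort")
}

#' Closed-form ground-truth decline rates for a selection
#'
#' The exact time-averaged decline `(s(t_end) - s(0)) / t_end` of the
#' noiseless disease model, averaged over a selection's trend-eligible
#' loci. This is the oracle that pipeline slope estimates are compared
#' against in parameter-recovery checks.
#'
#' @param truth The `ground_truth` component of a cohort.
#' @param eye_index Which eye.
#' @param selection A `loci_selection` frozen at baseline.
#' @param grid The `test_grid`.
#' @param window_years End of the window, years (default the full
#'   follow-up).
#' @return Mean true rate in dB/year over the selected loci (`NA` for an
#'   empty selection).
#' @export
truth_rates <- function(truth, eye_index, selection, grid,
                        window_years = NULL) {
  cfg <- truth$config
  if (is.null(window_years)) {
    window_years <- (cfg$n_visits - 1) * cfg$visit_interval
  }
  ids <- selection$locus_ids[selection$trend_eligible]
  if (!length(ids)) return(NA_real_)
  r <- grid$loci$eccentricity[ids]
  r0 <- truth$r0[eye_index]
  s0 <- true_sensitivity(r, 0, r0, cfg)
  s1 <- true_sensitivity(r, window_years, r0, cfg)
  mean((s1 - s0) / window_years)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("synthetic cohort: ", x$config$n_eyes, " eyes, ",
      x$config$n_visits, " visits at ", x$config$visit_interval,
      "-year intervals (seed ", x$config$seed, ")\n", sep = "")
  invisible(x)
}
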