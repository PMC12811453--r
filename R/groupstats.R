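#' One-way repeated-measures ANOVA across the four metrics
#'
#' Compares per-eye values (progression slopes or baseline means) across
#' the four metrics with a within-subjects one-way ANOVA:
#' `F = MS_metric / MS_error` on `(k - 1, (k - 1)(n - 1))` degrees of
#' freedom, `k = 4` metrics, `n` complete-case eyes. No sphericity
#' correction is applied by default. When the omnibus test is significant,
#' Bonferroni-corrected pairwise comparisons identify which metrics differ.
#'
#' @param m Numeric matrix or data frame, rows = eyes, columns = metrics.
#'   Rows with any missing value are dropped (complete-case analysis).
#' @param pairwise_always Compute pairwise comparisons even when the
#'   omnibus test is not significant (default `FALSE`, matching the
#'   convention of gating post hocs on the omnibus result).
#' @param alpha Omnibus significance level gating the post hocs.
#' @param gg_correction Apply the Greenhouse-Geisser sphericity correction
#'   to the omnibus degrees of freedom (default `FALSE`).
#' @return List of class `rm_anova_result`: `F`, `df` (numerator,
#'   denominator), `p`, `n` (complete cases), `n_dropped`, `epsilon` (GG
#'   epsilon when requested), and `pairwise` (data frame from
#'   [bonferroni_pairwise()], or `NULL` when gated off).
#' @export
rm_anova <- function(m, pairwise_always = FALSE, alpha = 0.05,
                     gg_correction = FALSE) {
  m <- as.matrix(m)
  cc <- stats::complete.cases(m)
  n_dropped <- sum(!cc)
  m <- m[cc, , drop = FALSE]
  n <- nrow(m); k <- ncol(m)
  if (n < 2L) stop("repeated-measures ANOVA needs >= 2 complete-case eyes.",
                   call. = FALSE)
  # within-subjects one-way ANOVA via aov with a subject error stratum
  d <- data.frame(value = as.vector(m),
                  metric = factor(rep(colnames(m) %||% seq_len(k), each = n)),
                  subject = factor(rep(seq_len(n), times = k)))
  fit <- stats::aov(value ~ metric + Error(subject), data = d)
  tab <- summary(fit)[["Error: Within"]][[1]]
  Fstat <- tab["metric", "F value"]
  df1 <- tab["metric", "Df"]; df2 <- tab["Residuals", "Df"]
  ss_metric <- tab["metric", "Sum Sq"]; ss_err <- tab["Residuals", "Sum Sq"]
  if (ss_metric <= 1e-12 * max(ss_metric + ss_err, 1)) {
    # no metric effect at all (identical columns up to a subject shift):
    # report F = 0, p = 1 rather than a 0/0 artefact
    Fstat <- 0
  }
  eps <- NA_real_
  if (gg_correction) {
    eps <- .gg_epsilon(m)
    p <- stats::pf(Fstat, df1 * eps, df2 * eps, lower.tail = FALSE)
  } else if (Fstat == 0) {
    p <- 1
  } else {
    p <- tab["metric", "Pr(>F)"]
  }
  pw <- if (pairwise_always || (!is.na(p) && p < alpha)) {
    bonferroni_pairwise(m)
  }
  structure(list(F = unname(Fstat), df = c(df1, df2), p = unname(p),
                 n = n, n_dropped = n_dropped, epsilon = eps,
                 pairwise = pw),
            class = "rm_anova_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Greenhouse-Geisser epsilon from the sample covariance of the k columns.
.gg_epsilon <- function(m) {
  S <- stats::cov(m)
  k <- ncol(S)
  dbar <- mean(diag(S)); sbar <- mean(S)
  num <- (k * (dbar - sbar))^2
  den <- (k - 1) * (sum(S^2) - 2 * k * mean(rowMeans(S)^2) + k^2 * sbar^2)
  max(1 / (k - 1), min(1, num / den))
}

#' Bonferroni-corrected pairwise paired t-tests
#'
#' All `k(k-1)/2` pairwise paired t-tests between metric columns, with
#' each p value multiplied by the number of comparisons and capped at 1.
#' A pair whose difference vector has zero variance yields a degenerate
#' sentinel (`NA` statistic, flagged) rather than a fabricated p value.
#'
#' @param m Numeric matrix, rows = eyes, columns = metrics (complete
#'   cases).
#' @param alpha Significance level on the corrected p values.
#' @return Data frame: `a`, `b`, `mean_diff`, `t`, `p_raw`, `p_bonf`,
#'   `significant`, `degenerate`.
#' @export
bonferroni_pairwise <- function(m, alpha = 0.05) {
  m <- as.matrix(m)
  k <- ncol(m)
  nms <- colnames(m) %||% paste0("V", seq_len(k))
  pairs <- utils::combn(k, 2)
  n_comp <- ncol(pairs)
  rows <- lapply(seq_len(n_comp), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    d <- m[, i1] - m[, i2]
    if (stats::sd(d) == 0) {
      data.frame(a = nms[i1], b = nms[i2], mean_diff = mean(d),
                 t = NA_real_, p_raw = NA_real_, p_bonf = NA_real_,
                 significant = NA, degenerate = TRUE)
    } else {
      tt <- stats::t.test(m[, i1], m[, i2], paired = TRUE)
      data.frame(a = nms[i1], b = nms[i2], mean_diff = mean(d),
                 t = unname(tt$statistic), p_raw = tt$p.value,
                 p_bonf = min(1, n_comp * tt$p.value),
                 significant = min(1, n_comp * tt$p.value) < alpha,
                 degenerate = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Baseline metric versus age regression
#'
#' Ordinary least-squares fit of a baseline metric against age, reported
#' in the `y = ax + b` form with the coefficient of determination.
#'
#' @param values Per-eye baseline metric values, dB.
#' @param ages Per-eye ages, years.
#' @return List of class `age_fit`: `slope`, `intercept`, `r_squared`,
#'   `n`, and `label` (the formatted equation).
#' @export
baseline_age_fit <- function(values, ages) {
  ok <- is.finite(values) & is.finite(ages)
  values <- values[ok]; ages <- ages[ok]
  if (length(values) < 3L) stop("need >= 3 eyes.", call. = FALSE)
  if (stats::sd(ages) == 0) stop("ages are constant: slope undefined.", call. = FALSE)
  fit <- stats::lm(values ~ ages)
  co <- stats::coef(fit)
  r2 <- summary(fit)$r.squared
  structure(list(slope = unname(co[2]), intercept = unname(co[1]),
                 r_squared = r2, n = length(values),
                 label = sprintf("y = %.2fx + %.2f, R2 = %.2f",
                                 co[2], co[1], r2)),
            class = "age_fit")
}

#' @export
print.rm_anova_result <- function(x, ...) {
  cat(sprintf("repeated-measures ANOVA: F(%g, %g) = %.4g, p = %.4g (n = %d eyes",
              x$df[1], x$df[2], x$F, x$p, x$n))
  if (x$n_dropped) cat(", ", x$n_dropped, " dropped", sep = "")
  cat(")\n")
  if (!is.null(x$pairwise)) {
    cat("pairwise (Bonferroni-corrected):\n")
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}

#' @export
print.age_fit <- function(x, ...) {
  cat(x$label, " (n = ", x$n, ")\n", sep = "")
  invisible(x)
}
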