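#' Egger's linear regression test for funnel-plot asymmetry
#'
#' Ordinary least squares of the standardized effect `log_or_i / se_i` on
#' precision `1 / se_i` (the original unweighted formulation). Under funnel
#' symmetry the standardized effect is proportional to precision and the
#' intercept is zero; a non-zero intercept indicates small-study asymmetry,
#' conventionally read as publication bias when p < 0.05. The test is on
#' the intercept with k - 2 degrees of freedom.
#'
#' @param effects A data.frame with `log_or`, `se` columns or a list of
#'   `effect_estimate` objects; k >= 3 and at least two distinct se values.
#' @return An object of class `egger_result`: `intercept`, `intercept_se`,
#'   `slope`, `t_statistic`, `p_value`, `k`.
#' @export
egger_test <- function(effects) {
  eff <- as_effects_df(effects)
  k <- nrow(eff)
  if (k < 3L) stop_insufficient("Egger's test requires at least 3 studies")
  precision <- 1 / eff$se
  if (diff(range(precision)) < sqrt(.Machine$double.eps) * max(precision)) {
    stop_degenerate("all studies have identical standard errors; the Egger regression is degenerate")
  }
  fit <- stats::lm(std_effect ~ precision,
                   data = data.frame(std_effect = eff$log_or / eff$se,
                                     precision = precision))
  coefs <- summary(fit)$coefficients
  structure(
    list(intercept = coefs["(Intercept)", "Estimate"],
         intercept_se = coefs["(Intercept)", "Std. Error"],
         slope = coefs["precision", "Estimate"],
         t_statistic = coefs["(Intercept)", "t value"],
         p_value = coefs["(Intercept)", "Pr(>|t|)"],
         k = k),
    class = "egger_result"
  )
}

#' @export
print.egger_result <- function(x, ...) {
  cat(sprintf("<egger_result> intercept = %.3f (SE %.3f), t = %.3f (%d df), p = %.4f\n",
              x$intercept, x$intercept_se, x$t_statistic, x$k - 2L, x$p_value))
  invisible(x)
}

#' Begg-Mazumdar rank correlation test for publication bias
#'
#' Kendall rank correlation between the standardized deviates
#' `(theta_i - theta_fixed) / sqrt(v_i - v_fixed)` and the sampling
#' variances `v_i`, where `theta_fixed` and `v_fixed` are the fixed
#' inverse-variance pooled estimate and its variance. The score is the
#' concordant-minus-discordant pair count; the p-value uses the normal
#' approximation for Kendall's statistic with a continuity correction.
#' Supplementary to the funnel plot and Egger regression.
#'
#' @inheritParams egger_test
#' @return An object of class `begg_result`: `score` (C - D), `tau`,
#'   `z`, `p_value`, `k`.
#' @export
begg_rank_test <- function(effects) {
  eff <- as_effects_df(effects)
  k <- nrow(eff)
  if (k < 3L) stop_insufficient("Begg's rank test requires at least 3 studies")
  v <- eff$se^2
  w <- 1 / v
  theta_fixed <- sum(w * eff$log_or) / sum(w)
  v_fixed <- 1 / sum(w)
  dev <- (eff$log_or - theta_fixed) / sqrt(pmax(v - v_fixed, .Machine$double.eps))
  score <- 0L
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      score <- score + sign(dev[j] - dev[i]) * sign(v[j] - v[i])
    }
  }
  score <- as.integer(score)
  tau <- score / (k * (k - 1) / 2)
  sd_score <- sqrt(k * (k - 1) * (2 * k + 5) / 18)
  z <- if (score == 0) 0 else (abs(score) - 1) / sd_score
  structure(
    list(score = score, tau = tau, z = z,
         p_value = min(1, 2 * stats::pnorm(z, lower.tail = FALSE)),
         k = k),
    class = "begg_result"
  )
}

#' @export
print.begg_result <- function(x, ...) {
  cat(sprintf("<begg_result> Kendall score = %d (tau = %.3f), z = %.3f, p = %.4f\n",
              x$score, x$tau, x$z, x$p_value))
  invisible(x)
}

#' Funnel-plot coordinates and pseudo-confidence guide lines
#'
#' One point per study (`log_or` horizontal, `se` vertical, conventionally
#' plotted with the se axis inverted) plus guide lines at
#' `center +/- 1.96 * se` over a grid of standard errors, centred on the
#' fixed inverse-variance pooled estimate (or on the single effect when
#' k = 1).
#'
#' @inheritParams egger_test
#' @param se_grid Standard-error grid for the guide lines; defaults to 50
#'   points from 0 to 1.1 * max(se).
#' @return A list of class `funnel_data`: `points` (study, log_or, se),
#'   `guides` (se, lower, upper), `center`. Empty input yields empty
#'   components.
#' @export
funnel_data <- function(effects, se_grid = NULL) {
  if (is.null(effects) ||
      (is.data.frame(effects) && nrow(effects) == 0L) ||
      (is.list(effects) && !is.data.frame(effects) && length(effects) == 0L)) {
    return(structure(list(points = data.frame(study = character(),
                                              log_or = numeric(),
                                              se = numeric()),
                          guides = data.frame(se = numeric(), lower = numeric(),
                                              upper = numeric()),
                          center = NA_real_),
                     class = "funnel_data"))
  }
  eff <- as_effects_df(effects)
  w <- 1 / eff$se^2
  center <- sum(w * eff$log_or) / sum(w)
  if (is.null(se_grid)) se_grid <- seq(0, 1.1 * max(eff$se), length.out = 50L)
  if (any(se_grid < 0)) stop_validation("se_grid must be non-negative")
  structure(
    list(points = data.frame(study = eff$study, log_or = eff$log_or,
                             se = eff$se, stringsAsFactors = FALSE),
         guides = data.frame(se = se_grid,
                             lower = center - Z95 * se_grid,
                             upper = center + Z95 * se_grid),
         center = center),
    class = "funnel_data"
  )
}

#' Leave-one-out (one-way) sensitivity analysis
#'
#' Deletes each study in turn and re-runs the full Q-test-selected pooling
#' on the remaining k - 1 studies; model selection is re-made on every
#' subset, so each row is a complete meta-analysis in its own right.
#'
#' @param studies A [study_collection()] with k >= 3.
#' @param model One of [genetic_models()].
#' @param alpha_het,correction Passed to [select_and_pool()].
#' @return A data.frame with one row per omitted study (`omitted`, `k`,
#'   `or`, `ci_low`, `ci_high`, `method`, `het_p`), in input order, with
#'   the full `pooled_result` objects in `attr(, "results")`.
#' @export
leave_one_out <- function(studies, model = genetic_models(),
                          alpha_het = 0.05,
                          correction = c("none", "haldane")) {
  model <- match.arg(model)
  correction <- match.arg(correction)
  if (!inherits(studies, "study_collection")) {
    stop_validation("studies must be a study_collection")
  }
  k <- length(studies)
  if (k < 3L) stop_insufficient("leave-one-out requires at least 3 studies")
  labels <- study_labels(studies)
  results <- lapply(seq_len(k), function(i) {
    select_and_pool(studies[-i], model, alpha_het, correction)
  })
  out <- data.frame(
    omitted = labels,
    k = vapply(results, function(r) r$k, integer(1)),
    or = vapply(results, function(r) r$or_pooled, numeric(1)),
    ci_low = vapply(results, function(r) r$ci_low, numeric(1)),
    ci_high = vapply(results, function(r) r$ci_high, numeric(1)),
    method = vapply(results, function(r) r$method, character(1)),
    het_p = vapply(results, function(r) r$heterogeneity$p_value, numeric(1)),
    stringsAsFactors = FALSE
  )
  attr(out, "results") <- stats::setNames(results, labels)
  out
}
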