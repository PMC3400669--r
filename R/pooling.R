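#' Cochran's Q heterogeneity test and DerSimonian-Laird tau-squared
#'
#' Fixed inverse-variance weights `w_i = 1/se_i^2` give the pooled mean
#' `theta_hat = sum(w*theta)/sum(w)`; `Q = sum(w*(theta - theta_hat)^2)` is
#' chi-square with k-1 df under homogeneity. The between-study variance is
#' the DerSimonian-Laird moment estimator
#' `tau^2 = max(0, (Q - (k-1)) / (sum(w) - sum(w^2)/sum(w)))`, and
#' `I^2 = max(0, (Q - df)/Q) * 100`.
#'
#' @param effects A data.frame with columns `log_or` and `se` (e.g. from
#'   [study_effects()]), or a list of `effect_estimate` objects.
#' @return An object of class `heterogeneity_result`: `q`, `df`, `p_value`,
#'   `i_squared`, `tau_squared`, `k`.
#' @export
cochran_q <- function(effects) {
  eff <- as_effects_df(effects)
  k <- nrow(eff)
  if (k < 2L) stop_insufficient("heterogeneity assessment requires at least 2 studies")
  w <- 1 / eff$se^2
  theta_hat <- sum(w * eff$log_or) / sum(w)
  q <- sum(w * (eff$log_or - theta_hat)^2)
  df <- k - 1L
  tau_squared <- max(0, (q - df) / (sum(w) - sum(w^2) / sum(w)))
  structure(
    list(q = q, df = df,
         p_value = stats::pchisq(q, df = df, lower.tail = FALSE),
         i_squared = if (q > 0) max(0, (q - df) / q) * 100 else 0,
         tau_squared = tau_squared, k = k),
    class = "heterogeneity_result"
  )
}

#' @export
print.heterogeneity_result <- function(x, ...) {
  cat(sprintf("<heterogeneity_result> Q = %.3f (%d df), p = %.4f, I2 = %.1f%%, tau2 = %.4f\n",
              x$q, x$df, x$p_value, x$i_squared, x$tau_squared))
  invisible(x)
}

new_pooled_result <- function(log_or, se, method, weights, heterogeneity, k,
                              model = NA_character_, stratum_label = NA_character_) {
  structure(
    list(or_pooled = exp(log_or),
         ci_low = exp(log_or - Z95 * se),
         ci_high = exp(log_or + Z95 * se),
         log_or = log_or, se = se,
         method = method,
         weights = weights / sum(weights),
         heterogeneity = heterogeneity,
         k = k, model = model, stratum_label = stratum_label),
    class = "pooled_result"
  )
}

#' @export
print.pooled_result <- function(x, ...) {
  meth <- switch(x$method,
                 mantel_haenszel_fixed = "Mantel-Haenszel fixed effects",
                 dersimonian_laird_random = "DerSimonian-Laird random effects",
                 x$method)
  cat(sprintf("<pooled_result>%s%s k = %d, %s\n  OR = %.3f (95%% CI %.3f-%.3f)\n",
              if (is.na(x$model)) "" else paste0(" ", x$model),
              if (is.na(x$stratum_label)) "" else paste0(" [", x$stratum_label, "]"),
              x$k, meth, x$or_pooled, x$ci_low, x$ci_high))
  if (!is.null(x$heterogeneity)) {
    cat(sprintf("  heterogeneity: Q p = %.4f, I2 = %.1f%%, tau2 = %.4f\n",
                x$heterogeneity$p_value, x$heterogeneity$i_squared,
                x$heterogeneity$tau_squared))
  }
  invisible(x)
}

#' Mantel-Haenszel fixed-effects pooled odds ratio
#'
#' `OR_MH = sum(a_i d_i / n_i) / sum(b_i c_i / n_i)`, with the 95% CI from
#' the Robins-Breslow-Greenland variance of `ln OR_MH`. The attached
#' heterogeneity statistics come from [cochran_q()] on the per-study Woolf
#' effects (the usual companion even when MH is the pooled estimator); for a
#' single table no heterogeneity is attached.
#'
#' @param tables List of [build_contingency()] fourfold tables (k >= 1).
#' @param correction Continuity policy for the per-study effects feeding the
#'   heterogeneity statistics and weights display; the MH sums themselves
#'   use the raw cells.
#' @return A `pooled_result` with `method = "mantel_haenszel_fixed"`.
#' @export
pool_mantel_haenszel <- function(tables, correction = c("none", "haldane")) {
  correction <- match.arg(correction)
  if (inherits(tables, "fourfold_table")) tables <- list(tables)
  if (!length(tables)) stop_insufficient("pooling requires at least 1 table")
  a <- vapply(tables, function(t) t$a, numeric(1))
  b <- vapply(tables, function(t) t$b, numeric(1))
  cc <- vapply(tables, function(t) t$c, numeric(1))
  d <- vapply(tables, function(t) t$d, numeric(1))
  labels <- vapply(tables, function(t) t$study_label, character(1))
  n <- a + b + cc + d
  R_i <- a * d / n
  S_i <- b * cc / n
  R <- sum(R_i)
  S <- sum(S_i)
  if (R == 0 || S == 0) {
    stop_undefined("all tables are degenerate: the Mantel-Haenszel odds ratio is undefined")
  }
  P_i <- (a + d) / n
  Q_i <- (b + cc) / n
  # Robins-Breslow-Greenland variance of ln OR_MH
  var_rbg <- sum(P_i * R_i) / (2 * R^2) +
    sum(P_i * S_i + Q_i * R_i) / (2 * R * S) +
    sum(Q_i * S_i) / (2 * S^2)
  het <- if (length(tables) >= 2L) {
    cochran_q(data.frame(study = labels,
                         log_or = vapply(tables, function(t)
                           log_odds_ratio(t, correction)$log_or, numeric(1)),
                         se = vapply(tables, function(t)
                           log_odds_ratio(t, correction)$se, numeric(1))))
  } else NULL
  new_pooled_result(log_or = log(R / S), se = sqrt(var_rbg),
                    method = "mantel_haenszel_fixed",
                    weights = stats::setNames(S_i, labels),
                    heterogeneity = het, k = length(tables))
}

#' DerSimonian-Laird random-effects pooled odds ratio
#'
#' Random-effects weights `w_i = 1/(se_i^2 + tau^2)` with tau-squared from
#' [cochran_q()]; pooled `ln OR = sum(w*theta)/sum(w)` and 95% CI
#' `exp(estimate +/- 1.96/sqrt(sum(w)))`. When `Q <= k-1` (tau^2 truncated
#' to zero) this reduces to the fixed inverse-variance pool.
#'
#' @param effects A data.frame with `log_or`, `se` columns or a list of
#'   `effect_estimate` objects; k >= 2.
#' @return A `pooled_result` with `method = "dersimonian_laird_random"`.
#' @export
pool_dersimonian_laird <- function(effects) {
  eff <- as_effects_df(effects)
  if (nrow(eff) < 2L) stop_insufficient("random-effects pooling requires at least 2 studies")
  het <- cochran_q(eff)
  w <- 1 / (eff$se^2 + het$tau_squared)
  log_or <- sum(w * eff$log_or) / sum(w)
  new_pooled_result(log_or = log_or, se = 1 / sqrt(sum(w)),
                    method = "dersimonian_laird_random",
                    weights = stats::setNames(w, eff$study),
                    heterogeneity = het, k = nrow(eff))
}

#' Pool one genetic model with Q-test model selection
#'
#' Implements the heterogeneity-driven rule: compute Cochran's Q on the
#' per-study effects; if its p-value exceeds `alpha_het` (no evidence of
#' heterogeneity) pool with Mantel-Haenszel fixed effects, otherwise with
#' DerSimonian-Laird random effects. The boundary is strict: fixed effects
#' iff p > alpha_het.
#'
#' @param studies A [study_collection()] with k >= 2.
#' @param model One of [genetic_models()].
#' @param alpha_het Heterogeneity significance level (default 0.05).
#' @param correction Continuity policy passed to [log_odds_ratio()].
#' @return A `pooled_result`; its `method` field records the choice.
#' @examples
#' select_and_pool(egf_glioma_studies(), "AA_vs_GG")
#' @export
select_and_pool <- function(studies, model = genetic_models(),
                            alpha_het = 0.05,
                            correction = c("none", "haldane")) {
  model <- match.arg(model)
  correction <- match.arg(correction)
  if (!inherits(studies, "study_collection")) {
    stop_validation("studies must be a study_collection")
  }
  if (length(studies) < 2L) stop_insufficient("model selection requires at least 2 studies")
  if (!is.numeric(alpha_het) || length(alpha_het) != 1L ||
      alpha_het <= 0 || alpha_het >= 1) {
    stop_validation("alpha_het must be in (0,1)")
  }
  eff <- study_effects(studies, model, correction)
  het <- cochran_q(eff)
  res <- if (het$p_value > alpha_het) {
    tables <- lapply(studies$studies, build_contingency, model = model)
    pool_mantel_haenszel(tables, correction)
  } else {
    pool_dersimonian_laird(eff)
  }
  res$model <- model
  res
}

#' Subgroup meta-analysis by ethnicity or control source
#'
#' Partitions the collection by the stratifier and applies
#' [select_and_pool()] within each stratum independently, so the
#' fixed/random choice is re-made per stratum.
#'
#' @param studies A [study_collection()].
#' @param stratifier `"ethnicity"` or `"control_source"`.
#' @param model One of [genetic_models()].
#' @param alpha_het,correction Passed to [select_and_pool()].
#' @return Named list of `pooled_result`, one per stratum present, each
#'   with `stratum_label` set; strata follow the enumeration order.
#' @export
stratified_analysis <- function(studies,
                                stratifier = c("ethnicity", "control_source"),
                                model = genetic_models(),
                                alpha_het = 0.05,
                                correction = c("none", "haldane")) {
  stratifier <- match.arg(stratifier)
  model <- match.arg(model)
  if (!inherits(studies, "study_collection")) {
    stop_validation("studies must be a study_collection")
  }
  values <- vapply(studies$studies, function(s) s[[stratifier]], character(1))
  levels_present <- intersect(switch(stratifier,
                                     ethnicity = ETHNICITIES,
                                     control_source = CONTROL_SOURCES),
                              values)
  out <- lapply(levels_present, function(v) {
    idx <- which(values == v)
    if (length(idx) < 2L) {
      stop_insufficient(sprintf(
        "stratum '%s' of %s has %d study(ies); at least 2 are required",
        v, stratifier, length(idx)))
    }
    res <- select_and_pool(studies[idx], model, alpha_het, correction)
    res$stratum_label <- v
    res
  })
  stats::setNames(out, levels_present)
}
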