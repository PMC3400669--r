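# Shared internal helpers: classed conditions and the 95% z quantile.

# two-sided 95% normal quantile, fixed once for all intervals
Z95 <- stats::qnorm(0.975)

snpmeta_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "snpmeta_error")))
}

stop_validation <- function(msg) snpmeta_stop(msg, "snpmeta_validation_error")
stop_parse <- function(msg) snpmeta_stop(msg, "snpmeta_parse_error")
stop_insufficient <- function(msg) snpmeta_stop(msg, "snpmeta_insufficient_studies")
stop_undefined <- function(msg) snpmeta_stop(msg, "snpmeta_undefined_effect")
stop_degenerate <- function(msg) snpmeta_stop(msg, "snpmeta_degenerate_regression")

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}

# Coerce the various effect representations (data.frame, list of
# effect_estimate, single effect_estimate) to a data.frame with columns
# study, log_or, se.
as_effects_df <- function(effects) {
  if (inherits(effects, "effect_estimate")) effects <- list(effects)
  if (is.list(effects) && !is.data.frame(effects) &&
      all(vapply(effects, inherits, logical(1), "effect_estimate"))) {
    effects <- data.frame(
      study = vapply(effects, function(e) e$study_label, character(1)),
      log_or = vapply(effects, function(e) e$log_or, numeric(1)),
      se = vapply(effects, function(e) e$se, numeric(1)),
      stringsAsFactors = FALSE
    )
  }
  if (!is.data.frame(effects)) {
    stop_validation("effects must be a data.frame or a list of effect_estimate objects")
  }
  if (!all(c("log_or", "se") %in% names(effects))) {
    stop_validation("effects must have columns 'log_or' and 'se'")
  }
  if (!"study" %in% names(effects)) {
    effects$study <- paste0("study_", seq_len(nrow(effects)))
  }
  if (any(!is.finite(effects$log_or)) || any(!is.finite(effects$se)) ||
      any(effects$se <= 0)) {
    stop_validation("all effects must have finite log_or and se > 0")
  }
  effects
}
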