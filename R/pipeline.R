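#' Run the full meta-analysis pipeline
#'
#' End-to-end analysis of a study table: per-study effects under every
#' requested genetic model, Hardy-Weinberg QC of the control arms, pooled
#' results overall and within the requested strata (with Q-test-driven
#' fixed/random selection per cell), Egger and Begg publication-bias tests
#' per model, leave-one-out sensitivity per model, and funnel-plot data.
#' The CLI and report writers add no computation beyond this function.
#'
#' @param input Path to a delimited study table, a [study_collection()], or
#'   the sentinel `"fixture"` for the bundled seven-study dataset.
#' @param models Subset of [genetic_models()] (default all four).
#' @param stratify Subset of `c("ethnicity", "control_source")` (default
#'   both); use `character(0)` for overall-only.
#' @param alpha_het Heterogeneity threshold for model selection, in (0,1).
#' @param correction Continuity-correction policy for per-study effects.
#' @param out_dir Optional directory; when given, all tables are written as
#'   TSV plus a key-value summary and decision log (see [write_report()]).
#' @param verbose Print the model-selection log as it is produced.
#' @return A list of class `meta_report`: `collection`, `effects`, `hwe`,
#'   `pooled`, `bias`, `leave_one_out`, `funnel`, `log`.
#' @examples
#' rep <- run_full_analysis("fixture", models = "AA_vs_GG")
#' rep$pooled
#' @export
run_full_analysis <- function(input = "fixture",
                              models = genetic_models(),
                              stratify = c("ethnicity", "control_source"),
                              alpha_het = 0.05,
                              correction = c("none", "haldane"),
                              out_dir = NULL,
                              verbose = FALSE) {
  correction <- match.arg(correction)
  models <- match.arg(models, genetic_models(), several.ok = TRUE)
  if (length(stratify)) {
    stratify <- match.arg(stratify, c("ethnicity", "control_source"),
                          several.ok = TRUE)
  }
  collection <- if (inherits(input, "study_collection")) {
    input
  } else if (identical(input, "fixture")) {
    egf_glioma_studies()
  } else {
    read_study_table(input)
  }
  if (length(collection) < 2L) {
    stop_insufficient("the analysis requires at least 2 parsed studies")
  }

  log_lines <- character()
  note <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    if (verbose) message(line)
    log_lines <<- c(log_lines, line)
  }

  pooled_row <- function(res, stratum_type, stratum) {
    het <- res$heterogeneity
    note("model=%s stratum=%s k=%d Q_p=%.4f -> %s",
         res$model, stratum, res$k, het$p_value, res$method)
    data.frame(model = res$model, stratum_type = stratum_type,
               stratum = stratum, k = res$k,
               or = res$or_pooled, ci_low = res$ci_low, ci_high = res$ci_high,
               q = het$q, het_p = het$p_value, i_squared = het$i_squared,
               tau_squared = het$tau_squared, method = res$method,
               stringsAsFactors = FALSE)
  }

  effects <- do.call(rbind, lapply(models, study_effects,
                                   collection = collection,
                                   correction = correction))
  hwe <- hwe_table(collection)

  pooled <- list()
  bias <- list()
  loo <- list()
  funnel <- list()
  for (m in models) {
    overall <- select_and_pool(collection, m, alpha_het, correction)
    pooled[[length(pooled) + 1L]] <- pooled_row(overall, "overall", "Total")
    for (strat in stratify) {
      for (res in stratified_analysis(collection, strat, m, alpha_het,
                                      correction)) {
        pooled[[length(pooled) + 1L]] <- pooled_row(res, strat, res$stratum_label)
      }
    }
    eff_m <- effects[effects$model == m, ]
    if (nrow(eff_m) >= 3L) {
      eg <- egger_test(eff_m)
      bg <- begg_rank_test(eff_m)
      bias[[length(bias) + 1L]] <- data.frame(
        model = m, k = eg$k,
        egger_intercept = eg$intercept, egger_t = eg$t_statistic,
        egger_p = eg$p_value,
        begg_score = bg$score, begg_tau = bg$tau, begg_z = bg$z,
        begg_p = bg$p_value, stringsAsFactors = FALSE)
      loo_m <- leave_one_out(collection, m, alpha_het, correction)
      attr(loo_m, "results") <- NULL
      loo[[length(loo) + 1L]] <- cbind(model = m, loo_m,
                                       stringsAsFactors = FALSE)
    }
    fd <- funnel_data(eff_m)
    funnel[[m]] <- fd
  }

  report <- structure(
    list(collection = collection,
         effects = effects,
         hwe = hwe,
         pooled = do.call(rbind, pooled),
         bias = if (length(bias)) do.call(rbind, bias) else NULL,
         leave_one_out = if (length(loo)) do.call(rbind, loo) else NULL,
         funnel = funnel,
         log = log_lines),
    class = "meta_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.meta_report <- function(x, ...) {
  cat(sprintf("<meta_report> %d studies, %d pooled rows\n",
              length(x$collection), nrow(x$pooled)))
  print(x$pooled, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write a meta_report as delimited text tables
#'
#' Emits `effects.tsv`, `hwe.tsv`, `pooled.tsv`, `bias.tsv`,
#' `leave_one_out.tsv`, `funnel.tsv` (points for all models),
#' `summary.txt` (one `key=value` line per pooled row, full precision) and
#' `log.txt` (the model-selection log). Presentation rounding (2 decimals
#' for ORs, 3 for p-values) appears only in `summary.txt`'s `display` keys;
#' the TSVs carry full precision.
#'
#' @param report A `meta_report` from [run_full_analysis()].
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!inherits(report, "meta_report")) stop_validation("report must be a meta_report")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, file) {
    if (!is.null(df)) {
      utils::write.table(df, file.path(dir, file), sep = "\t",
                         row.names = FALSE, quote = FALSE)
    }
  }
  tsv(as.data.frame(report$collection), "studies.tsv")
  tsv(report$effects, "effects.tsv")
  tsv(report$hwe, "hwe.tsv")
  tsv(report$pooled, "pooled.tsv")
  tsv(report$bias, "bias.tsv")
  tsv(report$leave_one_out, "leave_one_out.tsv")
  funnel_points <- do.call(rbind, lapply(names(report$funnel), function(m) {
    pts <- report$funnel[[m]]$points
    if (nrow(pts)) cbind(model = m, pts, stringsAsFactors = FALSE) else NULL
  }))
  tsv(funnel_points, "funnel.tsv")
  keyvals <- apply(report$pooled, 1, function(row) {
    key <- sprintf("%s.%s", row[["model"]], gsub("\\s+", "_", row[["stratum"]]))
    sprintf("%s=or:%s,ci:%s-%s,het_p:%s,method:%s,display:%.2f (%.2f-%.2f) p=%.3f",
            key, row[["or"]], row[["ci_low"]], row[["ci_high"]],
            row[["het_p"]], row[["method"]],
            as.numeric(row[["or"]]), as.numeric(row[["ci_low"]]),
            as.numeric(row[["ci_high"]]), as.numeric(row[["het_p"]]))
  })
  writeLines(keyvals, file.path(dir, "summary.txt"))
  writeLines(report$log, file.path(dir, "log.txt"))
  invisible(dir)
}

#' Simulation study: calibration of the full pipeline
#'
#' Repeatedly simulates a collection from `config` (one derived substream
#' per replicate) and runs the Q-test-selected pooling per genetic model,
#' summarising estimation and test calibration against the generator's
#' known truth.
#'
#' Per model the summary reports the mean and SD of the pooled OR, the
#' 95% CI coverage of the replicate truth (the analytic per-study contrast
#' OR, geometric-mean-averaged over studies; for the codominant contrasts
#' with `tau = 0` this is exactly `or_AA` or `or_GA`), the Q-test rejection
#' rate at `alpha_het` and the Egger-test rejection rate at 0.05.
#'
#' @param config A [sim_config()].
#' @param n_reps Number of replicates (>= 1).
#' @param models Subset of [genetic_models()].
#' @param alpha_het Heterogeneity threshold.
#' @return A data.frame of class `sim_study_summary`, one row per model,
#'   with the per-replicate results in `attr(, "replicates")`.
#' @export
run_simulation_study <- function(config = sim_config(), n_reps = 200L,
                                 models = genetic_models(),
                                 alpha_het = 0.05) {
  if (!inherits(config, "sim_config")) stop_validation("config must be a sim_config")
  if (!is_count(n_reps) || n_reps < 1) {
    stop_validation("n_reps must be a positive integer")
  }
  models <- match.arg(models, genetic_models(), several.ok = TRUE)
  rep_rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cfg_r <- config
    cfg_r$seed <- substream_seed(config$seed, r, salt = 15485863L)
    sim <- simulate_collection(cfg_r)
    rows <- lapply(models, function(m) {
      res <- select_and_pool(sim$collection, m, alpha_het, "haldane")
      truth_or <- exp(mean(log(sim$truth[[paste0("or_", m)]])))
      eff <- study_effects(sim$collection, m, "haldane")
      egger_p <- if (nrow(eff) >= 3L) egger_test(eff)$p_value else NA_real_
      data.frame(rep = r, model = m, or = res$or_pooled,
                 ci_low = res$ci_low, ci_high = res$ci_high,
                 method = res$method, het_p = res$heterogeneity$p_value,
                 truth_or = truth_or,
                 covered = res$ci_low <= truth_or & truth_or <= res$ci_high,
                 egger_p = egger_p, stringsAsFactors = FALSE)
    })
    rep_rows[[r]] <- do.call(rbind, rows)
  }
  reps <- do.call(rbind, rep_rows)
  summary <- do.call(rbind, lapply(models, function(m) {
    sub <- reps[reps$model == m, ]
    data.frame(model = m, n_reps = n_reps,
               mean_or = mean(sub$or), sd_or = stats::sd(sub$or),
               mean_truth_or = mean(sub$truth_or),
               ci_coverage = mean(sub$covered),
               q_reject_rate = mean(sub$het_p <= alpha_het),
               egger_reject_rate = mean(sub$egger_p < 0.05, na.rm = TRUE),
               random_effects_rate = mean(sub$method == "dersimonian_laird_random"),
               stringsAsFactors = FALSE)
  }))
  attr(summary, "replicates") <- reps
  class(summary) <- c("sim_study_summary", class(summary))
  summary
}
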