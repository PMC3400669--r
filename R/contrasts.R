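#' The four genetic-model contrasts
#'
#' Collapsing rules from three genotypes to a 2x2 exposed/unexposed split,
#' with the A-carrying category as "exposed" throughout (so OR > 1 means the
#' variant A allele increases disease odds):
#' \describe{
#'   \item{AA_vs_GG}{codominant homozygote contrast; GA is dropped}
#'   \item{GA_vs_GG}{codominant heterozygote contrast; AA is dropped}
#'   \item{dominant}{AA+GA versus GG}
#'   \item{recessive}{AA versus GA+GG}
#' }
#'
#' @return Character vector of the four model names.
#' @export
genetic_models <- function() c("AA_vs_GG", "GA_vs_GG", "dominant", "recessive")

#' Build the 2x2 table for one study under one genetic model
#'
#' @param study A [study()] object.
#' @param model One of [genetic_models()].
#' @return An object of class `fourfold_table` with cells `a` (exposed
#'   cases), `b` (exposed controls), `c` (unexposed cases), `d` (unexposed
#'   controls) and the study label. Zero cells are permitted here and
#'   handled by [log_odds_ratio()].
#' @examples
#' s <- egf_glioma_studies()$studies[[1]]
#' build_contingency(s, "recessive")
#' @export
build_contingency <- function(study, model = genetic_models()) {
  model <- match.arg(model)
  if (!inherits(study, "snp_study")) stop_validation("study must be an snp_study")
  ca <- gt_vec(study$cases)
  co <- gt_vec(study$controls)
  cells <- switch(model,
    AA_vs_GG = c(a = ca[["AA"]], b = co[["AA"]], c = ca[["GG"]], d = co[["GG"]]),
    GA_vs_GG = c(a = ca[["GA"]], b = co[["GA"]], c = ca[["GG"]], d = co[["GG"]]),
    dominant = c(a = ca[["GA"]] + ca[["AA"]], b = co[["GA"]] + co[["AA"]],
                 c = ca[["GG"]], d = co[["GG"]]),
    recessive = c(a = ca[["AA"]], b = co[["AA"]],
                  c = ca[["GG"]] + ca[["GA"]], d = co[["GG"]] + co[["GA"]])
  )
  structure(list(a = unname(cells["a"]), b = unname(cells["b"]),
                 c = unname(cells["c"]), d = unname(cells["d"]),
                 study_label = study$label, model = model),
            class = "fourfold_table")
}

#' @export
print.fourfold_table <- function(x, ...) {
  cat(sprintf("<fourfold_table> %s (%s)\n            exposed unexposed\n  cases    %7g %9g\n  controls %7g %9g\n",
              x$study_label, x$model, x$a, x$c, x$b, x$d))
  invisible(x)
}

#' Per-study log odds ratio with Woolf variance
#'
#' Computes `log_or = ln(ad/bc)` and its Woolf standard error
#' `sqrt(1/a + 1/b + 1/c + 1/d)`. With `correction = "haldane"`, 0.5 is
#' added to all four cells when any cell is zero (Haldane-Anscombe) and the
#' `corrected` flag is set; with the default `"none"`, a zero cell leaves
#' the log OR undefined and is an error.
#'
#' @param table A [build_contingency()] fourfold table, or anything with
#'   numeric fields `a`, `b`, `c`, `d`.
#' @param correction Continuity-correction policy, `"none"` or `"haldane"`.
#' @return An object of class `effect_estimate`: `log_or`, `se`,
#'   `study_label`, `corrected`.
#' @export
log_odds_ratio <- function(table, correction = c("none", "haldane")) {
  correction <- match.arg(correction)
  cells <- c(a = table$a, b = table$b, c = table$c, d = table$d)
  if (any(!is.finite(cells)) || any(cells < 0)) {
    stop_validation("table cells must be non-negative numbers")
  }
  label <- if (is.null(table$study_label)) "<unnamed>" else table$study_label
  if ((cells["a"] + cells["c"]) == 0 || (cells["b"] + cells["d"]) == 0 ||
      (cells["a"] + cells["b"]) == 0 || (cells["c"] + cells["d"]) == 0) {
    stop_undefined(sprintf(
      "study '%s': an entire table margin is zero; the odds ratio is undefined",
      label))
  }
  corrected <- FALSE
  if (any(cells == 0)) {
    if (correction == "haldane") {
      cells <- cells + 0.5
      corrected <- TRUE
    } else {
      stop_undefined(sprintf(
        "study '%s': zero cell with correction = \"none\"; enable the Haldane-Anscombe correction",
        label))
    }
  }
  structure(
    list(log_or = log(cells[["a"]] * cells[["d"]] / (cells[["b"]] * cells[["c"]])),
         se = sqrt(sum(1 / cells)),
         study_label = label,
         corrected = corrected),
    class = "effect_estimate"
  )
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("<effect_estimate> %s: OR = %.4f (log OR %.4f, SE %.4f)%s\n",
              x$study_label, exp(x$log_or), x$log_or, x$se,
              if (x$corrected) " [continuity-corrected]" else ""))
  invisible(x)
}

#' Per-study effect table for one genetic model
#'
#' Builds every study's 2x2 table under `model` and estimates its log odds
#' ratio. The returned data frame is the package's exchange format for
#' effect lists and matches the exportable layout
#' `study,model,a,b,c,d,log_or,se,or,ci_low,ci_high,corrected`.
#'
#' @param collection A [study_collection()].
#' @param model One of [genetic_models()].
#' @param correction Passed to [log_odds_ratio()].
#' @return A data.frame with one row per study.
#' @export
study_effects <- function(collection, model = genetic_models(),
                          correction = c("none", "haldane")) {
  model <- match.arg(model)
  correction <- match.arg(correction)
  if (!inherits(collection, "study_collection")) {
    stop_validation("collection must be a study_collection")
  }
  rows <- lapply(collection$studies, function(s) {
    tab <- build_contingency(s, model)
    est <- log_odds_ratio(tab, correction)
    data.frame(study = s$label, model = model,
               a = tab$a, b = tab$b, c = tab$c, d = tab$d,
               log_or = est$log_or, se = est$se,
               or = exp(est$log_or),
               ci_low = exp(est$log_or - Z95 * est$se),
               ci_high = exp(est$log_or + Z95 * est$se),
               corrected = est$corrected,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
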