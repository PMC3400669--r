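ETHNICITIES <- c("Asian", "Caucasian")
CONTROL_SOURCES <- c("Hospital", "Population")

# case-insensitive match against a closed stratum enumeration
match_stratum <- function(x, levels, what, label = NULL) {
  if (length(x) != 1L || is.na(x)) {
    stop_validation(sprintf("%s must be one of %s", what,
                            paste(levels, collapse = ", ")))
  }
  i <- match(tolower(trimws(x)), tolower(levels))
  if (is.na(i)) {
    who <- if (is.null(label)) "" else sprintf(" (study '%s')", label)
    stop_validation(sprintf("unknown %s '%s'%s; expected one of %s",
                            what, x, who, paste(levels, collapse = ", ")))
  }
  levels[i]
}

#' A single case-control genotype study
#'
#' @param label Study label (conventionally first author + year); must be
#'   unique within a collection.
#' @param ethnicity One of `"Asian"`, `"Caucasian"` (case-insensitive).
#' @param control_source One of `"Hospital"`, `"Population"`
#'   (case-insensitive).
#' @param cases,controls [genotype_counts()] for each arm.
#' @param year Optional publication year.
#' @return An object of class `snp_study`.
#' @examples
#' study("Bao 2011", "Asian", "Hospital",
#'       cases = genotype_counts(64, 71, 25),
#'       controls = genotype_counts(141, 151, 28))
#' @export
study <- function(label, ethnicity, control_source, cases, controls,
                  year = NA_integer_) {
  if (!is.character(label) || length(label) != 1L || !nzchar(label)) {
    stop_validation("study label must be a non-empty string")
  }
  if (!inherits(cases, "genotype_counts") || !inherits(controls, "genotype_counts")) {
    stop_validation(sprintf("cases and controls of study '%s' must be genotype_counts", label))
  }
  structure(
    list(label = label,
         year = as.integer(year),
         ethnicity = match_stratum(ethnicity, ETHNICITIES, "ethnicity", label),
         control_source = match_stratum(control_source, CONTROL_SOURCES,
                                        "control source", label),
         cases = cases, controls = controls),
    class = "snp_study"
  )
}

#' @export
print.snp_study <- function(x, ...) {
  cat(sprintf("<snp_study> %s [%s, %s-based]\n  cases    GG/GA/AA = %d/%d/%d (n=%d)\n  controls GG/GA/AA = %d/%d/%d (n=%d)\n",
              x$label, x$ethnicity, x$control_source,
              x$cases$n_GG, x$cases$n_GA, x$cases$n_AA, x$cases$total,
              x$controls$n_GG, x$controls$n_GA, x$controls$n_AA,
              x$controls$total))
  invisible(x)
}

#' An ordered collection of studies
#'
#' @param studies List of [study()] objects with unique labels.
#' @param provenance Free-text note on where the data came from.
#' @return An object of class `study_collection`.
#' @export
study_collection <- function(studies, provenance = "") {
  if (!is.list(studies) || !all(vapply(studies, inherits, logical(1), "snp_study"))) {
    stop_validation("studies must be a list of snp_study objects")
  }
  labels <- vapply(studies, function(s) s$label, character(1))
  dup <- labels[duplicated(labels)]
  if (length(dup)) {
    stop_validation(sprintf("duplicate study label(s): %s",
                            paste(unique(dup), collapse = ", ")))
  }
  structure(list(studies = studies, provenance = provenance),
            class = "study_collection")
}

#' @export
length.study_collection <- function(x) length(x$studies)

#' @export
`[.study_collection` <- function(x, i) {
  study_collection(x$studies[i], provenance = x$provenance)
}

study_labels <- function(x) vapply(x$studies, function(s) s$label, character(1))

#' @export
print.study_collection <- function(x, ...) {
  cat(sprintf("<study_collection> %d studies", length(x)))
  if (nzchar(x$provenance)) cat(" |", x$provenance)
  cat("\n")
  print(as.data.frame(x), row.names = FALSE)
  invisible(x)
}

#' @describeIn study_collection Flatten to the count-mode delimited layout
#'   (one row per study).
#' @param x A `study_collection`.
#' @param ... Unused.
#' @export
as.data.frame.study_collection <- function(x, ...) {
  do.call(rbind, lapply(x$studies, function(s) {
    data.frame(study = s$label, year = s$year,
               ethnicity = s$ethnicity, source = s$control_source,
               n_case = s$cases$total, n_control = s$controls$total,
               case_GG = s$cases$n_GG, case_GA = s$cases$n_GA,
               case_AA = s$cases$n_AA,
               ctrl_GG = s$controls$n_GG, ctrl_GA = s$controls$n_GA,
               ctrl_AA = s$controls$n_AA,
               stringsAsFactors = FALSE)
  }))
}
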