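#' Configuration for the case-control genotype study simulator
#'
#' Defaults emulate the bundled seven-study world: study arms between a few
#' dozen and several hundred subjects, control A-allele frequencies spanning
#' the 0.27-0.60 range observed across the bundled studies, a 3:4
#' Asian:Caucasian mix with mostly hospital-based control series, and no
#' true genotype effect or between-study heterogeneity.
#'
#' @param k Number of studies (>= 1).
#' @param n_case_range,n_control_range Inclusive integer ranges for the per-
#'   study arm sizes.
#' @param allele_freq_A_range Range (within (0,1)) for the control A-allele
#'   frequency, drawn uniformly per study.
#' @param or_GA,or_AA True per-genotype odds ratios of GA and AA versus GG.
#' @param tau Between-study SD of the shared multiplicative shift applied
#'   (on the log scale) to both non-reference genotype odds ratios.
#' @param ethnicity_mix Named probabilities over `c("Asian", "Caucasian")`.
#' @param control_source_mix Named probabilities over
#'   `c("Hospital", "Population")`.
#' @param seed Integer seed; per-study substreams are derived from it, so
#'   increasing `k` extends a collection without reshuffling earlier
#'   studies.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(k = 7L,
                       n_case_range = c(40L, 700L),
                       n_control_range = c(75L, 700L),
                       allele_freq_A_range = c(0.27, 0.60),
                       or_GA = 1, or_AA = 1, tau = 0,
                       ethnicity_mix = c(Asian = 3 / 7, Caucasian = 4 / 7),
                       control_source_mix = c(Hospital = 5 / 7, Population = 2 / 7),
                       seed = 1L) {
  if (!is_count(k) || k < 1) stop_validation("k must be a positive integer")
  for (r in list(n_case_range, n_control_range)) {
    if (length(r) != 2L || !is_count(r[1]) || !is_count(r[2]) ||
        r[1] < 1 || r[2] < r[1]) {
      stop_validation("arm size ranges must be non-empty positive integer ranges")
    }
  }
  fr <- allele_freq_A_range
  if (length(fr) != 2L || fr[1] <= 0 || fr[2] >= 1 || fr[2] < fr[1]) {
    stop_validation("allele_freq_A_range must be a non-empty range inside (0,1)")
  }
  if (!is.numeric(or_GA) || or_GA <= 0 || !is.numeric(or_AA) || or_AA <= 0) {
    stop_validation("or_GA and or_AA must be positive")
  }
  if (!is.numeric(tau) || tau < 0) stop_validation("tau must be >= 0")
  for (mix in list(ethnicity_mix, control_source_mix)) {
    if (any(mix < 0) || sum(mix) <= 0) stop_validation("stratum mixes must be non-negative with positive sum")
  }
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop_validation("seed must be a finite number")
  }
  structure(
    list(k = as.integer(k),
         n_case_range = as.integer(n_case_range),
         n_control_range = as.integer(n_control_range),
         allele_freq_A_range = fr,
         or_GA = or_GA, or_AA = or_AA, tau = tau,
         ethnicity_mix = ethnicity_mix / sum(ethnicity_mix),
         control_source_mix = control_source_mix / sum(control_source_mix),
         seed = as.integer(seed %% 2147483647)),
    class = "sim_config"
  )
}

# deterministic per-study / per-replicate substream seeds below 2^31
substream_seed <- function(seed, i, salt = 104729L) {
  as.integer((as.double(seed) + as.double(salt) * i) %% 2147483647)
}

# analytic odds ratio implied by a pair of genotype probability vectors
# (GG, GA, AA) under one contrast
contrast_or <- function(p_case, p_ctrl, model) {
  odds <- function(p, exposed, unexposed) {
    sum(p[exposed]) / sum(p[unexposed])
  }
  idx <- switch(model,
    AA_vs_GG = list(e = 3L, u = 1L),
    GA_vs_GG = list(e = 2L, u = 1L),
    dominant = list(e = 2:3, u = 1L),
    recessive = list(e = 3L, u = 1:2)
  )
  odds(p_case, idx$e, idx$u) / odds(p_ctrl, idx$e, idx$u)
}

#' Simulate a collection of case-control genotype studies with known truth
#'
#' Per study: the control A-allele frequency `q` is drawn uniformly from its
#' range; control genotype probabilities follow Hardy-Weinberg
#' `(p^2, 2pq, q^2)` with `p = 1 - q`; a study-level shift
#' `delta ~ Normal(0, tau^2)` is drawn; case genotype probabilities are
#' proportional to the control probabilities times
#' `(1, or_GA * e^delta, or_AA * e^delta)`; genotype counts are multinomial
#' within each arm; strata are assigned from the configured mixes. The
#' codominant contrasts therefore have true per-study odds ratios
#' `or_AA * e^delta` and `or_GA * e^delta` exactly, while the dominant and
#' recessive true odds ratios also depend on `q`.
#'
#' @param config A [sim_config()].
#' @return A list of class `simulated_collection`: `collection` (a
#'   [study_collection()]) and `truth`, a data.frame with one row per study
#'   carrying `q_A`, `delta`, the generating genotype probabilities and the
#'   analytic odds ratio of every contrast.
#' @export
simulate_collection <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) stop_validation("config must be a sim_config")
  studies <- vector("list", config$k)
  truth_rows <- vector("list", config$k)
  eps <- 1e-6
  for (i in seq_len(config$k)) {
    set.seed(substream_seed(config$seed, i))
    q <- stats::runif(1, config$allele_freq_A_range[1], config$allele_freq_A_range[2])
    while (q <= eps || q >= 1 - eps) {
      q <- stats::runif(1, config$allele_freq_A_range[1], config$allele_freq_A_range[2])
    }
    p <- 1 - q
    p_ctrl <- c(p^2, 2 * p * q, q^2)
    delta <- if (config$tau > 0) stats::rnorm(1, 0, config$tau) else 0
    wts <- p_ctrl * c(1, config$or_GA * exp(delta), config$or_AA * exp(delta))
    p_case <- wts / sum(wts)
    n_case <- sample_range(config$n_case_range)
    n_ctrl <- sample_range(config$n_control_range)
    case_counts <- stats::rmultinom(1, n_case, p_case)[, 1]
    ctrl_counts <- stats::rmultinom(1, n_ctrl, p_ctrl)[, 1]
    ethnicity <- sample(names(config$ethnicity_mix), 1, prob = config$ethnicity_mix)
    source <- sample(names(config$control_source_mix), 1,
                     prob = config$control_source_mix)
    label <- sprintf("sim_%03d", i)
    studies[[i]] <- study(label, ethnicity, source,
                          cases = genotype_counts(case_counts[1], case_counts[2],
                                                  case_counts[3]),
                          controls = genotype_counts(ctrl_counts[1], ctrl_counts[2],
                                                     ctrl_counts[3]))
    truth_rows[[i]] <- data.frame(
      study = label, q_A = q, delta = delta,
      p_case_GG = p_case[1], p_case_GA = p_case[2], p_case_AA = p_case[3],
      p_ctrl_GG = p_ctrl[1], p_ctrl_GA = p_ctrl[2], p_ctrl_AA = p_ctrl[3],
      or_AA_vs_GG = contrast_or(p_case, p_ctrl, "AA_vs_GG"),
      or_GA_vs_GG = contrast_or(p_case, p_ctrl, "GA_vs_GG"),
      or_dominant = contrast_or(p_case, p_ctrl, "dominant"),
      or_recessive = contrast_or(p_case, p_ctrl, "recessive"),
      stringsAsFactors = FALSE
    )
  }
  truth <- do.call(rbind, truth_rows)
  attr(truth, "config") <- config
  structure(
    list(collection = study_collection(studies,
                                       provenance = sprintf("simulated (seed %d)",
                                                            config$seed)),
         truth = truth),
    class = "simulated_collection"
  )
}

sample_range <- function(range) {
  if (range[1] == range[2]) range[1] else
    sample(seq(range[1], range[2]), 1L)
}

#' @export
print.simulated_collection <- function(x, ...) {
  cfg <- attr(x$truth, "config")
  cat(sprintf("<simulated_collection> k = %d, or_GA = %g, or_AA = %g, tau = %g, seed = %d\n",
              cfg$k, cfg$or_GA, cfg$or_AA, cfg$tau, cfg$seed))
  invisible(x)
}

#' Simulate effect estimates from a symmetric (null) funnel
#'
#' Draws `log_or_i ~ Normal(0, se_i^2)` at the given standard errors.
#' Drives the type-I-error calibration of the Egger and Begg tests.
#'
#' @param k Number of studies (>= 3).
#' @param se_grid Positive standard errors, recycled to length `k`.
#' @param seed Integer seed.
#' @return A data.frame of effects (`study`, `log_or`, `se`, `corrected`).
#' @export
simulate_null_funnel <- function(k, se_grid, seed = 1L) {
  if (!is_count(k) || k < 3) stop_insufficient("a funnel simulation requires k >= 3")
  se_grid <- as.numeric(se_grid)
  if (!length(se_grid) || any(!is.finite(se_grid)) || any(se_grid <= 0)) {
    stop_validation("se_grid must contain positive standard errors")
  }
  se <- rep_len(se_grid, k)
  set.seed(as.integer(seed %% 2147483647))
  data.frame(study = sprintf("null_%03d", seq_len(k)),
             log_or = stats::rnorm(k, 0, se),
             se = se, corrected = FALSE,
             stringsAsFactors = FALSE)
}
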