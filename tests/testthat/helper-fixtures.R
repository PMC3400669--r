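# Published per-study arm sizes and genotype proportions of the bundled
# seven-study EGF +61G/A glioma dataset, transcribed once for reconstruction
# and HWE oracle checks.
table1_freqs <- function() {
  data.frame(
    study = c("Bao 2011", "Wang 2010", "Pinto 2009", "Liu 2009",
              "Costa 2007", "Vauleon 2007", "Bhowmick 2004"),
    year = c(2011, 2010, 2009, 2009, 2007, 2007, 2004),
    ethnicity = c("Asian", "Asian", "Caucasian", "Asian", "Caucasian",
                  "Caucasian", "Caucasian"),
    source = c("Hospital", "Population", "Hospital", "Hospital", "Hospital",
               "Population", "Hospital"),
    n_case = c(160, 672, 165, 168, 197, 209, 42),
    n_control = c(320, 693, 200, 194, 570, 214, 76),
    case_fGG = c(0.400, 0.443, 0.285, 0.446, 0.284, 0.211, 0.357),
    case_fGA = c(0.444, 0.454, 0.479, 0.464, 0.492, 0.488, 0.381),
    case_fAA = c(0.156, 0.103, 0.236, 0.089, 0.223, 0.301, 0.262),
    ctrl_fGG = c(0.441, 0.528, 0.280, 0.474, 0.230, 0.145, 0.158),
    ctrl_fGA = c(0.472, 0.398, 0.460, 0.443, 0.467, 0.561, 0.487),
    ctrl_fAA = c(0.088, 0.074, 0.260, 0.082, 0.304, 0.294, 0.355),
    hwe_p_printed = c(0.162, 0.917, 0.260, 0.510, 0.142, 0.031, 0.909),
    stringsAsFactors = FALSE
  )
}

# enumeration oracle: the minimal achievable max |count - n*freq| over all
# integer triples summing to n
enum_min_maxdev <- function(n, freqs) {
  target <- n * freqs
  best <- Inf
  for (gg in 0:n) {
    for (ga in 0:(n - gg)) {
      dev <- max(abs(c(gg, ga, n - gg - ga) - target))
      if (dev < best) best <- dev
    }
  }
  best
}

make_effects <- function(log_or, se, study = NULL) {
  if (is.null(study)) study <- sprintf("s%02d", seq_along(log_or))
  data.frame(study = study, log_or = log_or, se = se,
             stringsAsFactors = FALSE)
}

# collection of k studies with identical counts (labels kept unique)
identical_collection <- function(k, cases = c(30, 50, 20),
                                 controls = c(40, 45, 15)) {
  study_collection(lapply(seq_len(k), function(i) {
    study(sprintf("twin_%d", i), "Asian", "Hospital",
          cases = genotype_counts(cases[1], cases[2], cases[3]),
          controls = genotype_counts(controls[1], controls[2], controls[3]))
  }))
}

fixture_effects <- function(model) study_effects(egf_glioma_studies(), model)
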