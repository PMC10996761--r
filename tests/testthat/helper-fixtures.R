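# Hand-built micro-patients and train generators shared across tests.

make_contacts <- function(ids, xyz, hemisphere = "R", lobe = "temporal",
                          shaft = "S1", soz = FALSE, resected = FALSE) {
  n <- length(ids)
  data.frame(contact_id = ids,
             shaft_id = rep_len(shaft, n),
             x_mm = xyz[, 1], y_mm = xyz[, 2], z_mm = xyz[, 3],
             hemisphere = rep_len(hemisphere, n),
             lobe = rep_len(lobe, n),
             region = "test_region",
             is_soz = rep_len(soz, n),
             is_resected = rep_len(resected, n),
             stringsAsFactors = FALSE)
}

make_events <- function(contact_id, onsets, category = "fRonO",
                        peak_freq_hz = 400) {
  data.frame(contact_id = rep_len(contact_id, length(onsets)),
             onset_s = onsets,
             category = rep_len(category, length(onsets)),
             peak_freq_hz = rep_len(peak_freq_hz, length(onsets)),
             stringsAsFactors = FALSE)
}

# a small deterministic patient: 4 contacts on a line 10 mm apart,
# regular (non-Poisson) FR trains of decreasing rate
tiny_patient <- function(duration_min = 10, engel = "IA") {
  ids <- c("A1", "A2", "A3", "A4")
  xyz <- cbind(c(10, 20, 30, 40), 0, 0)
  contacts <- make_contacts(ids, xyz, soz = c(TRUE, TRUE, FALSE, FALSE),
                            resected = c(TRUE, TRUE, TRUE, FALSE))
  dur_s <- duration_min * 60
  events <- rbind(
    make_events("A1", seq(1, dur_s - 1, by = 20)),         # 3/min
    make_events("A2", seq(2, dur_s - 1, by = 30)),         # 2/min
    make_events("A3", seq(3, dur_s - 1, by = 60)),         # 1/min
    make_events("A4", seq(10, dur_s - 1, by = 120), "RonS", 120))
  fr_patient("tiny", contacts, events, duration_min, engel = engel)
}

poisson_train <- function(rate_per_min, duration_min) {
  n <- stats::rpois(1L, rate_per_min * duration_min)
  sort(stats::runif(n, 0, duration_min * 60))
}

jittered_copy <- function(train, p_copy = 0.8, jitter_sd_s = 0.02) {
  keep <- stats::runif(length(train)) < p_copy
  sort(pmax(0, train[keep] + stats::rnorm(sum(keep), 0, jitter_sd_s)))
}

# an fr_svm whose decision value is a large constant of the given sign:
# a stub classifier for exercising the simulator's control flow
stub_svm <- function(always = FALSE) {
  structure(list(center = stats::setNames(rep(0, 4), FEATURE_NAMES <- c(
                   "fr_rr", "spatial_frnet", "temporal_frnet_a", "temporal_frnet_b")),
                 scale = stats::setNames(rep(1, 4), FEATURE_NAMES),
                 gamma = 0.25, cost = 1,
                 sv = matrix(1e6, 1, 4), coefs = 1e-6,
                 rho = if (always) -10 else 10,
                 positive_is_szfree = TRUE,
                 n_train = 4, labels = c(TRUE, TRUE, FALSE, FALSE)),
            class = "fr_svm")
}

# the fixed-seed synthetic reference cohort, built once per test run
reference_cohort_synth <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cohort <- generate_cohort(synth_config(), seed = 20260925)
      cf <- cohort_features(cohort)
      cache <<- list(cohort = cohort, features = cf$features,
                     labels = cf$labels, graphs = cf$graphs, rates = cf$rates)
    }
    cache
  }
})
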