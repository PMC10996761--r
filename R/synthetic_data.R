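## Synthetic SEEG patient generator.
##
## Emulates the statistical structure the pipeline assumes: linear depth
## electrodes in a brain-shaped bounding box, a spatially clustered
## "autonomous core" of contacts emitting independent high-rate
## FR>350 Hz Poisson trains (high rate, low mutual information), a
## "halo" of lower-rate contacts whose FR trains are thinned, jittered
## copies of shared latent trains (modest rate, high mutual
## information), background ripples everywhere, and a spherical actual
## resection around the (possibly displaced) core centroid. The ground
## truth outcome rule is sharp: seizure free iff every core contact is
## resected.

#' Configuration of the synthetic cohort generator
#'
#' Ranges are sampled uniformly per patient (sizes) or per node (rates).
#' Defaults mirror typical SEEG implants and FR statistics: 8-16 shafts
#' of 7-15 contacts at 5 mm spacing, 30 min recordings, a 3-6 contact
#' autonomous core at 2-10 FR/min, a 6-12 contact halo at 0.2-1 FR/min
#' coupled through shared latent trains (copy probability 0.7, 20 ms
#' jitter).
#'
#' @param n_patients cohort size.
#' @param shafts_range shafts per patient.
#' @param contacts_per_shaft contacts per shaft.
#' @param spacing_mm inter-contact spacing along a shaft.
#' @param duration_min recording duration (minutes).
#' @param core_size autonomous core size (contacts).
#' @param core_rate FR>350 Hz rate range for core contacts (/min).
#' @param halo_size halo size (contacts).
#' @param halo_rate FR>350 Hz rate range for halo contacts (/min).
#' @param n_latent number of shared latent trains behind the halo;
#'   each latent group shares one rate drawn from `halo_rate` and every
#'   member copies latent events with probability `p_copy`.
#' @param p_copy maximal copy probability from a latent train.
#' @param jitter_sd_ms jitter applied to copied events (ms).
#' @param frons_fraction fraction of FR events emitted as fRonS.
#' @param rons_rate,rono_rate background ripple rate ranges (/min).
#' @param resection_radius_mm radius range of the actual resection.
#' @param displacement_mm centre displacement range for "failed"
#'   resections.
#' @param displaced_fraction fraction of the cohort receiving a
#'   displaced resection.
#' @param label_flip probability of flipping the ground-truth outcome
#'   label (noise injection; default 0).
#' @return list of class `fr_synth_config`.
#' @export
synth_config <- function(n_patients = 18,
                         shafts_range = c(8, 16),
                         contacts_per_shaft = c(7, 15),
                         spacing_mm = 5,
                         duration_min = 30,
                         core_size = c(3, 6),
                         core_rate = c(2, 10),
                         halo_size = c(6, 12),
                         halo_rate = c(0.2, 1),
                         n_latent = 2,
                         p_copy = 0.7,
                         jitter_sd_ms = 20,
                         frons_fraction = 0.4,
                         rons_rate = c(0.02, 0.3),
                         rono_rate = c(0.05, 0.5),
                         resection_radius_mm = c(20, 30),
                         displacement_mm = c(20, 40),
                         displaced_fraction = 0.5,
                         label_flip = 0) {
  cfg <- as.list(environment())
  for (nm in c("shafts_range", "contacts_per_shaft", "core_size", "core_rate",
               "halo_size", "halo_rate", "rons_rate", "rono_rate",
               "resection_radius_mm", "displacement_mm")) {
    rg <- cfg[[nm]]
    if (length(rg) != 2 || any(rg < 0) || rg[1] > rg[2])
      stop(nm, " must be an ordered nonnegative range")
  }
  if (cfg$p_copy < 0 || cfg$p_copy > 1) stop("p_copy must be in [0, 1]")
  structure(cfg, class = "fr_synth_config")
}

## fixed geometric lobe partition of MNI-like coordinates: the pipeline
## only needs categorical labels for the three-lobe rule
lobe_of <- function(x, y, z) {
  ifelse(y > 15, "frontal",
  ifelse(y < -65, "occipital",
  ifelse(z < -5, "temporal",
  ifelse(z > 35, "parietal",
  ifelse(abs(x) < 38, "insula", "other")))))
}

runif_range <- function(n, range) stats::runif(n, range[1], range[2])
sample_range <- function(range) {
  if (range[1] == range[2]) as.integer(range[1])
  else sample(seq(range[1], range[2]), 1L)
}

poisson_train <- function(rate_per_min, duration_min) {
  n <- stats::rpois(1L, rate_per_min * duration_min)
  sort(stats::runif(n, 0, duration_min * 60))
}

## event rows for a set of FR onsets: fRonS (200-600 Hz) with
## probability frons_fraction, else fRonO above 350 Hz
fr_event_rows <- function(contact_id, onsets, frons_fraction) {
  if (length(onsets) == 0) return(NULL)
  is_s <- stats::runif(length(onsets)) < frons_fraction
  data.frame(contact_id = contact_id, onset_s = onsets,
             category = ifelse(is_s, "fRonS", "fRonO"),
             peak_freq_hz = ifelse(is_s,
                                   stats::runif(length(onsets), 250, 595),
                                   stats::runif(length(onsets), 355, 595)),
             stringsAsFactors = FALSE)
}

generate_patient_impl <- function(config, patient_id, displaced) {
  dur <- config$duration_min
  ## --- electrode geometry: linear shafts entering laterally ---
  n_shafts <- sample_range(config$shafts_range)
  contacts <- NULL
  for (s in seq_len(n_shafts)) {
    hemi <- if (s %% 2 == 0) "L" else "R"
    entry <- c(if (hemi == "L") -70 else 70,
               stats::runif(1, -85, 55), stats::runif(1, -40, 60))
    dirv <- c(if (hemi == "L") 1 else -1,
              stats::rnorm(1, 0, 0.25), stats::rnorm(1, 0, 0.25))
    dirv <- dirv / sqrt(sum(dirv^2))
    n_c <- sample_range(config$contacts_per_shaft)
    pos <- entry + outer(config$spacing_mm * (seq_len(n_c) - 1), dirv)
    contacts <- rbind(contacts, data.frame(
      contact_id = sprintf("S%02dC%02d", s, seq_len(n_c)),
      shaft_id = sprintf("S%02d", s),
      x_mm = pos[, 1], y_mm = pos[, 2], z_mm = pos[, 3],
      hemisphere = hemi, stringsAsFactors = FALSE))
  }
  contacts$lobe <- lobe_of(contacts$x_mm, contacts$y_mm, contacts$z_mm)
  contacts$region <- paste0(tolower(contacts$hemisphere), "_", contacts$lobe)
  ## --- planted structure: compact core + halo in one hemisphere ---
  hemi0 <- names(which.max(table(contacts$hemisphere)))
  cand <- which(contacts$hemisphere == hemi0)
  seed_idx <- sample(cand, 1L)
  xyz <- contact_coords(contacts)
  d_seed <- sqrt(colSums((t(xyz[cand, , drop = FALSE]) - xyz[seed_idx, ])^2))
  ord <- cand[order(d_seed)]
  n_core <- min(sample_range(config$core_size), length(ord))
  core <- contacts$contact_id[ord[seq_len(n_core)]]
  n_halo <- min(sample_range(config$halo_size), length(ord) - n_core)
  halo <- contacts$contact_id[ord[n_core + seq_len(n_halo)]]
  ## --- event trains ---
  events <- NULL
  for (id in core)
    events <- rbind(events, fr_event_rows(
      id, poisson_train(runif_range(1, config$core_rate), dur),
      config$frons_fraction))
  ## each latent group shares one target rate so every member copies at
  ## the full p_copy: pairwise co-occurrence stays at p_copy^2 of the
  ## latent events, the construction that makes halo MI high
  group_rate <- runif_range(config$n_latent, config$halo_rate)
  latents <- lapply(seq_len(config$n_latent), function(i)
    poisson_train(group_rate[i] / config$p_copy, dur))
  latent_of <- rep_len(seq_len(config$n_latent), length(halo))
  for (i in seq_along(halo)) {
    lt <- latents[[latent_of[i]]]
    keep <- stats::runif(length(lt)) < config$p_copy
    onsets <- sort(pmin(pmax(lt[keep] + stats::rnorm(sum(keep), 0,
                                                     config$jitter_sd_ms / 1000),
                             0), dur * 60))
    events <- rbind(events, fr_event_rows(halo[i], onsets, config$frons_fraction))
  }
  for (i in seq_len(nrow(contacts))) {
    id <- contacts$contact_id[i]
    rons <- poisson_train(runif_range(1, config$rons_rate), dur)
    rono <- poisson_train(runif_range(1, config$rono_rate), dur)
    if (length(rons))
      events <- rbind(events, data.frame(
        contact_id = id, onset_s = rons, category = "RonS",
        peak_freq_hz = stats::runif(length(rons), 85, 195),
        stringsAsFactors = FALSE))
    if (length(rono))
      events <- rbind(events, data.frame(
        contact_id = id, onset_s = rono, category = "RonO",
        peak_freq_hz = stats::runif(length(rono), 85, 195),
        stringsAsFactors = FALSE))
  }
  ## --- SOZ and actual resection ---
  core_xyz <- xyz[match(core, contacts$contact_id), , drop = FALSE]
  centroid <- colMeans(core_xyz)
  soz <- union(core, contacts$contact_id[
    contacts$hemisphere == hemi0 &
      sqrt(colSums((t(xyz) - centroid)^2)) < 15])
  contacts$is_soz <- contacts$contact_id %in% soz
  res_center <- centroid
  if (displaced) {
    u <- stats::rnorm(3)
    res_center <- centroid + u / sqrt(sum(u^2)) *
      runif_range(1, config$displacement_mm)
  }
  res_radius <- runif_range(1, config$resection_radius_mm)
  if (!displaced) {
    ## a resection aimed at the focus encompasses it: the cavity radius
    ## covers the core's spatial extent plus a surgical margin
    core_extent <- max(sqrt(colSums((t(core_xyz) - centroid)^2)))
    res_radius <- max(res_radius, core_extent + 5)
  }
  d_res <- sqrt(colSums((t(xyz) - res_center)^2))
  contacts$is_resected <- d_res <= res_radius & contacts$hemisphere == hemi0
  seizure_free <- all(core %in% contacts$contact_id[contacts$is_resected])
  if (config$label_flip > 0 && stats::runif(1) < config$label_flip)
    seizure_free <- !seizure_free
  engel <- if (seizure_free) sample(c("IA", "IB"), 1L)
    else sample(c("IIB", "IIIA", "IVB"), 1L)
  patient <- fr_patient(patient_id, contacts,
                        events[order(events$contact_id, events$onset_s), ],
                        duration_min = dur, engel = engel)
  truth <- list(core = core, halo = halo, hemisphere = hemi0,
                core_centroid = centroid, resection_center = res_center,
                resection_radius = res_radius, displaced = displaced,
                seizure_free = seizure_free,
                core_lobes = unique(contacts$lobe[contacts$contact_id %in% core]))
  list(patient = patient, truth = truth)
}

#' Generate one synthetic patient
#'
#' Draws electrode geometry, planted core/halo structure, event trains,
#' SOZ membership and an actual resection under `config`, fully
#' deterministic under `seed`. If a draw yields fewer than two
#' FR-generating contacts it is retried (bounded).
#'
#' @param config [synth_config()].
#' @param seed integer seed.
#' @param patient_id identifier for the generated record.
#' @param displaced force a displaced ("failed") resection; by default
#'   drawn with probability `config$displaced_fraction`.
#' @return list with `patient` (an `fr_patient`) and `truth` (core and
#'   halo ids, resection geometry, ground-truth outcome).
#' @export
generate_patient <- function(config = synth_config(), seed = 1,
                             patient_id = sprintf("SYN%04d", seed %% 10000),
                             displaced = NULL) {
  withr::with_seed(seed, {
    if (is.null(displaced)) displaced <- stats::runif(1) < config$displaced_fraction
    for (try in 1:10) {
      out <- generate_patient_impl(config, patient_id, displaced)
      n_fr <- sum(contact_rates(out$patient)$fr350 > 0)
      if (n_fr >= 2) return(out)
    }
    stop("could not generate a patient with two FR-generating contacts")
  })
}

#' Generate a synthetic cohort with balanced outcomes
#'
#' Half of the patients (rounded down, positions randomized) receive a
#' displaced resection and are therefore almost surely not seizure free
#' under the all-core-resected ground-truth rule; the rest receive a
#' resection centred on the core.
#'
#' @param config [synth_config()].
#' @param seed integer seed.
#' @return list of class `fr_synth_cohort`: elements as returned by
#'   [generate_patient()].
#' @export
generate_cohort <- function(config = synth_config(), seed = 1) {
  n <- config$n_patients
  if (n < 6) stop("cohort needs at least 6 patients")
  plan <- withr::with_seed(seed, {
    displaced <- sample(rep(c(TRUE, FALSE), length.out = n))
    seeds <- sample.int(2^30, n)
    list(displaced = displaced, seeds = seeds)
  })
  cohort <- lapply(seq_len(n), function(i)
    generate_patient(config, seed = plan$seeds[i],
                     patient_id = sprintf("SYN%02d", i),
                     displaced = plan$displaced[i]))
  class(cohort) <- "fr_synth_cohort"
  cohort
}

#' Feature/label pairs of a synthetic cohort
#'
#' Computes, for every patient, the four FR factors with respect to the
#' actual resection and the ground-truth seizure-freedom label —
#' the training set for [fr_svm()]. MI graphs are returned for reuse.
#'
#' @param cohort a [generate_cohort()] result.
#' @param opts [fr_options()].
#' @return list with `features` (n x 4 matrix), `labels` (logical),
#'   `graphs`, `rates` (lists, one per patient).
#' @export
cohort_features <- function(cohort, opts = fr_options()) {
  graphs <- lapply(cohort, function(el) build_mi_graph(el$patient, opts))
  rates <- lapply(cohort, function(el) contact_rates(el$patient))
  features <- do.call(rbind, lapply(seq_along(cohort), function(i) {
    p <- cohort[[i]]$patient
    resected <- p$contacts$contact_id[p$contacts$is_resected]
    as_feature_row(feature_vector(p, resected, graph = graphs[[i]],
                                  rates = rates[[i]], opts = opts))
  }))
  labels <- vapply(cohort, function(el) el$truth$seizure_free, logical(1))
  list(features = features, labels = labels, graphs = graphs, rates = rates)
}

#' Write a synthetic cohort to the standard on-disk layout
#'
#' Each patient is written with [write_patient()]; synthetic records
#' are indistinguishable from real ones to the pipeline readers.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_cohort <- function(cohort, dir) {
  for (el in cohort) write_patient(el$patient, dir)
  invisible(dir)
}
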