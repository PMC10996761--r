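#' @keywords internal
"_PACKAGE"

## Closed vocabularies shared across the package
HEMISPHERES <- c("L", "R")
LOBES <- c("frontal", "temporal", "parietal", "occipital", "insula", "other")
EVENT_CATEGORIES <- c("fRonO", "fRonS", "RonO", "RonS")
RIPPLE_CATEGORIES <- c("RonO", "RonS")
FR_CATEGORIES <- c("fRonO", "fRonS")

CONTACT_COLUMNS <- c("contact_id", "shaft_id", "x_mm", "y_mm", "z_mm",
                     "hemisphere", "lobe", "region", "is_soz", "is_resected")
EVENT_COLUMNS <- c("contact_id", "onset_s", "category", "peak_freq_hz")

## NA carrying a reason: degenerate metrics return this instead of a silent 0/0
flagged_na <- function(flag) structure(NA_real_, flag = flag)

#' Flag attached to a degenerate metric value
#'
#' Metrics that are undefined for a given input (for example a resection
#' ratio when no event of the family was detected, or a path length over
#' fewer than two nodes) return `NA` carrying a short `flag` attribute
#' naming the reason. `metric_flag()` retrieves it.
#'
#' @param x a value returned by one of the metric functions.
#' @return the flag string, or `NULL` when `x` is an ordinary value.
#' @export
metric_flag <- function(x) attr(x, "flag", exact = TRUE)

#' Map an Engel outcome class to the seizure-free dichotomy
#'
#' Engel class I (any letter subclass, e.g. "IA", "IB", "IC", "ID") is
#' seizure free; classes II, III and IV are not. The comparison is on the
#' leading Roman numeral, so "IIIA" is correctly non-seizure-free even
#' though it starts with "I".
#'
#' @param engel Engel class string (e.g. `"IA"`, `"IIIA"`), or `NA`.
#' @return logical; `NA` if `engel` is missing.
#' @export
engel_seizure_free <- function(engel) {
  if (length(engel) != 1L) return(vapply(engel, engel_seizure_free, logical(1)))
  if (is.na(engel) || !nzchar(engel)) return(NA)
  cls <- sub("^(IV|III|II|I).*$", "\\1", trimws(as.character(engel)))
  if (!cls %in% c("I", "II", "III", "IV"))
    stop("unrecognized Engel class: ", engel)
  cls == "I"
}

frequency_band <- function(category) {
  ## ripple categories 80-200 Hz, fast-ripple categories 200-600 Hz
  if (category %in% RIPPLE_CATEGORIES) c(80, 200) else c(200, 600)
}

validate_contacts <- function(contacts) {
  missing <- setdiff(CONTACT_COLUMNS, names(contacts))
  if (length(missing))
    stop("contacts table is missing column(s): ", paste(missing, collapse = ", "))
  contacts$contact_id <- as.character(contacts$contact_id)
  contacts$shaft_id <- as.character(contacts$shaft_id)
  contacts$region <- as.character(contacts$region)
  for (col in c("x_mm", "y_mm", "z_mm")) {
    contacts[[col]] <- as.numeric(contacts[[col]])
    if (any(!is.finite(contacts[[col]])))
      stop("non-finite coordinate in column ", col)
  }
  if (anyDuplicated(contacts$contact_id))
    stop("duplicate contact_id: ",
         paste(unique(contacts$contact_id[duplicated(contacts$contact_id)]),
               collapse = ", "))
  if (!all(contacts$hemisphere %in% HEMISPHERES))
    stop("hemisphere must be one of: ", paste(HEMISPHERES, collapse = ", "))
  if (!all(contacts$lobe %in% LOBES))
    stop("lobe must be one of: ", paste(LOBES, collapse = ", "))
  contacts$is_soz <- as.logical(contacts$is_soz)
  contacts$is_resected <- as.logical(contacts$is_resected)
  if (any(is.na(contacts$is_soz)) || any(is.na(contacts$is_resected)))
    stop("is_soz / is_resected must be logical with no missing values")
  rownames(contacts) <- NULL
  contacts
}

validate_events <- function(events, contacts, duration_min = NULL) {
  missing <- setdiff(EVENT_COLUMNS, names(events))
  if (length(missing))
    stop("events table is missing column(s): ", paste(missing, collapse = ", "))
  events$contact_id <- as.character(events$contact_id)
  events$onset_s <- as.numeric(events$onset_s)
  events$category <- as.character(events$category)
  events$peak_freq_hz <- as.numeric(events$peak_freq_hz)
  if (nrow(events) == 0L) return(events)
  unknown <- setdiff(unique(events$contact_id), contacts$contact_id)
  if (length(unknown))
    stop("event(s) reference unknown contact(s): ", paste(unknown, collapse = ", "))
  if (any(events$onset_s < 0)) stop("negative event onset time")
  if (!is.null(duration_min) && any(events$onset_s > duration_min * 60))
    stop("event onset beyond the recording duration")
  if (!all(events$category %in% EVENT_CATEGORIES))
    stop("event category must be one of: ", paste(EVENT_CATEGORIES, collapse = ", "))
  for (cat in unique(events$category)) {
    band <- frequency_band(cat)
    f <- events$peak_freq_hz[events$category == cat]
    if (any(f <= band[1] - 1e-9) || any(f > band[2] + 1e-9))
      stop("peak_freq_hz outside the ", band[1], "-", band[2],
           " Hz band for category ", cat)
  }
  rownames(events) <- NULL
  events
}

validate_rns_leads <- function(rns) {
  stim <- rns$stim_coords
  if (is.list(stim)) stim <- do.call(rbind, lapply(stim, as.numeric))
  stim <- matrix(as.numeric(as.matrix(stim)), ncol = 3)
  if (nrow(stim) != 8L)
    stop("RNS leads must have exactly 8 stimulation coordinates (2 leads x 4 contacts)")
  lead_types <- rns$lead_types
  if (is.null(lead_types)) lead_types <- c("depth", "depth")
  if (!all(lead_types %in% c("depth", "strip")))
    stop("RNS lead_types must be 'depth' or 'strip'")
  ## bilateral iff the two leads' mean coordinates lie in opposite hemispheres
  m1 <- colMeans(stim[1:4, , drop = FALSE])
  m2 <- colMeans(stim[5:8, , drop = FALSE])
  structure(list(stim_coords = stim, lead_types = lead_types,
                 bilateral = sign(m1[1]) != sign(m2[1])),
            class = "fr_rns_leads")
}

#' Assemble and validate a patient record
#'
#' The record bundles the electrode-contact table, the detected-event
#' catalog and the recording metadata used by every downstream stage.
#' Validation enforces the closed hemisphere/lobe vocabularies, the
#' per-category peak-frequency bands (ripples 80-200 Hz, fast ripples
#' 200-600 Hz), referential integrity of `events$contact_id`, and
#' non-negative onsets within the recording. Recordings shorter than 10
#' or longer than 60 minutes are accepted with a warning, mirroring the
#' usual inclusion window for artifact-free non-REM sleep SEEG.
#'
#' @param patient_id patient identifier.
#' @param contacts data frame with columns `contact_id`, `shaft_id`,
#'   `x_mm`, `y_mm`, `z_mm` (MNI millimetres), `hemisphere` (L/R),
#'   `lobe`, `region`, `is_soz`, `is_resected`.
#' @param events data frame with columns `contact_id`, `onset_s`,
#'   `category` (fRonO/fRonS/RonO/RonS), `peak_freq_hz`.
#' @param duration_min recording duration in minutes (> 0).
#' @param engel Engel outcome class string, or `NA` when unknown.
#' @param rns optional list with `stim_coords` (8x3 matrix, MNI mm) and
#'   `lead_types` (two of "depth"/"strip").
#' @return an object of class `fr_patient`.
#' @export
fr_patient <- function(patient_id, contacts, events, duration_min,
                       engel = NA_character_, rns = NULL) {
  if (!is.numeric(duration_min) || length(duration_min) != 1L || duration_min <= 0)
    stop("duration_min must be a single positive number")
  if (duration_min < 10 || duration_min > 60)
    warning("recording duration ", duration_min,
            " min is outside the usual 10-60 min inclusion window")
  contacts <- validate_contacts(as.data.frame(contacts, stringsAsFactors = FALSE))
  events <- validate_events(as.data.frame(events, stringsAsFactors = FALSE),
                            contacts, duration_min)
  engel <- if (is.null(engel)) NA_character_ else as.character(engel)
  structure(list(
    patient_id = as.character(patient_id),
    contacts = contacts,
    events = events,
    duration_min = duration_min,
    engel = engel,
    seizure_free = engel_seizure_free(engel),
    rns = if (!is.null(rns)) validate_rns_leads(rns) else NULL
  ), class = "fr_patient")
}

#' @export
print.fr_patient <- function(x, ...) {
  cat("SEEG patient record:", x$patient_id, "\n")
  cat("  contacts:", nrow(x$contacts),
      sprintf("(%d SOZ, %d resected)", sum(x$contacts$is_soz),
              sum(x$contacts$is_resected)), "\n")
  cat("  events:  ", nrow(x$events), "over", x$duration_min, "min\n")
  cat("  outcome: ", if (is.na(x$engel)) "unknown" else
    sprintf("Engel %s (%s)", x$engel,
            if (isTRUE(x$seizure_free)) "seizure free" else "not seizure free"),
    "\n")
  if (!is.null(x$rns))
    cat("  RNS:     ", if (x$rns$bilateral) "bilateral" else "unilateral",
        "leads (", paste(x$rns$lead_types, collapse = "+"), ")\n")
  invisible(x)
}

#' Load a patient from the standard on-disk layout
#'
#' Reads the contacts TSV, the events CSV and the metadata JSON and
#' returns a validated [fr_patient()] record. Seizure freedom is derived
#' from the Engel class (class I = seizure free).
#'
#' @param electrodes_path path to the contacts TSV.
#' @param events_path path to the events CSV.
#' @param meta_path path to the metadata JSON with keys `patient_id`,
#'   `duration_min`, `engel` and optionally `rns`.
#' @return an `fr_patient` object.
#' @export
load_patient <- function(electrodes_path, events_path, meta_path) {
  for (p in c(electrodes_path, events_path, meta_path))
    if (!file.exists(p)) stop("file not found: ", p)
  contacts <- utils::read.delim(electrodes_path, sep = "\t",
                                stringsAsFactors = FALSE,
                                colClasses = c(contact_id = "character",
                                               shaft_id = "character"))
  events <- utils::read.csv(events_path, stringsAsFactors = FALSE,
                            colClasses = c(contact_id = "character"))
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  fr_patient(patient_id = meta$patient_id,
             contacts = contacts, events = events,
             duration_min = as.numeric(meta$duration_min),
             engel = if (is.null(meta$engel)) NA_character_ else meta$engel,
             rns = meta$rns)
}

#' Write a patient to the standard on-disk layout
#'
#' Inverse of [load_patient()]: writes `<stem>_contacts.tsv`,
#' `<stem>_events.csv` and `<stem>_meta.json` under `dir`.
#'
#' @param patient an `fr_patient`.
#' @param dir output directory (created if needed).
#' @param stem file-name stem; default the patient id.
#' @return invisibly, the three paths written.
#' @export
write_patient <- function(patient, dir, stem = patient$patient_id) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(stem, c("_contacts.tsv", "_events.csv", "_meta.json")))
  utils::write.table(patient$contacts, paths[1], sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.csv(patient$events, paths[2], row.names = FALSE, quote = FALSE)
  meta <- list(patient_id = patient$patient_id,
               duration_min = patient$duration_min,
               engel = patient$engel)
  if (!is.null(patient$rns))
    meta$rns <- list(stim_coords = unclass(patient$rns$stim_coords),
                     lead_types = patient$rns$lead_types)
  jsonlite::write_json(meta, paths[3], auto_unbox = TRUE, digits = NA, null = "null")
  invisible(paths)
}

#' Per-patient metrics report
#'
#' Computes one row of summary metrics per patient: the SOZ, RonS, RonO
#' and FR resection ratios against the actual resection, the spatial and
#' temporal FR network factors, and the number of MI-network nodes with
#' local efficiency greater than zero. When `path` is given the table is
#' written as CSV with a trailing `mean +/- sem` summary row appended for
#' cohorts of more than one patient.
#'
#' @param patients a single `fr_patient` or a list of them.
#' @param path optional CSV output path.
#' @param opts analysis options from [fr_options()].
#' @return the metrics data frame, invisibly when `path` is given.
#' @export
write_metrics_report <- function(patients, path = NULL, opts = fr_options()) {
  if (inherits(patients, "fr_patient")) patients <- list(patients)
  rows <- lapply(patients, function(p) {
    resected <- p$contacts$contact_id[p$contacts$is_resected]
    g <- build_mi_graph(p, opts = opts)
    fv <- feature_vector(p, resected, graph = g, opts = opts)
    le <- if (g$degenerate) numeric(0) else
      vapply(seq_along(g$nodes), function(i) local_efficiency(g, i), numeric(1))
    data.frame(
      patient_id = p$patient_id,
      engel = p$engel,
      seizure_free = p$seizure_free,
      soz_rr = as.numeric(soz_resection_ratio(p, resected)),
      rons_rr = as.numeric(event_resection_ratio(p, "RonS", resected)),
      rono_rr = as.numeric(event_resection_ratio(p, "RonO", resected)),
      fr_rr = as.numeric(fv$fr_rr),
      fr_all_rr = as.numeric(event_resection_ratio(p, "fr_all", resected)),
      spatial_frnet = as.numeric(fv$spatial_frnet),
      temporal_frnet_a = as.numeric(fv$temporal_frnet_a),
      temporal_frnet_b = as.numeric(fv$temporal_frnet_b),
      n_mi_nodes_le_pos = sum(le > 0),
      stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  if (!is.null(path)) {
    out <- report
    if (nrow(out) > 1L) {
      num <- vapply(out, is.numeric, logical(1))
      mu <- vapply(out[num], function(v) mean(v, na.rm = TRUE), numeric(1))
      sem <- vapply(out[num], function(v) {
        v <- v[!is.na(v)]
        if (length(v) < 2) NA_real_ else stats::sd(v) / sqrt(length(v))
      }, numeric(1))
      summ <- out[1, ]
      summ[] <- NA
      summ$patient_id <- "mean +/- sem"
      summ[names(mu)] <- mu
      sem_row <- summ
      sem_row$patient_id <- "sem"
      sem_row[names(sem)] <- sem
      out <- rbind(out, summ, sem_row)
    }
    utils::write.csv(format(out, digits = 6), path, row.names = FALSE, quote = FALSE)
    return(invisible(report))
  }
  report
}

#' Analysis options
#'
#' Central knob set shared by the network and simulation stages.
#'
#' @param mi_estimator `"adaptive"` (Darbellay-Vajda adaptive partitioning
#'   of the inter-event-interval / cross-train latency plane, the default)
#'   or `"binned"` (fixed-width binned event counts with Miller-Madow
#'   corrected plug-in MI).
#' @param mi_bin_s bin width in seconds for the binned estimator.
#' @param mi_min_events minimum events per train for a nonzero MI.
#' @param frnetB_scope `"unresected"` (default) or `"all"`: node set over
#'   which temporal FRnet-B averages local efficiency.
#' @param kernel_scale `"fixed"` (gamma = 1/number of factors) or
#'   `"auto"` (e1071 default gamma = 1/data dimension on scaled data).
#' @param sphere_margin_mm buffer added around each new candidate node
#'   when growing the virtual-resection sphere.
#' @param rns_field_radius_mm stimulation-field radius around each RNS
#'   contact (contacts strictly closer are "stimulated").
#' @param fr_rate_threshold candidate threshold on the FR>350 Hz rate
#'   (events/min) for the primary virtual-resection ordering.
#' @return a list of class `fr_options`.
#' @export
fr_options <- function(mi_estimator = c("adaptive", "binned"),
                       mi_bin_s = 1,
                       mi_min_events = 2,
                       frnetB_scope = c("unresected", "all"),
                       kernel_scale = c("fixed", "auto"),
                       sphere_margin_mm = 10,
                       rns_field_radius_mm = 15,
                       fr_rate_threshold = 1) {
  structure(list(
    mi_estimator = match.arg(mi_estimator),
    mi_bin_s = mi_bin_s,
    mi_min_events = mi_min_events,
    frnetB_scope = match.arg(frnetB_scope),
    kernel_scale = match.arg(kernel_scale),
    sphere_margin_mm = sphere_margin_mm,
    rns_field_radius_mm = rns_field_radius_mm,
    fr_rate_threshold = fr_rate_threshold
  ), class = "fr_options")
}

contact_coords <- function(contacts, ids = NULL) {
  if (!is.null(ids)) contacts <- contacts[match(ids, contacts$contact_id), , drop = FALSE]
  m <- as.matrix(contacts[, c("x_mm", "y_mm", "z_mm")])
  rownames(m) <- contacts$contact_id
  m
}
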