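## Event families:
##   fr350  - fRonO with peak frequency > 350 Hz, plus all fRonS (200-600 Hz)
##   fr_all - all fast ripples (fRonO + fRonS, 200-600 Hz)
##   RonS   - ripples on spikes, RonO - ripples on oscillations
EVENT_FAMILIES <- c("fr350", "fr_all", "RonS", "RonO")

#' Does an event belong to the FR>350 Hz family?
#'
#' The family driving every network metric: fast ripples on oscillations
#' with peak frequency above 350 Hz, together with all fast ripples on
#' spikes (any peak frequency in the 200-600 Hz band).
#'
#' @param category event category (fRonO/fRonS/RonO/RonS), vectorized.
#' @param peak_freq_hz peak frequency in Hz.
#' @return logical vector.
#' @export
is_fr350 <- function(category, peak_freq_hz) {
  (category == "fRonO" & peak_freq_hz > 350) | category == "fRonS"
}

family_mask <- function(events, family) {
  switch(family,
         fr350 = is_fr350(events$category, events$peak_freq_hz),
         fr_all = events$category %in% FR_CATEGORIES,
         RonS = events$category == "RonS",
         RonO = events$category == "RonO",
         stop("unknown event family: ", family))
}

#' Per-contact event rates
#'
#' Events per minute for each contact and each event family
#' (FR>350 Hz, all FR 200-600 Hz, RonS, RonO).
#'
#' @param patient an `fr_patient`.
#' @return data frame with one row per contact and columns `contact_id`,
#'   `fr350`, `fr_all`, `RonS`, `RonO` (rates in events/min).
#' @export
contact_rates <- function(patient) {
  if (patient$duration_min <= 0) stop("recording duration must be positive")
  ids <- patient$contacts$contact_id
  out <- data.frame(contact_id = ids, stringsAsFactors = FALSE)
  for (fam in EVENT_FAMILIES) {
    ev <- patient$events[family_mask(patient$events, fam), , drop = FALSE]
    counts <- table(factor(ev$contact_id, levels = ids))
    out[[fam]] <- as.numeric(counts) / patient$duration_min
  }
  out
}

#' Event resection (or stimulation) ratio
#'
#' Fraction of the family's events recorded on the given contact set:
#' events on `resected` contacts over all events of the family. The same
#' definition with a stimulated contact set gives the RNS stimulation
#' ratio. Undefined (flagged `NA`) when the family has no events at all.
#'
#' @param patient an `fr_patient`.
#' @param family one of `"fr350"`, `"fr_all"`, `"RonS"`, `"RonO"`.
#' @param resected character vector of contact ids.
#' @return ratio in \[0, 1\], or flagged `NA` (see [metric_flag()]).
#' @export
event_resection_ratio <- function(patient, family, resected) {
  ev <- patient$events[family_mask(patient$events, family), , drop = FALSE]
  if (nrow(ev) == 0L) return(flagged_na("no events in family"))
  sum(ev$contact_id %in% resected) / nrow(ev)
}

#' SOZ resection (or stimulation) ratio
#'
#' Resected SOZ contacts over all SOZ contacts — a contact-count ratio,
#' unlike the event-count [event_resection_ratio()].
#'
#' @param patient an `fr_patient`.
#' @param resected character vector of contact ids.
#' @return ratio in \[0, 1\], or flagged `NA` when the patient has no
#'   SOZ contacts.
#' @export
soz_resection_ratio <- function(patient, resected) {
  soz <- patient$contacts$contact_id[patient$contacts$is_soz]
  if (length(soz) == 0L) return(flagged_na("no SOZ contacts"))
  sum(soz %in% resected) / length(soz)
}
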