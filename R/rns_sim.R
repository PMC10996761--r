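## Responsive-neurostimulation (RNS) geometry and metrics: which SEEG
## contacts fall inside the stimulation field of the eight RNS contacts
## (two leads of four), the SOZ / FR stimulation ratios, the stimulated
## global efficiency of the MI subnetwork, and virtual lead placement at
## the highest-rate FR sites.

#' SEEG contacts inside the RNS stimulation field
#'
#' Contacts whose minimum Euclidean distance to any of the eight RNS
#' stimulation contacts is strictly below the field radius (default
#' 15 mm, matching the extent of a monopolar 1-3 mA stimulation field).
#'
#' @param contacts contacts data frame (see [fr_patient()]).
#' @param leads an RNS lead set (`fr_rns_leads`, or a list with
#'   `stim_coords` an 8 x 3 matrix).
#' @param field_radius_mm stimulation-field radius in mm.
#' @return character vector of stimulated contact ids.
#' @export
stimulated_set <- function(contacts, leads, field_radius_mm = 15) {
  if (!inherits(leads, "fr_rns_leads")) leads <- validate_rns_leads(leads)
  xyz <- contact_coords(contacts)
  dmin <- apply(xyz, 1, function(p)
    sqrt(min(colSums((t(leads$stim_coords) - p)^2))))
  contacts$contact_id[dmin < field_radius_mm]
}

#' RNS stimulation metrics
#'
#' For a stimulated contact set: the SOZ stimulation ratio (stimulated
#' SOZ contacts over all SOZ contacts), the FR stimulation ratio
#' (FR>350 Hz events on stimulated contacts over all FR>350 Hz events),
#' and the RNS temporal FRnet — the global efficiency of the MI
#' subgraph induced on the stimulated contacts together with their
#' first-degree MI neighbours. Lower values of the latter indicate
#' stimulation of autonomous (temporally independent) FR sites.
#'
#' @param patient an `fr_patient`.
#' @param stim character vector of stimulated contact ids.
#' @param g [build_mi_graph()] result.
#' @return list of class `fr_rns_metrics` with `soz_sr`, `fr_sr`,
#'   `rns_temporal_frnet`, `stimulated`, `neighbors`.
#' @export
rns_metrics <- function(patient, stim, g = NULL) {
  if (is.null(g)) g <- build_mi_graph(patient)
  soz_sr <- soz_resection_ratio(patient, stim)
  fr_sr <- event_resection_ratio(patient, "fr350", stim)
  stim_nodes <- intersect(stim, g$nodes)
  nbrs <- character(0)
  if (length(stim_nodes) > 0 && !g$degenerate) {
    idx <- match(stim_nodes, g$nodes)
    nbr_idx <- which(colSums(g$adjacency[idx, , drop = FALSE] > 0) > 0)
    nbrs <- setdiff(g$nodes[nbr_idx], stim_nodes)
  }
  sub <- union(stim_nodes, nbrs)
  sge <- if (length(sub) < 2) flagged_na("degenerate stimulated subgraph")
    else global_efficiency(g, sub)
  structure(list(soz_sr = soz_sr, fr_sr = fr_sr, rns_temporal_frnet = sge,
                 stimulated = sort(stim), neighbors = sort(nbrs)),
            class = "fr_rns_metrics")
}

#' @export
print.fr_rns_metrics <- function(x, ...) {
  cat(sprintf("RNS metrics: SOZ SR %.3f | FR SR %.3f | RNS temporal FRnet %.3f (%d stimulated, %d neighbours)\n",
              as.numeric(x$soz_sr), as.numeric(x$fr_sr),
              as.numeric(x$rns_temporal_frnet),
              length(x$stimulated), length(x$neighbors)))
  invisible(x)
}

## order a shaft's contacts along its principal axis
shaft_order <- function(contacts, shaft_id) {
  rows <- contacts[contacts$shaft_id == shaft_id, , drop = FALSE]
  if (nrow(rows) <= 1) return(rows$contact_id)
  xyz <- contact_coords(rows)
  d <- as.matrix(stats::dist(xyz))
  ends <- which(d == max(d), arr.ind = TRUE)[1, ]
  ## canonical orientation: origin = the endpoint with the smaller
  ## coordinate tuple, so the ordering does not depend on row order
  e <- xyz[c(ends[1], ends[2]), , drop = FALSE]
  flip <- (e[2, 1] < e[1, 1]) ||
    (e[2, 1] == e[1, 1] && (e[2, 2] < e[1, 2] ||
      (e[2, 2] == e[1, 2] && e[2, 3] < e[1, 3])))
  origin <- if (flip) ends[2] else ends[1]
  axis <- xyz[if (flip) ends[1] else ends[2], ] - xyz[origin, ]
  proj <- as.numeric((xyz - matrix(xyz[origin, ], nrow(xyz), 3, byrow = TRUE)) %*% axis)
  rows$contact_id[order(proj, rows$contact_id)]
}

## four contiguous contacts on the shaft, centred on a target contact
lead_window <- function(contacts, target_id) {
  shaft <- contacts$shaft_id[contacts$contact_id == target_id]
  ids <- shaft_order(contacts, shaft)
  n <- length(ids)
  if (n >= 4) {
    i <- match(target_id, ids)
    start <- min(max(1L, i - 1L), n - 3L)
    return(ids[start:(start + 3L)])
  }
  ## short shaft: use all its contacts, pad with the nearest contacts
  ## from other shafts
  lead <- ids
  centroid <- colMeans(contact_coords(contacts, lead))
  others <- contacts[contacts$shaft_id != shaft, , drop = FALSE]
  if (nrow(others) == 0) stop("cannot build a 4-contact lead: no second shaft")
  d <- sqrt(colSums((t(contact_coords(others)) - centroid)^2))
  c(lead, others$contact_id[order(d, others$contact_id)][seq_len(4 - n)])
}

#' Virtual RNS lead placement at the highest-rate FR sites
#'
#' Lead 1 is four contiguous contacts on the shaft carrying the
#' highest-rate FR>350 Hz contact, centred on it (clipped at the shaft
#' ends). Lead 2 repeats the construction around the highest-rate
#' contact of the opposite hemisphere for bilateral placement, or
#' around the highest-rate contact on a different shaft otherwise.
#'
#' @param patient an `fr_patient`.
#' @param rates optional precomputed [contact_rates()].
#' @param bilateral place one lead per hemisphere?
#' @return an `fr_rns_leads` object; the chosen contact ids are in
#'   attribute `contact_ids`.
#' @export
virtual_placement <- function(patient, rates = NULL, bilateral = FALSE) {
  if (is.null(rates)) rates <- contact_rates(patient)
  contacts <- patient$contacts
  r <- stats::setNames(rates$fr350, rates$contact_id)
  if (all(r == 0)) stop("no FR-generating contacts")
  top_of <- function(ids) {
    ids <- ids[r[ids] > 0]
    if (length(ids) == 0) return(NULL)
    ids[order(-r[ids], ids)][1]
  }
  top1 <- top_of(contacts$contact_id)
  lead1 <- lead_window(contacts, top1)
  hemi1 <- contacts$hemisphere[contacts$contact_id == top1]
  if (bilateral) {
    opp <- contacts$contact_id[contacts$hemisphere != hemi1]
    top2 <- top_of(opp)
    if (is.null(top2)) {
      if (length(opp) == 0) stop("bilateral placement needs contacts in both hemispheres")
      top2 <- opp[order(opp)][1]  # no FR contralaterally: fall back to any contact
    }
  } else {
    shaft1 <- contacts$shaft_id[contacts$contact_id == top1]
    elsewhere <- contacts$contact_id[contacts$shaft_id != shaft1]
    if (length(elsewhere) == 0) stop("cannot place a second lead: no second shaft")
    top2 <- top_of(elsewhere)
    if (is.null(top2)) top2 <- elsewhere[order(-r[elsewhere], elsewhere)][1]
  }
  lead2 <- lead_window(contacts, top2)
  ids <- c(lead1, lead2)
  leads <- validate_rns_leads(list(stim_coords = contact_coords(contacts, ids),
                                   lead_types = c("depth", "depth")))
  attr(leads, "contact_ids") <- ids
  leads
}

#' Actual-versus-virtual RNS report
#'
#' One row per patient comparing the stimulation metrics of the actual
#' RNS placement (when recorded) with the virtual placement at the
#' highest-rate FR sites.
#'
#' @param patients list of `fr_patient` objects.
#' @param path optional CSV output path.
#' @param opts [fr_options()].
#' @return data frame, invisibly when `path` is given.
#' @export
rns_report <- function(patients, path = NULL, opts = fr_options()) {
  if (inherits(patients, "fr_patient")) patients <- list(patients)
  rows <- lapply(patients, function(p) {
    g <- build_mi_graph(p, opts)
    rates <- contact_rates(p)
    out <- data.frame(patient_id = p$patient_id,
                      actual_soz_sr = NA_real_, actual_fr_sr = NA_real_,
                      actual_rns_frnet = NA_real_,
                      virtual_soz_sr = NA_real_, virtual_fr_sr = NA_real_,
                      virtual_rns_frnet = NA_real_, stringsAsFactors = FALSE)
    if (!is.null(p$rns)) {
      act <- rns_metrics(p, stimulated_set(p$contacts, p$rns,
                                           opts$rns_field_radius_mm), g)
      out$actual_soz_sr <- as.numeric(act$soz_sr)
      out$actual_fr_sr <- as.numeric(act$fr_sr)
      out$actual_rns_frnet <- as.numeric(act$rns_temporal_frnet)
    }
    bilateral <- if (!is.null(p$rns)) p$rns$bilateral else FALSE
    virt <- rns_metrics(p, stimulated_set(
      p$contacts, virtual_placement(p, rates, bilateral),
      opts$rns_field_radius_mm), g)
    out$virtual_soz_sr <- as.numeric(virt$soz_sr)
    out$virtual_fr_sr <- as.numeric(virt$fr_sr)
    out$virtual_rns_frnet <- as.numeric(virt$rns_temporal_frnet)
    out
  })
  report <- do.call(rbind, rows)
  if (!is.null(path)) {
    utils::write.csv(format(report, digits = 6), path, row.names = FALSE, quote = FALSE)
    return(invisible(report))
  }
  report
}
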