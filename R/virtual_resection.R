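## Iterative spherical virtual resection targeting autonomous (lowest
## local efficiency), high-rate FR sites.
##
## Procedure: candidates are contacts with FR>350 Hz rate above 1/min
## ordered by ascending local efficiency (most autonomous first),
## followed by the remaining FR-generating contacts by descending rate.
## The first candidate fixes the sphere centre; the initial radius is
## 1 cm. Each later iteration admits the next candidate outside the
## current sphere and grows the radius to its distance plus a 1 cm
## buffer (never shrinking). Contacts in the hemisphere opposite the
## centre are never resected. After every change of the resected set the
## four FR factors, SOZ RR and RonS RR are recomputed and the SVM
## queried; the simulation stops at the first seizure-free label, when
## the resected set spans three lobes (designated non-seizure-free), or
## when candidates run out.

#' Candidate ordering for the virtual resection
#'
#' Primary ordering: contacts with FR>350 Hz rate above the threshold
#' (default 1/min), most autonomous first (ascending local efficiency;
#' ties broken by higher rate, then contact id). Fallback ordering
#' appended: the remaining FR-generating contacts by descending rate
#' (ties by contact id).
#'
#' @param patient an `fr_patient`.
#' @param g [build_mi_graph()] result.
#' @param rates [contact_rates()] table.
#' @param opts [fr_options()].
#' @return character vector of contact ids, best candidate first.
#' @export
candidate_order <- function(patient, g, rates = NULL, opts = fr_options()) {
  if (is.null(rates)) rates <- contact_rates(patient)
  fr <- rates[rates$fr350 > 0, , drop = FALSE]
  if (nrow(fr) == 0) stop("no FR-generating contacts (poor sampling)")
  le <- vapply(fr$contact_id, function(id)
    if (id %in% g$nodes) local_efficiency(g, id) else 0, numeric(1))
  hot <- fr$fr350 > opts$fr_rate_threshold
  primary <- fr$contact_id[hot][order(le[hot], -fr$fr350[hot], fr$contact_id[hot])]
  rest <- fr$contact_id[!hot][order(-fr$fr350[!hot], fr$contact_id[!hot])]
  c(primary, rest)
}

#' Contacts inside a resection sphere
#'
#' Closed ball: contacts at Euclidean distance less than or equal to
#' `radius` from the centre, excluding contacts in the hemisphere
#' opposite the centre's.
#'
#' @param contacts contacts data frame (see [fr_patient()]).
#' @param center length-3 coordinate (MNI mm).
#' @param radius sphere radius in mm.
#' @param center_hemisphere `"L"` or `"R"`.
#' @return character vector of contact ids.
#' @export
sphere_members <- function(contacts, center, radius, center_hemisphere) {
  d2 <- (contacts$x_mm - center[1])^2 + (contacts$y_mm - center[2])^2 +
    (contacts$z_mm - center[3])^2
  contacts$contact_id[d2 <= radius^2 & contacts$hemisphere == center_hemisphere]
}

#' Run the iterative virtual resection
#'
#' Simulates the sphere-growing virtual resection for one patient under
#' a trained outcome SVM. See the module header for the procedure; the
#' three-lobe check precedes the SVM query in each iteration, so a
#' resection spanning three lobes is always designated non-seizure-free.
#'
#' @param patient an `fr_patient`.
#' @param model an [fr_svm()].
#' @param opts [fr_options()]; `sphere_margin_mm` is the initial radius
#'   and the buffer added around each admitted candidate.
#' @param graph,rates optional precomputed network and rate table.
#' @return object of class `fr_resection_trace`: per-iteration data
#'   frame plus `center`, `final_resected`, `status` (one of
#'   `"seizure_free"`, `"three_lobe_stop"`, `"candidates_exhausted"`).
#' @export
run_virtual_resection <- function(patient, model, opts = fr_options(),
                                  graph = NULL, rates = NULL) {
  if (is.null(rates)) rates <- contact_rates(patient)
  if (is.null(graph)) graph <- build_mi_graph(patient, opts)
  cands <- candidate_order(patient, graph, rates, opts)
  contacts <- patient$contacts
  center_id <- cands[1]
  crow <- contacts[contacts$contact_id == center_id, ]
  center <- c(crow$x_mm, crow$y_mm, crow$z_mm)
  hemi <- crow$hemisphere
  margin <- opts$sphere_margin_mm
  ## contralateral candidates can never enter the resected set
  cand_rows <- contacts[match(cands, contacts$contact_id), ]
  cands <- cands[cand_rows$hemisphere == hemi]
  dist_to_center <- function(id) {
    r <- contacts[contacts$contact_id == id, ]
    sqrt(sum((c(r$x_mm, r$y_mm, r$z_mm) - center)^2))
  }
  radius <- margin
  resected <- character(0)
  iter_rows <- list()
  status <- NA_character_
  k <- 0L
  queue <- cands
  repeat {
    if (k == 0L) {
      new_set <- sphere_members(contacts, center, radius, hemi)
      queue <- setdiff(queue, c(center_id, new_set))
    } else {
      ## admit the next candidate outside the current sphere
      queue <- setdiff(queue, resected)
      if (length(queue) == 0) { status <- "candidates_exhausted"; break }
      nxt <- queue[1]
      queue <- queue[-1]
      d <- dist_to_center(nxt)
      if (d <= radius) next  # already inside: consumed without a new query
      radius <- max(radius, d + margin)
      new_set <- sphere_members(contacts, center, radius, hemi)
    }
    if (k > 0L && setequal(new_set, resected)) next
    resected <- new_set
    k <- k + 1L
    lobes <- unique(contacts$lobe[contacts$contact_id %in% resected])
    fv <- feature_vector(patient, resected, graph = graph, rates = rates,
                         opts = opts)
    soz_rr <- soz_resection_ratio(patient, resected)
    rons_rr <- event_resection_ratio(patient, "RonS", resected)
    three_lobes <- length(lobes) >= 3
    label <- if (three_lobes) NA else as.logical(predict(model, fv))
    iter_rows[[k]] <- data.frame(
      iteration = k, radius_mm = radius, n_resected = length(resected),
      soz_rr = as.numeric(soz_rr), rons_rr = as.numeric(rons_rr),
      fr_rr = as.numeric(fv$fr_rr),
      spatial_frnet = as.numeric(fv$spatial_frnet),
      temporal_frnet_a = as.numeric(fv$temporal_frnet_a),
      temporal_frnet_b = as.numeric(fv$temporal_frnet_b),
      svm_label = label, n_lobes = length(lobes),
      stringsAsFactors = FALSE)
    iter_rows[[k]]$resected_set <- I(list(sort(resected)))
    if (three_lobes) { status <- "three_lobe_stop"; break }
    if (isTRUE(label)) { status <- "seizure_free"; break }
  }
  trace <- do.call(rbind, iter_rows)
  structure(list(patient_id = patient$patient_id, center_id = center_id,
                 center = center, hemisphere = hemi,
                 trace = trace, final_resected = sort(resected),
                 status = status,
                 virtual_seizure_free = identical(status, "seizure_free")),
            class = "fr_resection_trace")
}

#' @export
print.fr_resection_trace <- function(x, ...) {
  cat("Virtual resection:", x$patient_id, "\n")
  cat(sprintf("  centre %s (%s), %d iteration(s), final radius %.1f mm, %d contacts\n",
              x$center_id, x$hemisphere, nrow(x$trace),
              x$trace$radius_mm[nrow(x$trace)], length(x$final_resected)))
  cat("  outcome:", x$status, "\n")
  invisible(x)
}

#' @export
as.data.frame.fr_resection_trace <- function(x, ...) {
  x$trace[, setdiff(names(x$trace), "resected_set")]
}

#' @export
plot.fr_resection_trace <- function(x, ...) {
  tr <- x$trace
  metrics <- c("soz_rr", "rons_rr", "fr_rr", "spatial_frnet",
               "temporal_frnet_a", "temporal_frnet_b")
  cols <- c("black", "red", "darkgreen", "blue", "cyan3", "magenta")
  rng <- range(unlist(tr[metrics]), na.rm = TRUE)
  graphics::plot(tr$iteration, tr$fr_rr, type = "n", ylim = rng,
                 xlab = "virtual resection iteration", ylab = "metric value",
                 main = paste("Virtual resection:", x$patient_id), ...)
  for (i in seq_along(metrics))
    graphics::lines(tr$iteration, tr[[metrics[i]]], col = cols[i], type = "b")
  if (x$virtual_seizure_free)
    graphics::abline(v = nrow(tr), lty = 2)
  graphics::legend("topleft", legend = metrics, col = cols, lty = 1, cex = 0.7)
  invisible(x)
}

#' Write a virtual-resection trace as CSV
#'
#' One row per iteration: radius, set size, the six metrics, SVM label
#' and distinct-lobe count.
#'
#' @param x an `fr_resection_trace`.
#' @param path CSV output path.
#' @return invisibly, `path`.
#' @export
write_resection_trace <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Contingency comparison of virtual and actual resections
#'
#' Classifies every contact of the universe as TP (in both sets), FP
#' (virtual only), FN (actual only) or TN (neither) and derives
#' sensitivity, specificity, PPV, NPV, accuracy and F1, plus
#' `percent_r` (fraction of the actual resection covered by the virtual
#' one, identical to sensitivity) and `novel_r` (fraction of the
#' virtual set outside the actual resection).
#'
#' @param virtual,actual character vectors of contact ids.
#' @param universe all of the patient's contact ids.
#' @return list of class `fr_contingency`.
#' @export
overlap_contingency <- function(virtual, actual, universe) {
  virtual <- intersect(virtual, universe)
  actual <- intersect(actual, universe)
  tp <- length(intersect(virtual, actual))
  fp <- length(setdiff(virtual, actual))
  fn <- length(setdiff(actual, virtual))
  tn <- length(universe) - tp - fp - fn
  ratio <- function(num, den, flag) if (den == 0) flagged_na(flag) else num / den
  sens <- ratio(tp, tp + fn, "empty actual set")
  ppv <- ratio(tp, tp + fp, "empty virtual set")
  f1 <- if (is.na(sens) || is.na(ppv) || (as.numeric(ppv) + as.numeric(sens)) == 0)
    flagged_na("undefined F1") else
      2 * as.numeric(ppv) * as.numeric(sens) / (as.numeric(ppv) + as.numeric(sens))
  structure(list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = sens,
    specificity = ratio(tn, tn + fp, "no negatives"),
    ppv = ppv,
    npv = ratio(tn, tn + fn, "no predicted negatives"),
    accuracy = (tp + tn) / length(universe),
    f1 = f1,
    percent_r = sens,
    novel_r = ratio(fp, tp + fp, "empty virtual set")
  ), class = "fr_contingency")
}

#' @export
print.fr_contingency <- function(x, ...) {
  cat(sprintf("contingency: TP %d FP %d TN %d FN %d\n", x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("  sensitivity %.3f specificity %.3f ppv %.3f npv %.3f\n",
              as.numeric(x$sensitivity), as.numeric(x$specificity),
              as.numeric(x$ppv), as.numeric(x$npv)))
  cat(sprintf("  accuracy %.3f f1 %.3f percent_r %.3f novel_r %.3f\n",
              as.numeric(x$accuracy), as.numeric(x$f1),
              as.numeric(x$percent_r), as.numeric(x$novel_r)))
  invisible(x)
}
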