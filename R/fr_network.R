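## FR MI network: nodes are contacts generating at least one FR>350 Hz
## event; edge weights are MI (bits) between the onset-time trains; edge
## lengths are reciprocal MI (infinite where MI = 0).
##
## Conventions pinned throughout (Brain Connectivity Toolbox style):
##  * efficiencies (local, global) use adjacency normalized by its
##    maximum, so direct-edge-dominated graphs score in [0, 1];
##  * characteristic path length uses raw lengths 1/MI and averages over
##    ordered pairs with a finite path, reporting the infinite count;
##  * rate-distance radius graphs use the edge weights directly as path
##    lengths; radius = minimum nodal eccentricity.

fr350_trains <- function(patient) {
  ev <- patient$events[family_mask(patient$events, "fr350"), , drop = FALSE]
  split(ev$onset_s, factor(ev$contact_id, levels = patient$contacts$contact_id))
}

#' Build the FR>350 Hz mutual-information graph
#'
#' Nodes are the contacts generating at least one FR>350 Hz event; the
#' symmetric adjacency holds the pairwise MI (bits) between their
#' onset-time trains and the length matrix its element-wise reciprocal
#' (infinite where MI is zero). Patients with fewer than two
#' FR-generating contacts yield a degenerate graph (flagged; such
#' patients are excluded from cohort analyses as poor sampling), and a
#' `poor_sampling` flag marks patients with no contact generating fRonS
#' above 1/min.
#'
#' @param patient an `fr_patient`.
#' @param opts [fr_options()] controlling the MI estimator.
#' @return an object of class `fr_mi_graph` with elements `nodes`
#'   (contact ids), `adjacency`, `lengths`, `rates` (FR>350 rates/min),
#'   `coords`, and flags `degenerate`, `disconnected`, `poor_sampling`.
#' @export
build_mi_graph <- function(patient, opts = fr_options()) {
  rates <- contact_rates(patient)
  nodes <- rates$contact_id[rates$fr350 > 0]
  trains <- fr350_trains(patient)
  frons_rate <- vapply(split(
    patient$events$category == "fRonS",
    factor(patient$events$contact_id, levels = patient$contacts$contact_id)),
    sum, numeric(1)) / patient$duration_min
  poor_sampling <- !any(frons_rate > 1)
  n <- length(nodes)
  adj <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (n >= 2) {
    dur_s <- patient$duration_min * 60
    for (i in seq_len(n - 1)) {
      for (j in seq((i + 1), n)) {
        m <- mi_between_trains(sort(trains[[nodes[i]]]), sort(trains[[nodes[j]]]),
                               opts, duration_s = dur_s)
        adj[i, j] <- m
        adj[j, i] <- m
      }
    }
  }
  len <- 1 / adj
  len[adj == 0] <- Inf
  diag(len) <- 0
  structure(list(
    nodes = nodes,
    adjacency = adj,
    lengths = len,
    rates = stats::setNames(rates$fr350[match(nodes, rates$contact_id)], nodes),
    coords = contact_coords(patient$contacts, nodes),
    degenerate = n < 2,
    disconnected = n >= 2 && all(adj[upper.tri(adj)] == 0),
    poor_sampling = poor_sampling
  ), class = "fr_mi_graph")
}

#' @export
print.fr_mi_graph <- function(x, ...) {
  cat("FR>350 Hz MI network:", length(x$nodes), "nodes,",
      sum(x$adjacency[upper.tri(x$adjacency)] > 0), "positive-MI edges\n")
  if (x$degenerate) cat("  [degenerate: fewer than two FR-generating contacts]\n")
  if (x$disconnected) cat("  [no positive-MI edge: fully disconnected]\n")
  if (x$poor_sampling) cat("  [poor spatial sampling: no contact with fRonS > 1/min]\n")
  invisible(x)
}

node_index <- function(g, nodes) {
  if (is.character(nodes)) {
    idx <- match(nodes, g$nodes)
    idx[!is.na(idx)]
  } else as.integer(nodes)
}

## all-pairs shortest path lengths for a length matrix (Inf = no edge)
shortest_path_lengths <- function(len) {
  n <- nrow(len)
  if (n <= 1) return(matrix(0, n, n))
  a <- len
  a[!is.finite(a)] <- 0
  diag(a) <- 0
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::distances(g, algorithm = "dijkstra")
}

## induced-subgraph efficiency on normalized weights; 0 when < 2 nodes
subgraph_efficiency <- function(adj_norm, idx) {
  k <- length(idx)
  if (k < 2) return(0)
  sub <- adj_norm[idx, idx, drop = FALSE]
  len <- 1 / sub
  len[sub == 0] <- Inf
  diag(len) <- 0
  d <- shortest_path_lengths(len)
  inv <- 1 / d[upper.tri(d)]
  inv[!is.finite(inv)] <- 0
  mean(inv)
}

#' Weighted nodal local efficiency
#'
#' Efficiency of the subgraph induced by the node's neighbours (contacts
#' with a positive-MI edge to it), computed on the adjacency normalized
#' by its global maximum. Nodes with fewer than two neighbours score 0.
#'
#' @param g an `fr_mi_graph`.
#' @param node contact id or node index.
#' @param normalize divide adjacency by its maximum first (default).
#' @return local efficiency in \[0, 1\].
#' @export
local_efficiency <- function(g, node, normalize = TRUE) {
  i <- node_index(g, node)
  if (length(i) != 1L || is.na(i)) stop("unknown node: ", node)
  w <- g$adjacency
  mx <- max(w)
  if (normalize && mx > 0) w <- w / mx
  nbrs <- which(w[i, ] > 0)
  if (length(nbrs) < 2) return(0)
  subgraph_efficiency(w, nbrs)
}

#' Characteristic path length of a node subset
#'
#' Mean shortest-path length over ordered pairs in the subgraph induced
#' on `subset`, using lengths 1/MI. Pairs with no finite path are
#' excluded from the mean; their count is attached as attribute
#' `n_infinite`.
#'
#' @param g an `fr_mi_graph`.
#' @param subset contact ids or node indices; default all nodes.
#' @return mean path length, or flagged `NA` when fewer than two nodes
#'   or no finite pair exists.
#' @export
characteristic_path_length <- function(g, subset = g$nodes) {
  idx <- node_index(g, subset)
  if (length(idx) < 2) return(flagged_na("fewer than two nodes"))
  len <- g$lengths[idx, idx, drop = FALSE]
  d <- shortest_path_lengths(len)
  vals <- d[upper.tri(d)]
  fin <- vals[is.finite(vals)]
  if (length(fin) == 0) return(flagged_na("no finite pair"))
  structure(mean(fin), n_infinite = 2L * sum(!is.finite(vals)))
}

#' Global efficiency of a node subset
#'
#' Mean inverse shortest-path length over ordered pairs in the induced
#' subgraph (disconnected pairs contribute 0). Lengths are the raw
#' reciprocal MI, so a direct edge contributes its MI in bits and the
#' value is comparable across patients; set `normalize = TRUE` for the
#' max-normalized convention used by [local_efficiency()].
#'
#' @param g an `fr_mi_graph`.
#' @param subset contact ids or node indices; default all nodes.
#' @param normalize divide adjacency by its global maximum first.
#' @return efficiency value, or flagged `NA` for fewer than two nodes.
#' @export
global_efficiency <- function(g, subset = g$nodes, normalize = FALSE) {
  idx <- node_index(g, subset)
  if (length(idx) < 2) return(flagged_na("fewer than two nodes"))
  w <- g$adjacency
  mx <- max(w)
  if (normalize && mx > 0) w <- w / mx
  subgraph_efficiency(w, idx)
}

#' Radius of the complete rate-distance (or distance) graph
#'
#' Builds the complete graph on the given contacts with edge weights
#' either the mean of the two contacts' FR>350 Hz rates multiplied by
#' their Euclidean distance (mm) — the `rate_distance` rule — or the
#' distance alone, uses the weights directly as path lengths, and
#' returns the graph radius (minimum over nodes of the maximal
#' shortest-path distance). A single node has radius 0.
#'
#' @param coords numeric matrix (n x 3) of MNI coordinates in mm.
#' @param rates FR>350 Hz rates (events/min), required for
#'   `rate_distance`.
#' @param weight_rule `"rate_distance"` or `"distance_only"`.
#' @return radius, or flagged `NA` for an empty node set.
#' @export
graph_radius <- function(coords, rates = NULL,
                         weight_rule = c("rate_distance", "distance_only")) {
  weight_rule <- match.arg(weight_rule)
  coords <- matrix(as.numeric(coords), ncol = 3)
  n <- nrow(coords)
  if (n == 0) return(flagged_na("empty node set"))
  if (n == 1) return(0)
  d <- as.matrix(stats::dist(coords))
  if (weight_rule == "rate_distance") {
    if (is.null(rates) || length(rates) != n)
      stop("rate_distance rule needs one rate per node")
    w <- outer(rates, rates, function(a, b) (a + b) / 2) * d
  } else w <- d
  g <- igraph::make_full_graph(n)
  el <- igraph::as_edgelist(g)
  igraph::E(g)$weight <- w[cbind(el[, 1], el[, 2])]
  sp <- igraph::distances(g)
  min(apply(sp, 1, max))
}

#' Spatial FRnet (rate-distance radius resected difference)
#'
#' Square root of the (clamped-nonnegative) difference between the
#' rate-distance graph radius of all FR>350 Hz generating contacts and
#' that of the resected FR-generating contacts alone. Zero whenever the
#' resection contains every FR-generating contact; the units are
#' sqrt(rate x mm).
#'
#' @param patient an `fr_patient`.
#' @param resected character vector of resected contact ids.
#' @param rates optional precomputed [contact_rates()] table.
#' @return nonnegative value, or flagged `NA` with no FR-generating
#'   contacts.
#' @export
spatial_frnet <- function(patient, resected, rates = NULL) {
  if (is.null(rates)) rates <- contact_rates(patient)
  fr_nodes <- rates$contact_id[rates$fr350 > 0]
  if (length(fr_nodes) == 0) return(flagged_na("no FR-generating contacts"))
  r <- stats::setNames(rates$fr350[match(fr_nodes, rates$contact_id)], fr_nodes)
  whole <- graph_radius(contact_coords(patient$contacts, fr_nodes), r,
                        "rate_distance")
  res_nodes <- intersect(fr_nodes, resected)
  res <- if (length(res_nodes) <= 1) 0 else
    graph_radius(contact_coords(patient$contacts, res_nodes),
                 r[res_nodes], "rate_distance")
  sqrt(max(0, whole - res))
}

#' Temporal FRnet-A (resected/whole path-length ratio)
#'
#' Characteristic path length of the MI subgraph induced on the resected
#' FR nodes divided by that of the whole MI network.
#'
#' @param g an `fr_mi_graph`.
#' @param resected contact ids of the resected set.
#' @return nonnegative ratio, or flagged `NA` when either path length is
#'   undefined (degenerate subgraph).
#' @export
temporal_frnet_a <- function(g, resected) {
  denom <- characteristic_path_length(g, g$nodes)
  if (is.na(denom) || denom <= 0) return(flagged_na("whole-network path length undefined"))
  num <- characteristic_path_length(g, intersect(g$nodes, resected))
  if (is.na(num)) return(flagged_na(metric_flag(num)))
  as.numeric(num) / as.numeric(denom)
}

#' Temporal FRnet-B (mean positive local efficiency)
#'
#' Mean nodal local efficiency over the evaluated node set restricted to
#' nodes with efficiency greater than zero. By default the evaluated set
#' is the unresected MI nodes (`frnetB_scope = "unresected"`); with
#' `frnetB_scope = "all"` every node is evaluated. When no evaluated
#' node has positive efficiency (e.g. the whole network was resected)
#' the degenerate convention 1.0 is returned with a flag.
#'
#' @param g an `fr_mi_graph`.
#' @param resected contact ids of the resected set.
#' @param opts [fr_options()].
#' @return value in \[0, 1\] (1.0 with attribute `flag = "degenerate"`
#'   in the degenerate case).
#' @export
temporal_frnet_b <- function(g, resected, opts = fr_options()) {
  eval_nodes <- if (opts$frnetB_scope == "unresected")
    setdiff(g$nodes, resected) else g$nodes
  if (length(eval_nodes) == 0) return(structure(1.0, flag = "degenerate"))
  le <- vapply(eval_nodes, function(nd) local_efficiency(g, nd), numeric(1))
  le <- le[le > 0]
  if (length(le) == 0) return(structure(1.0, flag = "degenerate"))
  mean(le)
}

#' The four FR factors for a (virtual or actual) resection
#'
#' Computes the feature vector driving the outcome SVM: the FR>350 Hz
#' resection ratio, spatial FRnet, and temporal FRnet-A and FRnet-B, all
#' with respect to the given resected contact set. Degenerate components
#' carry flags (see [metric_flag()]) and are imputed at SVM training or
#' prediction time.
#'
#' @param patient an `fr_patient`.
#' @param resected character vector of resected contact ids.
#' @param graph optional precomputed [build_mi_graph()] result.
#' @param rates optional precomputed [contact_rates()] table.
#' @param opts [fr_options()].
#' @return list of class `fr_features` with `fr_rr`, `spatial_frnet`,
#'   `temporal_frnet_a`, `temporal_frnet_b`.
#' @export
feature_vector <- function(patient, resected, graph = NULL, rates = NULL,
                           opts = fr_options()) {
  if (is.null(rates)) rates <- contact_rates(patient)
  if (is.null(graph)) graph <- build_mi_graph(patient, opts)
  structure(list(
    fr_rr = event_resection_ratio(patient, "fr350", resected),
    spatial_frnet = spatial_frnet(patient, resected, rates),
    temporal_frnet_a = temporal_frnet_a(graph, resected),
    temporal_frnet_b = temporal_frnet_b(graph, resected, opts)
  ), class = "fr_features")
}

#' @export
print.fr_features <- function(x, ...) {
  cat(sprintf("FR factors: FR RR %.3f | spatial FRnet %.3f | temporal FRnet-A %.3f | temporal FRnet-B %.3f\n",
              as.numeric(x$fr_rr), as.numeric(x$spatial_frnet),
              as.numeric(x$temporal_frnet_a), as.numeric(x$temporal_frnet_b)))
  invisible(x)
}

as_feature_row <- function(fv) {
  vapply(c("fr_rr", "spatial_frnet", "temporal_frnet_a", "temporal_frnet_b"),
         function(nm) as.numeric(fv[[nm]]), numeric(1))
}

#' Export an MI graph for inspection
#'
#' Writes the positive-MI edges as a CSV edge list
#' (`node_a, node_b, mi_bits, length`) or as GraphML.
#'
#' @param g an `fr_mi_graph`.
#' @param path output file.
#' @param format `"csv"` or `"graphml"`.
#' @return invisibly, `path`.
#' @export
write_mi_graph <- function(g, path, format = c("csv", "graphml")) {
  format <- match.arg(format)
  ut <- which(upper.tri(g$adjacency) & g$adjacency > 0, arr.ind = TRUE)
  edges <- data.frame(node_a = g$nodes[ut[, 1]], node_b = g$nodes[ut[, 2]],
                      mi_bits = g$adjacency[ut], length = g$lengths[ut],
                      stringsAsFactors = FALSE)
  if (format == "csv") {
    utils::write.csv(edges, path, row.names = FALSE, quote = FALSE)
  } else {
    ig <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                        vertices = data.frame(name = g$nodes))
    igraph::write_graph(ig, path, format = "graphml")
  }
  invisible(path)
}
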