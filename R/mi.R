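## Mutual information between event-onset trains.
##
## Two estimators:
##  * "adaptive": the two trains are reduced to their joint inter-event
##    structure by sampling, at every event time of either train, the
##    elapsed time since the previous event of train a and of train b
##    (the two "interval clocks"); MI of that plane is estimated by
##    Darbellay-Vajda adaptive partitioning in rank space. When trains
##    are coupled the two clocks reset together and the sample
##    concentrates along the diagonal; when trains are independent
##    Poisson processes both clocks are independent exponentials. The
##    two axis orders are averaged so the estimate is exactly symmetric.
##  * "binned": fixed-width binned event counts, plug-in MI on the joint
##    count histogram with the Miller-Madow bias correction.
## Units are bits throughout.

## Darbellay-Vajda adaptive partitioning on a 2-D sample.
## Work in rank space (both marginals uniform); recursively split each
## cell at the marginal medians of the points it contains, keep splitting
## while a chi-square test on the four quadrant counts rejects local
## independence, and sum the plug-in contributions of the terminal cells.
dv_mi_2d <- function(x, y, chi2_crit = 7.815, chi2_crit_4x4 = 16.919,
                     min_cell = 8L) {
  n <- length(x)
  if (n < 2L) return(0)
  rx <- rank(x, ties.method = "first")
  ry <- rank(y, ties.method = "first")
  recurse <- function(idx, x0, x1, y0, y1) {
    nc <- length(idx)
    if (nc == 0L) return(0)
    terminal <- function() {
      p <- nc / n
      p * log2(p / (((x1 - x0) / n) * ((y1 - y0) / n)))
    }
    if (nc < min_cell) return(terminal())
    sx <- floor(stats::median(rx[idx]))
    sy <- floor(stats::median(ry[idx]))
    if (sx <= x0 || sx >= x1 || sy <= y0 || sy >= y1) return(terminal())
    ix <- rx[idx] <= sx
    iy <- ry[idx] <= sy
    nq <- c(sum(ix & iy), sum(ix & !iy), sum(!ix & iy), sum(!ix & !iy))
    ## expected quadrant counts under independence within the cell
    ## follow the sub-rectangle areas in rank space
    ax <- (sx - x0) / (x1 - x0)
    ay <- (sy - y0) / (y1 - y0)
    pq <- c(ax * ay, ax * (1 - ay), (1 - ax) * ay, (1 - ax) * (1 - ay))
    expd <- nc * pq
    chi2 <- sum((nq - expd)^2 / expd)
    split <- is.finite(chi2) && chi2 > chi2_crit
    ## the median 2x2 test is blind to dependence symmetric about the
    ## medians (a diagonal plus anti-diagonal cross balances the
    ## quadrants), so also test uniformity on a 4x4 quartile grid
    if (!split && nc >= 16L) {
      qx <- stats::quantile(rx[idx], c(0.25, 0.5, 0.75), type = 1)
      qy <- stats::quantile(ry[idx], c(0.25, 0.5, 0.75), type = 1)
      cx <- findInterval(rx[idx], qx, left.open = TRUE)
      cy <- findInterval(ry[idx], qy, left.open = TRUE)
      n16 <- tabulate(cx * 4L + cy + 1L, nbins = 16L)
      chi2_4 <- sum((n16 - nc / 16)^2 / (nc / 16))
      split <- chi2_4 > chi2_crit_4x4
    }
    if (!split) return(terminal())
    recurse(idx[ix & iy], x0, sx, y0, sy) +
      recurse(idx[ix & !iy], x0, sx, sy, y1) +
      recurse(idx[!ix & iy], sx, x1, y0, sy) +
      recurse(idx[!ix & !iy], sx, x1, sy, y1)
  }
  max(0, recurse(seq_len(n), 0, n, 0, n))
}

## Interval-clock sample: at each event time of either train (strictly
## after the first event of both), the elapsed time since the previous
## event of train a and since the previous event of train b.
interval_clock_pairs <- function(a, b) {
  probes <- sort(c(a, b))
  probes <- probes[probes > max(a[1L], b[1L])]
  if (length(probes) < 2L) return(NULL)
  ## previous event strictly before the probe
  xa <- probes - a[findInterval(probes, a, left.open = TRUE)]
  xb <- probes - b[findInterval(probes, b, left.open = TRUE)]
  cbind(xa, xb)
}

mi_adaptive <- function(a, b) {
  p <- interval_clock_pairs(a, b)
  if (is.null(p)) return(0)
  (dv_mi_2d(p[, 1], p[, 2]) + dv_mi_2d(p[, 2], p[, 1])) / 2
}

mi_binned <- function(a, b, bin_s, duration_s) {
  if (is.null(duration_s) || !is.finite(duration_s))
    duration_s <- max(a, b, 0) + bin_s
  breaks <- seq(0, duration_s + bin_s, by = bin_s)
  ca <- findInterval(a, breaks, rightmost.closed = FALSE)
  cb <- findInterval(b, breaks, rightmost.closed = FALSE)
  nb <- length(breaks) - 1L
  na_counts <- tabulate(ca, nbins = nb)
  nb_counts <- tabulate(cb, nbins = nb)
  jt <- table(na_counts, nb_counts)
  n <- sum(jt)
  pj <- jt / n
  px <- rowSums(pj)
  py <- colSums(pj)
  nz <- pj > 0
  mi <- sum(pj[nz] * log2(pj[nz] / (outer(px, py)[nz])))
  ## Miller-Madow: H_mm = H + (K-1)/2n (nats); for MI the corrections of
  ## the three entropies combine to (Kx + Ky - Kxy - 1) / 2n
  kx <- sum(px > 0); ky <- sum(py > 0); kxy <- sum(nz)
  mi <- mi + (kx + ky - kxy - 1) / (2 * n * log(2))
  max(0, mi)
}

#' Mutual information between two event-onset trains
#'
#' Estimates the mutual information (bits) between two trains of event
#' onset times, the edge weight of the FR MI network. The default
#' adaptive estimator pairs each train's inter-event intervals with the
#' latency to the nearest event of the other train and applies
#' Darbellay-Vajda adaptive partitioning; the result is the average of
#' the two directions and therefore exactly symmetric. The binned
#' estimator computes plug-in MI between fixed-width event counts with
#' the Miller-Madow correction.
#'
#' @param a,b numeric vectors of onset times in seconds, sorted
#'   ascending, non-negative.
#' @param opts [fr_options()]; `mi_estimator`, `mi_bin_s` and
#'   `mi_min_events` are used.
#' @param duration_s recording length in seconds (binned estimator
#'   only); defaults to the last event time plus one bin.
#' @return nonnegative MI estimate in bits; 0 when either train has
#'   fewer than `mi_min_events` events.
#' @export
mi_between_trains <- function(a, b, opts = fr_options(), duration_s = NULL) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (any(a < 0) || any(b < 0)) stop("negative event onset time")
  if (is.unsorted(a) || is.unsorted(b)) stop("onset times must be sorted ascending")
  if (length(a) < opts$mi_min_events || length(b) < opts$mi_min_events) return(0)
  if (opts$mi_estimator == "adaptive") mi_adaptive(a, b)
  else mi_binned(a, b, opts$mi_bin_s, duration_s)
}

#' Permutation p-value for train coupling
#'
#' Tests whether the MI between two trains exceeds what interval
#' shuffling can explain: surrogates of the first train are built by
#' randomly permuting its inter-event intervals (preserving the interval
#' distribution while destroying alignment with the second train), and
#' the observed MI is compared against the surrogate distribution.
#'
#' @param a,b onset-time vectors (seconds, sorted).
#' @param n_perm number of surrogates.
#' @param opts [fr_options()].
#' @param seed RNG seed for the surrogate draws.
#' @param duration_s passed to [mi_between_trains()].
#' @return list with `mi` (observed), `p` (upper-tail permutation
#'   p-value with the +1 correction) and `null` (surrogate MI values).
#' @export
mi_permutation_test <- function(a, b, n_perm = 199, opts = fr_options(),
                                seed = 1, duration_s = NULL) {
  obs <- mi_between_trains(a, b, opts, duration_s)
  null <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      isi <- diff(c(0, a))
      surro <- cumsum(sample(isi))
      mi_between_trains(sort(surro), b, opts, duration_s)
    }, numeric(1))
  })
  list(mi = obs, p = (1 + sum(null >= obs)) / (n_perm + 1), null = null)
}
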