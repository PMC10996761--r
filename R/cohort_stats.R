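## Cohort-level statistics: rank tests, the autonomy (rate vs local
## efficiency) k-means clustering, and the two-proportion power
## calculations for trial design.

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic with a chi-square p-value on k-1 degrees of
#' freedom. When every value is identical across groups the statistic is
#' 0 and p is 1 (the generic implementation would return 0/0).
#'
#' @param groups list of two or more numeric vectors.
#' @return list with `H`, `p`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stop("need at least two groups")
  if (any(vapply(groups, length, integer(1)) == 0)) stop("empty group")
  vals <- unlist(groups)
  if (length(unique(vals)) == 1L)
    return(list(H = 0, p = 1, df = length(groups) - 1L))
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), p = kt$p.value, df = unname(kt$parameter))
}

#' Exact Wilcoxon signed-rank test
#'
#' Two-sided p-value from the full signed-rank null distribution,
#' obtained by enumerating all 2^n sign assignments (n the number of
#' nonzero differences; zero differences are dropped, ties receive
#' average ranks). For n above `exact_max` a normal approximation with
#' tie correction is used instead.
#'
#' @param a first sample, or the paired differences when `b` is `NULL`.
#' @param b optional second sample (paired with `a`).
#' @param exact_max largest n for which the exact enumeration is used.
#' @return list with `W` (sum of positive-difference ranks), `p`
#'   (two-sided), `n` (nonzero differences), `exact`.
#' @export
wilcoxon_signrank_exact <- function(a, b = NULL, exact_max = 15) {
  d <- if (is.null(b)) as.numeric(a) else as.numeric(a) - as.numeric(b)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(list(W = 0, p = 1, n = 0L, exact = TRUE))
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_max) {
    ## distribution of W over all sign assignments by convolution on
    ## doubled ranks (average ranks can be half-integers)
    r2 <- round(2 * r)
    dist <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), dist)
      dist <- c(dist, numeric(ri)) + shifted
    }
    dist <- dist / sum(dist)
    w2 <- round(2 * w)
    p_le <- sum(dist[seq_len(w2 + 1L)])
    p_ge <- sum(dist[(w2 + 1L):length(dist)])
    p <- min(1, 2 * min(p_le, p_ge))
    return(list(W = w, p = p, n = n, exact = TRUE))
  }
  mu <- n * (n + 1) / 4
  tie_tab <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(tie_tab^3 - tie_tab) / 48
  z <- (w - mu) / sqrt(sigma2)
  list(W = w, p = min(1, 2 * stats::pnorm(-abs(z))), n = n, exact = FALSE)
}

#' Autonomy clustering of FR nodes
#'
#' k-means (default k = 2) on the z-scored plane of log FR>350 Hz rate
#' versus nodal local efficiency. The autonomous cluster — high-rate
#' nodes generating FR independently of the rest of the network — is
#' the one with the lowest mean local efficiency. When a resected-node
#' indicator is supplied the count of unresected autonomous nodes is
#' returned (the cohort statistic compared across outcome groups).
#'
#' @param log_rate per-node log FR rate (natural log of events/min).
#' @param le per-node local efficiency.
#' @param k number of clusters.
#' @param resected optional logical vector (`TRUE` = resected node).
#' @param seed RNG seed for the k-means restarts.
#' @param nstart number of k-means restarts.
#' @return list with `labels`, `autonomous` (cluster id), `centers`,
#'   and `n_unresected_autonomous` when `resected` is given.
#' @export
autonomy_clusters <- function(log_rate, le, k = 2, resected = NULL,
                              seed = 1, nstart = 25) {
  pts <- cbind(log_rate = log_rate, le = le)
  if (nrow(unique(pts)) < k)
    stop("fewer distinct points than clusters")
  z <- scale(pts)
  z[, apply(pts, 2, stats::sd) == 0] <- 0
  km <- withr::with_seed(seed, stats::kmeans(z, centers = k, nstart = nstart))
  mean_le <- vapply(seq_len(k), function(cl) mean(le[km$cluster == cl]), numeric(1))
  mean_rate <- vapply(seq_len(k), function(cl) mean(log_rate[km$cluster == cl]), numeric(1))
  ## autonomous = lowest mean LE; ties (e.g. a fully edgeless network)
  ## resolved toward the higher-rate cluster, matching the definition of
  ## autonomy as high-rate FR generation with low synchrony
  autonomous <- order(mean_le, -mean_rate)[1]
  out <- list(labels = km$cluster, autonomous = autonomous,
              centers = km$centers)
  if (!is.null(resected))
    out$n_unresected_autonomous <- sum(km$cluster == autonomous & !resected)
  out
}

#' Power of the two-sided unpooled two-proportion Z-test
#'
#' Power to detect the difference between two seizure-freedom
#' proportions with `n_per_arm` patients in each arm:
#' \deqn{\Phi(|\Delta|/SE - z_{1-\alpha/2}) + \Phi(-|\Delta|/SE - z_{1-\alpha/2})}
#' with the unpooled standard error
#' \eqn{SE = \sqrt{p_1(1-p_1)/n + p_2(1-p_2)/n}}.
#'
#' @param p_control,p_active the two proportions, in (0, 1).
#' @param n_per_arm patients per arm (>= 2).
#' @param alpha two-sided significance level.
#' @return power in (0, 1).
#' @export
two_proportion_power <- function(p_control, p_active, n_per_arm, alpha = 0.05) {
  for (p in c(p_control, p_active))
    if (!is.finite(p) || p <= 0 || p >= 1) stop("proportions must be in (0, 1)")
  if (n_per_arm < 2) stop("n_per_arm must be at least 2")
  se <- sqrt(p_control * (1 - p_control) / n_per_arm +
             p_active * (1 - p_active) / n_per_arm)
  delta <- abs(p_active - p_control)
  zc <- stats::qnorm(1 - alpha / 2)
  stats::pnorm(delta / se - zc) + stats::pnorm(-delta / se - zc)
}

#' Enrollment needed under an expected dropout rate
#'
#' Inflates the per-arm analytic sample size by the dropout fraction,
#' rounded up: `ceil(n / (1 - dropout))`.
#'
#' @param n_per_arm analytic sample size per arm.
#' @param dropout expected dropout fraction in \[0, 1).
#' @return integer enrolled count.
#' @export
enrollment_inflation <- function(n_per_arm, dropout) {
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  as.integer(ceiling(n_per_arm / (1 - dropout)))
}

#' Unresected autonomous-node count for one patient
#'
#' Convenience wrapper: builds the (log rate, local efficiency) plane
#' for the patient's MI nodes, clusters it with [autonomy_clusters()],
#' and counts autonomous nodes left outside the resected set.
#'
#' @param patient an `fr_patient`.
#' @param resected contact ids; default the actual resection.
#' @param g optional precomputed [build_mi_graph()].
#' @param k,seed passed to [autonomy_clusters()].
#' @return integer count (0 for degenerate MI graphs).
#' @export
unresected_autonomous_count <- function(patient,
                                        resected = patient$contacts$contact_id[patient$contacts$is_resected],
                                        g = NULL, k = 2, seed = 1) {
  if (is.null(g)) g <- build_mi_graph(patient)
  if (g$degenerate || length(g$nodes) < k) return(0L)
  le <- vapply(g$nodes, function(nd) local_efficiency(g, nd), numeric(1))
  cl <- tryCatch(
    autonomy_clusters(log(g$rates), le, k = k,
                      resected = g$nodes %in% resected, seed = seed),
    error = function(e) NULL)
  if (is.null(cl)) return(0L)
  as.integer(cl$n_unresected_autonomous)
}
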