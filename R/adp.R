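# Density-peaks clustering with point-adaptive k-NN density estimation and
# statistical merging of non-significant peaks.
#
# The density estimator follows the adaptive-neighbourhood family: for every
# point, the neighbourhood is grown while a likelihood-ratio test accepts
# local uniformity, capped at k_max; the log-density is then
# log(k*) - log(n * V_d * r_{k*}^d) with d the two-NN intrinsic dimension,
# and its statistical error 1/sqrt(k*). Provisional peaks are points whose
# density is not exceeded within their own adaptive neighbourhood; every
# other point joins the cluster of its nearest higher-density point; and two
# clusters merge when neither peak rises above their connecting saddle by
# more than Z times the propagated error (peak and saddle errors summed in
# quadrature). Determinism: ties broken by lowest observation index.

#' Clustering parameters for density-peaks clustering
#'
#' @param Z Merging significance: a cluster pair merges when the
#'   peak-minus-saddle log-density gap is below `Z` times its error.
#' @param k_max Cap on the adaptive neighbourhood size.
#' @param metric Distance metric: `"euclidean"`, `"periodic"` (minimal
#'   angular differences, degrees), or `"manhattan"`.
#' @param seed RNG seed (the algorithm is deterministic; kept for provenance).
#' @return A `clustering_params` list.
#' @export
clustering_params <- function(Z = 3, k_max = 100,
                              metric = c("euclidean", "periodic", "manhattan"),
                              seed = 1L) {
  if (Z <= 0) stop_hd("Z must be positive.", "invalid_spec_error")
  structure(list(Z = Z, k_max = as.integer(k_max),
                 metric = match.arg(metric), seed = as.integer(seed)),
            class = "clustering_params")
}

# Two-NN maximum-likelihood intrinsic dimension (ratio of the second to the
# first neighbour distance).
intrinsic_dimension_2nn <- function(D) {
  n <- nrow(D)
  r1 <- r2 <- numeric(n)
  for (i in seq_len(n)) {
    d <- sort(D[i, -i])
    r1[i] <- d[1]
    r2[i] <- d[2]
  }
  pos <- r1 > 0
  if (!any(pos)) stop_hd("All first-neighbour distances are zero.",
                         "zero_distance_error")
  mu <- r2[pos] / r1[pos]
  max(1, sum(pos) / sum(log(mu)))
}

# Adaptive k per point: grow k while an inner-ball/outer-shell split
# likelihood-ratio test accepts local uniformity (chi^2, 1 df).
adaptive_kstar <- function(dsort, d_id, k_max, k_min = 4,
                           lrt_threshold = qchisq(0.99, 1)) {
  kcap <- min(k_max, length(dsort))
  kstar <- k_min
  for (k in seq(k_min, kcap)) {
    k1 <- k %/% 2
    k2 <- k - k1
    p1 <- (dsort[k1] / dsort[k])^d_id
    p1 <- min(max(p1, 1e-12), 1 - 1e-12)
    ll <- function(x, p) if (x == 0) 0 else x * log(x / (k * p))
    stat <- 2 * (ll(k1, p1) + ll(k2, 1 - p1))
    if (stat > lrt_threshold) break
    kstar <- k
  }
  kstar
}

#' Density-peaks clustering of a feature matrix
#'
#' Deterministic density-peaks clustering: two-NN intrinsic dimension,
#' point-adaptive k-NN log-density with per-point error, peak detection
#' within adaptive neighbourhoods, assignment of each point to its nearest
#' higher-density point, and Z-controlled statistical merging of clusters
#' across saddles (see the package vignette for the merging statistic).
#'
#' @param observations Numeric matrix (rows = observations); a `metric`
#'   attribute set by [dihedral_features()] / [interface_map_features()] is
#'   honoured unless `params$metric` differs from its default.
#' @param params A [clustering_params()].
#' @param provenance Optional data frame (one row per observation) carried
#'   into the result, e.g. variant / replica labels.
#' @return A `cluster_result`: list with `labels` (integer per observation,
#'   1..n_clusters), `centers` (observation indices of peaks),
#'   `log_density`, `density_error`, `kstar`, `intrinsic_dim`, `n_initial`
#'   (cluster count before merging), `provenance`, `params`.
#' @export
adp_cluster <- function(observations, params = clustering_params(),
                        provenance = NULL) {
  X <- as.matrix(observations)
  n <- nrow(X)
  if (n < 10) stop_hd("Need at least 10 observations.", "invalid_spec_error")
  if (!is.null(provenance) && nrow(as_tibble(provenance)) != n) {
    stop_hd("Provenance must have one row per observation.",
            "invalid_spec_error")
  }
  metric <- attr(observations, "metric") %||% params$metric
  if (!identical(params$metric, "euclidean")) metric <- params$metric
  D <- feature_dist(X, metric)
  if (max(D) == 0) {
    stop_hd("All observations are identical (zero distances).",
            "zero_distance_error")
  }
  d_id <- intrinsic_dimension_2nn(D)
  ord_nb <- apply(D, 1, order)  # column i: indices sorted by distance to i
  kstar <- integer(n)
  logrho <- err <- numeric(n)
  for (i in seq_len(n)) {
    nb <- ord_nb[, i]
    nb <- nb[nb != i]
    dsort <- D[i, nb]
    # guard exact duplicates: treat zero distances as tiny
    dsort[dsort == 0] <- min(dsort[dsort > 0], 1e-12) / 2
    kstar[i] <- adaptive_kstar(dsort, d_id, params$k_max)
    logrho[i] <- log(kstar[i]) - log(n) - d_id * log(dsort[kstar[i]])
    err[i] <- 1 / sqrt(kstar[i])
  }
  # peaks: no strictly denser point within the adaptive neighbourhood
  is_peak <- logical(n)
  for (i in seq_len(n)) {
    nb <- ord_nb[, i]
    nb <- nb[nb != i][seq_len(kstar[i])]
    denser <- logrho[nb] > logrho[i] |
      (logrho[nb] == logrho[i] & nb < i)
    is_peak[i] <- !any(denser)
  }
  peaks <- which(is_peak)
  # assignment in order of decreasing density to nearest higher-density point
  ord_rho <- order(-logrho, seq_len(n))
  labels <- integer(n)
  peak_of <- integer(0)
  for (i in ord_rho) {
    if (is_peak[i]) {
      peak_of <- c(peak_of, i)
      labels[i] <- length(peak_of)
    } else {
      higher <- which(logrho > logrho[i] | (logrho == logrho[i] &
                                              seq_len(n) < i))
      j <- higher[which.min(D[i, higher])]
      labels[i] <- labels[j]
    }
  }
  n_initial <- length(peak_of)
  # saddle-based statistical merging
  merged <- merge_clusters(labels, peak_of, logrho, err, D, ord_nb, kstar,
                           params$Z)
  labels <- merged$labels
  centers <- merged$centers
  res <- structure(
    list(labels = labels, centers = centers, log_density = logrho,
         density_error = err, kstar = kstar, intrinsic_dim = d_id,
         n_initial = n_initial,
         provenance = if (is.null(provenance)) NULL else as_tibble(provenance),
         params = params),
    class = "cluster_result")
  res
}

# Iteratively merge cluster pairs whose peak-saddle gap is insignificant.
merge_clusters <- function(labels, peak_of, logrho, err, D, ord_nb, kstar, Z) {
  n <- length(labels)
  repeat {
    ids <- sort(unique(labels))
    if (length(ids) == 1) break
    # saddle between each cluster pair: densest border contact
    saddle <- list()
    for (i in seq_len(n)) {
      nb <- ord_nb[, i]
      nb <- nb[nb != i][seq_len(kstar[i])]
      for (j in nb[labels[nb] != labels[i]]) {
        a <- min(labels[i], labels[j])
        b <- max(labels[i], labels[j])
        key <- paste(a, b)
        cand <- if (logrho[i] < logrho[j]) i else j  # saddle-side point
        s <- saddle[[key]]
        if (is.null(s) || logrho[cand] > s$rho) {
          saddle[[key]] <- list(a = a, b = b, rho = logrho[cand],
                                err = err[cand])
        }
      }
    }
    # clusters with no within-neighbourhood border contact: fall back to the
    # closest inter-cluster point pair, so that Z -> Inf always merges fully
    for (a_id in ids) {
      for (b_id in ids[ids > a_id]) {
        key <- paste(a_id, b_id)
        if (!is.null(saddle[[key]])) next
        ia <- which(labels == a_id)
        ib <- which(labels == b_id)
        sub <- D[ia, ib, drop = FALSE]
        hit <- which(sub == min(sub), arr.ind = TRUE)[1, ]
        i <- ia[hit[1]]; j <- ib[hit[2]]
        cand <- if (logrho[i] < logrho[j]) i else j
        saddle[[key]] <- list(a = a_id, b = b_id, rho = logrho[cand],
                              err = err[cand])
      }
    }
    peak_rho <- vapply(ids, function(c) max(logrho[labels == c]), numeric(1))
    peak_err <- vapply(ids, function(c) {
      err[which(labels == c)[which.max(logrho[labels == c])]]
    }, numeric(1))
    names(peak_rho) <- names(peak_err) <- ids
    best <- NULL
    for (s in saddle) {
      gap <- min(peak_rho[as.character(s$a)] - s$rho,
                 peak_rho[as.character(s$b)] - s$rho)
      e <- sqrt(peak_err[as.character(s$a)]^2 +
                  peak_err[as.character(s$b)]^2 + s$err^2)
      sig <- gap / e
      if (is.null(best) || sig < best$sig) {
        best <- list(a = s$a, b = s$b, sig = sig)
      }
    }
    if (best$sig >= Z) break
    labels[labels == best$b] <- best$a
  }
  ids <- sort(unique(labels))
  relab <- match(labels, ids)
  centers <- vapply(ids, function(c) {
    members <- which(labels == c)
    members[which.max(logrho[members])]
  }, integer(1))
  list(labels = relab, centers = centers)
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d observations, %d cluster(s) (from %d peaks), intrinsic dim %.2f\n",
              length(x$labels), length(x$centers), x$n_initial,
              x$intrinsic_dim))
  invisible(x)
}

#' Provenance composition of each cluster
#'
#' Per cluster, the fraction of observations contributed by each provenance
#' group (e.g. variant and replica), plus a flag for clusters holding at
#' least `min_total_fraction` of all observations.
#'
#' @param result A `cluster_result` with recorded provenance.
#' @param min_total_fraction Flagging threshold on the cluster's share of all
#'   observations (default 0.1).
#' @return Tibble: `cluster`, provenance columns, `n`, `fraction` (within
#'   cluster), `cluster_fraction` (of all observations), `major`.
#' @export
cluster_composition <- function(result, min_total_fraction = 0.1) {
  if (is.null(result$provenance)) {
    stop_hd("No provenance recorded on this cluster result.",
            "empty_input_error")
  }
  df <- result$provenance |>
    mutate(cluster = result$labels)
  total <- nrow(df)
  df |>
    group_by(.data$cluster, dplyr::across(dplyr::all_of(
      setdiff(names(result$provenance), "cluster")))) |>
    summarise(n = n(), .groups = "drop_last") |>
    mutate(fraction = .data$n / sum(.data$n),
           cluster_fraction = sum(.data$n) / total,
           major = .data$cluster_fraction >= min_total_fraction) |>
    ungroup()
}
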