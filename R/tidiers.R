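#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an interaction network into an edge tibble
#'
#' @param x An `interaction_network`.
#' @param ... Unused.
#' @return Tibble of edges (`i`, `j`, `type`, `occurrence`).
#' @export
tidy.interaction_network <- function(x, ...) {
  out <- as_tibble(x)
  class(out) <- class(tibble())
  out
}

#' One-row summary of an interaction network
#'
#' @param x An `interaction_network`.
#' @param ... Unused.
#' @return Tibble: `n_nodes`, `n_edges`, `mean_occurrence`, `n_frames`.
#' @export
glance.interaction_network <- function(x, ...) {
  tibble(n_nodes = length(attr(x, "nodes")), n_edges = nrow(x),
         mean_occurrence = if (nrow(x)) mean(x$occurrence) else NA_real_,
         n_frames = attr(x, "n_frames"))
}

#' Tidy a cluster result into per-observation rows
#'
#' @param x A `cluster_result`.
#' @param ... Unused.
#' @return Tibble: `observation`, `cluster`, `log_density`, `kstar`, plus
#'   any provenance columns.
#' @export
tidy.cluster_result <- function(x, ...) {
  out <- tibble(observation = seq_along(x$labels), cluster = x$labels,
                log_density = x$log_density, kstar = x$kstar)
  if (!is.null(x$provenance)) out <- dplyr::bind_cols(out, x$provenance)
  out
}

#' One-row summary of a cluster result
#'
#' @param x A `cluster_result`.
#' @param ... Unused.
#' @return Tibble: `n_obs`, `n_clusters`, `n_initial_peaks`,
#'   `intrinsic_dim`, `Z`.
#' @export
glance.cluster_result <- function(x, ...) {
  tibble(n_obs = length(x$labels), n_clusters = length(x$centers),
         n_initial_peaks = x$n_initial, intrinsic_dim = x$intrinsic_dim,
         Z = x$params$Z)
}

#' Tidy an essential subspace
#'
#' @param x An `essential_subspace`.
#' @param ... Unused.
#' @return Tibble: `component`, `eigenvalue`, `variance_fraction`
#'   (cumulative share of total variance).
#' @export
tidy.essential_subspace <- function(x, ...) {
  tibble(component = seq_along(x$eigenvalues), eigenvalue = x$eigenvalues,
         variance_fraction = cumsum(x$eigenvalues) / x$total_variance)
}

#' One-row summary of an essential subspace
#'
#' @param x An `essential_subspace`.
#' @param ... Unused.
#' @return Tibble: `D`, `n_frames`, `total_variance`, `captured_variance`.
#' @export
glance.essential_subspace <- function(x, ...) {
  tibble(D = x$D, n_frames = x$n_frames, total_variance = x$total_variance,
         captured_variance = sum(x$eigenvalues[seq_len(x$D)]) /
           x$total_variance)
}
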