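# Configuration, orchestration and provenance for the end-to-end analysis:
# haplotypes -> scoring, trajectories -> metrics -> networks -> clustering.

#' Default pipeline configuration
#'
#' A single auditable home for the pipeline's fixed constants: the
#' equilibration cut, sampling strides, region definitions and thresholds.
#' Values can be overridden per call or via a YAML document.
#'
#' @return Nested list of defaults.
#' @export
default_config <- function() {
  list(
    inputs = list(vcf = NULL, cds_fasta = NULL, populations = NULL,
                  trajectories = list()),
    equilibration_ns = 960,
    strides = list(metrics_ps = 200, network_ps = 100, pca_ps = 500),
    regions = list(alpha4 = c(107, 131), alpha4_extended = c(106, 133),
                   nls = c(198, 213)),
    numbering_offset = -68,
    thresholds = list(haplotype_min_freq = 0.01, occurrence_cutoff = 0.2,
                      salt_bridge = 4.5, impact = 1),
    clustering = list(Z_alpha4 = 5, Z_other = 3, k_max = 100),
    pca = list(D = 30),
    seed = 1L
  )
}

#' Read a pipeline configuration from YAML
#'
#' Missing fields fall back to [default_config()].
#'
#' @param path YAML file.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  modifyList(default_config(), user)
}

#' Validate a pipeline configuration
#'
#' Checks paths, regions and thresholds, aggregating every problem rather
#' than failing at the first.
#'
#' @param config Configuration list (see [default_config()]).
#' @param n_residues Optional protein length used to bound-check regions.
#' @return Tibble of problems (`field`, `message`); zero rows when valid.
#' @export
validate_config <- function(config, n_residues = NULL) {
  problems <- list()
  note <- function(field, message) {
    problems[[length(problems) + 1L]] <<- tibble(field = field,
                                                 message = message)
  }
  for (nm in c("vcf", "cds_fasta", "populations")) {
    p <- config$inputs[[nm]]
    # in-memory objects (panels, sequences) are allowed in place of paths
    if (is.character(p) && length(p) == 1 && grepl("[/\\\\]|\\.", p) &&
        !file.exists(p) && !grepl("^[ACGTN]+$", p)) {
      note(paste0("inputs.", nm), sprintf("File not found: %s", p))
    }
  }
  for (p in config$inputs$trajectories) {
    if (is.character(p) && !file.exists(p)) {
      note("inputs.trajectories", sprintf("File not found: %s", p))
    }
  }
  th <- config$thresholds
  if (th$haplotype_min_freq < 0 || th$haplotype_min_freq > 1) {
    note("thresholds.haplotype_min_freq", "Must lie in [0, 1].")
  }
  if (th$occurrence_cutoff < 0 || th$occurrence_cutoff > 1) {
    note("thresholds.occurrence_cutoff", "Must lie in [0, 1].")
  }
  if (th$salt_bridge <= 0) note("thresholds.salt_bridge", "Must be positive.")
  if (config$equilibration_ns < 0) {
    note("equilibration_ns", "Must be non-negative.")
  }
  for (rn in names(config$regions)) {
    r <- config$regions[[rn]]
    if (length(r) != 2 || r[1] > r[2]) {
      note(paste0("regions.", rn), "Region must be c(first, last).")
    } else if (!is.null(n_residues)) {
      construct <- r + config$numbering_offset
      if (construct[1] < 1 || construct[2] > n_residues) {
        note(paste0("regions.", rn),
             sprintf("Residues %d-%d do not resolve on a %d-residue construct (offset %d).",
                     r[1], r[2], n_residues, config$numbering_offset))
      }
    }
  }
  if (length(problems) == 0) {
    tibble(field = character(0), message = character(0))
  } else {
    bind_rows(problems)
  }
}

#' Run the analysis pipeline on a configuration
#'
#' Executes the requested stages in dependency order (`haplotypes` before
#' `score`; `trajmetrics`, `network` and `cluster` each need trajectories),
#' writes per-stage outputs under `run_dir`, and records a provenance
#' manifest (`manifest.json`) with inputs, parameters, seeds and output
#' hashes. Identical config + seed reproduces deterministic stages
#' bit-for-bit.
#'
#' @param config Configuration list; `config$inputs` may carry in-memory
#'   objects (a `phased_panel`, `md_trajectory` objects, a CDS string) in
#'   place of file paths.
#' @param stages Character subset of
#'   `c("haplotypes", "score", "trajmetrics", "network", "cluster")`.
#' @param run_dir Output directory (created if needed).
#' @param scorers Ensemble of position scorers for the `score` stage.
#' @param variants Variant table (`pos`, `ref`, `alt`) for translation.
#' @return List of per-stage results (also written to `run_dir`).
#' @export
run_pipeline <- function(config, stages, run_dir = tempfile("haplodyn_run_"),
                         scorers = NULL, variants = NULL) {
  problems <- validate_config(config)
  if (nrow(problems) > 0) {
    stop_hd(paste0("Invalid configuration:\n",
                   paste(problems$field, problems$message, collapse = "\n")),
            "config_error")
  }
  known <- c("haplotypes", "score", "trajmetrics", "network", "cluster")
  stages <- match.arg(stages, known, several.ok = TRUE)
  dir.create(run_dir, showWarnings = FALSE, recursive = TRUE)
  results <- list()

  get_panel <- function() {
    inp <- config$inputs
    if (inherits(inp$vcf, "phased_panel")) return(inp$vcf)
    if (is.null(inp$vcf)) {
      stop_hd("Stage 'haplotypes' needs a phased panel input.",
              "dependency_error")
    }
    pops <- if (!is.null(inp$populations)) {
      utils::read.delim(inp$populations,
                        col.names = c("individual", "population"))
    }
    read_phased_vcf(inp$vcf, pops)
  }
  get_cds <- function() {
    inp <- config$inputs
    if (is.null(inp$cds_fasta)) {
      stop_hd("Stage 'score' needs a CDS input.", "dependency_error")
    }
    if (file.exists(inp$cds_fasta)) {
      as.character(Biostrings::readDNAStringSet(inp$cds_fasta)[[1]])
    } else inp$cds_fasta
  }
  get_trajs <- function(stage) {
    tr <- config$inputs$trajectories
    if (length(tr) == 0) {
      stop_hd(sprintf("Stage '%s' needs trajectory inputs.", stage),
              "dependency_error")
    }
    map(tr, function(t) {
      if (inherits(t, "md_trajectory")) t else
        read_trajectory_pdb(t, numbering_offset = config$numbering_offset)
    })
  }

  if ("haplotypes" %in% stages) {
    panel <- get_panel()
    tab <- enumerate_haplotypes(panel) |>
      filter_common(config$thresholds$haplotype_min_freq)
    utils::write.csv(tab, file.path(run_dir, "haplotypes.csv"),
                     row.names = FALSE)
    results$haplotypes <- tab
  }
  if ("score" %in% stages) {
    if (is.null(results$haplotypes)) {
      stop_hd("Stage 'score' requires stage 'haplotypes' output.",
              "dependency_error")
    }
    if (is.null(scorers) || is.null(variants)) {
      stop_hd("Stage 'score' needs `scorers` and `variants`.",
              "dependency_error")
    }
    cds <- get_cds()
    prot <- haplotype_protein_set(results$haplotypes, cds, variants)
    wt_seq <- prot$protein[prot$is_wildtype][1]
    scores <- bind_rows(map(seq_len(nrow(prot)), function(r) {
      pllr(scorers, wt_seq, prot$protein[r], haplotype = prot$pattern[r])
    }))
    out <- select(dplyr::left_join(prot, scores,
                                   by = c(pattern = "haplotype")),
                  "pattern", "protein_id", "is_wildtype", "pllr")
    utils::write.csv(out, file.path(run_dir, "scores.csv"),
                     row.names = FALSE)
    results$score <- out
  }
  if ("trajmetrics" %in% stages) {
    trajs <- get_trajs("trajmetrics")
    reg <- config$regions$alpha4
    region <- region_selection(reg[1]:reg[2], atoms = NULL)
    metrics <- map(trajs, function(tr) {
      labels <- assign_ss(tr, sampled_frames(tr, config$strides$metrics_ps))
      of <- ordered_fraction(labels, region,
                             numbering_offset = tr$numbering_offset,
                             seed = config$seed)
      of
    })
    out <- bind_rows(metrics, .id = "trajectory")
    utils::write.csv(out, file.path(run_dir, "ordered_fraction.csv"),
                     row.names = FALSE)
    results$trajmetrics <- out
  }
  if ("network" %in% stages) {
    trajs <- get_trajs("network")
    params <- contact_params(
      salt_bridge_cutoff = config$thresholds$salt_bridge,
      occurrence_cutoff = config$thresholds$occurrence_cutoff,
      network_stride_ps = config$strides$network_ps)
    nets <- map(trajs, function(tr) {
      per_type <- map(c("salt-bridge", "hydrogen-bond", "hydrophobic"),
                      ~ occurrence_network(tr, .x, params))
      combine_max(per_type)
    })
    bins <- map(nets, binarize, cutoff = config$thresholds$occurrence_cutoff)
    jac <- outer(seq_along(bins), seq_along(bins),
                 Vectorize(function(a, b) jaccard(bins[[a]], bins[[b]])))
    utils::write.csv(jac, file.path(run_dir, "jaccard.csv"))
    results$network <- list(networks = nets, jaccard = jac)
  }
  if ("cluster" %in% stages) {
    trajs <- get_trajs("cluster")
    reg <- config$regions$alpha4
    feats <- map(trajs, function(tr) {
      dihedral_features(tr, region = reg[1]:reg[2],
                        stride_ps = config$strides$pca_ps)
    })
    X <- do.call(rbind, feats)
    attr(X, "metric") <- "periodic"
    prov <- tibble(trajectory = rep(seq_along(feats),
                                    vapply(feats, nrow, integer(1))))
    cl <- adp_cluster(X, clustering_params(Z = config$clustering$Z_alpha4,
                                           k_max = config$clustering$k_max,
                                           metric = "periodic",
                                           seed = config$seed),
                      provenance = prov)
    utils::write.csv(tibble(observation = seq_along(cl$labels),
                            cluster = cl$labels,
                            trajectory = prov$trajectory),
                     file.path(run_dir, "clusters.csv"), row.names = FALSE)
    results$cluster <- cl
  }

  outputs <- list.files(run_dir, full.names = TRUE)
  outputs <- outputs[basename(outputs) != "manifest.json"]
  manifest <- list(
    package_version = as.character(utils::packageVersion("haplodyn")),
    stages = stages,
    seed = config$seed,
    parameters = config[setdiff(names(config), "inputs")],
    outputs = setNames(as.list(unname(tools::md5sum(outputs))),
                       basename(outputs))
  )
  jsonlite::write_json(manifest, file.path(run_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  results$run_dir <- run_dir
  invisible(results)
}
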