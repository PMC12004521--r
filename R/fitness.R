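# Pseudo-log-likelihood scoring of protein sequences under pluggable
# per-position scorers, and the haplotype score-variability statistic.

#' Construct a toy per-position scorer
#'
#' A deterministic position scorer backed by an explicit per-position table
#' of log-probabilities over a residue alphabet. Each row must exponentiate
#' and sum to 1 (within tolerance). Serves as the testable stand-in for a
#' learned sequence model in the scorer ensemble contract.
#'
#' @param log_table Numeric `length x alphabet_size` matrix of
#'   log-probabilities; column names are the alphabet.
#' @param id Scorer identifier (used in per-model score components).
#' @return A `position_scorer`.
#' @export
gen_toy_scorer <- function(log_table, id = "toy1") {
  log_table <- as.matrix(log_table)
  if (is.null(colnames(log_table))) {
    stop_hd("`log_table` needs column names giving the residue alphabet.",
            "invalid_spec_error")
  }
  sums <- rowSums(exp(log_table))
  # rounded log-probabilities are tolerated, grossly unnormalized rows are not
  if (any(abs(sums - 1) > 0.05)) {
    stop_hd("Each row of exp(log_table) must sum to 1.", "invalid_spec_error")
  }
  structure(list(log_table = log_table, alphabet = colnames(log_table),
                 length = nrow(log_table), id = id),
            class = "position_scorer")
}

#' Uniform toy scorer over an alphabet
#'
#' Every residue equally likely at every position; any substitution then has
#' a pseudo-log-likelihood ratio of exactly zero.
#'
#' @param length Sequence length.
#' @param alphabet Residue alphabet (default the 20 amino acids).
#' @param id Scorer identifier.
#' @return A `position_scorer`.
#' @export
uniform_scorer <- function(length, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY",
                                                       "")[[1]],
                           id = "uniform") {
  tab <- matrix(log(1 / base::length(alphabet)), length, base::length(alphabet),
                dimnames = list(NULL, alphabet))
  gen_toy_scorer(tab, id = id)
}

#' Per-position log-probabilities of the residues in a sequence
#'
#' @param scorer A `position_scorer`.
#' @param seq Protein sequence (character string).
#' @return Numeric vector, one log-probability per position.
#' @export
score_positions <- function(scorer, seq) {
  UseMethod("score_positions")
}

#' @export
score_positions.position_scorer <- function(scorer, seq) {
  chars <- strsplit(seq, "")[[1]]
  if (length(chars) != scorer$length) {
    stop_hd(sprintf("Sequence length %d does not match scorer length %d.",
                    length(chars), scorer$length), "length_error")
  }
  col <- match(chars, scorer$alphabet)
  if (anyNA(col)) {
    bad <- unique(chars[is.na(col)])
    stop_hd(sprintf("Residue(s) outside the scorer alphabet: %s.",
                    paste(bad, collapse = ", ")), "alphabet_error")
  }
  scorer$log_table[cbind(seq_along(chars), col)]
}

#' Pseudo-log-likelihood of a sequence
#'
#' Sum over positions of the scorer's log-probability of the residue present
#' (a single unmasked pass; no conditioning on masked positions).
#'
#' @param scorer A `position_scorer` (or any object with a
#'   [score_positions()] method).
#' @param seq Non-empty protein sequence.
#' @return Scalar log-likelihood.
#' @export
pseudo_log_likelihood <- function(scorer, seq) {
  if (!is.character(seq) || length(seq) != 1 || nchar(seq) == 0) {
    stop_hd("Sequence must be a non-empty character string.",
            "empty_sequence_error")
  }
  sum(score_positions(scorer, seq))
}

#' Pseudo-log-likelihood ratio between a variant and wild-type sequence
#'
#' Per ensemble member, the component is `PLL(alt) - PLL(wt)`; the reported
#' score is the arithmetic mean of the components. Positive scores mean the
#' variant sequence is more plausible (less disruptive) under the models;
#' negative scores flag a potentially harmful impact.
#'
#' @param ensemble A `position_scorer` or list of scorers.
#' @param wt,alt Wild-type and variant protein sequences (same length;
#'   substitution-only haplotypes).
#' @param haplotype Optional haplotype identifier carried into the result.
#' @return A one-row tibble (`fitness_score`): `haplotype`, `pllr`, and a
#'   list-column `components` of per-model log-ratios.
#' @export
pllr <- function(ensemble, wt, alt, haplotype = NA_character_) {
  if (inherits(ensemble, "position_scorer")) ensemble <- list(ensemble)
  if (length(ensemble) == 0) {
    stop_hd("Ensemble must contain at least one scorer.", "empty_input_error")
  }
  if (nchar(wt) != nchar(alt)) {
    stop_hd("Wild-type and variant sequences differ in length; only substitution haplotypes are comparable.",
            "unsupported_comparison_error")
  }
  comp <- vapply(ensemble, function(s) {
    pseudo_log_likelihood(s, alt) - pseudo_log_likelihood(s, wt)
  }, numeric(1))
  names(comp) <- vapply(ensemble, function(s) s$id %||% "scorer", character(1))
  out <- tibble(haplotype = haplotype, pllr = mean(comp),
                components = list(comp))
  class(out) <- c("fitness_score", class(out))
  out
}

#' Score variability of a transcript
#'
#' Maximum pairwise difference (max minus min) over a transcript's
#' haplotype-level scores. By convention the wild-type haplotype scores 0 and
#' is included in the set.
#'
#' @param scores Numeric vector of per-haplotype scores (including the
#'   wild-type 0), or a `fitness_score` tibble with a `pllr` column.
#' @return Non-negative scalar.
#' @export
score_variability <- function(scores) {
  if (is.data.frame(scores)) scores <- scores$pllr
  if (length(scores) == 0) {
    stop_hd("Need at least one score.", "empty_input_error")
  }
  max(scores) - min(scores)
}

#' Cohort-level summary of haplotype scores
#'
#' Aggregates per-haplotype scores over many genes/transcripts into the two
#' screening statistics used for prioritization: the share of haplotypes with
#' `|score| > impact_threshold` and, among transcripts with more than one
#' haplotype, the share whose score variability exceeds the same threshold.
#' Both statistics are reported with and without the wild-type rows, since
#' conventions differ on whether the reference haplotype counts as an
#' observation.
#'
#' @param score_table Tibble with columns `gene`, `transcript`, `haplotype`,
#'   `pllr`, and logical `is_wildtype`.
#' @param impact_threshold Absolute-score threshold (default 1).
#' @return List with `haplotype_scores` (input, unchanged),
#'   `transcript_variability` (per-transcript tibble) and `summary`
#'   (one-row tibble of the share statistics).
#' @export
cohort_score_table <- function(score_table, impact_threshold = 1) {
  if (nrow(score_table) == 0) {
    stop_hd("Empty cohort table.", "empty_input_error")
  }
  variability <- score_table |>
    group_by(.data$gene, .data$transcript) |>
    summarise(n_haplotypes = n(),
              variability = score_variability(.data$pllr), .groups = "drop")
  multi <- filter(variability, .data$n_haplotypes > 1)
  non_wt <- filter(score_table, !.data$is_wildtype)
  summary <- tibble(
    n_haplotypes = nrow(score_table),
    n_transcripts = nrow(variability),
    frac_impact = mean(abs(score_table$pllr) > impact_threshold),
    frac_impact_excl_wt = if (nrow(non_wt) > 0)
      mean(abs(non_wt$pllr) > impact_threshold) else NA_real_,
    frac_variable_transcripts = if (nrow(multi) > 0)
      mean(multi$variability > impact_threshold) else NA_real_
  )
  list(haplotype_scores = score_table,
       transcript_variability = variability,
       summary = summary)
}
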