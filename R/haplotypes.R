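#' Read a phased VCF into a panel of chromosomes
#'
#' Loads phased genotypes (GT with the `|` separator) into a long tibble of
#' per-chromosome alleles. Unphased records are rejected rather than imputed,
#' and multi-allelic sites are decomposed into biallelic records (one row per
#' alternate allele; the pattern string keys on alleles, not variant ids).
#'
#' @param path VCF file (uncompressed or gzipped).
#' @param populations Optional data frame with columns `individual`,
#'   `population` used to attach population labels.
#' @return A `phased_panel`: list with `alleles` (variants x chromosomes
#'   0/1 integer matrix), `variants` (tibble: `id`, `pos`, `ref`, `alt`),
#'   `individuals`, `population` (one label per individual).
#' @export
read_phased_vcf <- function(path, populations = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (any(grepl("/", gt, fixed = TRUE))) {
    stop_hd("Unphased genotypes found (GT with '/'); phase upstream.",
            "unphased_error")
  }
  if (anyNA(gt) || any(gt == ".")) {
    stop_hd("Missing genotypes found; the panel must be complete.",
            "incomplete_panel_error")
  }
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  individuals <- colnames(gt)
  split_gt <- function(row) {
    parts <- strsplit(row, "|", fixed = TRUE)
    matrix(as.integer(unlist(parts)), nrow = 2)
  }
  variants <- list()
  allele_rows <- list()
  for (r in seq_len(nrow(gt))) {
    alts <- strsplit(fix$ALT[r], ",", fixed = TRUE)[[1]]
    calls <- split_gt(gt[r, ])
    for (a in seq_along(alts)) {
      variants[[length(variants) + 1L]] <- tibble(
        id = if (length(alts) == 1) fix$ID[r] else
          paste0(fix$ID[r], "_", alts[a]),
        pos = as.integer(fix$POS[r]), ref = fix$REF[r], alt = alts[a])
      allele_rows[[length(allele_rows) + 1L]] <- as.integer(calls == a)
    }
  }
  alleles <- do.call(rbind, allele_rows)
  # flattening `calls == a` is column-major, so chromosomes already come in
  # (ind1_1, ind1_2, ind2_1, ...) order
  colnames(alleles) <- paste0(rep(individuals, each = 2), c("_1", "_2"))
  pop <- rep(NA_character_, length(individuals))
  if (!is.null(populations)) {
    pop <- populations$population[match(individuals, populations$individual)]
  }
  structure(list(alleles = alleles, variants = bind_rows(variants),
                 individuals = individuals, population = pop),
            class = "phased_panel")
}

#' @export
print.phased_panel <- function(x, ...) {
  cat(sprintf("<phased_panel> %d individuals x %d variant(s)\n",
              length(x$individuals), nrow(x$variants)))
  invisible(x)
}

#' Generate a phased diploid panel from known haplotype frequencies
#'
#' Samples `2 * n_individuals` chromosomes i.i.d. from a categorical
#' distribution over allele patterns. The generating haplotype of each
#' chromosome is kept as ground truth so that downstream enumeration can be
#' validated by exact counting.
#'
#' @param haplotype_defs List of `list(pattern = <0/1 integer vector>,
#'   freq = <target frequency>)`; frequencies must sum to 1 (within 1e-9).
#' @param n_individuals Number of diploid individuals (>= 1).
#' @param seed RNG seed.
#' @param populations Optional character vector of population labels to
#'   assign cyclically to individuals.
#' @return A `phased_panel` with a `ground_truth` attribute (integer vector:
#'   generating haplotype per chromosome).
#' @export
gen_phased_panel <- function(haplotype_defs, n_individuals, seed = 1L,
                             populations = NULL) {
  freqs <- vapply(haplotype_defs, function(h) h$freq, numeric(1))
  if (abs(sum(freqs) - 1) > 1e-9) {
    stop_hd("Haplotype frequencies must sum to 1.", "invalid_spec_error")
  }
  if (n_individuals < 1) stop_hd("Need n_individuals >= 1.",
                                 "invalid_spec_error")
  pats <- map(haplotype_defs, function(h) as.integer(h$pattern))
  nvar <- length(pats[[1]])
  stopifnot(all(vapply(pats, length, integer(1)) == nvar))
  n_chr <- 2L * n_individuals
  with_seed(seed, {
    draw <- sample.int(length(pats), n_chr, replace = TRUE, prob = freqs)
    alleles <- vapply(draw, function(k) pats[[k]], integer(nvar))
    alleles <- matrix(alleles, nrow = nvar)
    individuals <- sprintf("IND%04d", seq_len(n_individuals))
    colnames(alleles) <- paste0(rep(individuals, each = 2), c("_1", "_2"))
    pop <- if (is.null(populations)) rep("ALL", n_individuals) else
      rep(populations, length.out = n_individuals)
    panel <- structure(
      list(alleles = alleles,
           variants = tibble(id = sprintf("var%d", seq_len(nvar)),
                             pos = 3L * seq_len(nvar) - 2L,
                             ref = "A", alt = "C"),
           individuals = individuals, population = pop),
      class = "phased_panel")
    attr(panel, "ground_truth") <- draw
    panel
  })
}

#' Write a phased panel as a VCF file
#'
#' Minimal VCFv4.2 writer with phased GT fields (`|` separator), suitable for
#' round-tripping synthetic panels through [read_phased_vcf()].
#'
#' @param panel A `phased_panel`.
#' @param path Output path.
#' @param chrom Chromosome label.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(panel, path, chrom = "1") {
  n_ind <- length(panel$individuals)
  head_lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$individuals), collapse = "\t"))
  body <- vapply(seq_len(nrow(panel$variants)), function(r) {
    gt <- vapply(seq_len(n_ind), function(i) {
      paste0(panel$alleles[r, 2 * i - 1], "|", panel$alleles[r, 2 * i])
    }, character(1))
    paste(c(chrom, panel$variants$pos[r], panel$variants$id[r],
            panel$variants$ref[r], panel$variants$alt[r], ".", "PASS", ".",
            "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(head_lines, body), path)
  invisible(path)
}

#' Enumerate haplotypes of a phased panel
#'
#' One row per distinct allele pattern observed across all chromosomes, with
#' its global frequency (count over all chromosomes) and per-population
#' frequencies (count over that population's chromosomes). Frequencies sum
#' to 1 globally and within each population.
#'
#' @param panel A `phased_panel`.
#' @param variants Optional subset of variant ids to restrict the pattern to.
#' @return A tibble (`haplotype_table`): `pattern` (string of 0/1 alleles),
#'   `count`, `frequency`, then one `freq_<population>` column per
#'   population, ordered by decreasing global frequency.
#' @export
enumerate_haplotypes <- function(panel, variants = NULL) {
  alleles <- panel$alleles
  if (anyNA(alleles)) {
    stop_hd("Panel has missing alleles.", "incomplete_panel_error")
  }
  if (!is.null(variants)) {
    keep <- panel$variants$id %in% variants
    alleles <- alleles[keep, , drop = FALSE]
  }
  pats <- apply(alleles, 2, paste, collapse = "")
  chr_pop <- rep(panel$population, each = 2)
  tab <- tibble(pattern = pats, population = chr_pop) |>
    count(.data$pattern, name = "count") |>
    mutate(frequency = .data$count / sum(.data$count))
  pops <- unique(chr_pop[!is.na(chr_pop)])
  for (p in pops) {
    sub <- pats[chr_pop == p & !is.na(chr_pop)]
    cnt <- table(factor(sub, levels = tab$pattern))
    tab[[paste0("freq_", p)]] <- as.numeric(cnt) / max(1L, length(sub))
  }
  tab <- arrange(tab, dplyr::desc(.data$count))
  class(tab) <- c("haplotype_table", class(tab))
  tab
}

#' Filter haplotypes by global frequency
#'
#' Keeps rows with global frequency strictly greater than `min_freq`
#' (a row at exactly the threshold is dropped). Row order is preserved.
#'
#' @param table A haplotype table from [enumerate_haplotypes()].
#' @param min_freq Frequency threshold (default 0.01).
#' @return Filtered haplotype table.
#' @export
filter_common <- function(table, min_freq = 0.01) {
  filter(table, .data$frequency > min_freq)
}

#' Apply substitution variants to a coding sequence and translate
#'
#' Substitutes alternate alleles into the reference CDS at the recorded
#' 1-based coding positions, checks reference consistency, and translates
#' with the standard genetic code, truncating at the first stop codon.
#' Insertions/deletions are rejected: haplotypes carrying indels are out of
#' scope and must be set aside upstream.
#'
#' @param cds Reference coding sequence (character string or
#'   [Biostrings::DNAString]); length must be a multiple of 3.
#' @param variants Data frame with columns `pos` (1-based CDS position),
#'   `ref`, `alt` — one row per substitution to apply.
#' @return Amino-acid sequence (character string).
#' @export
apply_variants_to_cds <- function(cds, variants = NULL) {
  cds <- toupper(as.character(cds))
  if (nchar(cds) %% 3 != 0) {
    stop_hd("CDS length must be divisible by 3.", "invalid_cds_error")
  }
  bases <- strsplit(cds, "")[[1]]
  if (!is.null(variants) && nrow(variants) > 0) {
    for (r in seq_len(nrow(variants))) {
      ref <- toupper(variants$ref[r])
      alt <- toupper(variants$alt[r])
      pos <- variants$pos[r]
      if (nchar(ref) != 1 || nchar(alt) != 1) {
        stop_hd(sprintf("Variant at CDS position %d is an indel; only substitutions are supported.",
                        pos), "unsupported_variant_error")
      }
      if (pos < 1 || pos > length(bases)) {
        stop_hd(sprintf("CDS position %d out of bounds.", pos),
                "invalid_variant_error")
      }
      if (bases[pos] != ref) {
        stop_hd(sprintf("Reference mismatch at CDS position %d: CDS has %s, variant says %s.",
                        pos, bases[pos], ref), "reference_mismatch_error")
      }
      bases[pos] <- alt
    }
  }
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(paste(bases, collapse = "")),
    if.fuzzy.codon = "error"))
  sub("\\*.*$", "", aa)
}

#' Protein sequences for every haplotype in a table
#'
#' Translates each haplotype's allele pattern against the reference CDS,
#' deduplicates identical proteins (synonymous haplotypes map to the same
#' entry) and flags haplotypes yielding the reference protein as wild-type.
#'
#' @param table Haplotype table with a `pattern` column.
#' @param cds Reference coding sequence.
#' @param variants Data frame describing the variant sites in pattern order:
#'   columns `pos`, `ref`, `alt` (CDS coordinates).
#' @return Tibble: `pattern`, `protein_id`, `is_wildtype`, `protein`.
#' @export
haplotype_protein_set <- function(table, cds, variants) {
  wt <- apply_variants_to_cds(cds, NULL)
  rows <- map(table$pattern, function(p) {
    bits <- as.integer(strsplit(p, "")[[1]])
    if (length(bits) != nrow(variants)) {
      stop_hd("Pattern length does not match the variant table.",
              "invalid_variant_error")
    }
    prot <- apply_variants_to_cds(cds, variants[bits == 1, , drop = FALSE])
    tibble(pattern = p, protein = prot)
  })
  out <- bind_rows(rows) |>
    mutate(is_wildtype = .data$protein == wt)
  prots <- unique(out$protein)
  ids <- setNames(sprintf("prot%02d", seq_along(prots)), prots)
  ids[wt] <- "WT"
  out |>
    mutate(protein_id = unname(ids[.data$protein])) |>
    select("pattern", "protein_id", "is_wildtype", "protein")
}
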