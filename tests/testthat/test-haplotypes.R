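test_that("hand-written chromosomes enumerate to exact frequencies", {
  panel <- structure(list(
    alleles = matrix(c(0, 0, 0, 1, 0, 1, 1, 1), nrow = 2),
    variants = tibble::tibble(id = c("v1", "v2"), pos = c(1L, 4L),
                              ref = "A", alt = "C"),
    individuals = c("i1", "i2"), population = c("P1", "P2")),
    class = "phased_panel")
  tab <- enumerate_haplotypes(panel)
  freq <- setNames(tab$frequency, tab$pattern)
  expect_equal(freq[["00"]], 0.25)
  expect_equal(freq[["01"]], 0.5)
  expect_equal(freq[["11"]], 0.25)
  expect_equal(sum(tab$frequency), 1)
  # per-population frequencies each sum to 1
  expect_equal(sum(tab$freq_P1), 1)
  expect_equal(sum(tab$freq_P2), 1)
  # missing alleles rejected
  panel$alleles[1, 1] <- NA
  expect_error(enumerate_haplotypes(panel), class = "incomplete_panel_error")
})

test_that("common-haplotype filter uses a strict threshold", {
  tab <- tibble::tibble(
    pattern = sprintf("p%d", 1:6), count = 1:6,
    frequency = c(0.404, 0.423, 0.106, 0.02, 0.028, 0.019))
  expect_equal(nrow(filter_common(tab, 0.01)), 6L)
  tab2 <- tibble::tibble(pattern = "q", count = 1L, frequency = 0.01)
  expect_equal(nrow(filter_common(tab2, 0.01)), 0L)
  expect_equal(nrow(filter_common(tab[0, ])), 0L)
  # ordering preserved
  expect_equal(filter_common(tab, 0.05)$pattern, c("p1", "p2", "p3"))
})

test_that("substitutions translate position-locally with the standard code", {
  # 151-codon CDS, codon 151 = CTG (Leu), preceded by 150 GCT (Ala) codons
  cds <- paste0(strrep("GCT", 150), "CTG")
  wt <- apply_variants_to_cds(cds, NULL)
  expect_equal(nchar(wt), 151L)
  expect_equal(substr(wt, 151, 151), "L")
  # CTG -> CCG: T at CDS position 151*3-1 = 452 becomes C => L151P
  mut <- apply_variants_to_cds(cds, tibble::tibble(pos = 452, ref = "T",
                                                   alt = "C"))
  expect_equal(substr(mut, 151, 151), "P")
  expect_equal(substr(mut, 1, 150), substr(wt, 1, 150))

  expect_error(apply_variants_to_cds(cds, tibble::tibble(pos = 452,
                                                         ref = "G", alt = "C")),
               class = "reference_mismatch_error")
  expect_error(apply_variants_to_cds(cds, tibble::tibble(pos = 452,
                                                         ref = "TG", alt = "C")),
               class = "unsupported_variant_error")
  expect_error(apply_variants_to_cds("GCTA", NULL),
               class = "invalid_cds_error")
  # translation stops at the first stop codon
  expect_equal(apply_variants_to_cds("GCTTAAGCT", NULL), "A")
})

test_that("haplotype protein sets deduplicate synonymous changes", {
  # codon 2 GCT: GCT->GCC synonymous (pos 6 T>C); codon 3 CTG->CCG missense
  cds <- "ATGGCTCTG"
  variants <- tibble::tibble(pos = c(6, 8), ref = c("T", "T"),
                             alt = c("C", "C"))
  tab <- tibble::tibble(pattern = c("00", "10", "01"), count = c(2L, 1L, 1L),
                        frequency = c(0.5, 0.25, 0.25))
  prot <- haplotype_protein_set(tab, cds, variants)
  expect_equal(nrow(prot), 3L)
  expect_true(all(prot$is_wildtype[1:2]))      # synonymous maps to WT protein
  expect_equal(prot$protein_id[1], prot$protein_id[2])
  expect_false(prot$is_wildtype[3])
  expect_equal(prot$protein[3], "MAP")
})

test_that("enumeration on generated panels conserves planted frequencies", {
  defs <- list(list(pattern = c(0, 0, 0), freq = 0.6),
               list(pattern = c(1, 0, 1), freq = 0.3),
               list(pattern = c(0, 1, 0), freq = 0.1))
  panel <- gen_phased_panel(defs, 300, seed = 21,
                            populations = c("A", "B", "C"))
  gt <- attr(panel, "ground_truth")
  tab <- enumerate_haplotypes(panel)
  expect_equal(sum(tab$frequency), 1)
  for (p in c("A", "B", "C")) {
    expect_equal(sum(tab[[paste0("freq_", p)]]), 1)
  }
  # exact counting, not estimation
  for (k in seq_along(defs)) {
    key <- paste(defs[[k]]$pattern, collapse = "")
    cnt <- tab$count[tab$pattern == key]
    if (length(cnt) == 0) cnt <- 0L
    expect_equal(cnt, sum(gt == k))
  }
})

test_that("unphased genotypes are rejected on load", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
    "1\t100\trs1\tA\tC\t.\tPASS\t.\tGT\t0/1"), path)
  expect_error(read_phased_vcf(path), class = "unphased_error")
})

test_that("multi-allelic records decompose into biallelic patterns", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2",
    "1\t100\trs1\tA\tC,G\t.\tPASS\t.\tGT\t0|1\t2|0"), path)
  panel <- read_phased_vcf(path)
  expect_equal(nrow(panel$variants), 2L)
  tab <- enumerate_haplotypes(panel)
  freq <- setNames(tab$frequency, tab$pattern)
  expect_equal(freq[["00"]], 0.5)   # chromosomes S1_1 and S2_2
  expect_equal(freq[["10"]], 0.25)  # C allele
  expect_equal(freq[["01"]], 0.25)  # G allele
})
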