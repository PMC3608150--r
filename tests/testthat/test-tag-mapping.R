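make_index_two_genes <- function() {
  tag_a <- paste0("CATG", strrep("A", 17))
  tag_b <- paste0("CATG", strrep("A", 16), "C") # 1MM from tag_a
  tag_c <- paste0("CATG", strrep("T", 17))
  genes <- toy_genes(c(paste0("GG", tag_a), paste0("GG", tag_b, "TT", tag_c)))
  list(index = build_reference_index(genes),
       tag_a = tag_a, tag_b = tag_b, tag_c = tag_c)
}

test_that("assignment categories follow the stratum rules", {
  fx <- make_index_two_genes()
  counts <- setNames(c(5, 7), c(fx$tag_a, fx$tag_c))
  clean <- lib_from_counts(counts)
  asg <- assign_tags(clean, fx$index)
  a <- asg[asg$tag == fx$tag_a, ]
  # exact hit on g1 wins although g2's tag_b is 1 mismatch away
  expect_equal(a$category, "gene_unambiguous")
  expect_equal(a$gene_id, "g1")
  expect_equal(a$stratum, "exact")
  expect_equal(a$orientation, "sense")
  c_row <- asg[asg$tag == fx$tag_c, ]
  expect_equal(c_row$gene_id, "g2")
})

test_that("a tag matching two genes is ambiguous", {
  shared <- paste0("CATG", strrep("G", 17))
  genes <- toy_genes(c(paste0("AA", shared), paste0("TT", shared)))
  idx <- build_reference_index(genes)
  clean <- lib_from_counts(setNames(4, shared))
  asg <- assign_tags(clean, idx)
  expect_equal(asg$category, "gene_ambiguous")
  expect_true(is.na(asg$gene_id))
  expect_equal(sort(attr(asg, "ambiguous_genes")[[1]]), c("g1", "g2"))
})

test_that("1MM assignment agrees with exhaustive variant scan", {
  fx <- make_index_two_genes()
  probe <- paste0("CATG", strrep("A", 16), "G") # 1MM from tag_a AND tag_b
  clean <- lib_from_counts(setNames(3, probe))
  asg <- assign_tags(clean, fx$index)
  want <- brute_gene_hits(probe, fx$index$tags)
  expect_equal(asg$stratum, want$stratum)
  expect_equal(asg$category, "gene_ambiguous")
  expect_equal(sort(attr(asg, "ambiguous_genes")[[1]]),
               sort(unique(want$hits$gene_id)))
})

test_that("genome-only and unknown categories resolve correctly", {
  gene_seq <- paste0("CATG", strrep("A", 17))
  intergenic <- paste0("CATG", strrep("C", 17))
  genome <- c(chr1 = paste0(gene_seq, "TTTT", intergenic))
  idx <- build_reference_index(toy_genes(gene_seq), genome = genome)
  nowhere <- paste0("CATG", strrep("GT", 8), "G")
  clean <- lib_from_counts(setNames(c(2, 3), c(intergenic, nowhere)))
  asg <- assign_tags(clean, idx)
  expect_equal(asg$category[asg$tag == intergenic], "genome_only")
  expect_equal(asg$category[asg$tag == nowhere], "unknown")
  expect_equal(asg$stratum[asg$tag == nowhere], "none")
})

test_that("library summary partition identities hold on simulated data", {
  cfg <- sim_config(n_genes = 80, depth = 30000, seed = 5,
                    error_rate = 0.01, n_rate = 0.005, adaptor_rate = 0.01)
  ref <- simulate_reference(cfg)
  truth <- simulate_expression(cfg, ref)
  idx <- index_from_reference(ref)
  for (lib in c("Br", "F1")) {
    reads <- simulate_library_reads(ref, truth, lib, cfg)
    res <- process_library(reads, lib, idx, adaptors = cfg$adaptor)
    s <- res$summary
    expect_equal(s$gene_total + s$genome_total + s$unknown_total, s$clean_total)
    expect_equal(s$gene_distinct + s$genome_distinct + s$unknown_distinct,
                 s$clean_distinct)
    expect_lte(s$unambiguous_total, s$gene_total)
    expect_lte(s$unambiguous_distinct, s$gene_distinct)
    expect_lte(s$unambiguous_tag_mapped_genes, s$tag_mapped_genes)
    expect_lte(s$both_strand_genes, s$unambiguous_tag_mapped_genes)
  }
})

test_that("empty library summarizes to zeros", {
  idx <- build_reference_index(toy_genes(paste0("CATG", strrep("A", 17))))
  clean <- tag_library(setNames(numeric(0), character(0)), "empty", "clean")
  asg <- assign_tags(clean, idx)
  s <- summarize_library(asg, clean)
  expect_equal(s$clean_total, 0)
  expect_equal(s$gene_total + s$genome_total + s$unknown_total, 0)
  expect_equal(s$tag_mapped_genes, 0L)
})

test_that("summarize_library rejects mismatched inputs", {
  fx <- make_index_two_genes()
  clean1 <- lib_from_counts(setNames(5, fx$tag_a))
  clean2 <- lib_from_counts(setNames(5, fx$tag_c))
  asg <- assign_tags(clean1, fx$index)
  expect_error(summarize_library(asg, clean2), "cover")
})

test_that("TPM follows the clean-total invariant and gene absence means zero", {
  fx <- make_index_two_genes()
  clean <- lib_from_counts(setNames(50, fx$tag_a))
  asg <- assign_tags(clean, fx$index)
  prof <- compute_profile(asg, 2e6, "L")
  expect_equal(prof$sense_tpm[prof$gene_id == "g1"], 25)
  expect_false("g2" %in% prof$gene_id)
  expect_error(compute_profile(asg, 0, "L"), "positive")
})

test_that("total TPM is bounded by 1e6 with equality iff fully unambiguous", {
  cfg <- sim_config(n_genes = 50, depth = 20000, seed = 9, error_rate = 0,
                    n_rate = 0, adaptor_rate = 0, shared_tag_fraction = 0)
  ref <- simulate_reference(cfg)
  truth <- simulate_expression(cfg, ref)
  idx <- index_from_reference(ref)
  reads <- simulate_library_reads(ref, truth, "Br", cfg)
  res <- process_library(reads, "Br", idx)
  tot_tpm <- sum(res$profile$sense_tpm) + sum(res$profile$antisense_tpm)
  expect_lte(tot_tpm, 1e6 + 1e-6)
  all_unamb <- res$summary$unambiguous_total == res$summary$clean_total
  expect_equal(isTRUE(all.equal(tot_tpm, 1e6)), all_unamb)
})

test_that("profiles are invariant to input tag order", {
  fx <- make_index_two_genes()
  counts <- setNames(c(5, 7), c(fx$tag_a, fx$tag_c))
  p1 <- compute_profile(assign_tags(lib_from_counts(counts), fx$index), 1e4, "L")
  p2 <- compute_profile(assign_tags(lib_from_counts(rev(counts)), fx$index), 1e4, "L")
  expect_equal(p1, p2, ignore_attr = TRUE)
})

test_that("estimated TPM tracks truth on error-free simulation", {
  cfg <- sim_config(n_genes = 150, depth = 1e5, seed = 31, error_rate = 0,
                    n_rate = 0, adaptor_rate = 0)
  ref <- simulate_reference(cfg)
  truth <- simulate_expression(cfg, ref)
  idx <- index_from_reference(ref)
  reads <- simulate_library_reads(ref, truth, "Bo", cfg)
  res <- process_library(reads, "Bo", idx)
  m <- match(res$profile$gene_id, truth$gene_id)
  rho <- cor(res$profile$sense_tpm, truth$abund_Bo[m], method = "spearman")
  expect_gte(rho, 0.9)
})
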