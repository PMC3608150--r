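test_that("single-site transcript yields exactly one sense tag", {
  s <- paste0("AAA", "CATG", strrep("A", 17))
  idx <- build_reference_index(toy_genes(s))
  sense <- idx$tags[idx$tags$orientation == "sense", ]
  expect_equal(nrow(sense), 1L)
  expect_equal(sense$tag, paste0("CATG", strrep("A", 17)))
  expect_equal(sense$site_rank, 1L)
  # reverse complement has a CATG iff the brute-force scan finds one
  expect_equal(sum(idx$tags$orientation == "antisense"),
               length(scan_tags(rc(s))))
})

test_that("tag enumeration matches brute-force offset scan on tandem CATG repeats", {
  s <- strrep("CATG", 6) # 24 nt; only offset 1 leaves 17 nt after the anchor
  idx <- build_reference_index(toy_genes(s))
  sense <- idx$tags[idx$tags$orientation == "sense", ]
  expect_equal(sort(sense$tag), sort(scan_tags(s)))
  anti <- idx$tags[idx$tags$orientation == "antisense", ]
  expect_equal(sort(anti$tag), sort(scan_tags(rc(s))))
})

test_that("site_rank orders sites 3' to 5'", {
  # two sites: CATG at 1 and at 30
  s <- paste0("CATG", strrep("A", 25), "CATG", strrep("C", 17))
  idx <- build_reference_index(toy_genes(s))
  sense <- idx$tags[idx$tags$orientation == "sense", ]
  expect_equal(nrow(sense), 2L)
  # the 3'-most site (offset 30) must have rank 1
  expect_equal(sense$site_rank[sense$tag == paste0("CATG", strrep("C", 17))], 1L)
  expect_equal(sense$site_rank[sense$tag == paste0("CATG", strrep("A", 17))], 2L)
})

test_that("two genes sharing a 21-mer both appear under that tag key", {
  shared <- paste0("CATG", strrep("G", 17))
  g1 <- paste0(rand_dna(30, seed = 11), shared)
  g2 <- paste0(shared, rand_dna(30))
  idx <- build_reference_index(toy_genes(c(g1, g2)))
  hit <- query_tag(shared, idx)
  expect_equal(hit$stratum, "exact")
  expect_equal(sort(unique(hit$gene_hits$gene_id)), c("g1", "g2"))
})

test_that("genes without CATG sites are reported, not an error", {
  no_catg <- gsub("CATG", "AATG", rand_dna(200, seed = 3), fixed = TRUE)
  no_catg <- gsub("CATG", "AATG", no_catg, fixed = TRUE) # rc-created sites too
  genes <- toy_genes(c(no_catg, paste0("TT", "CATG", strrep("A", 17))))
  # keep only genes where neither strand has a usable site for gene 1
  if (length(scan_tags(no_catg)) + length(scan_tags(rc(no_catg))) == 0) {
    idx <- build_reference_index(genes)
    expect_true("g1" %in% idx$genes_without_tags)
    expect_false("g2" %in% idx$genes_without_tags)
  }
  short <- toy_genes("CATGAA", ids = "tiny")
  idx2 <- build_reference_index(short)
  expect_equal(idx2$genes_without_tags, "tiny")
  expect_equal(nrow(idx2$tags), 0L)
})

test_that("query_tag agrees with exhaustive Hamming scan on random toy genomes", {
  set.seed(101)
  for (rep in 1:5) {
    seqs <- replicate(6, paste0(rand_dna(40), "CATG", rand_dna(40)))
    idx <- build_reference_index(toy_genes(seqs))
    probes <- c(
      sample(idx$tags$tag, min(4, nrow(idx$tags))),
      replicate(4, rand_tag()),
      # distance-1 perturbations of real tags
      vapply(sample(idx$tags$tag, 3), function(t) {
        p <- sample(21, 1)
        substr(t, p, p) <- sample(setdiff(BASES, substr(t, p, p)), 1)
        t
      }, character(1))
    )
    for (tag in probes) {
      got <- query_tag(tag, idx)
      want <- brute_gene_hits(tag, idx$tags)
      if (nrow(want$hits) > 0) {
        expect_equal(got$stratum, want$stratum)
        expect_equal(sort(unique(got$gene_hits$gene_id)),
                     sort(unique(want$hits$gene_id)))
      } else {
        expect_equal(nrow(got$gene_hits), 0L)
      }
    }
  }
})

test_that("exact gene hits pre-empt 1MM hits of other genes", {
  tag_a <- paste0("CATG", strrep("A", 17))
  tag_b <- paste0("CATG", strrep("A", 16), "C") # Hamming 1 from tag_a
  genes <- toy_genes(c(paste0("GG", tag_a), paste0("GG", tag_b)))
  idx <- build_reference_index(genes)
  got <- query_tag(tag_a, idx)
  expect_equal(got$stratum, "exact")
  expect_equal(unique(got$gene_hits$gene_id), "g1")
})

test_that("tags with N never match", {
  idx <- build_reference_index(toy_genes(paste0("CATG", strrep("A", 30))))
  got <- query_tag(paste0("CATG", strrep("A", 16), "N"), idx)
  expect_equal(got$stratum, "none")
  expect_equal(nrow(got$gene_hits), 0L)
  expect_false(got$genome_hit)
})

test_that("genome-only tags are found at the right stratum", {
  gene_seq <- paste0("CATG", strrep("A", 17))
  intergenic <- paste0("CATG", strrep("C", 17))
  genome <- c(chr1 = paste0(gene_seq, "TTTT", intergenic))
  idx <- build_reference_index(toy_genes(gene_seq), genome = genome)
  got <- query_tag(intergenic, idx)
  expect_equal(nrow(got$gene_hits), 0L)
  expect_true(got$genome_hit)
  expect_equal(got$stratum, "exact")
  # 1 mismatch from the intergenic tag only
  probe <- paste0("CATG", strrep("C", 16), "G")
  got2 <- query_tag(probe, idx)
  expect_true(got2$genome_hit)
  expect_equal(got2$stratum, "1MM")
})

test_that("index is deterministic and order-invariant", {
  seqs <- replicate(5, paste0(rand_dna(30), "CATG", rand_dna(30)))
  g <- toy_genes(seqs)
  i1 <- build_reference_index(g)
  i2 <- build_reference_index(g[sample(nrow(g)), ])
  expect_identical(i1$tags, i2$tags)
})

test_that("sense tags of genome-substring transcripts are in the genome tag set", {
  set.seed(42)
  transcript <- paste0(rand_dna(50), "CATG", rand_dna(50))
  genome <- c(chr1 = paste0(rand_dna(80), transcript, rand_dna(80)))
  idx <- build_reference_index(toy_genes(transcript), genome = genome)
  sense <- idx$tags$tag[idx$tags$orientation == "sense"]
  for (t in sense) expect_true(query_tag(t, idx)$genome_hit)
})

test_that("virtual tag database round-trips through TSV", {
  idx <- build_reference_index(toy_genes(paste0("AA", "CATG", rand_dna(40, seed = 9))))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_virtual_tags(idx, path)
  back <- read.delim(path, stringsAsFactors = FALSE)
  expect_equal(back, idx$tags)
})
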