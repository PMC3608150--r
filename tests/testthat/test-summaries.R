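test_that("abundance distribution matches hand binning", {
  lib <- lib_from_counts(setNames(c(3, 4, 150), c(rand_tag(), rand_tag(), rand_tag())))
  d <- abundance_distribution(lib)
  expect_equal(d$distinct[d$bin == "[2,5]"], 2)
  expect_equal(d$total[d$bin == "[2,5]"], 7)
  expect_equal(d$distinct[d$bin == ">100"], 1)
  expect_equal(d$total[d$bin == ">100"], 150)
  expect_equal(sum(d$distinct), lib$distinct)
  expect_equal(sum(d$total), lib$total)
  expect_equal(sum(d$distinct_pct), 100, tolerance = 1e-9)
  expect_equal(sum(d$total_pct), 100, tolerance = 1e-9)
  expect_error(abundance_distribution(lib, bin_lower = c(2, 2, 5)), "increasing")
})

test_that("empty library bins to zeros", {
  lib <- tag_library(setNames(numeric(0), character(0)), "e", "clean")
  d <- abundance_distribution(lib)
  expect_true(all(d$distinct == 0))
  expect_true(all(d$total == 0))
})

test_that("saturation curve is monotone and ends at full gene detection", {
  cfg <- sim_config(n_genes = 60, depth = 20000, seed = 19, error_rate = 0,
                    n_rate = 0, adaptor_rate = 0)
  ref <- simulate_reference(cfg)
  truth <- simulate_expression(cfg, ref)
  idx <- index_from_reference(ref)
  res <- process_library(simulate_library_reads(ref, truth, "F1", cfg), "F1", idx)
  curve <- saturation_curve(res$clean, res$assignments, step = 2000, seed = 4)
  expect_true(all(diff(curve$genes_detected) >= 0))
  expect_equal(curve$genes_detected[nrow(curve)],
               res$summary$unambiguous_tag_mapped_genes)
  expect_error(saturation_curve(res$clean, res$assignments, step = 0), "positive")
})

test_that("saturation detection probability matches enumeration on a two-gene toy", {
  # library: tag1 (gene A) x 3 copies, tag2 (gene B) x 1 copy
  tag_a <- paste0("CATG", strrep("A", 17))
  tag_b <- paste0("CATG", strrep("C", 17))
  idx <- build_reference_index(toy_genes(c(paste0("GG", tag_a), paste0("GG", tag_b))))
  clean <- lib_from_counts(setNames(c(3, 2), c(tag_a, tag_b)))
  asg <- assign_tags(clean, idx)
  # at depth 1 the expected detected-gene count is exactly 1 (one draw, one gene)
  hits <- vapply(1:500, function(s) {
    saturation_curve(clean, asg, step = 1, seed = s)$genes_detected[1]
  }, numeric(1))
  expect_true(all(hits == 1))
  # at depth 2: P(two distinct genes) = 1 - P(both from A) - P(both from B)
  #            = 1 - C(3,2)/C(5,2) - C(2,2)/C(5,2) = 1 - 4/10
  both <- vapply(1:1000, function(s) {
    saturation_curve(clean, asg, step = 2, seed = s)$genes_detected[1]
  }, numeric(1))
  expect_lt(abs(mean(both == 2) - 0.6), 0.05)
})

test_that("ratio distribution matches hand computation", {
  t1 <- rand_tag(); t2 <- rand_tag(); t3 <- rand_tag(); t4 <- rand_tag()
  a <- lib_from_counts(setNames(c(10, 10, 10), c(t1, t2, t3)), "A")
  b <- lib_from_counts(setNames(c(12, 55, 33), c(t1, t2, t4)), "B")
  rd <- ratio_distribution(a, b, normalized = FALSE)
  expect_equal(rd$n_shared, 2)
  expect_equal(rd$n_a_only, 1)
  expect_equal(rd$n_b_only, 1)
  expect_equal(rd$bins$count[rd$bins$bin == "[1,2)"], 1) # 10 vs 12
  expect_equal(rd$bins$count[rd$bins$bin == ">5"], 1)    # 10 vs 55
  expect_equal(sum(rd$bins$fraction), 1)
})

test_that("identical libraries put all shared tags in [1,2)", {
  counts <- setNames(c(5, 9, 40), c(rand_tag(), rand_tag(), rand_tag()))
  a <- lib_from_counts(counts, "A")
  b <- lib_from_counts(counts, "B")
  rd <- ratio_distribution(a, b)
  expect_equal(rd$bins$fraction[rd$bins$bin == "[1,2)"], 1)
})

test_that("normalization flag changes ratios when totals differ", {
  t1 <- rand_tag()
  a <- lib_from_counts(setNames(c(10, 90), c(t1, rand_tag())), "A")  # total 100
  b <- lib_from_counts(setNames(c(30, 270), c(t1, rand_tag())), "B") # total 300
  raw <- ratio_distribution(a, b, normalized = FALSE)
  nrm <- ratio_distribution(a, b, normalized = TRUE)
  expect_equal(raw$bins$count[raw$bins$bin == "[3,4)"], 1)
  expect_equal(nrm$bins$count[nrm$bins$bin == "[1,2)"], 1)
})

test_that("overlap partition counts sum to the union", {
  o <- expression_overlaps(list(A = c("g1", "g2"), B = c("g2", "g3")))
  expect_equal(o$count[o$A & !o$B], 1)
  expect_equal(o$count[!o$A & o$B], 1)
  expect_equal(o$count[o$A & o$B], 1)
  disjoint <- expression_overlaps(list(A = "g1", B = "g2"))
  expect_equal(disjoint$count[disjoint$A & disjoint$B], 0)
  set.seed(13)
  sets <- lapply(1:4, function(i) sample(sprintf("g%02d", 1:40), 20))
  names(sets) <- LETTERS[1:4]
  o4 <- expression_overlaps(sets)
  expect_equal(nrow(o4), 15)
  expect_equal(sum(o4$count), length(unique(unlist(sets))))
  expect_error(expression_overlaps(c(sets, list(E = "g1"))), "4 sets")
})

test_that("clustering merges identical rows first and matches brute-force on 1-D toy", {
  m <- rbind(a = c(1, 1), b = c(1, 1), c = c(5, 5), d = c(9, 9))
  ct <- cluster_degs(m, n_clusters = 2)
  expect_equal(ct$hclust$height[1], 0) # identical rows merge at height 0
  expect_equal(unname(ct$clusters["a"]), unname(ct$clusters["b"]))
  # brute-force average-linkage agglomeration on a 1-D toy
  x <- c(0, 1, 5, 20)
  mm <- cbind(x)
  rownames(mm) <- letters[1:4]
  ct2 <- cluster_degs(mm, n_clusters = 2)
  # manual: merge {0,1} at 1; then {5} joins at avg(5, 4)=4.5; {20} last
  expect_equal(sort(ct2$hclust$height), c(1, 4.5, mean(c(20, 19, 15))))
  expect_equal(unname(ct2$clusters[c("a", "b", "c")]), rep(1, 3))
  expect_equal(unname(ct2$clusters["d"]), 2)
})

test_that("cluster partition is invariant to gene order", {
  set.seed(17)
  m <- matrix(rnorm(60 * 4), nrow = 60,
              dimnames = list(sprintf("g%02d", 1:60), NULL))
  ct <- cluster_degs(m, n_clusters = 5)
  perm <- sample(60)
  ct2 <- cluster_degs(m[perm, ], n_clusters = 5)
  # same partition up to label names
  expect_equal(length(unique(paste(ct$clusters[rownames(m)],
                                   ct2$clusters[rownames(m)]))), 5L)
  expect_error(cluster_degs(m[0, , drop = FALSE]), "non-empty")
})

test_that("planted two-regime DEG structure is recovered by clustering", {
  set.seed(23)
  # regime 1: up in F1 vs parents, down in F2-F4 vs F1; regime 2: opposite
  n1 <- 40; n2 <- 40
  center1 <- c(2, 2, -2, -2, -2, 2)
  center2 <- c(-2, -2, 2, 2, 2, -2)
  m <- rbind(
    matrix(rep(center1, each = n1), nrow = n1) + rnorm(n1 * 6, 0, 0.4),
    matrix(rep(center2, each = n2), nrow = n2) + rnorm(n2 * 6, 0, 0.4)
  )
  rownames(m) <- sprintf("g%02d", 1:(n1 + n2))
  ct <- cluster_degs(m, n_clusters = 2)
  truth_lab <- rep(1:2, c(n1, n2))
  tab <- table(ct$clusters, truth_lab)
  agreement <- sum(apply(tab, 1, max)) / (n1 + n2)
  expect_gte(agreement, 0.95)
})

test_that("hypergeometric enrichment matches support enumeration", {
  # N=10, K=4, n=5, k=3: enumerate the support by combinatorics
  enum_p <- sum(vapply(3:4, function(i)
    choose(4, i) * choose(6, 5 - i) / choose(10, 5), numeric(1)))
  bg <- sprintf("g%02d", 1:10)
  fg <- bg[1:5]
  ann <- data.frame(gene_id = c(bg[c(1, 2, 3, 6)]), term = "T1")
  res <- term_enrichment(fg, bg, ann)
  expect_equal(res$p_value, enum_p, tolerance = 1e-12)
  expect_equal(res$k, 3)
  expect_equal(res$K, 4)
})

test_that("degenerate enrichment cases give p = 1", {
  bg <- sprintf("g%02d", 1:10)
  ann_all <- data.frame(gene_id = bg, term = "ALL")
  res <- term_enrichment(bg[1:4], bg, ann_all)
  expect_equal(res$p_value, 1)
  res2 <- term_enrichment(bg, bg, data.frame(gene_id = bg[1:3], term = "T"))
  expect_equal(res2$p_value, 1)
  expect_equal(res2$k, res2$K)
  expect_error(term_enrichment(c(bg, "zz"), bg, ann_all), "subset")
})
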