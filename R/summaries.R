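#' Tag abundance distribution of a clean library
#'
#' Bins distinct tags by copy number and reports, per bin, the number of
#' distinct tags and the total copies they carry, with percentages of the
#' library's distinct and total counts. Default bins follow the standard DGE
#' report: [2,5], [6,10], [11,20], [21,50], [51,100], >100 (clean libraries
#' contain no singletons).
#'
#' @param lib a clean-stage `TagLibrary`.
#' @param bin_lower strictly increasing integer lower bin edges; each bin
#'   runs to the next edge minus one, the last to infinity.
#' @return an `AbundanceDistribution` data.frame: bin, distinct,
#'   distinct_pct, total, total_pct.
#' @export
abundance_distribution <- function(lib, bin_lower = c(2, 6, 11, 21, 51, 101)) {
  stopifnot(inherits(lib, "TagLibrary"))
  if (any(diff(bin_lower) <= 0)) stop("bin edges must be strictly increasing")
  upper <- c(bin_lower[-1] - 1, Inf)
  fin <- is.finite(upper)
  labels <- character(length(bin_lower))
  labels[fin] <- sprintf("[%d,%d]", bin_lower[fin], as.integer(upper[fin]))
  labels[!fin] <- sprintf(">%d", bin_lower[!fin] - 1L)
  counts <- lib$counts
  distinct <- numeric(length(bin_lower))
  total <- numeric(length(bin_lower))
  for (i in seq_along(bin_lower)) {
    sel <- counts >= bin_lower[i] & counts <= upper[i]
    distinct[i] <- sum(sel)
    total[i] <- sum(counts[sel])
  }
  out <- data.frame(
    bin = labels, distinct = distinct,
    distinct_pct = if (lib$distinct > 0) 100 * distinct / lib$distinct else 0,
    total = total,
    total_pct = if (lib$total > 0) 100 * total / lib$total else 0
  )
  class(out) <- c("AbundanceDistribution", "data.frame")
  out
}

#' Sequencing saturation curve
#'
#' Subsamples the library's tag copies without replacement at increasing
#' depths and counts the unambiguously tag-mapped genes detected at each
#' depth, to judge whether sequencing depth suffices for transcriptome
#' coverage. The curve is non-decreasing and ends at the library's full
#' unambiguous gene count.
#'
#' @param lib a clean `TagLibrary`.
#' @param assignments the library's `TagAssignment` (supplies the tag-to-gene
#'   map; only unambiguous genes count as detected).
#' @param step depth increment (> 0); depths are `step, 2*step, ...` up to
#'   the library total.
#' @param seed integer seed for the subsampling permutation.
#' @return a `SaturationCurve` data.frame: depth, genes_detected.
#' @export
saturation_curve <- function(lib, assignments, step, seed = 1L) {
  stopifnot(inherits(lib, "TagLibrary"), inherits(assignments, "TagAssignment"))
  if (step <= 0) stop("step must be positive")
  m <- match(names(lib$counts), assignments$tag)
  if (anyNA(m)) stop("assignments do not cover the library's tags")
  gene_of_tag <- ifelse(assignments$category[m] == "gene_unambiguous",
                        assignments$gene_id[m], NA_character_)
  copies <- rep(gene_of_tag, lib$counts)
  set.seed(seed)
  perm <- sample(copies, length(copies))
  first_seen <- which(!duplicated(perm) & !is.na(perm))
  depths <- unique(c(seq(step, lib$total, by = step), lib$total))
  out <- data.frame(depth = depths,
                    genes_detected = vapply(depths, function(d)
                      sum(first_seen <= d), numeric(1)))
  attr(out, "seed") <- seed
  class(out) <- c("SaturationCurve", "data.frame")
  out
}

#' Fold-change ratio distribution between two libraries
#'
#' For distinct tags present in both libraries, the ratio of (by default
#' per-million normalized) copy numbers, folded to >= 1, is binned as
#' [1,2), [2,3), [3,4), [4,5], (5,Inf). Tags present in only one library are
#' counted as library-specific and excluded from the shared-fraction
#' denominator.
#'
#' @param lib_a,lib_b clean `TagLibrary` objects.
#' @param normalized scale counts to per-million before forming ratios
#'   (default `TRUE`).
#' @return a `RatioDistribution` list: `bins` (data.frame: bin, count,
#'   fraction over shared tags), `n_shared`, `n_a_only`, `n_b_only`.
#' @export
ratio_distribution <- function(lib_a, lib_b, normalized = TRUE) {
  stopifnot(inherits(lib_a, "TagLibrary"), inherits(lib_b, "TagLibrary"))
  tags_a <- names(lib_a$counts)
  tags_b <- names(lib_b$counts)
  shared <- intersect(tags_a, tags_b)
  ca <- lib_a$counts[shared]
  cb <- lib_b$counts[shared]
  if (normalized) {
    ca <- 1e6 * ca / lib_a$total
    cb <- 1e6 * cb / lib_b$total
  }
  ratio <- pmax(ca, cb) / pmin(ca, cb)
  labels <- c("[1,2)", "[2,3)", "[3,4)", "[4,5]", ">5")
  count <- c(sum(ratio >= 1 & ratio < 2), sum(ratio >= 2 & ratio < 3),
             sum(ratio >= 3 & ratio < 4), sum(ratio >= 4 & ratio <= 5),
             sum(ratio > 5))
  bins <- data.frame(bin = labels, count = count,
                     fraction = if (length(shared)) count / length(shared)
                                else rep(0, 5L))
  structure(
    list(bins = bins, n_shared = length(shared),
         n_a_only = length(setdiff(tags_a, shared)),
         n_b_only = length(setdiff(tags_b, shared))),
    class = "RatioDistribution"
  )
}

#' Venn partition of 2-4 gene sets
#'
#' Counts the genes in every intersection region of up to four named sets
#' (commonly vs specifically expressed genes across libraries).
#'
#' @param gene_sets named list of 2-4 character vectors.
#' @return an `OverlapSets` data.frame: one row per non-empty-by-construction
#'   region, with a logical membership column per set and `count`; region
#'   counts sum to the union size.
#' @export
expression_overlaps <- function(gene_sets) {
  if (!is.list(gene_sets) || is.null(names(gene_sets)) ||
      any(!nzchar(names(gene_sets)))) {
    stop("gene_sets must be a named list")
  }
  k <- length(gene_sets)
  if (k < 2L || k > 4L) {
    stop("between 2 and 4 sets supported; run larger designs pairwise")
  }
  universe <- unique(unlist(gene_sets, use.names = FALSE))
  member <- vapply(gene_sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L,
                                               dimnames = list(NULL, names(gene_sets)))
  patterns <- expand.grid(rep(list(c(TRUE, FALSE)), k))
  names(patterns) <- names(gene_sets)
  patterns <- patterns[rowSums(patterns) > 0L, , drop = FALSE]
  count <- apply(patterns, 1L, function(p) {
    if (length(universe) == 0L) return(0L)
    sum(apply(member, 1L, function(row) all(row == p)))
  })
  out <- cbind(patterns, count = as.integer(count))
  rownames(out) <- NULL
  class(out) <- c("OverlapSets", "data.frame")
  out
}

#' Hierarchical clustering of differentially expressed genes
#'
#' Agglomerative clustering of a gene-by-comparison log2-ratio matrix
#' (Euclidean distance, average linkage by default, as in HCE-era analyses),
#' cut into flat clusters. Cells untested in a comparison should be imputed
#' as 0 by the caller (no evidence of change).
#'
#' @param log2_matrix numeric matrix, rows = genes (rownames = gene ids),
#'   columns = comparisons.
#' @param linkage linkage method for [stats::hclust()] (default
#'   `"average"`).
#' @param n_clusters number of flat clusters (default 12).
#' @return a `ClusterTree` list: `hclust` (the fitted tree), `clusters`
#'   (named integer vector of flat labels), `centers` (cluster-by-comparison
#'   mean log2-ratio matrix).
#' @export
cluster_degs <- function(log2_matrix, linkage = "average", n_clusters = 12L) {
  if (!is.matrix(log2_matrix) || nrow(log2_matrix) == 0L) {
    stop("log2_matrix must be a non-empty numeric matrix")
  }
  if (n_clusters < 1L || n_clusters > nrow(log2_matrix)) {
    stop("n_clusters must be between 1 and the number of genes")
  }
  hc <- hclust(dist(log2_matrix, method = "euclidean"), method = linkage)
  clusters <- cutree(hc, k = n_clusters)
  centers <- do.call(rbind, lapply(sort(unique(clusters)), function(cl) {
    colMeans(log2_matrix[clusters == cl, , drop = FALSE])
  }))
  rownames(centers) <- sort(unique(clusters))
  structure(list(hclust = hc, clusters = clusters, centers = centers),
            class = "ClusterTree")
}

#' @export
print.ClusterTree <- function(x, ...) {
  cat(sprintf("ClusterTree: %d genes in %d flat clusters\n",
              length(x$clusters), nrow(x$centers)))
  print(table(x$clusters))
  invisible(x)
}

#' Hypergeometric term enrichment
#'
#' Tests each annotation term represented in the foreground for
#' over-representation relative to the background universe, using the
#' hypergeometric upper tail, with Benjamini-Hochberg adjustment across the
#' tested terms.
#'
#' @param foreground character vector of genes of interest (must be a subset
#'   of `background`).
#' @param background character vector: the gene universe.
#' @param gene_to_terms data.frame with columns `gene_id` and `term`.
#' @param q_threshold significance cutoff on the adjusted value (default
#'   0.05).
#' @return an `EnrichmentRecord` data.frame: term, k, K, n, N, p_value,
#'   q_value, significant; one row per term with at least one foreground
#'   gene, ordered by p-value.
#' @export
term_enrichment <- function(foreground, background, gene_to_terms,
                            q_threshold = 0.05) {
  foreground <- unique(foreground)
  background <- unique(background)
  if (!all(foreground %in% background)) {
    stop("foreground must be a subset of background")
  }
  stopifnot(all(c("gene_id", "term") %in% names(gene_to_terms)))
  ann <- gene_to_terms[gene_to_terms$gene_id %in% background, , drop = FALSE]
  ann <- ann[!duplicated(ann[c("gene_id", "term")]), , drop = FALSE]
  N <- length(background)
  n <- length(foreground)
  terms <- unique(ann$term[ann$gene_id %in% foreground])
  if (length(terms) == 0L) {
    out <- data.frame(term = character(0), k = integer(0), K = integer(0),
                      n = integer(0), N = integer(0), p_value = numeric(0),
                      q_value = numeric(0), significant = logical(0))
    class(out) <- c("EnrichmentRecord", "data.frame")
    return(out)
  }
  K <- vapply(terms, function(t) sum(ann$term == t), integer(1))
  k <- vapply(terms, function(t)
    sum(ann$term == t & ann$gene_id %in% foreground), integer(1))
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  q <- bh_fdr(p)
  out <- data.frame(term = terms, k = k, K = K, n = n, N = N,
                    p_value = p, q_value = q,
                    significant = q <= q_threshold,
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("EnrichmentRecord", "data.frame")
  out
}
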