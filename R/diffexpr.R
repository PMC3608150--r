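#' Audic-Claverie conditional p-value for a pair of tag counts
#'
#' Given `x` tags for a gene in library A (total `n_a`) and `y` in library B
#' (total `n_b`), the conditional distribution of `y` given `x` under equal
#' relative abundance is
#' \deqn{P(y \mid x) = \left(\frac{n_b}{n_a}\right)^{y}
#'   \frac{(x+y)!}{x!\,y!\,(1+n_b/n_a)^{x+y+1}},}
#' a negative binomial with size `x + 1` and success probability
#' `n_a / (n_a + n_b)`. The two-sided p-value doubles the smaller of the two
#' tails `P(Y <= y | x)` and `P(X <= x | y)`, capped at 1. These tails
#' satisfy the exact identity `P(X <= x | y) = P(Y > y | x)`, so the test is
#' exactly symmetric in the two libraries -- swapping `(x, n_a)` with
#' `(y, n_b)` returns the same p-value, and `x = y` with equal totals gives
#' p = 1 -- which in turn makes the downstream screen antisymmetric under
#' exchanging control and experimental libraries. Tails are accumulated in
#' log space, summing whichever tail is the smaller one directly for
#' numerical stability at deep library totals.
#'
#' @param x,y non-negative integer counts (vectors are recycled to the longer
#'   length).
#' @param n_a,n_b positive library totals.
#' @return numeric vector of p-values in `[0, 1]`.
#' @references Audic S, Claverie JM (1997) The significance of digital gene
#'   expression profiles. Genome Res 7:986-995.
#' @export
ac_pvalue <- function(x, y, n_a, n_b) {
  if (any(x < 0) || any(y < 0)) stop("counts must be non-negative")
  if (n_a <= 0 || n_b <= 0) stop("library totals must be positive")
  n <- max(length(x), length(y))
  x <- rep_len(as.numeric(x), n)
  y <- rep_len(as.numeric(y), n)
  r <- n_b / n_a
  logr <- log(n_b) - log(n_a)
  log1pr <- log1p(r)
  logpmf <- function(xi, ks) {
    lgamma(xi + ks + 1) - lgamma(xi + 1) - lgamma(ks + 1) +
      ks * logr - (xi + ks + 1) * log1pr
  }
  p <- numeric(n)
  for (i in seq_len(n)) {
    xi <- x[i]
    yi <- y[i]
    if (yi <= (xi + 1) * r) {
      # lower tail is the small one: sum it exactly
      lp <- logpmf(xi, 0:yi)
      m <- max(lp)
      lower <- min(1, exp(m) * sum(exp(lp - m)))
      p[i] <- min(1, 2 * min(lower, 1 - lower))
    } else {
      # upper tail P(Y > y) is the small one: sum forward until negligible
      S <- 0
      k <- yi + 1
      repeat {
        ks <- seq(k, k + 511)
        term <- exp(logpmf(xi, ks))
        S <- S + sum(term)
        last <- term[length(term)]
        # stop once the running terms are negligible; `last == 0` guards the
        # deep-tail case where S itself is denormal and S * 1e-17 underflows
        if (last == 0 || last < S * 1e-17) break
        k <- k + 512
      }
      p[i] <- min(1, 2 * min(S, 1 - S))
    }
  }
  p
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment across one comparison's tested genes (delegates to
#' [stats::p.adjust()] with `method = "BH"`).
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of q-values, same order as the input.
#' @export
bh_fdr <- function(p_values) {
  if (length(p_values) == 0L) return(numeric(0))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

# TPM floor used when one library has zero expression, so log ratios stay
# finite (0.001 TPM stands in for 0).
TPM_FLOOR <- 0.001

#' Pairwise differential expression screen between two libraries
#'
#' Tests every gene sense-expressed in at least one of the two libraries
#' (genes absent from both are excluded before FDR adjustment). Ratios are
#' `log2(max(tpm_b, 0.001) / max(tpm_a, 0.001))` with library A as control;
#' p-values come from [ac_pvalue()] on the sense counts, adjusted with
#' [bh_fdr()] across all tested genes of this comparison. A gene is
#' significant when `fdr <= 0.001` and `|log2 ratio| >= 1`.
#'
#' @param control,experimental `GeneExpressionProfile` objects from
#'   [compute_profile()] (library A and B of "A vs B").
#' @param fdr_threshold,lfc_threshold significance thresholds (defaults
#'   0.001 and 1).
#' @return a `ComparisonResult`: list with `control_id`, `experimental_id`,
#'   `records` (data.frame: gene_id, raw_a, raw_b, tpm_a, tpm_b, log2_ratio,
#'   p_value, fdr, significant, direction), `n_up`, `n_down`.
#' @export
compare_libraries <- function(control, experimental,
                              fdr_threshold = 0.001, lfc_threshold = 1) {
  stopifnot(inherits(control, "GeneExpressionProfile"),
            inherits(experimental, "GeneExpressionProfile"))
  id_a <- attr(control, "library_id")
  id_b <- attr(experimental, "library_id")
  if (identical(id_a, id_b)) stop("control and experimental ids are identical")
  n_a <- attr(control, "clean_total")
  n_b <- attr(experimental, "clean_total")

  genes <- sort(union(control$gene_id[control$sense_count > 0],
                      experimental$gene_id[experimental$sense_count > 0]))
  ma <- match(genes, control$gene_id)
  mb <- match(genes, experimental$gene_id)
  raw_a <- ifelse(is.na(ma), 0, control$sense_count[ma])
  raw_b <- ifelse(is.na(mb), 0, experimental$sense_count[mb])
  tpm_a <- ifelse(is.na(ma), 0, control$sense_tpm[ma])
  tpm_b <- ifelse(is.na(mb), 0, experimental$sense_tpm[mb])

  log2_ratio <- log2(pmax(tpm_b, TPM_FLOOR) / pmax(tpm_a, TPM_FLOOR))
  p_value <- ac_pvalue(raw_a, raw_b, n_a, n_b)
  fdr <- bh_fdr(p_value)
  significant <- fdr <= fdr_threshold & abs(log2_ratio) >= lfc_threshold
  direction <- ifelse(!significant, "none",
                      ifelse(log2_ratio > 0, "up", "down"))

  records <- data.frame(gene_id = genes, raw_a = raw_a, raw_b = raw_b,
                        tpm_a = tpm_a, tpm_b = tpm_b,
                        log2_ratio = log2_ratio, p_value = p_value,
                        fdr = fdr, significant = significant,
                        direction = direction, stringsAsFactors = FALSE)
  structure(
    list(control_id = id_a, experimental_id = id_b, records = records,
         n_up = sum(direction == "up"), n_down = sum(direction == "down")),
    class = "ComparisonResult"
  )
}

#' @export
print.ComparisonResult <- function(x, ...) {
  cat(sprintf("ComparisonResult: %s vs %s (A = control)\n",
              x$control_id, x$experimental_id))
  cat(sprintf("  genes tested: %d; up: %d, down: %d\n",
              nrow(x$records), x$n_up, x$n_down))
  invisible(x)
}

#' Top up- and down-regulated genes of a comparison
#'
#' Significant genes ranked by `|log2 ratio|` (descending), ties broken by
#' smaller FDR then lexicographic gene id. Genes expressed in only one of the
#' two samples (zero sense count in the other) are excluded, matching the
#' convention of the published top-20 tables.
#'
#' @param result a `ComparisonResult`.
#' @param k number of genes per direction (default 20).
#' @return list with data.frames `up` and `down` (at most `k` rows each).
#' @export
top_k <- function(result, k = 20L) {
  stopifnot(inherits(result, "ComparisonResult"), k >= 1)
  r <- result$records
  r <- r[r$significant & r$raw_a > 0 & r$raw_b > 0, , drop = FALSE]
  pick <- function(dir) {
    d <- r[r$direction == dir, , drop = FALSE]
    d <- d[order(-abs(d$log2_ratio), d$fdr, d$gene_id), , drop = FALSE]
    head(d, k)
  }
  list(up = pick("up"), down = pick("down"))
}

#' Write a comparison as TSV (per-gene screening table)
#'
#' Columns mirror the published per-comparison tables: gene, TPM and raw
#' count in each library, log2 ratio, p-value, FDR, significance call.
#'
#' @param result a `ComparisonResult`.
#' @param path output path.
#' @export
write_comparison <- function(result, path) {
  stopifnot(inherits(result, "ComparisonResult"))
  r <- result$records
  df <- data.frame(gene = r$gene_id, tpm_control = r$tpm_a,
                   tpm_experimental = r$tpm_b, raw_control = r$raw_a,
                   raw_experimental = r$raw_b, log2_ratio = r$log2_ratio,
                   p_value = r$p_value, fdr = r$fdr,
                   significant = r$significant, direction = r$direction)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
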