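# Shared fixtures and independent oracles, built in code.

BASES <- c("A", "C", "G", "T")

rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

rc <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# Brute-force scan: all CATG-anchored 21-mers of one strand string.
scan_tags <- function(s) {
  out <- character(0)
  if (nchar(s) < 21) return(out)
  for (i in 1:(nchar(s) - 20)) {
    if (substr(s, i, i + 3) == "CATG") out <- c(out, substr(s, i, i + 20))
  }
  out
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Exhaustive <=1-mismatch gene lookup over an index's full tag table.
brute_gene_hits <- function(tag, tag_df, max_mm = 1) {
  d <- vapply(tag_df$tag, hamming, numeric(1), b = tag)
  exact <- tag_df[d == 0, , drop = FALSE]
  if (nrow(exact) > 0) return(list(stratum = "exact", hits = exact))
  mm <- tag_df[d <= max_mm, , drop = FALSE]
  if (nrow(mm) > 0) return(list(stratum = "1MM", hits = mm))
  list(stratum = "none", hits = tag_df[0, ])
}

toy_genes <- function(seqs, ids = sprintf("g%d", seq_along(seqs))) {
  data.frame(gene_id = ids, strand = "+", transcript_seq = seqs,
             stringsAsFactors = FALSE)
}

# A library object straight from a named count vector (clean by fiat).
lib_from_counts <- function(counts, id = "L", stage = "clean") {
  tag_library(counts, id, stage = stage)
}

# A profile object from per-gene sense counts.
profile_from_counts <- function(sense, total, id, antisense = NULL) {
  genes <- names(sense)
  anti <- if (is.null(antisense)) rep(0, length(genes)) else antisense
  out <- data.frame(gene_id = genes, sense_count = unname(sense),
                    antisense_count = unname(anti),
                    sense_tpm = unname(1e6 * sense / total),
                    antisense_tpm = unname(1e6 * anti / total),
                    stringsAsFactors = FALSE)
  attr(out, "clean_total") <- total
  attr(out, "library_id") <- id
  class(out) <- c("GeneExpressionProfile", "data.frame")
  out
}

# Direct-summation Audic-Claverie oracle: normalized conditional pmf via a
# multiplicative recurrence, tails summed term by term.
ac_oracle <- function(x, y, na, nb, extra = 400) {
  r <- nb / na
  kmax <- y + extra
  pmf <- numeric(kmax + 1)
  pmf[1] <- 1 / (1 + r)^(x + 1)
  for (k in 0:(kmax - 1)) pmf[k + 2] <- pmf[k + 1] * (x + k + 1) / (k + 1) * r / (1 + r)
  lower <- sum(pmf[1:(y + 1)])
  upper <- sum(pmf[(y + 2):(kmax + 1)])
  min(1, 2 * min(lower, upper))
}

# Random 21-mer tag starting with CATG.
rand_tag <- function() paste0("CATG", rand_dna(17))
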