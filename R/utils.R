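# Tag geometry: the NlaIII anchor and total tag length are fixed by the assay.
TAG_ANCHOR <- "CATG"
TAG_LEN <- 21L

.bases <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Thin wrapper around [Biostrings::reverseComplement()] that accepts and
#' returns plain character vectors. `N` is preserved.
#'
#' @param x character vector of DNA sequences (alphabet A, C, G, T, N).
#' @return character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Tally a character vector of tags into a named integer count vector,
# sorted by tag. sort()+rle keeps this linear-ish and dependency-free.
count_tags <- function(tags) {
  if (length(tags) == 0L) {
    x <- integer(0)
    names(x) <- character(0)
    return(x)
  }
  s <- sort(tags, method = "radix")
  r <- rle(s)
  counts <- r$lengths
  names(counts) <- r$values
  counts
}

# All CATG-anchored start offsets (1-based) in `seq` with a full tag inside.
catg_tag_starts <- function(seq) {
  if (nchar(seq) < TAG_LEN) return(integer(0))
  m <- gregexpr(TAG_ANCHOR, seq, fixed = TRUE)[[1]]
  if (m[1] == -1L) return(integer(0))
  starts <- as.integer(m)
  starts[starts + TAG_LEN - 1L <= nchar(seq)]
}

# All CATG-anchored 21-mers of `seq` (one strand), 5'->3' order.
catg_tags <- function(seq) {
  st <- catg_tag_starts(seq)
  if (length(st) == 0L) return(character(0))
  substring(seq, st, st + TAG_LEN - 1L)
}

# The 63 Hamming-distance-1 variants of a 21-mer (3 substitutions x 21 sites).
tag_variants_1mm <- function(tag) {
  chars <- strsplit(tag, "", fixed = TRUE)[[1]]
  out <- character(0)
  for (i in seq_len(TAG_LEN)) {
    for (b in .bases[.bases != chars[i]]) {
      v <- chars
      v[i] <- b
      out <- c(out, paste(v, collapse = ""))
    }
  }
  out
}

# Percentage formatters used by the printed summary tables.
pct1 <- function(x, n) round(100 * x / n, 1)
pct2 <- function(x, n) round(100 * x / n, 2)

random_dna <- function(n) {
  paste(sample(.bases, n, replace = TRUE), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
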