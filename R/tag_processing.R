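#' Construct a tag library
#'
#' A `TagLibrary` holds the distinct 21-mer tags of one sequencing library
#' with their copy numbers. `stage = "raw"` libraries come straight from tag
#' extraction; `stage = "clean"` libraries have passed the adaptor, N and
#' singleton filters, so every tag starts with CATG, contains no N and has
#' copy number >= 2.
#'
#' @param counts named non-negative integer vector (names are 21-mer tags).
#' @param library_id library identifier.
#' @param stage `"raw"` or `"clean"`.
#' @param n_reads number of input reads the library was built from (raw
#'   libraries only; used for copy-conservation accounting).
#' @param n_empty number of reads yielding no tag (no CATG with 17 nt after).
#' @return a `TagLibrary` object with fields `library_id`, `counts`, `total`,
#'   `distinct`, `stage`, `n_reads`, `n_empty`.
#' @export
tag_library <- function(counts, library_id, stage = c("raw", "clean"),
                        n_reads = NA_integer_, n_empty = NA_integer_) {
  stage <- match.arg(stage)
  counts <- counts[counts > 0]
  storage.mode(counts) <- "double" # totals can exceed .Machine$integer.max
  if (length(counts) && is.null(names(counts))) {
    stop("`counts` must be named by tag sequence")
  }
  if (stage == "clean" && length(counts)) {
    bad <- nchar(names(counts)) != TAG_LEN |
      substr(names(counts), 1L, 4L) != TAG_ANCHOR |
      grepl("N", names(counts), fixed = TRUE) | counts < 2
    if (any(bad)) stop("clean library violates the clean-tag invariants")
  }
  structure(
    list(library_id = library_id, counts = counts, total = sum(counts),
         distinct = length(counts), stage = stage,
         n_reads = n_reads, n_empty = n_empty),
    class = "TagLibrary"
  )
}

#' @export
print.TagLibrary <- function(x, ...) {
  cat(sprintf("TagLibrary '%s' (%s): %s tag copies, %d distinct tags\n",
              x$library_id, x$stage, format(x$total, big.mark = ","),
              x$distinct))
  invisible(x)
}

#' Extract the CATG-anchored 21-mer tag from each read
#'
#' The tag starts at the first CATG in the read and keeps the 17 following
#' nucleotides. Reads with no CATG, or whose first CATG has fewer than 17 nt
#' after it, yield `NA` (an "empty" read).
#'
#' @param reads character vector of read sequences.
#' @return character vector of 21-mer tags, `NA` where no tag was found.
#' @export
extract_tag <- function(reads) {
  if (length(reads) == 0L) return(character(0))
  reads <- toupper(reads)
  pos <- regexpr(TAG_ANCHOR, reads, fixed = TRUE)
  start <- as.integer(pos)
  ok <- start > 0L & start + TAG_LEN - 1L <= nchar(reads)
  out <- rep(NA_character_, length(reads))
  out[ok] <- substring(reads[ok], start[ok], start[ok] + TAG_LEN - 1L)
  out
}

#' Build the raw tag library from reads
#'
#' @param reads character vector of read sequences (e.g. from
#'   [read_fastq_reads()]).
#' @param library_id library identifier.
#' @return a raw-stage `TagLibrary`; its `n_empty` field counts reads that
#'   produced no tag, so `n_reads = total + n_empty`.
#' @export
build_raw_library <- function(reads, library_id) {
  tags <- extract_tag(reads)
  empty <- sum(is.na(tags))
  tag_library(count_tags(tags[!is.na(tags)]), library_id, stage = "raw",
              n_reads = length(reads), n_empty = empty)
}

#' Apply the clean-tag filters to a raw library
#'
#' Filters are applied in a fixed order, each tag copy being attributed to
#' the first filter that removes it: (1) tags containing any adaptor sequence
#' as a substring, (2) tags containing one or more N, (3) singleton tags
#' (copy number 1). The order makes the copy-conservation identity
#' `n_reads = clean total + n_empty + n_adaptor + n_lowquality +
#' n_singleton_copies` well defined.
#'
#' Filtering is idempotent: running a clean library through again returns it
#' unchanged with an all-zero report.
#'
#' @param raw a `TagLibrary` (normally raw-stage).
#' @param adaptors character vector of adaptor sequences (may be empty).
#' @return list with `library` (clean-stage `TagLibrary`) and `report`, a
#'   `FilterReport` list with fields `n_empty`, `n_adaptor`, `n_lowquality`,
#'   `n_singleton_tags`, `n_singleton_copies`.
#' @export
clean_library <- function(raw, adaptors = character(0)) {
  stopifnot(inherits(raw, "TagLibrary"))
  counts <- raw$counts
  tags <- names(counts) %||% character(0)

  is_adaptor <- rep(FALSE, length(tags))
  for (a in toupper(adaptors)) {
    if (!nzchar(a)) next
    is_adaptor <- is_adaptor | grepl(a, tags, fixed = TRUE)
    if (nchar(a) > TAG_LEN) {
      # a tag lying wholly inside a longer adaptor is adaptor-derived too
      wins <- substring(a, seq_len(nchar(a) - TAG_LEN + 1L),
                        seq(TAG_LEN, nchar(a)))
      is_adaptor <- is_adaptor | tags %in% wins
    }
  }
  n_adaptor <- sum(counts[is_adaptor])

  has_n <- grepl("N", tags, fixed = TRUE) & !is_adaptor
  n_lowquality <- sum(counts[has_n])

  singleton <- counts == 1 & !is_adaptor & !has_n
  n_singleton_tags <- sum(singleton)
  n_singleton_copies <- sum(counts[singleton])

  keep <- !is_adaptor & !has_n & !singleton
  clean <- tag_library(counts[keep], raw$library_id, stage = "clean")

  report <- structure(
    list(
      n_empty = if (is.na(raw$n_empty)) 0 else raw$n_empty,
      n_adaptor = unname(n_adaptor),
      n_lowquality = unname(n_lowquality),
      n_singleton_tags = unname(n_singleton_tags),
      n_singleton_copies = unname(n_singleton_copies)
    ),
    class = "FilterReport"
  )
  list(library = clean, report = report)
}

#' @export
print.FilterReport <- function(x, ...) {
  cat("FilterReport\n")
  cat("  empty reads (no usable CATG):", x$n_empty, "\n")
  cat("  adaptor tag copies:", x$n_adaptor, "\n")
  cat("  low-quality (N) tag copies:", x$n_lowquality, "\n")
  cat(sprintf("  singleton tags: %d (%d copies)\n",
              x$n_singleton_tags, x$n_singleton_copies))
  invisible(x)
}

#' Write a tag library as a two-column TSV (tag, count)
#' @param lib a `TagLibrary`.
#' @param path output path.
#' @export
write_tag_library <- function(lib, path) {
  stopifnot(inherits(lib, "TagLibrary"))
  df <- data.frame(tag = names(lib$counts) %||% character(0),
                   count = unname(lib$counts))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a filter report as JSON
#' @param report a `FilterReport`.
#' @param path output path.
#' @export
write_filter_report <- function(report, path) {
  stopifnot(inherits(report, "FilterReport"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
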