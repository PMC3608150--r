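#' Build the virtual CATG tag database from gene models
#'
#' Scans every transcript for CATG-anchored 21-mers on both strands and
#' registers them as virtual tags, mirroring how an NlaIII DGE tag is expected
#' to arise from a transcript. All anchored sites are indexed, not only the
#' 3'-most one, because internal and antisense tags are informative in this
#' assay; `site_rank` records the 3' to 5' order (rank 1 = 3'-most site on
#' that strand) so a canonical-site-only view can be recovered downstream.
#'
#' A genome-wide tag set is kept alongside the gene-derived index so that
#' clean tags absent from any transcript can still be recognized as genomic
#' ("Mapping to Genome" category) rather than unknown.
#'
#' @param genes data.frame with columns `gene_id`, `strand` (`+`/`-`),
#'   `transcript_seq` (spliced, 5' to 3'), and optionally `chrom`. Gene ids
#'   must be unique; sequences use the alphabet A/C/G/T/N.
#' @param genome optional named character vector (or `DNAStringSet`) of
#'   chromosome sequences. When supplied, every CATG-anchored 21-mer on either
#'   strand of every chromosome enters the genome tag set; when `NULL` the
#'   genome tag set is built from the transcripts themselves (both strands).
#' @return an object of class `ReferenceTagIndex` with elements:
#'   `tags` (data.frame: tag, gene_id, orientation, site_rank),
#'   `genes_without_tags` (gene ids with no CATG-anchored tag site), and
#'   internal hash environments used by [query_tag()].
#' @seealso [query_tag()], [write_virtual_tags()]
#' @export
build_reference_index <- function(genes, genome = NULL) {
  stopifnot(is.data.frame(genes), nrow(genes) > 0L)
  required <- c("gene_id", "transcript_seq")
  if (!all(required %in% names(genes))) {
    stop("`genes` needs columns gene_id and transcript_seq")
  }
  if (anyDuplicated(genes$gene_id)) stop("gene_id values must be unique")
  seqs <- toupper(genes$transcript_seq)
  if (any(!nzchar(seqs))) stop("empty transcript sequence")
  if (any(grepl("[^ACGTN]", seqs))) stop("transcript alphabet must be A/C/G/T/N")

  rows <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    s <- seqs[i]
    sense <- catg_tags(s)
    anti <- catg_tags(revcomp(s))
    n_s <- length(sense)
    n_a <- length(anti)
    if (n_s + n_a == 0L) next
    rows[[i]] <- data.frame(
      tag = c(sense, anti),
      gene_id = genes$gene_id[i],
      orientation = rep(c("sense", "antisense"), c(n_s, n_a)),
      # tags come back 5'->3' along each scanned strand; rank 1 is the 3'-most
      site_rank = c(rev(seq_len(n_s)), rev(seq_len(n_a))),
      stringsAsFactors = FALSE
    )
  }
  tag_df <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(tag_df)) {
    tag_df <- data.frame(tag = character(0), gene_id = character(0),
                         orientation = character(0), site_rank = integer(0))
  }
  # order-independence of the gene input: canonical row order
  tag_df <- tag_df[order(tag_df$tag, tag_df$gene_id, tag_df$orientation,
                         tag_df$site_rank), , drop = FALSE]
  rownames(tag_df) <- NULL

  gene_env <- new.env(hash = TRUE, parent = emptyenv())
  if (nrow(tag_df) > 0L) {
    # one entry per (tag, gene, orientation); rows are rank-sorted so the
    # retained site_rank is the 3'-most site
    dedup <- tag_df[!duplicated(tag_df[c("tag", "gene_id", "orientation")]), ,
                    drop = FALSE]
    split_hits <- split(dedup[c("gene_id", "orientation", "site_rank")],
                        dedup$tag)
    list2env(split_hits, envir = gene_env)
  }

  genome_env <- new.env(hash = TRUE, parent = emptyenv())
  if (is.null(genome)) {
    chroms <- seqs
  } else {
    if (methods::is(genome, "DNAStringSet")) genome <- as.character(genome)
    chroms <- toupper(unname(unlist(genome)))
  }
  for (chrom in chroms) {
    for (t in catg_tags(chrom)) assign(t, TRUE, envir = genome_env)
    for (t in catg_tags(revcomp(chrom))) assign(t, TRUE, envir = genome_env)
  }

  has_tags <- unique(tag_df$gene_id)
  structure(
    list(
      tags = tag_df,
      genes_without_tags = setdiff(genes$gene_id, has_tags),
      gene_env = gene_env,
      genome_env = genome_env
    ),
    class = "ReferenceTagIndex"
  )
}

#' @export
print.ReferenceTagIndex <- function(x, ...) {
  cat("ReferenceTagIndex\n")
  cat("  distinct virtual tags:", length(ls(x$gene_env)), "\n")
  cat("  tag records:", nrow(x$tags),
      sprintf("(%d sense, %d antisense)",
              sum(x$tags$orientation == "sense"),
              sum(x$tags$orientation == "antisense")), "\n")
  cat("  genome tag set size:", length(ls(x$genome_env)), "\n")
  if (length(x$genes_without_tags)) {
    cat("  genes without any tag site:", length(x$genes_without_tags), "\n")
  }
  invisible(x)
}

# Unique (gene_id, orientation) hits from a list of hit data.frames.
.collapse_hits <- function(hit_list) {
  hit_list <- hit_list[!vapply(hit_list, is.null, logical(1))]
  if (!length(hit_list)) return(NULL)
  df <- do.call(rbind, hit_list)
  df <- df[!duplicated(df[c("gene_id", "orientation")]), , drop = FALSE]
  df[order(df$gene_id, df$orientation), , drop = FALSE]
}

#' Query one tag against the reference index
#'
#' Resolution is strictly stratified: an exact transcript match wins over any
#' 1-mismatch match, and the genome tag set is checked exact-first as well.
#' A tag containing `N` matches nothing.
#'
#' @param tag a 21-mer character scalar.
#' @param index a [build_reference_index()] result.
#' @return list with `stratum` (`"exact"`, `"1MM"` or `"none"`),
#'   `gene_hits` (data.frame: gene_id, orientation, site_rank; zero rows when
#'   no gene matches), and `genome_hit` (logical).
#' @export
query_tag <- function(tag, index) {
  stopifnot(inherits(index, "ReferenceTagIndex"), is.character(tag),
            length(tag) == 1L)
  if (nchar(tag) != TAG_LEN) stop("tag must be a 21-mer")
  empty <- data.frame(gene_id = character(0), orientation = character(0),
                      site_rank = integer(0))
  if (grepl("[^ACGT]", tag)) {
    return(list(stratum = "none", gene_hits = empty, genome_hit = FALSE))
  }

  exact <- get0(tag, envir = index$gene_env, inherits = FALSE)
  if (!is.null(exact)) {
    return(list(stratum = "exact", gene_hits = exact,
                genome_hit = !is.null(get0(tag, envir = index$genome_env,
                                           inherits = FALSE))))
  }

  variants <- tag_variants_1mm(tag)
  hits <- .collapse_hits(mget(variants, envir = index$gene_env,
                              ifnotfound = list(NULL)))
  genome_exact <- !is.null(get0(tag, envir = index$genome_env,
                                inherits = FALSE))
  genome_1mm <- genome_exact ||
    any(!vapply(mget(variants, envir = index$genome_env,
                     ifnotfound = list(NULL)), is.null, logical(1)))

  if (!is.null(hits)) {
    list(stratum = "1MM", gene_hits = hits, genome_hit = genome_1mm)
  } else if (genome_exact) {
    list(stratum = "exact", gene_hits = empty, genome_hit = TRUE)
  } else if (genome_1mm) {
    list(stratum = "1MM", gene_hits = empty, genome_hit = TRUE)
  } else {
    list(stratum = "none", gene_hits = empty, genome_hit = FALSE)
  }
}

#' Write the virtual tag database as TSV
#'
#' Columns: tag, gene_id, orientation, site_rank.
#'
#' @param index a `ReferenceTagIndex`.
#' @param path output file path.
#' @export
write_virtual_tags <- function(index, path) {
  stopifnot(inherits(index, "ReferenceTagIndex"))
  write.table(index$tags, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Vectorized 1MM variant lookup used by assign_tags(): returns, for a
# character vector of tags, a list of collapsed gene-hit data.frames and a
# logical genome-hit-at-<=1MM vector. Chunked so the 63 x n variant strings
# never all exist at once.
.batch_query_1mm <- function(tags, index, chunk = 4000L) {
  n <- length(tags)
  gene_hits <- vector("list", n)
  genome_1mm <- logical(n)
  if (n == 0L) return(list(gene_hits = gene_hits, genome_1mm = genome_1mm))
  for (lo in seq(1L, n, by = chunk)) {
    hi <- min(lo + chunk - 1L, n)
    idx <- lo:hi
    tg <- tags[idx]
    acc <- vector("list", length(idx))
    gm <- logical(length(idx))
    for (pos in seq_len(TAG_LEN)) {
      pre <- substr(tg, 1L, pos - 1L)
      cur <- substr(tg, pos, pos)
      suf <- substr(tg, pos + 1L, TAG_LEN)
      for (b in .bases) {
        keep <- cur != b & cur != "N"
        if (!any(keep)) next
        var <- paste0(pre[keep], b, suf[keep])
        res <- mget(var, envir = index$gene_env, ifnotfound = list(NULL))
        found <- which(!vapply(res, is.null, logical(1)))
        for (j in found) {
          k <- which(keep)[j]
          acc[[k]] <- c(acc[[k]], res[j])
        }
        gres <- mget(var, envir = index$genome_env, ifnotfound = list(NULL))
        gm[keep] <- gm[keep] | !vapply(gres, is.null, logical(1))
      }
    }
    for (k in seq_along(idx)) {
      if (!is.null(acc[[k]])) gene_hits[[idx[k]]] <- .collapse_hits(acc[[k]])
    }
    genome_1mm[idx] <- gm
  }
  list(gene_hits = gene_hits, genome_1mm = genome_1mm)
}
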