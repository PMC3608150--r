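#' Assign clean tags to genes via the reference index
#'
#' Every distinct clean tag is resolved at its best stratum (exact before
#' 1 mismatch). A tag whose best-stratum hits fall in exactly one gene is
#' `gene_unambiguous` and carries that gene and an orientation; hits in more
#' than one gene make it `gene_ambiguous`; a tag matching the genome tag set
#' only (at <= 1 mismatch) is `genome_only`; anything else is `unknown`.
#'
#' A tag hitting one gene at several sites is credited once. A tag hitting
#' one gene in both orientations at the same stratum is credited as sense
#' (sense transcription is the parsimonious origin); these cases are recorded
#' in the `both_orientation` attribute.
#'
#' @param clean a clean-stage `TagLibrary`.
#' @param index a `ReferenceTagIndex`.
#' @return data.frame of class `TagAssignment` with columns `tag`, `count`,
#'   `category`, `gene_id` (NA unless unambiguous), `orientation` (NA unless
#'   unambiguous), `stratum`, plus attribute `ambiguous_genes`: a list, per
#'   ambiguous tag, of the gene ids in its hit set (used for the tag-mapped
#'   gene accounting).
#' @export
assign_tags <- function(clean, index) {
  stopifnot(inherits(clean, "TagLibrary"), inherits(index, "ReferenceTagIndex"))
  if (clean$stage != "clean") stop("assign_tags() expects a clean library")
  tags <- names(clean$counts) %||% character(0)
  n <- length(tags)
  category <- rep("unknown", n)
  gene_id <- rep(NA_character_, n)
  orientation <- rep(NA_character_, n)
  stratum <- rep("none", n)
  amb_genes <- vector("list", n)
  both_orient <- character(0)

  if (n > 0L) {
    exact_hits <- mget(tags, envir = index$gene_env, ifnotfound = list(NULL))
    has_exact <- !vapply(exact_hits, is.null, logical(1))
    genome_exact <- !vapply(
      mget(tags, envir = index$genome_env, ifnotfound = list(NULL)),
      is.null, logical(1))

    need_1mm <- which(!has_exact)
    mm <- .batch_query_1mm(tags[need_1mm], index)

    for (i in seq_len(n)) {
      if (has_exact[i]) {
        hits <- exact_hits[[i]]
        st <- "exact"
      } else {
        j <- match(i, need_1mm)
        hits <- mm$gene_hits[[j]]
        st <- "1MM"
      }
      if (!is.null(hits) && nrow(hits) > 0L) {
        hits <- hits[!duplicated(hits[c("gene_id", "orientation")]), ,
                     drop = FALSE]
        genes <- unique(hits$gene_id)
        stratum[i] <- st
        if (length(genes) == 1L) {
          category[i] <- "gene_unambiguous"
          gene_id[i] <- genes
          orients <- unique(hits$orientation)
          if (length(orients) > 1L) {
            orientation[i] <- "sense"
            both_orient <- c(both_orient, tags[i])
          } else {
            orientation[i] <- orients
          }
        } else {
          category[i] <- "gene_ambiguous"
          amb_genes[[i]] <- genes
        }
      } else {
        # no gene hit at <= 1MM: genome category, exact checked first
        if (genome_exact[i]) {
          category[i] <- "genome_only"
          stratum[i] <- "exact"
        } else {
          j <- match(i, need_1mm)
          hit_1mm <- if (is.na(j)) FALSE else mm$genome_1mm[j]
          if (hit_1mm) {
            category[i] <- "genome_only"
            stratum[i] <- "1MM"
          }
        }
      }
    }
  }

  out <- data.frame(tag = tags, count = unname(clean$counts),
                    category = category, gene_id = gene_id,
                    orientation = orientation, stratum = stratum,
                    stringsAsFactors = FALSE)
  attr(out, "ambiguous_genes") <- amb_genes
  attr(out, "both_orientation") <- both_orient
  attr(out, "library_id") <- clean$library_id
  class(out) <- c("TagAssignment", "data.frame")
  out
}

#' Library-level tag category accounting
#'
#' Produces the per-library accounting table of the standard DGE report:
#' total and distinct tag counts per category (gene-mapped, with the
#' unambiguous subset; genome-only; unknown), plus gene-level tallies.
#' `tag_mapped_genes` counts genes reached by any tag, including membership
#' in an ambiguous tag's hit set; `unambiguous_tag_mapped_genes` requires at
#' least one unambiguous tag; `both_strand_genes` requires unambiguous tags
#' in both orientations.
#'
#' The category partition is exact by construction:
#' gene + genome + unknown = clean total (and likewise for distinct counts).
#'
#' @param assignments a `TagAssignment` data.frame from [assign_tags()].
#' @param clean the clean `TagLibrary` the assignments were computed from.
#' @return a `LibrarySummary` list.
#' @export
summarize_library <- function(assignments, clean) {
  stopifnot(inherits(assignments, "TagAssignment"),
            inherits(clean, "TagLibrary"))
  if (!setequal(assignments$tag, names(clean$counts) %||% character(0)) ||
      nrow(assignments) != clean$distinct) {
    stop("assignments do not cover exactly the library's distinct tags")
  }
  cat_tot <- function(cats) sum(assignments$count[assignments$category %in% cats])
  cat_dis <- function(cats) sum(assignments$category %in% cats)

  gene_cats <- c("gene_unambiguous", "gene_ambiguous")
  unamb <- assignments$category == "gene_unambiguous"
  amb_genes <- attr(assignments, "ambiguous_genes")
  genes_any <- unique(c(assignments$gene_id[unamb],
                        unlist(amb_genes, use.names = FALSE)))
  genes_unamb_sense <- unique(assignments$gene_id[
    unamb & assignments$orientation == "sense"])
  genes_unamb_anti <- unique(assignments$gene_id[
    unamb & assignments$orientation == "antisense"])

  structure(
    list(
      library_id = clean$library_id,
      clean_total = clean$total,
      clean_distinct = clean$distinct,
      gene_total = cat_tot(gene_cats),
      gene_distinct = cat_dis(gene_cats),
      unambiguous_total = cat_tot("gene_unambiguous"),
      unambiguous_distinct = cat_dis("gene_unambiguous"),
      genome_total = cat_tot("genome_only"),
      genome_distinct = cat_dis("genome_only"),
      unknown_total = cat_tot("unknown"),
      unknown_distinct = cat_dis("unknown"),
      tag_mapped_genes = length(genes_any),
      unambiguous_tag_mapped_genes =
        length(unique(c(genes_unamb_sense, genes_unamb_anti))),
      both_strand_genes = length(intersect(genes_unamb_sense,
                                           genes_unamb_anti))
    ),
    class = "LibrarySummary"
  )
}

#' @export
print.LibrarySummary <- function(x, ...) {
  cat(sprintf("LibrarySummary '%s'\n", x$library_id))
  print(format_library_summary(x), row.names = FALSE)
  invisible(x)
}

#' Format a library summary as the standard accounting table
#'
#' Recomputes the printed percentages from the integer counts:
#' "% of clean tag" columns are 100 * count / clean total, to two decimals.
#'
#' @param x a `LibrarySummary`, or a named list/vector carrying the same
#'   count fields (so a published table's integers can be re-checked).
#' @param n_ref_genes optional reference gene count for the "% of ref genes"
#'   rows (omitted when `NA`).
#' @return data.frame with columns `statistic`, `value` (counts and
#'   percentages interleaved, percentages to 2 decimal places).
#' @export
format_library_summary <- function(x, n_ref_genes = NA) {
  g <- function(f) x[[f]]
  rows <- list(
    c("Clean tag total", g("clean_total")),
    c("Clean tag distinct", g("clean_distinct")),
    c("Tag mapping to gene, total", g("gene_total")),
    c("Tag mapping to gene, distinct", g("gene_distinct")),
    c("Unambiguous tag mapping to gene, total", g("unambiguous_total")),
    c("Unambiguous total % of clean tag",
      pct2(g("unambiguous_total"), g("clean_total"))),
    c("Unambiguous tag mapping to gene, distinct", g("unambiguous_distinct")),
    c("Unambiguous distinct % of clean tag",
      pct2(g("unambiguous_distinct"), g("clean_distinct"))),
    c("Tag-mapped genes", g("tag_mapped_genes")),
    c("Unambiguous tag-mapped genes", g("unambiguous_tag_mapped_genes")),
    c("Mapping to genome, total", g("genome_total")),
    c("Genome total % of clean tag", pct2(g("genome_total"), g("clean_total"))),
    c("Mapping to genome, distinct", g("genome_distinct")),
    c("Unknown tag, total", g("unknown_total")),
    c("Unknown total % of clean tag",
      pct2(g("unknown_total"), g("clean_total"))),
    c("Unknown tag, distinct", g("unknown_distinct"))
  )
  if (!is.na(n_ref_genes)) {
    rows <- c(rows, list(
      c("Tag-mapped genes % of ref genes",
        pct2(g("tag_mapped_genes"), n_ref_genes)),
      c("Unambiguous tag-mapped genes % of ref genes",
        pct2(g("unambiguous_tag_mapped_genes"), n_ref_genes))
    ))
  }
  data.frame(statistic = vapply(rows, `[[`, "", 1L),
             value = as.numeric(vapply(rows, `[[`, "", 2L)))
}

#' Write library summaries as a TSV table (libraries as columns)
#' @param summaries list of `LibrarySummary` objects.
#' @param path output path.
#' @export
write_library_summaries <- function(summaries, path) {
  cols <- lapply(summaries, function(s) format_library_summary(s)$value)
  df <- data.frame(statistic = format_library_summary(summaries[[1]])$statistic)
  for (i in seq_along(summaries)) df[[summaries[[i]]$library_id]] <- cols[[i]]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-gene expression profile of one library
#'
#' Accumulates unambiguous tag copies per (gene, orientation) and normalizes
#' to TPM: `tpm = 1e6 * count / clean_total`, with the library's total clean
#' tag count as denominator (not its mapped-tag count), so TPM values are
#' comparable across categories of mapping efficiency.
#'
#' @param assignments a `TagAssignment` data.frame.
#' @param clean_total total clean tag copies of the library (> 0).
#' @param library_id library identifier.
#' @return a `GeneExpressionProfile`: data.frame with columns `gene_id`,
#'   `sense_count`, `antisense_count`, `sense_tpm`, `antisense_tpm`; genes
#'   with no unambiguous tag are absent (treated as 0 downstream). Attributes
#'   `clean_total`, `library_id`.
#' @export
compute_profile <- function(assignments, clean_total, library_id) {
  stopifnot(inherits(assignments, "TagAssignment"))
  if (!is.numeric(clean_total) || clean_total <= 0) {
    stop("clean_total must be positive")
  }
  un <- assignments[assignments$category == "gene_unambiguous", , drop = FALSE]
  genes <- sort(unique(un$gene_id))
  sense <- setNames(numeric(length(genes)), genes)
  anti <- setNames(numeric(length(genes)), genes)
  if (nrow(un) > 0L) {
    s <- tapply(un$count[un$orientation == "sense"],
                un$gene_id[un$orientation == "sense"], sum)
    a <- tapply(un$count[un$orientation == "antisense"],
                un$gene_id[un$orientation == "antisense"], sum)
    sense[names(s)] <- s
    anti[names(a)] <- a
  }
  out <- data.frame(gene_id = genes, sense_count = unname(sense),
                    antisense_count = unname(anti),
                    sense_tpm = unname(1e6 * sense / clean_total),
                    antisense_tpm = unname(1e6 * anti / clean_total),
                    stringsAsFactors = FALSE)
  attr(out, "clean_total") <- clean_total
  attr(out, "library_id") <- library_id
  class(out) <- c("GeneExpressionProfile", "data.frame")
  out
}

#' Write an expression matrix across libraries as TSV
#'
#' One row per gene over the union of genes; per library four columns:
#' `<id>_sense_raw`, `<id>_antisense_raw`, `<id>_sense_norm`,
#' `<id>_antisense_norm` (norm = TPM).
#'
#' @param profiles list of `GeneExpressionProfile` objects.
#' @param path output path.
#' @export
write_expression_matrix <- function(profiles, path) {
  genes <- sort(unique(unlist(lapply(profiles, function(p) p$gene_id))))
  df <- data.frame(gene = genes, stringsAsFactors = FALSE)
  for (p in profiles) {
    id <- attr(p, "library_id")
    m <- match(genes, p$gene_id)
    df[[paste0(id, "_sense_raw")]] <- ifelse(is.na(m), 0, p$sense_count[m])
    df[[paste0(id, "_antisense_raw")]] <-
      ifelse(is.na(m), 0, p$antisense_count[m])
    df[[paste0(id, "_sense_norm")]] <- ifelse(is.na(m), 0, p$sense_tpm[m])
    df[[paste0(id, "_antisense_norm")]] <-
      ifelse(is.na(m), 0, p$antisense_tpm[m])
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
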