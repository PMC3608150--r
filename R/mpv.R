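#' In-silico mid-parent library
#'
#' Pools the raw unambiguous tag counts of the two parental libraries
#' (per gene and orientation) and sums their clean totals, so the mid-parent
#' value (MPV) library behaves like an equal RNA mixture of the two parents
#' sequenced at their combined depth. With near-equal parental totals the
#' resulting TPM equals the mean of the parental TPMs to first order.
#'
#' @param br,bo parental `GeneExpressionProfile` objects.
#' @param library_id identifier for the pseudo-library (default `"MPV"`).
#' @return a `GeneExpressionProfile` (additionally classed `MPVProfile`) with
#'   per-gene summed counts and TPM over the combined clean total.
#' @export
mid_parent_profile <- function(br, bo, library_id = "MPV") {
  stopifnot(inherits(br, "GeneExpressionProfile"),
            inherits(bo, "GeneExpressionProfile"))
  total <- attr(br, "clean_total") + attr(bo, "clean_total")
  genes <- sort(union(br$gene_id, bo$gene_id))
  m1 <- match(genes, br$gene_id)
  m2 <- match(genes, bo$gene_id)
  sense <- ifelse(is.na(m1), 0, br$sense_count[m1]) +
    ifelse(is.na(m2), 0, bo$sense_count[m2])
  anti <- ifelse(is.na(m1), 0, br$antisense_count[m1]) +
    ifelse(is.na(m2), 0, bo$antisense_count[m2])
  out <- data.frame(gene_id = genes, sense_count = sense,
                    antisense_count = anti,
                    sense_tpm = 1e6 * sense / total,
                    antisense_tpm = 1e6 * anti / total,
                    stringsAsFactors = FALSE)
  attr(out, "clean_total") <- total
  attr(out, "library_id") <- library_id
  class(out) <- c("MPVProfile", "GeneExpressionProfile", "data.frame")
  out
}

#' Classify hybrid gene expression as additive or non-additive
#'
#' Compares the hybrid library against the in-silico mid-parent library with
#' the same machinery and thresholds as the DEG screen ([compare_libraries()]:
#' Audic-Claverie test, FDR <= 0.001, |log2 ratio| >= 1). Significant genes
#' are non-additive, split into above-MPV (hybrid higher) and below-MPV, and
#' cross-tabulated by parental bias (Br TPM vs Bo TPM; exact ties form their
#' own `Br=Bo` row rather than being merged).
#'
#' @param hybrid hybrid `GeneExpressionProfile`.
#' @param mpv the [mid_parent_profile()] of the parents.
#' @param br,bo the parental profiles (for the bias cross-tabulation).
#' @param fdr_threshold,lfc_threshold significance thresholds (defaults as in
#'   the DEG screen).
#' @return list with `classes` (data.frame: gene_id, class in
#'   `additive`/`nonadditive_above`/`nonadditive_below`, parental_bias,
#'   log2_ratio, fdr), `summary` (a `NonAdditiveSummary`), and `comparison`
#'   (the underlying `ComparisonResult`).
#' @export
classify_non_additive <- function(hybrid, mpv, br, bo,
                                  fdr_threshold = 0.001, lfc_threshold = 1) {
  stopifnot(inherits(mpv, "GeneExpressionProfile"))
  cmp <- compare_libraries(mpv, hybrid, fdr_threshold = fdr_threshold,
                           lfc_threshold = lfc_threshold)
  r <- cmp$records
  class_vec <- ifelse(!r$significant, "additive",
                      ifelse(r$log2_ratio > 0, "nonadditive_above",
                             "nonadditive_below"))
  b1 <- ifelse(is.na(match(r$gene_id, br$gene_id)), 0,
               br$sense_tpm[match(r$gene_id, br$gene_id)])
  b2 <- ifelse(is.na(match(r$gene_id, bo$gene_id)), 0,
               bo$sense_tpm[match(r$gene_id, bo$gene_id)])
  bias <- ifelse(b1 > b2, "Br>Bo", ifelse(b1 < b2, "Br<Bo", "Br=Bo"))
  classes <- data.frame(gene_id = r$gene_id, class = class_vec,
                        parental_bias = bias, log2_ratio = r$log2_ratio,
                        fdr = r$fdr, stringsAsFactors = FALSE)
  list(classes = classes, summary = non_additive_summary(classes),
       comparison = cmp)
}

#' Summarize non-additive classifications (counts only)
#'
#' Builds the count skeleton of the non-additivity table: total non-additive
#' genes `a`, the above-MPV (`b`) and below-MPV (`c`) splits, and the same
#' three counts within each parental-bias row. All printed percentages are
#' derived from these integers by [format_mpv_summary()].
#'
#' @param classes the per-gene class data.frame from
#'   [classify_non_additive()], or a pre-tabulated list of counts (fields
#'   `a`, `b`, `c`, and `rows`: data.frame with bias, a, b, c).
#' @return a `NonAdditiveSummary`: list(`a`, `b`, `c`, `rows`).
#' @export
non_additive_summary <- function(classes) {
  if (is.list(classes) && !is.data.frame(classes) &&
      all(c("a", "b", "c", "rows") %in% names(classes))) {
    return(structure(classes, class = "NonAdditiveSummary"))
  }
  na_cls <- classes[classes$class != "additive", , drop = FALSE]
  biases <- c("Br>Bo", "Br<Bo", "Br=Bo")
  rows <- do.call(rbind, lapply(biases, function(bv) {
    d <- na_cls[na_cls$parental_bias == bv, , drop = FALSE]
    data.frame(bias = bv, a = nrow(d),
               b = sum(d$class == "nonadditive_above"),
               c = sum(d$class == "nonadditive_below"))
  }))
  # the tie row is reported only when non-empty, as published tables omit it
  rows <- rows[rows$a > 0 | rows$bias != "Br=Bo", , drop = FALSE]
  structure(
    list(a = nrow(na_cls),
         b = sum(na_cls$class == "nonadditive_above"),
         c = sum(na_cls$class == "nonadditive_below"),
         rows = rows),
    class = "NonAdditiveSummary"
  )
}

#' Format a non-additivity summary with recomputed percentages
#'
#' Reproduces the published table layout from the integer counts alone.
#' Percentages (one decimal place): each row's `a` as a share of total `a`;
#' each row's `b` (`c`) as a share of total `b` (`c`); and the within-row
#' fractions `b/a` and `c/a`.
#'
#' @param x a `NonAdditiveSummary`.
#' @return data.frame with columns `row`, `a`, `a_pct`, `b`, `b_pct`,
#'   `b_over_a_pct`, `c`, `c_pct`, `c_over_a_pct` (NA where the published
#'   layout leaves the cell blank).
#' @export
format_mpv_summary <- function(x) {
  stopifnot(inherits(x, "NonAdditiveSummary"))
  top <- data.frame(row = "Hybrid vs MPV", a = x$a, a_pct = NA_real_,
                    b = x$b, b_pct = NA_real_,
                    b_over_a_pct = pct1(x$b, x$a),
                    c = x$c, c_pct = NA_real_,
                    c_over_a_pct = pct1(x$c, x$a))
  body <- data.frame(row = x$rows$bias, a = x$rows$a,
                     a_pct = pct1(x$rows$a, x$a),
                     b = x$rows$b, b_pct = pct1(x$rows$b, x$b),
                     b_over_a_pct = pct1(x$rows$b, x$rows$a),
                     c = x$rows$c, c_pct = pct1(x$rows$c, x$c),
                     c_over_a_pct = pct1(x$rows$c, x$rows$a))
  rbind(top, body)
}

#' @export
print.NonAdditiveSummary <- function(x, ...) {
  cat("NonAdditiveSummary (hybrid vs mid-parent value)\n")
  print(format_mpv_summary(x), row.names = FALSE)
  invisible(x)
}

#' Write the non-additivity outputs as TSV
#' @param result a [classify_non_additive()] result.
#' @param summary_path,classes_path output paths (either may be `NULL`).
#' @export
write_mpv_tables <- function(result, summary_path = NULL, classes_path = NULL) {
  if (!is.null(summary_path)) {
    write.table(format_mpv_summary(result$summary), summary_path, sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if (!is.null(classes_path)) {
    write.table(result$classes, classes_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(NULL)
}
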