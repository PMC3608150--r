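#' Run the per-library stages of the DGE pipeline
#'
#' Convenience wrapper chaining raw-library construction, clean-tag
#' filtering, tag-to-gene assignment, category accounting and TPM profiling
#' for one library of reads.
#'
#' @param reads character vector of read sequences.
#' @param library_id library identifier.
#' @param index a `ReferenceTagIndex`.
#' @param adaptors adaptor sequences for the clean filter; sequences longer
#'   than a tag are matched through their CATG-anchored 21-mer as well.
#' @return list with `raw`, `clean` (both `TagLibrary`), `report`
#'   (`FilterReport`), `assignments` (`TagAssignment`), `summary`
#'   (`LibrarySummary`) and `profile` (`GeneExpressionProfile`, `NULL` when
#'   no clean tags survive).
#' @export
process_library <- function(reads, library_id, index,
                            adaptors = character(0)) {
  adaptor_tags <- extract_tag(adaptors)
  adaptors <- unique(c(adaptors, adaptor_tags[!is.na(adaptor_tags)]))
  raw <- build_raw_library(reads, library_id)
  cl <- clean_library(raw, adaptors = adaptors)
  assignments <- assign_tags(cl$library, index)
  summary <- summarize_library(assignments, cl$library)
  profile <- if (cl$library$total > 0) {
    compute_profile(assignments, cl$library$total, library_id)
  }
  list(raw = raw, clean = cl$library, report = cl$report,
       assignments = assignments, summary = summary, profile = profile)
}

#' Reference index straight from a simulated reference
#'
#' @param ref a [simulate_reference()] result.
#' @return a `ReferenceTagIndex` over the simulated gene models and genome.
#' @export
index_from_reference <- function(ref) {
  stopifnot(inherits(ref, "SimulatedReference"))
  build_reference_index(ref$genes[c("gene_id", "chrom", "strand",
                                    "transcript_seq")],
                        genome = ref$genome)
}
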