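#' Simulation configuration for the seven-library DGE study design
#'
#' Defines the study conditions the simulator emulates: two diploid parents
#' (`Br`, `Bo`), four hybrid generations (`F1`-`F4`) and a "natural"
#' allopolyploid library (`N`), each sequenced as 35-bp tag reads. Defaults
#' are chosen to echo the structure of a real NlaIII DGE experiment at a
#' desk-scale depth.
#'
#' @param n_genes number of genes (default 2000).
#' @param gene_length transcript length range in nt (default 300-1500).
#' @param n_chromosomes chromosomes the genes are placed on (default 5).
#' @param depth raw reads per library (default 1e6; real libraries run
#'   ~6e6, the default keeps full-pipeline runs to minutes).
#' @param error_rate per-base substitution error rate (default 0.005).
#' @param n_rate per-base N-masking rate (default 0.002).
#' @param adaptor_rate fraction of reads that are adaptor contamination
#'   (default 0.005).
#' @param adaptor the 35-nt adaptor sequence (contains a CATG so adaptor
#'   reads yield a recognizable adaptor tag).
#' @param antisense_fraction fraction of genes transcribed also from the
#'   antisense strand (default 0.36, the fraction reported for this assay).
#' @param antisense_expression fraction of a flagged gene's reads that come
#'   from the antisense strand (default 0.3).
#' @param shared_tag_fraction fraction of genes belonging to a planted
#'   ambiguity pair sharing an exact 21-mer tag (default 0.05).
#' @param parent_specific_fraction fraction of genes expressed in only one
#'   parent, per parent (default 0.05).
#' @param nonadditive_fraction fraction of expressed genes with planted
#'   non-additive F1 regulation (default 0.3).
#' @param nonadditive_up_share share of non-additive genes deviating above
#'   the mid-parent value (default 0.607, the direction balance reported for
#'   this design).
#' @param effect_size range of planted |log2| deviations from MPV (default
#'   1-3).
#' @param attenuation per-generation fraction of the F1 deviation reverting
#'   toward MPV in F2-F4 (default 0.5).
#' @param canonical_site_prob probability a read starts at the 3'-most CATG
#'   site rather than an internal one (default 0.7).
#' @param seed integer seed (mandatory; every downstream draw derives from
#'   it).
#' @return a `SimulationConfig` list.
#' @export
sim_config <- function(n_genes = 2000L,
                       gene_length = c(300L, 1500L),
                       n_chromosomes = 5L,
                       depth = 1e6,
                       error_rate = 0.005,
                       n_rate = 0.002,
                       adaptor_rate = 0.005,
                       adaptor = "AGATCGGAAGAGCCATGTCGGAACTCCAGTCACAT",
                       antisense_fraction = 0.36,
                       antisense_expression = 0.3,
                       shared_tag_fraction = 0.05,
                       parent_specific_fraction = 0.05,
                       nonadditive_fraction = 0.3,
                       nonadditive_up_share = 0.607,
                       effect_size = c(1, 3),
                       attenuation = 0.5,
                       canonical_site_prob = 0.7,
                       seed) {
  if (missing(seed)) stop("a seed is mandatory")
  rates <- c(error_rate, n_rate, adaptor_rate, antisense_fraction,
             antisense_expression, shared_tag_fraction,
             parent_specific_fraction, nonadditive_fraction,
             nonadditive_up_share, attenuation, canonical_site_prob)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (depth <= 0) stop("depth must be positive")
  if (gene_length[1] < 21L) stop("gene length must allow a 21-mer tag")
  if (is.na(extract_tag(adaptor))) {
    stop("adaptor must contain a CATG with 17 nt following")
  }
  structure(as.list(environment()), class = "SimulationConfig")
}

SIM_LIBRARIES <- c("Br", "Bo", "F1", "F2", "F3", "F4", "N")

.plant <- function(s, pos) {
  substr(s, pos, pos + 3L) <- TAG_ANCHOR
  s
}

# Guarantee a valid sense tag site (planted in the first half), a shared tag
# region (middle) and, when required, an antisense tag site (planted so its
# sense-strand footprint stays clear of the first-half and middle regions).
.ensure_sense <- function(s) {
  if (length(catg_tag_starts(s))) return(s)
  .plant(s, sample.int(max(1L, nchar(s) %/% 2L - 20L), 1L))
}

.ensure_antisense <- function(s) {
  s2 <- revcomp(s)
  if (length(catg_tag_starts(s2))) return(s)
  hi <- nchar(s) %/% 2L - 41L
  if (hi < 1L) hi <- 1L
  revcomp(.plant(s2, sample.int(hi, 1L)))
}

#' Simulate a toy genome and gene models
#'
#' Generates random transcripts (each guaranteed at least one CATG-anchored
#' tag site), plants shared 21-mer tags into the configured fraction of gene
#' pairs (ambiguity), guarantees an antisense tag site for genes flagged as
#' antisense-transcribed, and assembles chromosomes by embedding each gene
#' (strand-aware) between random intergenic spacers, so every transcript is
#' a verbatim genome substring.
#'
#' @param config a [sim_config()].
#' @return a `SimulatedReference` list: `genome` (named character vector),
#'   `genes` (data.frame: gene_id, chrom, strand, start, end,
#'   transcript_seq, antisense, ambiguity_partner), and precomputed 35-nt
#'   read templates used by [simulate_library_reads()].
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  n <- config$n_genes
  lens <- sample(config$gene_length[1]:config$gene_length[2], n, replace = TRUE)
  seqs <- vapply(lens, random_dna, character(1))
  seqs <- vapply(seqs, .ensure_sense, character(1), USE.NAMES = FALSE)

  # planted ambiguity: pairs of genes sharing an exact sense 21-mer
  partner <- rep(NA_character_, n)
  ids <- sprintf("gene%04d", seq_len(n))
  n_pairs <- floor(config$shared_tag_fraction * n / 2)
  if (n_pairs > 0L) {
    chosen <- sample.int(n, 2L * n_pairs)
    for (j in seq_len(n_pairs)) {
      a <- chosen[2L * j - 1L]
      b <- chosen[2L * j]
      tag_a <- catg_tags(seqs[a])[1]
      pos <- nchar(seqs[b]) %/% 2L + 1L
      substr(seqs[b], pos, pos + TAG_LEN - 1L) <- tag_a
      partner[a] <- ids[b]
      partner[b] <- ids[a]
    }
  }

  antisense <- runif(n) < config$antisense_fraction
  for (i in which(antisense)) seqs[i] <- .ensure_antisense(seqs[i])
  # final guarantee: planting passes above cannot leave a gene without a
  # sense tag site (re-plant in the untouched first half if one was lost)
  seqs <- vapply(seqs, .ensure_sense, character(1), USE.NAMES = FALSE)

  # chromosome assembly: spacer + oriented gene + spacer + ...
  chrom_of <- rep_len(seq_len(config$n_chromosomes), n)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  genome <- setNames(character(config$n_chromosomes),
                     sprintf("chr%d", seq_len(config$n_chromosomes)))
  start <- integer(n)
  end <- integer(n)
  for (ch in seq_len(config$n_chromosomes)) {
    parts <- character(0)
    offset <- 0L
    for (i in which(chrom_of == ch)) {
      spacer <- random_dna(sample(100:300, 1L))
      embedded <- if (strand[i] == "+") seqs[i] else revcomp(seqs[i])
      parts <- c(parts, spacer, embedded)
      start[i] <- offset + nchar(spacer) + 1L
      end[i] <- start[i] + nchar(seqs[i]) - 1L
      offset <- end[i]
    }
    parts <- c(parts, random_dna(sample(100:300, 1L)))
    genome[ch] <- paste(parts, collapse = "")
  }

  genes <- data.frame(gene_id = ids, chrom = names(genome)[chrom_of],
                      strand = strand, start = start, end = end,
                      transcript_seq = seqs, antisense = antisense,
                      ambiguity_partner = partner, stringsAsFactors = FALSE)
  ref <- list(genome = genome, genes = genes)
  ref$templates <- .build_read_templates(ref)
  class(ref) <- "SimulatedReference"
  ref
}

# Precompute, per (gene, orientation, site), the 35-nt read template starting
# at the CATG site; sites are ordered canonical (3'-most) first, then the
# remaining sites 5'->3'. Short tails are padded with random bases (fixed at
# reference-build time, mimicking read-through into downstream sequence).
.build_read_templates <- function(ref) {
  n <- nrow(ref$genes)
  k_sense <- integer(n); off_sense <- integer(n)
  k_anti <- integer(n); off_anti <- integer(n)
  tmpl <- character(0)
  for (i in seq_len(n)) {
    for (orient in c("sense", "antisense")) {
      s <- ref$genes$transcript_seq[i]
      if (orient == "antisense") s <- revcomp(s)
      starts <- catg_tag_starts(s)
      if (length(starts)) {
        starts <- c(starts[length(starts)], starts[-length(starts)])
      }
      reads <- vapply(starts, function(st) {
        r <- substr(s, st, st + 34L)
        if (nchar(r) < 35L) r <- paste0(r, random_dna(35L - nchar(r)))
        r
      }, character(1))
      if (orient == "sense") {
        off_sense[i] <- length(tmpl); k_sense[i] <- length(reads)
      } else {
        off_anti[i] <- length(tmpl); k_anti[i] <- length(reads)
      }
      tmpl <- c(tmpl, reads)
    }
  }
  list(reads = tmpl, off_sense = off_sense, k_sense = k_sense,
       off_anti = off_anti, k_anti = k_anti)
}

#' Simulate the seven-library expression truth
#'
#' Parental relative abundances are drawn from a heavy-tailed log-normal (a
#' few high-abundance genes, most genes low), with a configurable fraction
#' of parent-specific genes. The F1 truth is the mid-parent mixture with
#' planted non-additive log2 deviations on a configured fraction of
#' expressed genes; F2-F4 attenuate those deviations geometrically toward
#' MPV; the natural library is an independent draw near MPV. Abundances per
#' library are normalized to sum to 1.
#'
#' @param config a [sim_config()].
#' @param ref a [simulate_reference()] result.
#' @return a `SimulationTruth` data.frame: per gene, `abund_<lib>` for the
#'   seven libraries, `class` (`additive` / `nonadditive_above` /
#'   `nonadditive_below`), `log2_dev` (planted F1 deviation), and the
#'   `parental_bias`, `antisense`, `ambiguity_partner` flags.
#' @export
simulate_expression <- function(config, ref) {
  stopifnot(inherits(config, "SimulationConfig"),
            inherits(ref, "SimulatedReference"))
  set.seed(config$seed + 1L)
  n <- config$n_genes
  base <- rlnorm(n, meanlog = 0, sdlog = 1.5)
  br <- base * rlnorm(n, 0, 0.2)
  bo <- base * rlnorm(n, 0, 0.2)
  specific <- sample.int(n, min(n, 2L * round(config$parent_specific_fraction * n)))
  half <- length(specific) %/% 2L
  bo[specific[seq_len(half)]] <- 0                      # Br-specific genes
  br[specific[setdiff(seq_along(specific), seq_len(half))]] <- 0
  br <- br / sum(br)
  bo <- bo / sum(bo)

  mpv <- (br + bo) / 2
  expressed <- which(mpv > 0)
  n_na <- round(config$nonadditive_fraction * length(expressed))
  planted <- sample(expressed, n_na)
  dev <- numeric(n)
  if (n_na > 0L) {
    mag <- runif(n_na, config$effect_size[1], config$effect_size[2])
    sign_up <- runif(n_na) < config$nonadditive_up_share
    dev[planted] <- ifelse(sign_up, mag, -mag)
  }
  f1 <- mpv * 2^dev
  f1 <- f1 / sum(f1)
  gen <- function(k) {
    x <- mpv * 2^(dev * (1 - config$attenuation)^k)
    x / sum(x)
  }
  f2 <- gen(1); f3 <- gen(2); f4 <- gen(3)
  nat <- mpv * 2^rnorm(n, 0, 0.15)
  nat[mpv == 0] <- 0
  nat <- nat / sum(nat)

  cls <- rep("additive", n)
  cls[dev > 0] <- "nonadditive_above"
  cls[dev < 0] <- "nonadditive_below"
  out <- data.frame(
    gene_id = ref$genes$gene_id,
    abund_Br = br, abund_Bo = bo, abund_F1 = f1, abund_F2 = f2,
    abund_F3 = f3, abund_F4 = f4, abund_N = nat,
    class = cls, log2_dev = dev,
    parental_bias = ifelse(br > bo, "Br>Bo", ifelse(br < bo, "Br<Bo", "Br=Bo")),
    antisense = ref$genes$antisense,
    ambiguity_partner = ref$genes$ambiguity_partner,
    stringsAsFactors = FALSE
  )
  class(out) <- c("SimulationTruth", "data.frame")
  out
}

# In-place substitution / N-masking over a read vector, event count binomial
# in (reads x read length) at `rate`.
.mutate_reads <- function(reads, rate, mask_n = FALSE) {
  if (rate <= 0 || length(reads) == 0L) return(reads)
  m <- rbinom(1L, length(reads) * 35L, rate)
  if (m == 0L) return(reads)
  i <- sample.int(length(reads), m, replace = TRUE)
  p <- sample.int(35L, m, replace = TRUE)
  if (mask_n) {
    for (e in seq_len(m)) substr(reads[i[e]], p[e], p[e]) <- "N"
  } else {
    repl <- sample(.bases, m, replace = TRUE)
    for (e in seq_len(m)) {
      old <- substr(reads[i[e]], p[e], p[e])
      b <- repl[e]
      if (b == old) b <- .bases[match(old, .bases) %% 4L + 1L]
      substr(reads[i[e]], p[e], p[e]) <- b
    }
  }
  reads
}

#' Simulate the 35-bp tag reads of one library
#'
#' Reads are drawn multinomially from the library's true gene abundances.
#' Each read starts at one of its gene's CATG tag sites (3'-most with
#' probability `canonical_site_prob`, otherwise uniformly among internal
#' sites), on the antisense strand for the configured fraction of reads of
#' antisense-flagged genes. Adaptor contamination replaces whole reads;
#' substitution errors and N masking are applied per base. All randomness
#' derives from the config seed plus the library's fixed index, so each
#' library is reproducible independently of the others.
#'
#' @param ref a `SimulatedReference`.
#' @param truth a `SimulationTruth`.
#' @param library_id one of `"Br"`, `"Bo"`, `"F1"`-`"F4"`, `"N"`.
#' @param config the [sim_config()].
#' @return character vector of `depth` reads.
#' @export
simulate_library_reads <- function(ref, truth, library_id, config) {
  stopifnot(inherits(ref, "SimulatedReference"),
            inherits(truth, "SimulationTruth"))
  lib_idx <- match(library_id, SIM_LIBRARIES)
  if (is.na(lib_idx)) stop("unknown library_id: ", library_id)
  set.seed(config$seed + 100L * lib_idx)
  n <- as.integer(config$depth)
  abund <- truth[[paste0("abund_", library_id)]]
  tm <- ref$templates

  is_adapt <- runif(n) < config$adaptor_rate
  nr <- sum(!is_adapt)
  g <- sample.int(config$n_genes, nr, replace = TRUE, prob = abund)
  anti <- ref$genes$antisense[g] & runif(nr) < config$antisense_expression
  anti[anti & tm$k_anti[g] == 0L] <- FALSE
  k <- ifelse(anti, tm$k_anti[g], tm$k_sense[g])
  off <- ifelse(anti, tm$off_anti[g], tm$off_sense[g])
  u <- runif(nr)
  site <- ifelse(k <= 1L | u < config$canonical_site_prob, 1L,
                 2L + as.integer(floor(runif(nr) * (k - 1L))))
  site <- pmin(site, k)
  reads <- character(n)
  reads[!is_adapt] <- tm$reads[off + site]
  reads[is_adapt] <- config$adaptor
  reads <- .mutate_reads(reads, config$error_rate, mask_n = FALSE)
  .mutate_reads(reads, config$n_rate, mask_n = TRUE)
}

#' Simulate and write a full seven-library data set
#'
#' Writes the genome FASTA, gene models GFF3, one FASTQ per library, the
#' truth table TSV and the configuration echo JSON into `out_dir`.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if missing).
#' @param libraries which libraries to emit (default all seven).
#' @return invisible list of file paths plus the in-memory `ref` and
#'   `truth` objects.
#' @export
simulate_reads <- function(config, out_dir,
                           libraries = SIM_LIBRARIES) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ref <- simulate_reference(config)
  truth <- simulate_expression(config, ref)
  genome_path <- file.path(out_dir, "genome.fa")
  gff_path <- file.path(out_dir, "genes.gff3")
  write_fasta(ref$genome, genome_path)
  write_gene_models(ref$genes, gff_path)
  fastq <- character(0)
  for (lib in libraries) {
    reads <- simulate_library_reads(ref, truth, lib, config)
    path <- file.path(out_dir, paste0(lib, ".fastq"))
    write_fastq(reads, path, id_prefix = lib)
    fastq[lib] <- path
  }
  truth_path <- file.path(out_dir, "truth.tsv")
  write.table(truth, truth_path, sep = "\t", quote = FALSE, row.names = FALSE)
  config_path <- file.path(out_dir, "config.json")
  cfg <- unclass(config)
  jsonlite::write_json(cfg, config_path, auto_unbox = TRUE, digits = NA)
  invisible(list(genome = genome_path, gff3 = gff_path, fastq = fastq,
                 truth = truth_path, config = config_path,
                 ref = ref, truth_table = truth))
}
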