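#' Simulate a small RNA read set with known ground truth
#'
#' Draws `n_reads` reads multinomially over the category space
#' (miRNA locus x arm x end offset, piRNA loci, spike-ins). miRNA read cores
#' are taken from the hairpin-sense reference sequence with the
#' Microprocessor-cut end displaced by the genotype's offset distribution
#' (5' end for 5p arms, 3' end for 3p arms; the opposite end is canonical).
#' A 1-3 nt 3' tail is appended with probability `tail_rate`, drawn from the
#' genotype's U-biased alphabet; the truth labels whether the drawn tail
#' happens to match the downstream genomic continuation
#' ("templated lookalike"), since only mismatching tails are decidably
#' untemplated. piRNA and spike-in reads are emitted untailed. Reads are in
#' DNA alphabet (U written as T) and mature-strand orientation.
#'
#' @param bundle a `ref_bundle` from [make_reference()].
#' @param genotype a `genotype_spec` covering all miRNA loci in the bundle.
#' @param n_reads number of reads to emit (exactly; truth counts sum to it).
#' @param replicate_id replicate label recorded in read ids.
#' @param seed integer seed; byte-identical output for fixed inputs.
#' @param class_props relative read mass of the three feature classes; classes
#'   with no loci in the bundle are dropped and the rest renormalized.
#' @param umi if TRUE, attach a random 8-mer UMI to each read.
#' @return list with `reads` (data.frame: id, sequence, optional umi),
#'   `read_truth` (one row per read: class, feature, locus, arm, offset, tail,
#'   tail_is_untemplated, templated_lookalike) and `truth` (per-category
#'   probabilities and realized counts).
#' @export
simulate_reads <- function(bundle, genotype, n_reads, replicate_id = 1,
                           seed = 1,
                           class_props = c(miRNA = 0.55, piRNA = 0.40,
                                           spikein = 0.05),
                           umi = FALSE) {
  stopifnot(inherits(bundle, "ref_bundle"), inherits(genotype, "genotype_spec"),
            n_reads > 0)
  m <- bundle$mirna_loci
  if (nrow(m) && !all(m$name %in% genotype$loci))
    stop("genotype does not cover all loci in the bundle")

  withr::with_seed(seed, {
    flank <- 10L
    loc <- mature_local_coords(bundle)
    cats <- list()
    if (nrow(m)) {
      for (i in seq_len(nrow(m))) {
        ext <- hairpin_sense_seq(bundle, m$name[i], flank)
        w_locus <- m$base_abundance[i] * genotype$multipliers[[m$name[i]]]
        for (arm in c("5p", "3p")) {
          d <- genotype_offset_dist(genotype, m$name[i], arm)
          offs <- as.integer(names(d))
          for (j in seq_along(offs)) {
            off <- offs[j]
            if (arm == "5p") {
              s <- loc$l5_start[i] + off; e <- loc$l5_end[i]
            } else {
              s <- loc$l3_start[i]; e <- loc$l3_end[i] + off
            }
            if (s < -flank || e > nchar(ext) - 2L * flank + flank)
              stop("offset pushes read outside hairpin+flank")
            core <- substr(ext, s + flank + 1L, e + flank)
            down <- substr(ext, e + flank + 1L, e + flank + 3L)
            cats[[length(cats) + 1L]] <- data.frame(
              class = "miRNA", locus = m$name[i], arm = arm, offset = off,
              feature = paste0(m$name[i], "-", arm), core = core,
              downstream = down, w = w_locus * 0.5 * d[j],
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    p <- bundle$pirna_loci
    if (nrow(p)) {
      for (i in seq_len(nrow(p))) {
        sq <- contig_substr(bundle$contigs[[p$contig[i]]], p$start[i], p$end[i])
        if (p$strand[i] == "-") sq <- revcomp(sq)
        cats[[length(cats) + 1L]] <- data.frame(
          class = "piRNA", locus = p$name[i], arm = NA_character_,
          offset = NA_integer_, feature = p$name[i], core = sq,
          downstream = "", w = p$base_abundance[i], stringsAsFactors = FALSE)
      }
    }
    s <- bundle$spikeins
    if (nrow(s)) {
      for (i in seq_len(nrow(s))) {
        cats[[length(cats) + 1L]] <- data.frame(
          class = "spikein", locus = s$name[i], arm = NA_character_,
          offset = NA_integer_, feature = s$name[i], core = s$sequence[i],
          downstream = "", w = s$input_amount[i], stringsAsFactors = FALSE)
      }
    }
    cats <- do.call(rbind, cats)
    if (is.null(cats) || !nrow(cats)) stop("bundle holds no loci to simulate")

    # class shares, renormalized over classes present
    present <- intersect(names(class_props), unique(cats$class))
    share <- class_props[present] / sum(class_props[present])
    prob <- numeric(nrow(cats))
    for (cl in present) {
      idx <- cats$class == cl
      prob[idx] <- share[[cl]] * cats$w[idx] / sum(cats$w[idx])
    }
    counts <- as.vector(rmultinom(1, n_reads, prob))

    expanded <- rep.int(seq_len(nrow(cats)), counts)
    idx <- expanded[sample.int(length(expanded))]  # shuffled read order
    rt <- cats[idx, c("class", "locus", "arm", "offset", "feature")]
    seqs <- cats$core[idx]
    down <- cats$downstream[idx]

    # 3' tails on miRNA reads
    tail <- character(length(idx))
    is_mir <- rt$class == "miRNA"
    has_tail <- is_mir & runif(length(idx)) < genotype$tail_rate
    if (any(has_tail)) {
      n_t <- sum(has_tail)
      tl <- sample(1:3, n_t, replace = TRUE,
                   prob = genotype$tail_length_weights)
      aw <- genotype$tail_alphabet_weights
      b <- function() sample(names(aw), n_t, replace = TRUE, prob = aw)
      full <- paste0(b(), b(), b())
      tail[has_tail] <- substr(full, 1, tl)
    }
    seqs <- paste0(seqs, tail)
    if (any(nchar(seqs) < 16 | nchar(seqs) > 30))
      stop("constructed read length outside 16-30 nt")

    lookalike <- ifelse(tail == "", NA,
                        tail == substr(down, 1, nchar(tail)))
    rt$tail <- tail
    rt$tail_is_untemplated <- ifelse(tail == "", NA, !lookalike)
    rt$templated_lookalike <- lookalike
    rt$id <- sprintf("%s_rep%s_r%06d", genotype$name, replicate_id,
                     seq_along(idx))
    rownames(rt) <- NULL

    reads <- data.frame(id = rt$id, sequence = seqs, stringsAsFactors = FALSE)
    if (umi) reads$umi <- random_dna(nrow(reads), 8)

    truth <- cats[, c("class", "locus", "arm", "offset", "feature")]
    truth$prob <- prob
    truth$count <- counts
    rownames(truth) <- NULL
    list(reads = reads, read_truth = rt[, c("id", "class", "feature", "locus",
                                            "arm", "offset", "tail",
                                            "tail_is_untemplated",
                                            "templated_lookalike")],
         truth = truth)
  })
}

#' Write reads to FASTQ (Phred+33, constant Q40)
#'
#' UMIs, when present, are appended to the read id as `_UMI:<seq>`.
#'
#' @param reads data.frame with `id` and `sequence` (optionally `umi`).
#' @param path output FASTQ path.
#' @return invisible path.
#' @export
write_reads_fastq <- function(reads, path) {
  ids <- reads$id
  if (!is.null(reads$umi)) ids <- paste0(ids, "_UMI:", reads$umi)
  dna <- Biostrings::DNAStringSet(setNames(reads$sequence, ids))
  q <- Biostrings::PhredQuality(strrep("I", nchar(reads$sequence)))
  qs <- Biostrings::QualityScaledDNAStringSet(dna, q)
  Biostrings::writeQualityScaledXStringSet(qs, path)
  invisible(path)
}

#' Read a FASTQ or FASTA file into a read table
#'
#' UMIs encoded in the id as `_UMI:<seq>` are split into their own column.
#'
#' @param path input path.
#' @param format "fastq" or "fasta".
#' @return data.frame with `id`, `sequence`, and `umi` where present.
#' @export
read_reads <- function(path, format = "fastq") {
  x <- Biostrings::readDNAStringSet(path, format = format)
  ids <- names(x)
  df <- data.frame(id = ids, sequence = as.character(x),
                   stringsAsFactors = FALSE)
  has_umi <- grepl("_UMI:", ids, fixed = TRUE)
  if (any(has_umi)) {
    df$umi <- ifelse(has_umi, sub(".*_UMI:", "", ids), NA_character_)
    df$id <- sub("_UMI:.*$", "", ids)
  }
  rownames(df) <- NULL
  df
}
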