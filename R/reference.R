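#' Generate a synthetic miRNA/piRNA/spike-in reference bundle
#'
#' Builds a small synthetic genome carrying miRNA hairpin loci (with annotated
#' 5p and 3p mature arms), piRNA loci, and a set of spike-in sequences that are
#' absent from the genomic contigs. Hairpins are constructed as
#' lower-stem / 5p arm / apical loop / 3p arm / lower-stem, with the 3p arm an
#' imperfect reverse complement of the 5p arm so the locus folds like a
#' pri-miRNA. The annotated mature-arm boundaries define the canonical
#' Microprocessor cleavage coordinates used by the isomiR fidelity analysis.
#'
#' All contig coordinates are 0-based half-open; [write_reference()] converts
#' to 1-based inclusive GFF3 on output.
#'
#' @param n_mirna,n_pirna,n_spikein number of loci of each class.
#' @param seed integer seed; output is byte-identical for a fixed seed/config.
#' @param arm_len mature arm length (nt).
#' @param loop_len apical loop length (nt).
#' @param lower_stem lower stem length on each side of the arms (nt).
#' @param flank guaranteed flanking genomic sequence on each side of every
#'   hairpin (nt, must be >= 10).
#' @param frac_minus fraction of miRNA loci placed on the minus strand.
#' @param frac_clustered fraction of miRNA loci assigned to genomic clusters.
#' @param frac_intronic fraction of miRNA loci flagged intronic.
#' @param frac_idr1_sensitive fraction of miRNA loci flagged IDR1-sensitive
#'   (ground truth only; downstream genotype specs realize the abundance
#'   effect).
#' @return A `ref_bundle` list with elements `contigs` (named character),
#'   `mirna_loci`, `pirna_loci`, `spikeins` (data frames) and the generator
#'   settings as attributes.
#' @export
make_reference <- function(n_mirna = 10, n_pirna = 20, n_spikein = 4,
                           seed = 1, arm_len = 22, loop_len = 15,
                           lower_stem = 8, flank = 30,
                           frac_minus = 0.3, frac_clustered = 0.3,
                           frac_intronic = 0.3, frac_idr1_sensitive = 0.25) {
  stopifnot(n_mirna >= 0, n_pirna >= 0, n_spikein >= 0, flank >= 10)
  withr::with_seed(seed, {
    hp_len <- 2L * lower_stem + 2L * arm_len + loop_len
    gap <- flank + 20L

    build_hairpin <- function() {
      arm5 <- random_dna(1, arm_len)
      arm3 <- revcomp(arm5)
      # a few mismatches so the two arms are sequence-distinct
      pos <- sample(seq_len(arm_len), 4)
      for (p in pos) {
        cur <- substr(arm3, p, p)
        substr(arm3, p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
      }
      paste0(random_dna(1, lower_stem), arm5, random_dna(1, loop_len),
             arm3, random_dna(1, lower_stem))
    }

    # -- miRNA contig ------------------------------------------------------
    mirna <- NULL
    contig1 <- random_dna(1, gap)
    if (n_mirna > 0) {
      strand <- ifelse(runif(n_mirna) < frac_minus, "-", "+")
      # cluster assignment: consecutive pairs share a cluster id
      n_clust <- floor(n_mirna * frac_clustered / 2)
      cluster_id <- rep(NA_character_, n_mirna)
      if (n_clust > 0) {
        idx <- seq_len(2 * n_clust)
        cluster_id[idx] <- rep(sprintf("cl%02d", seq_len(n_clust)), each = 2)
      }
      rows <- vector("list", n_mirna)
      for (i in seq_len(n_mirna)) {
        hp <- build_hairpin()
        hp_start <- nchar(contig1)
        ins <- if (strand[i] == "+") hp else revcomp(hp)
        contig1 <- paste0(contig1, ins, random_dna(1, gap))
        hp_end <- hp_start + hp_len
        # mature intervals in hairpin-sense local coordinates
        l5s <- lower_stem; l5e <- lower_stem + arm_len
        l3s <- lower_stem + arm_len + loop_len
        l3e <- l3s + arm_len
        if (strand[i] == "+") {
          m5 <- c(hp_start + l5s, hp_start + l5e)
          m3 <- c(hp_start + l3s, hp_start + l3e)
        } else {
          m5 <- c(hp_end - l5e, hp_end - l5s)
          m3 <- c(hp_end - l3e, hp_end - l3s)
        }
        rows[[i]] <- data.frame(
          name = sprintf("syn-mir-%02d", i), contig = "chrI",
          strand = strand[i], hp_start = hp_start, hp_end = hp_end,
          m5_start = m5[1], m5_end = m5[2], m3_start = m3[1], m3_end = m3[2],
          cluster_id = cluster_id[i],
          intronic = runif(1) < frac_intronic,
          idr1_sensitive = runif(1) < frac_idr1_sensitive,
          base_abundance = exp(rnorm(1, 0, 0.8)),
          stringsAsFactors = FALSE
        )
      }
      mirna <- do.call(rbind, rows)
    } else {
      mirna <- data.frame(name = character(), contig = character(),
                          strand = character(), hp_start = integer(),
                          hp_end = integer(), m5_start = integer(),
                          m5_end = integer(), m3_start = integer(),
                          m3_end = integer(), cluster_id = character(),
                          intronic = logical(), idr1_sensitive = logical(),
                          base_abundance = numeric(),
                          stringsAsFactors = FALSE)
    }

    # -- piRNA contig (21U-RNA-like: 21 nt starting with T) ---------------
    contig2 <- random_dna(1, 50)
    pirna <- data.frame(name = character(), contig = character(),
                        start = integer(), end = integer(),
                        strand = character(), base_abundance = numeric(),
                        stringsAsFactors = FALSE)
    if (n_pirna > 0) {
      rows <- vector("list", n_pirna)
      for (i in seq_len(n_pirna)) {
        s <- paste0("T", random_dna(1, 20))
        st <- nchar(contig2)
        contig2 <- paste0(contig2, s, random_dna(1, 30))
        rows[[i]] <- data.frame(
          name = sprintf("21ur-%03d", i), contig = "chrIV",
          start = st, end = st + 21L, strand = "+",
          base_abundance = exp(rnorm(1, 0, 0.5)),
          stringsAsFactors = FALSE)
      }
      pirna <- do.call(rbind, rows)
    }

    contigs <- c(chrI = contig1, chrIV = contig2)

    # -- spike-ins: must not occur in any contig --------------------------
    spike <- data.frame(name = character(), sequence = character(),
                        input_amount = numeric(), stringsAsFactors = FALSE)
    if (n_spikein > 0) {
      seqs <- character(n_spikein)
      for (i in seq_len(n_spikein)) {
        repeat {
          s <- random_dna(1, 22)
          if (!any(vapply(contigs, function(ct) grepl(s, ct, fixed = TRUE),
                          logical(1))) && !(s %in% seqs)) break
        }
        seqs[i] <- s
      }
      spike <- data.frame(name = sprintf("spike-%02d", seq_len(n_spikein)),
                          sequence = seqs,
                          input_amount = 2 ^ (seq_len(n_spikein) - 1),
                          stringsAsFactors = FALSE)
    }

    bundle <- structure(
      list(contigs = contigs, mirna_loci = mirna, pirna_loci = pirna,
           spikeins = spike),
      class = "ref_bundle", flank = flank, arm_len = arm_len,
      loop_len = loop_len, lower_stem = lower_stem, seed = seed)
    validate_reference(bundle)
    bundle
  })
}

#' Validate a reference bundle's structural invariants
#'
#' Checks that every annotated interval lies within its contig, mature arms
#' are nested and non-overlapping within their hairpin with 5p preceding 3p
#' in hairpin sense, names are unique across feature classes, every hairpin
#' has at least 10 nt of flank available, and spike-in sequences are absent
#' from all contigs.
#'
#' @param bundle a `ref_bundle`.
#' @return The bundle, invisibly; errors describe the first violated invariant.
#' @export
validate_reference <- function(bundle) {
  stopifnot(inherits(bundle, "ref_bundle"))
  m <- bundle$mirna_loci
  clen <- nchar(bundle$contigs)
  all_names <- c(m$name, bundle$pirna_loci$name, bundle$spikeins$name)
  if (anyDuplicated(all_names))
    stop("locus names are not unique across feature classes")
  if (nrow(m)) {
    if (any(m$hp_start < 0 | m$hp_end > clen[m$contig]))
      stop("hairpin interval outside contig")
    if (any(m$hp_start < 10 | m$hp_end > clen[m$contig] - 10))
      stop("hairpin lacks 10 nt of flanking sequence")
    ok_nested <- m$m5_start >= m$hp_start & m$m5_end <= m$hp_end &
      m$m3_start >= m$hp_start & m$m3_end <= m$hp_end
    if (!all(ok_nested)) stop("mature interval not nested in hairpin")
    # on hairpin sense, 5p must precede 3p without overlap
    loc <- mature_local_coords(bundle)
    if (!all(loc$l5_end <= loc$l3_start))
      stop("mature arms overlap or 3p precedes 5p in hairpin sense")
  }
  p <- bundle$pirna_loci
  if (nrow(p) && any(p$start < 0 | p$end > clen[p$contig]))
    stop("piRNA interval outside contig")
  s <- bundle$spikeins
  if (nrow(s)) {
    if (any(nchar(s$sequence) < 16 | nchar(s$sequence) > 30))
      stop("spike-in length outside 16-30 nt")
    hit <- vapply(s$sequence, function(sq)
      any(vapply(bundle$contigs, function(ct) grepl(sq, ct, fixed = TRUE),
                 logical(1))), logical(1))
    if (any(hit)) stop("spike-in sequence present in a contig")
  }
  invisible(bundle)
}

# mature intervals in hairpin-sense local coordinates (0 = hairpin start)
mature_local_coords <- function(bundle) {
  m <- bundle$mirna_loci
  plus <- m$strand == "+"
  l5s <- ifelse(plus, m$m5_start - m$hp_start, m$hp_end - m$m5_end)
  l5e <- ifelse(plus, m$m5_end - m$hp_start, m$hp_end - m$m5_start)
  l3s <- ifelse(plus, m$m3_start - m$hp_start, m$hp_end - m$m3_end)
  l3e <- ifelse(plus, m$m3_end - m$hp_start, m$hp_end - m$m3_start)
  data.frame(name = m$name, l5_start = l5s, l5_end = l5e,
             l3_start = l3s, l3_end = l3e, stringsAsFactors = FALSE)
}

#' Extract the hairpin-sense sequence of a locus with flanks
#'
#' Returns the hairpin plus `flank` nt on each side, oriented 5'->3' along the
#' hairpin (mature-strand) sense; for minus-strand loci this is the reverse
#' complement of the contig interval. Position 0 of the hairpin-local
#' coordinate frame maps to character `flank + 1` of the returned string.
#'
#' @param bundle a `ref_bundle`.
#' @param name miRNA locus name.
#' @param flank flank length (nt); must not exceed the guaranteed flank of the
#'   bundle.
#' @return character scalar.
#' @export
hairpin_sense_seq <- function(bundle, name, flank = 10) {
  m <- bundle$mirna_loci
  i <- match(name, m$name)
  if (is.na(i)) stop("unknown miRNA locus: ", name)
  ct <- bundle$contigs[[m$contig[i]]]
  s <- m$hp_start[i] - flank
  e <- m$hp_end[i] + flank
  if (s < 0 || e > nchar(ct)) stop("requested flank exceeds contig bounds")
  x <- contig_substr(ct, s, e)
  if (m$strand[i] == "-") x <- revcomp(x) else x
}

#' Write a reference bundle to FASTA + GFF3
#'
#' Contigs go to `<prefix>.fa` (60-column wrapped FASTA, spike-ins appended as
#' their own contigs named `spike_<name>` so mappers can see them), and the
#' annotation to `<prefix>.gff3` with feature types
#' `miRNA_primary_transcript`, `miRNA` (Name=<locus>-5p/-3p), `piRNA` and
#' `spikein`, converted to 1-based inclusive coordinates.
#'
#' @param bundle a `ref_bundle`.
#' @param prefix output path prefix.
#' @return invisible character vector of the two paths written.
#' @export
write_reference <- function(bundle, prefix) {
  fa <- paste0(prefix, ".fa")
  gff <- paste0(prefix, ".gff3")
  seqs <- c(bundle$contigs,
            setNames(bundle$spikeins$sequence,
                     paste0("spike_", bundle$spikeins$name)))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), fa, width = 60)

  m <- bundle$mirna_loci
  rows <- list()
  if (nrow(m)) {
    g <- zero_based_to_gff(m$hp_start, m$hp_end)
    rows$hp <- data.frame(seqnames = m$contig, start = g$first, end = g$last,
                          strand = m$strand, type = "miRNA_primary_transcript",
                          Name = m$name, stringsAsFactors = FALSE)
    g5 <- zero_based_to_gff(m$m5_start, m$m5_end)
    g3 <- zero_based_to_gff(m$m3_start, m$m3_end)
    rows$m5 <- data.frame(seqnames = m$contig, start = g5$first, end = g5$last,
                          strand = m$strand, type = "miRNA",
                          Name = paste0(m$name, "-5p"), stringsAsFactors = FALSE)
    rows$m3 <- data.frame(seqnames = m$contig, start = g3$first, end = g3$last,
                          strand = m$strand, type = "miRNA",
                          Name = paste0(m$name, "-3p"), stringsAsFactors = FALSE)
  }
  p <- bundle$pirna_loci
  if (nrow(p)) {
    gp <- zero_based_to_gff(p$start, p$end)
    rows$pi <- data.frame(seqnames = p$contig, start = gp$first, end = gp$last,
                          strand = p$strand, type = "piRNA", Name = p$name,
                          stringsAsFactors = FALSE)
  }
  s <- bundle$spikeins
  if (nrow(s)) {
    rows$sp <- data.frame(seqnames = paste0("spike_", s$name), start = 1L,
                          end = nchar(s$sequence), strand = "+",
                          type = "spikein", Name = s$name,
                          stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(tab$seqnames,
                               IRanges::IRanges(tab$start, tab$end),
                               strand = tab$strand)
  gr$type <- tab$type
  gr$Name <- tab$Name
  gr$ID <- tab$Name
  rtracklayer::export(gr, gff, format = "gff3")
  invisible(c(fa, gff))
}
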