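#' Length-filter and UMI-collapse a read table
#'
#' Retains reads whose length is within `[min_len, max_len]` (inclusive on
#' both ends, the standard small RNA convention) and, when `collapse_umi` is
#' TRUE, collapses records identical in (sequence, UMI) to a single survivor.
#' Reads with the same sequence but different UMIs are distinct molecules and
#' are all retained.
#'
#' @param reads data.frame with `id`, `sequence` and optionally `umi`.
#' @param min_len,max_len inclusive length bounds (nt).
#' @param collapse_umi collapse PCR duplicates by (sequence, UMI)?
#' @return filtered (and possibly collapsed) read data.frame.
#' @export
preprocess_reads <- function(reads, min_len = 16, max_len = 30,
                             collapse_umi = FALSE) {
  stopifnot(is.data.frame(reads), all(c("id", "sequence") %in% names(reads)))
  if (any(!nzchar(reads$sequence)))
    stop("empty read sequence at record ", which(!nzchar(reads$sequence))[1])
  bad <- grepl("[^ACGTN]", reads$sequence)
  if (any(bad))
    stop("non-ACGTN character in read at record ", which(bad)[1])
  len <- nchar(reads$sequence)
  out <- reads[len >= min_len & len <= max_len, , drop = FALSE]
  if (collapse_umi) {
    if (is.null(out$umi)) stop("collapse_umi = TRUE but reads carry no UMI")
    key <- paste(out$sequence, out$umi, sep = "\r")
    out <- out[!duplicated(key), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

# alignment target set: miRNA hairpins +/- flank (hairpin sense), piRNA and
# spike-in sequences
build_alignment_index <- function(bundle, flank = 10) {
  stopifnot(inherits(bundle, "ref_bundle"))
  m <- bundle$mirna_loci
  targets <- list()
  if (nrow(m)) {
    loc <- mature_local_coords(bundle)
    for (i in seq_len(nrow(m))) {
      targets[[length(targets) + 1L]] <- list(
        name = m$name[i], class = "miRNA",
        seq = hairpin_sense_seq(bundle, m$name[i], flank), flank = flank,
        l5 = c(loc$l5_start[i], loc$l5_end[i]),
        l3 = c(loc$l3_start[i], loc$l3_end[i]))
    }
  }
  p <- bundle$pirna_loci
  if (nrow(p)) {
    for (i in seq_len(nrow(p))) {
      sq <- contig_substr(bundle$contigs[[p$contig[i]]], p$start[i], p$end[i])
      if (p$strand[i] == "-") sq <- revcomp(sq)
      targets[[length(targets) + 1L]] <-
        list(name = p$name[i], class = "piRNA", seq = sq, flank = 0L)
    }
  }
  s <- bundle$spikeins
  if (nrow(s)) {
    for (i in seq_len(nrow(s))) {
      targets[[length(targets) + 1L]] <-
        list(name = s$name[i], class = "spikein", seq = s$sequence[i],
             flank = 0L)
    }
  }
  structure(targets, class = "alignment_index")
}

# all (possibly overlapping) occurrences of `pat` in `subj`, 1-based
all_occurrences <- function(pat, subj) {
  res <- integer(0)
  from <- 1L
  n <- nchar(subj)
  repeat {
    i <- regexpr(pat, substr(subj, from, n), fixed = TRUE)
    if (i == -1L) break
    pos <- from + as.integer(i) - 1L
    res <- c(res, pos)
    from <- pos + 1L
  }
  res
}

# all exact-substring placements of `core` in targets; returns rows
find_placements <- function(core, targets) {
  rows <- list()
  for (tg in targets) {
    m <- all_occurrences(core, tg$seq)
    if (!length(m)) next
    for (pos in m) {
      rows[[length(rows) + 1L]] <-
        list(target = tg, start = pos - 1L - tg$flank)  # local 0-based
    }
  }
  rows
}

#' Align a read to the reference by exact-core matching with bounded 3' tail
#'
#' For t = 0..3, the read's prefix of length L - t is searched as an exact
#' substring (zero substitutions, no 5' clipping) of every miRNA hairpin
#' +/- flank in hairpin-sense orientation and of every piRNA and spike-in
#' sequence. Only placements at the smallest t (maximal matched core) are
#' reported; each receives fractional weight 1/n over the n reported
#' placements. For miRNA targets the arm is 5p or 3p when the core midpoint
#' lies inside that mature interval, else "other". The matched core must be
#' at least 13 nt (16 nt minimum read length minus the 3 nt tail allowance).
#'
#' @param sequence read sequence (character scalar).
#' @param index an index from [build_alignment_index()], or a `ref_bundle`
#'   (indexed on the fly).
#' @param max_tail maximum unmatched 3' tail length.
#' @param read_id id copied into the output rows.
#' @return data.frame of alignments (read_id, target, class, arm, start, end,
#'   tail, n_hits, weight); zero rows when the read has no placement.
#' @export
align_read <- function(sequence, index, max_tail = 3, read_id = NA_character_) {
  if (inherits(index, "ref_bundle")) index <- build_alignment_index(index)
  L <- nchar(sequence)
  empty <- data.frame(read_id = character(0), target = character(0),
                      class = character(0), arm = character(0),
                      start = integer(0), end = integer(0),
                      tail = character(0), n_hits = integer(0),
                      weight = numeric(0), stringsAsFactors = FALSE)
  for (t in 0:max_tail) {
    core_len <- L - t
    if (core_len < 13) break
    core <- substr(sequence, 1, core_len)
    hits <- find_placements(core, index)
    if (!length(hits)) next
    n <- length(hits)
    rows <- lapply(hits, function(h) {
      tg <- h$target
      start <- h$start
      end <- start + core_len
      arm <- "other"
      if (tg$class == "miRNA") {
        mid <- start + (core_len - 1) / 2
        if (mid >= tg$l5[1] && mid < tg$l5[2]) arm <- "5p"
        else if (mid >= tg$l3[1] && mid < tg$l3[2]) arm <- "3p"
      } else arm <- NA_character_
      data.frame(read_id = read_id, target = tg$name, class = tg$class,
                 arm = arm, start = start, end = end,
                 tail = substr(sequence, core_len + 1, L),
                 n_hits = n, weight = 1 / n, stringsAsFactors = FALSE)
    })
    return(do.call(rbind, rows))
  }
  empty
}

#' Align a read table, deduplicating identical sequences
#'
#' @param reads data.frame with `id` and `sequence`.
#' @param index alignment index or `ref_bundle`.
#' @param max_tail maximum unmatched 3' tail length.
#' @return data.frame of alignments for all reads with >= 1 placement.
#' @export
align_reads <- function(reads, index, max_tail = 3) {
  if (inherits(index, "ref_bundle")) index <- build_alignment_index(index)
  uniq <- unique(reads$sequence)
  per_seq <- lapply(uniq, align_read, index = index, max_tail = max_tail)
  names(per_seq) <- uniq
  out <- lapply(seq_len(nrow(reads)), function(i) {
    a <- per_seq[[reads$sequence[i]]]
    if (!nrow(a)) return(NULL)
    a$read_id <- reads$id[i]
    a
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- align_read("X", index)[0, ]
  rownames(out) <- NULL
  out
}

#' Fractional feature counting for one sample
#'
#' Each read contributes its weight (1/n over its placements) to every
#' feature it aligns to; miRNA counts are kept per arm (`<locus>-5p`,
#' `<locus>-3p`, with loop-straddling cores under `<locus>-other`). The sum
#' of counts equals the number of reads with at least one alignment.
#'
#' @param alignments data.frame from [align_reads()] (one sample).
#' @param bundle the `ref_bundle` the alignments refer to.
#' @return data.frame (feature, class, count) covering all annotated
#'   features, zero-filled.
#' @export
count_features <- function(alignments, bundle) {
  m <- bundle$mirna_loci
  feats <- data.frame(
    feature = c(if (nrow(m)) c(paste0(m$name, "-5p"), paste0(m$name, "-3p"),
                               paste0(m$name, "-other")),
                bundle$pirna_loci$name, bundle$spikeins$name),
    class = c(rep("miRNA", 3 * nrow(m)),
              rep("piRNA", nrow(bundle$pirna_loci)),
              rep("spikein", nrow(bundle$spikeins))),
    stringsAsFactors = FALSE)
  feats$count <- 0
  if (nrow(alignments)) {
    known <- alignments$target %in% c(m$name, bundle$pirna_loci$name,
                                      bundle$spikeins$name)
    if (!all(known))
      stop("alignment references unknown locus: ",
           alignments$target[!known][1])
    key <- ifelse(alignments$class == "miRNA",
                  paste0(alignments$target, "-",
                         ifelse(alignments$arm %in% c("5p", "3p"),
                                alignments$arm, "other")),
                  alignments$target)
    agg <- tapply(alignments$weight, key, sum)
    i <- match(names(agg), feats$feature)
    feats$count[i] <- as.numeric(agg)
  }
  feats
}

#' Assemble a feature x sample count matrix
#'
#' @param sample_counts named list of [count_features()] outputs (one per
#'   sample; names become column names).
#' @return list with `counts` (matrix), `feature_class` (named character).
#' @export
count_matrix <- function(sample_counts) {
  stopifnot(length(sample_counts) >= 1, !is.null(names(sample_counts)))
  f0 <- sample_counts[[1]]$feature
  mat <- vapply(sample_counts, function(x) {
    stopifnot(identical(x$feature, f0))
    x$count
  }, numeric(length(f0)))
  mat <- matrix(mat, nrow = length(f0),
                dimnames = list(f0, names(sample_counts)))
  list(counts = mat,
       feature_class = setNames(sample_counts[[1]]$class, f0))
}

#' Size factors from piRNA totals or spike-in totals
#'
#' s_j = T_j / geometric_mean(T_1..T_n) where T_j is the total count of the
#' chosen feature class in sample j; normalized counts are raw / s_j. The
#' geometric mean of the factors is 1 by construction.
#'
#' @param cm list from [count_matrix()] (or a matrix plus `feature_class`).
#' @param method "pirna_total" or "spikein".
#' @param feature_class needed only when `cm` is a bare matrix.
#' @return named numeric of per-sample size factors with attribute `method`.
#' @export
compute_size_factors <- function(cm, method = c("pirna_total", "spikein"),
                                 feature_class = NULL) {
  method <- match.arg(method)
  if (is.list(cm) && !is.null(cm$counts)) {
    counts <- cm$counts; feature_class <- cm$feature_class
  } else counts <- cm
  stopifnot(ncol(counts) >= 2, !is.null(feature_class))
  cls <- if (method == "pirna_total") "piRNA" else "spikein"
  rows <- names(feature_class)[feature_class == cls]
  totals <- colSums(counts[rows, , drop = FALSE])
  if (any(totals <= 0))
    stop("zero ", cls, " total in sample(s): ",
         paste(colnames(counts)[totals <= 0], collapse = ", "))
  s <- totals / geomean(totals)
  attr(s, "method") <- method
  s
}

#' Normalize a count matrix by size factors
#'
#' @param counts feature x sample matrix.
#' @param sf size factors from [compute_size_factors()].
#' @return normalized matrix.
#' @export
normalize_counts <- function(counts, sf) {
  stopifnot(ncol(counts) == length(sf))
  sweep(counts, 2, sf, "/")
}

#' Simplified differential abundance on normalized small RNA counts
#'
#' Per feature: baseMean is the mean normalized count over all samples;
#' log2FC is the difference in mean log2(normalized + 0.5) between treatment
#' and control; the p-value is a Welch two-sample t-test on the same
#' log2-scale values; Benjamini-Hochberg adjustment is applied over the
#' features passing the detection filter (baseMean > `min_mean`). Calls:
#' "low" when baseMean <= min_mean, "down"/"up" when padj < alpha and
#' |log2FC| exceeds the threshold in the corresponding direction, else "ns".
#' This is a deliberately self-contained replacement for a negative-binomial
#' Wald test: no dispersion shrinkage is performed.
#'
#' @param counts feature x sample raw count matrix.
#' @param sf per-sample size factors.
#' @param groups character/factor of sample group labels (length ncol).
#' @param treatment,control group labels to contrast (treatment - control).
#' @param lfc_threshold,alpha,min_mean call thresholds.
#' @return `de_result` data.frame: feature, baseMean, log2FC, p, padj, call.
#' @export
differential_abundance <- function(counts, sf, groups, treatment, control,
                                   lfc_threshold = 1, alpha = 0.05,
                                   min_mean = 5) {
  stopifnot(length(groups) == ncol(counts))
  a <- which(groups == treatment); b <- which(groups == control)
  if (length(a) < 2 || length(b) < 2)
    stop("each contrasted group needs at least 2 replicates")
  norm <- normalize_counts(counts, sf)
  lg <- log2(norm + 0.5)
  baseMean <- rowMeans(norm)
  log2FC <- rowMeans(lg[, a, drop = FALSE]) - rowMeans(lg[, b, drop = FALSE])
  p <- vapply(seq_len(nrow(lg)), function(i) {
    xa <- lg[i, a]; xb <- lg[i, b]
    tryCatch(t.test(xa, xb)$p.value,
             error = function(e)
               if (isTRUE(all.equal(mean(xa), mean(xb)))) 1 else 0)
  }, numeric(1))
  tested <- baseMean > min_mean
  padj <- rep(NA_real_, length(p))
  padj[tested] <- p.adjust(p[tested], method = "BH")
  call <- rep("ns", length(p))
  call[tested & !is.na(padj) & padj < alpha & log2FC < -lfc_threshold] <- "down"
  call[tested & !is.na(padj) & padj < alpha & log2FC > lfc_threshold] <- "up"
  call[!tested] <- "low"
  out <- data.frame(feature = rownames(counts), baseMean = baseMean,
                    log2FC = log2FC, p = p, padj = padj, call = call,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("de_result", "data.frame")
  out
}
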