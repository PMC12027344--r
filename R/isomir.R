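#' Call the templated status of a 3' tail
#'
#' A tail is `templated_ambiguous` when it matches the genomic continuation
#' base-for-base (it could be genuine alternative cleavage or a coincidental
#' templated-looking addition) and `untemplated_unambiguous` when any
#' position mismatches; only the latter can be removed as a definite
#' untemplated addition.
#'
#' @param tail 3' tail string (0-3 nt; "" gives "none").
#' @param downstream_genomic genomic sequence immediately 3' of the matched
#'   core, at least as long as the tail.
#' @return one of "none", "templated_ambiguous", "untemplated_unambiguous".
#' @export
call_tail_status <- function(tail, downstream_genomic) {
  if (nchar(tail) > 3) stop("tail longer than 3 nt")
  if (!nzchar(tail)) return("none")
  if (nchar(downstream_genomic) < nchar(tail))
    stop("downstream genomic sequence shorter than tail")
  if (tail == substr(downstream_genomic, 1, nchar(tail)))
    "templated_ambiguous" else "untemplated_unambiguous"
}

#' Classify an aligned miRNA read as an isomiR
#'
#' Computes signed end offsets (observed - canonical, along the hairpin
#' 5'->3' sense) against the annotated mature ends of the aligned arm, and
#' the 3' tail status from the genomic continuation. Under this sign
#' convention a shift "toward the basal junction" is -1 on the 5p arm's 5'
#' end and +1 on the 3p arm's 3' end. A templated-ambiguous tail is counted
#' as part of the templated 3' coordinate (it cannot be distinguished from
#' alternative cleavage), so it shifts `offset3` by its length.
#'
#' @param aln one alignment row (from [align_read()]) with arm "5p" or "3p".
#' @param bundle the `ref_bundle`.
#' @param flank flank used at alignment time.
#' @return `isomir_record` data.frame row: locus, arm, offset5, offset3,
#'   tail, tail_status, weight.
#' @export
classify_isomir <- function(aln, bundle, flank = 10) {
  stopifnot(aln$arm %in% c("5p", "3p"))
  m <- bundle$mirna_loci
  i <- match(aln$target, m$name)
  if (is.na(i)) stop("alignment references unknown locus: ", aln$target)
  ext <- hairpin_sense_seq(bundle, aln$target, flank)
  hp_len <- nchar(ext) - 2L * flank
  if (aln$start < -flank || aln$end > hp_len + flank)
    stop("alignment core outside hairpin +/- flank")
  loc <- mature_local_coords(bundle)[i, ]
  can <- if (aln$arm == "5p") c(loc$l5_start, loc$l5_end) else
    c(loc$l3_start, loc$l3_end)
  down <- substr(ext, aln$end + flank + 1L, nchar(ext))
  status <- call_tail_status(aln$tail, down)
  end_templated <- aln$end +
    if (status == "templated_ambiguous") nchar(aln$tail) else 0L
  out <- data.frame(locus = aln$target, arm = aln$arm,
                    offset5 = aln$start - can[1],
                    offset3 = end_templated - can[2],
                    tail = aln$tail, tail_status = status,
                    weight = aln$weight, stringsAsFactors = FALSE)
  class(out) <- c("isomir_record", "data.frame")
  out
}

#' Classify all 5p/3p miRNA alignments of a sample
#'
#' @param alignments data.frame from [align_reads()].
#' @param bundle the `ref_bundle`.
#' @param flank flank used at alignment time.
#' @return data.frame of isomiR records (zero rows if none).
#' @export
classify_isomirs <- function(alignments, bundle, flank = 10) {
  keep <- alignments$class == "miRNA" & alignments$arm %in% c("5p", "3p")
  a <- alignments[keep, , drop = FALSE]
  if (!nrow(a))
    return(data.frame(locus = character(0), arm = character(0),
                      offset5 = integer(0), offset3 = integer(0),
                      tail = character(0), tail_status = character(0),
                      weight = numeric(0), stringsAsFactors = FALSE))
  # classification depends only on (target, arm, start, end, tail): dedupe
  key <- paste(a$target, a$arm, a$start, a$end, a$tail, sep = "\r")
  u <- !duplicated(key)
  proto <- do.call(rbind, lapply(which(u), function(j)
    classify_isomir(a[j, ], bundle, flank)))
  idx <- match(key, key[u])
  out <- proto[idx, ]
  out$weight <- a$weight
  rownames(out) <- NULL
  out
}

#' Aggregate the Microprocessor-cut end distribution of one arm
#'
#' Removes records with unambiguous untemplated 3' additions, then
#' aggregates read weight by the offset of the end Microprocessor generates:
#' the 5' end (offset5) for 5p arms, the 3' end (offset3, templated-tail
#' inclusive) for 3p arms. Arms whose expression (baseMean) does not exceed
#' `min_base_mean` return an empty marker and are excluded from fidelity
#' analysis.
#'
#' @param records isomiR records of a single (locus, arm).
#' @param base_mean the arm's baseMean from the matching differential
#'   abundance analysis.
#' @param min_base_mean inclusion threshold (arm kept when baseMean exceeds
#'   it).
#' @return `end_distribution` list: locus, arm, end_of_interest, offsets
#'   (named fractions), total_weight, pct_canonical; or NULL (empty marker)
#'   when under-expressed or no usable records remain.
#' @export
end_distribution <- function(records, base_mean, min_base_mean = 25) {
  if (!nrow(records)) return(NULL)
  if (length(unique(records$locus)) > 1 || length(unique(records$arm)) > 1)
    stop("records mix loci or arms")
  if (base_mean <= min_base_mean) return(NULL)
  keep <- records$tail_status != "untemplated_unambiguous"
  r <- records[keep, , drop = FALSE]
  if (!nrow(r)) return(NULL)
  arm <- r$arm[1]
  off <- if (arm == "5p") r$offset5 else r$offset3
  agg <- tapply(r$weight, off, sum)
  frac <- agg / sum(agg)
  structure(list(locus = r$locus[1], arm = arm,
                 end_of_interest = if (arm == "5p") "five_prime" else
                   "three_prime",
                 offsets = setNames(as.numeric(frac), names(frac)),
                 total_weight = sum(agg),
                 pct_canonical = 100 * unname(
                   if ("0" %in% names(frac)) frac[["0"]] else 0)),
            class = "end_distribution")
}

#' End distributions for every expressed arm of a sample
#'
#' @param records isomiR records (all arms).
#' @param de `de_result` providing baseMean per `<locus>-<arm>` feature.
#' @param min_base_mean inclusion threshold.
#' @return named list of `end_distribution` objects (names `<locus>-<arm>`),
#'   under-expressed arms omitted.
#' @export
end_distributions <- function(records, de, min_base_mean = 25) {
  if (!nrow(records)) return(list())
  key <- paste0(records$locus, "-", records$arm)
  out <- list()
  for (k in unique(key)) {
    bm <- de$baseMean[match(k, de$feature)]
    if (is.na(bm)) next
    d <- end_distribution(records[key == k, , drop = FALSE], bm,
                          min_base_mean)
    if (!is.null(d)) out[[k]] <- d
  }
  out
}

#' Compare cleavage fidelity between two genotypes for one arm
#'
#' Canonical / non-canonical weights are rounded half-to-even to integer
#' counts and compared by a two-sided Fisher exact test on the 2x2 table.
#' The shift direction reported is the sign of the modal non-canonical
#' offset in the second (mutant) distribution.
#'
#' @param dist_a,dist_b `end_distribution` objects for the same (locus, arm),
#'   typically control and mutant.
#' @return one-row data.frame: locus, arm, pct_canonical_a/_b, canonical and
#'   non-canonical integer counts per genotype, p, shift_direction (-1, 0,
#'   +1), delta_pct (b - a).
#' @export
compare_fidelity <- function(dist_a, dist_b) {
  stopifnot(inherits(dist_a, "end_distribution"),
            inherits(dist_b, "end_distribution"),
            dist_a$locus == dist_b$locus, dist_a$arm == dist_b$arm)
  counts <- function(d) {
    tot <- round(d$total_weight)
    can <- round(d$total_weight * d$pct_canonical / 100)
    c(can = can, non = tot - can)
  }
  ca <- counts(dist_a); cb <- counts(dist_b)
  if (sum(ca) == 0 || sum(cb) == 0)
    stop("zero total in one genotype; comparison skipped")
  p <- fisher.test(matrix(c(ca, cb), nrow = 2, byrow = TRUE))$p.value
  noncan <- dist_b$offsets[names(dist_b$offsets) != "0"]
  shift <- if (!length(noncan)) 0L else
    sign(as.integer(names(noncan)[which.max(noncan)]))
  data.frame(locus = dist_a$locus, arm = dist_a$arm,
             pct_canonical_a = dist_a$pct_canonical,
             pct_canonical_b = dist_b$pct_canonical,
             can_a = ca[["can"]], non_a = ca[["non"]],
             can_b = cb[["can"]], non_b = cb[["non"]],
             p = p, shift_direction = shift,
             delta_pct = dist_b$pct_canonical - dist_a$pct_canonical,
             stringsAsFactors = FALSE)
}

#' Genotype-wide cleavage fidelity comparison with BH adjustment
#'
#' Runs [compare_fidelity()] on every arm present in both genotypes, adjusts
#' p-values by Benjamini-Hochberg across all compared arms, and flags a
#' significant fidelity change when padj < `alpha` AND the absolute change
#' in percent-canonical is at least `min_delta_pct` points (the effect-size
#' floor suppresses trivially significant tiny shifts at high depth).
#'
#' @param dists_a,dists_b named lists from [end_distributions()] for the two
#'   genotypes.
#' @param alpha significance level on padj.
#' @param min_delta_pct minimum |delta pct_canonical| for a call.
#' @return data.frame with one row per shared arm plus padj and
#'   `significant` columns.
#' @export
fidelity_comparison <- function(dists_a, dists_b, alpha = 0.05,
                                min_delta_pct = 10) {
  shared <- intersect(names(dists_a), names(dists_b))
  if (!length(shared))
    return(data.frame(locus = character(0), arm = character(0)))
  rows <- do.call(rbind, lapply(shared, function(k)
    compare_fidelity(dists_a[[k]], dists_b[[k]])))
  rows$padj <- p.adjust(rows$p, method = "BH")
  rows$significant <- rows$padj < alpha & abs(rows$delta_pct) >= min_delta_pct
  rownames(rows) <- NULL
  rows
}
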