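#' Construct a genotype specification for read simulation
#'
#' A genotype spec encodes, per miRNA locus, the abundance multiplier relative
#' to the reference baseline, the distribution of signed end offsets at the
#' Microprocessor-cut end of each arm (5' end of the 5p arm, 3' end of the 3p
#' arm), and the 3' tailing model. Offsets follow the hairpin 5'->3' sign
#' convention: negative = upstream, positive = downstream, so "toward the
#' basal junction" is -1 on the 5p 5' end and +1 on the 3p 3' end.
#'
#' @param name genotype label, e.g. "WT" or "dIDR1".
#' @param loci character vector of miRNA locus names covered by this genotype.
#' @param multipliers named positive numeric; per-locus abundance multiplier
#'   (unnamed scalar recycles to all loci; default 1).
#' @param offset5p,offset3p named probability vectors over signed offsets
#'   (names like "-1","0","1") for the Microprocessor-cut end of each arm.
#' @param offset_overrides optional named list `locus -> list(`5p` = dist,
#'   `3p` = dist)` for loci with genotype-specific cleavage-site shifts
#'   (e.g. a mir-259-like 1 bp shift toward the basal junction).
#' @param tail_rate probability that a read carries a 1-3 nt untemplated-drawn
#'   3' tail.
#' @param tail_alphabet_weights named weights over A/C/G/T for tail bases;
#'   the default is uridine-biased (U is written as T in DNA space).
#' @param tail_length_weights weights over tail lengths 1..3.
#' @return a `genotype_spec` list.
#' @export
genotype_spec <- function(name, loci,
                          multipliers = 1,
                          offset5p = c(`-1` = 0.05, `0` = 0.90, `1` = 0.05),
                          offset3p = c(`-1` = 0.05, `0` = 0.90, `1` = 0.05),
                          offset_overrides = NULL,
                          tail_rate = 0.1,
                          tail_alphabet_weights = c(A = 0.10, C = 0.05,
                                                    G = 0.05, T = 0.80),
                          tail_length_weights = c(0.6, 0.3, 0.1)) {
  if (is.null(names(multipliers))) {
    stopifnot(length(multipliers) == 1)
    multipliers <- setNames(rep(multipliers, length(loci)), loci)
  }
  if (!all(loci %in% names(multipliers)))
    stop("genotype does not cover all loci")
  stopifnot(all(multipliers > 0), tail_rate >= 0, tail_rate <= 1)
  check_dist <- function(d) {
    stopifnot(!is.null(names(d)), all(d >= 0),
              abs(sum(d) - 1) < 1e-9,
              !anyNA(suppressWarnings(as.integer(names(d)))))
  }
  check_dist(offset5p); check_dist(offset3p)
  if (!is.null(offset_overrides)) {
    stopifnot(all(names(offset_overrides) %in% loci))
    lapply(offset_overrides, function(o) lapply(o, check_dist))
  }
  structure(list(name = name, loci = loci,
                 multipliers = multipliers[loci],
                 offset5p = offset5p, offset3p = offset3p,
                 offset_overrides = offset_overrides,
                 tail_rate = tail_rate,
                 tail_alphabet_weights = tail_alphabet_weights /
                   sum(tail_alphabet_weights),
                 tail_length_weights = tail_length_weights /
                   sum(tail_length_weights)),
            class = "genotype_spec")
}

# offset distribution for (locus, arm) under a genotype
genotype_offset_dist <- function(genotype, locus, arm) {
  ov <- genotype$offset_overrides
  if (!is.null(ov) && locus %in% names(ov) && arm %in% names(ov[[locus]]))
    return(ov[[locus]][[arm]])
  if (arm == "5p") genotype$offset5p else genotype$offset3p
}
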