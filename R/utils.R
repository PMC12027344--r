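#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif rbinom rmultinom t.test fisher.test phyper
#'   cor.test p.adjust sd complete.cases setNames coef resid
#' @importFrom utils head read.csv write.csv read.delim write.table
NULL

geomean <- function(x) exp(mean(log(x)))

# 0-based half-open [start, end) <-> GFF3 1-based inclusive [first, last]
zero_based_to_gff <- function(start, end) {
  stopifnot(all(end > start))
  list(first = start + 1L, last = end)
}

gff_to_zero_based <- function(first, last) {
  stopifnot(all(last >= first))
  list(start = first - 1L, end = last)
}

# substring of a contig in 0-based half-open coordinates
contig_substr <- function(seq, start, end) {
  substr(seq, start + 1L, end)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
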