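# Independent oracles used by the tests. These deliberately avoid the
# package's own code paths (and the library calls the package uses for the
# same quantity).

oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

# rebuild the alignment target sequences straight from the bundle tables
oracle_targets <- function(bundle, flank = 10) {
  out <- list()
  m <- bundle$mirna_loci
  for (i in seq_len(nrow(m))) {
    ct <- bundle$contigs[[m$contig[i]]]
    s <- substr(ct, m$hp_start[i] - flank + 1, m$hp_end[i] + flank)
    if (m$strand[i] == "-") s <- oracle_revcomp(s)
    if (m$strand[i] == "+") {
      l5 <- c(m$m5_start[i], m$m5_end[i]) - m$hp_start[i]
      l3 <- c(m$m3_start[i], m$m3_end[i]) - m$hp_start[i]
    } else {
      l5 <- c(m$hp_end[i] - m$m5_end[i], m$hp_end[i] - m$m5_start[i])
      l3 <- c(m$hp_end[i] - m$m3_end[i], m$hp_end[i] - m$m3_start[i])
    }
    out[[length(out) + 1]] <- list(name = m$name[i], class = "miRNA",
                                   seq = s, flank = flank, l5 = l5, l3 = l3)
  }
  p <- bundle$pirna_loci
  for (i in seq_len(nrow(p))) {
    s <- substr(bundle$contigs[[p$contig[i]]], p$start[i] + 1, p$end[i])
    if (p$strand[i] == "-") s <- oracle_revcomp(s)
    out[[length(out) + 1]] <- list(name = p$name[i], class = "piRNA",
                                   seq = s, flank = 0)
  }
  sp <- bundle$spikeins
  for (i in seq_len(nrow(sp))) {
    out[[length(out) + 1]] <- list(name = sp$name[i], class = "spikein",
                                   seq = sp$sequence[i], flank = 0)
  }
  out
}

# brute-force exact-substring alignment: enumerate every (target, position, t)
oracle_align <- function(sequence, targets, max_tail = 3) {
  L <- nchar(sequence)
  for (t in 0:max_tail) {
    core_len <- L - t
    if (core_len < 13) break
    core <- substr(sequence, 1, core_len)
    rows <- list()
    for (tg in targets) {
      ns <- nchar(tg$seq)
      if (ns < core_len) next
      for (pos in 1:(ns - core_len + 1)) {
        if (substr(tg$seq, pos, pos + core_len - 1) == core) {
          start <- pos - 1 - tg$flank
          arm <- NA_character_
          if (tg$class == "miRNA") {
            mid <- start + (core_len - 1) / 2
            arm <- "other"
            if (mid >= tg$l5[1] && mid < tg$l5[2]) arm <- "5p"
            if (mid >= tg$l3[1] && mid < tg$l3[2]) arm <- "3p"
          }
          rows[[length(rows) + 1]] <- data.frame(
            target = tg$name, class = tg$class, arm = arm,
            start = start, end = start + core_len,
            tail = substr(sequence, core_len + 1, L),
            stringsAsFactors = FALSE)
        }
      }
    }
    if (length(rows)) {
      out <- do.call(rbind, rows)
      out$n_hits <- nrow(out)
      out$weight <- 1 / nrow(out)
      return(out[order(out$target, out$start), , drop = FALSE])
    }
  }
  data.frame(target = character(0), class = character(0), arm = character(0),
             start = integer(0), end = integer(0), tail = character(0),
             n_hits = integer(0), weight = numeric(0))
}

# two-sided Fisher exact p for a 2x2 table by exhaustive enumeration of all
# tables with the observed margins (standard "probability <= observed" rule
# with the customary 1e-7 relative tolerance)
oracle_fisher2x2 <- function(a, b, c, d) {
  m <- a + b          # row 1 margin
  n <- c + d          # row 2 margin
  k <- a + c          # column 1 margin
  lo <- max(0, k - n); hi <- min(k, m)
  logp <- function(x) lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k)
  lp_obs <- logp(a)
  xs <- lo:hi
  lps <- vapply(xs, logp, numeric(1))
  sum(exp(lps[lps <= lp_obs + log(1 + 1e-7)]))
}

# one-sided hypergeometric enrichment tail P(X >= k) by direct summation
oracle_hyper_tail <- function(k, size_a, size_b, universe) {
  xs <- k:min(size_a, size_b)
  sum(vapply(xs, function(x)
    exp(lchoose(size_a, x) + lchoose(universe - size_a, size_b - x) -
          lchoose(universe, size_b)), numeric(1)))
}

# Welch two-sample t-test from the textbook formulas
oracle_welch <- function(x, y) {
  v1 <- var(x) / length(x); v2 <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(x) - 1) + v2^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}
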