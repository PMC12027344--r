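# Hand-assembled reference bundles with fully known coordinates, used where
# tests need exact expected offsets rather than generator output.

.rand_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

.empty_pirna <- function() data.frame(
  name = character(0), contig = character(0), start = integer(0),
  end = integer(0), strand = character(0), base_abundance = numeric(0),
  stringsAsFactors = FALSE)

.empty_spike <- function() data.frame(
  name = character(0), sequence = character(0), input_amount = numeric(0),
  stringsAsFactors = FALSE)

# one plus-strand and one minus-strand hairpin, 22 nt arms, 15 nt loop,
# 8 nt lower stems, 12 nt flanks; when dup_arm = TRUE a second plus-strand
# locus shares the first locus' 5p arm sequence (multi-mapping case)
manual_bundle <- function(dup_arm = FALSE) {
  withr::with_seed(42, {
    mk_hp <- function(arm5, arm3) {
      list(ls1 = .rand_dna(1, 8), arm5 = arm5, loop = .rand_dna(1, 15),
           arm3 = arm3, ls2 = .rand_dna(1, 8))
    }
    a5a <- .rand_dna(1, 22); a3a <- .rand_dna(1, 22)
    a5b <- .rand_dna(1, 22); a3b <- .rand_dna(1, 22)
    hp_a <- mk_hp(a5a, a3a)
    hp_b <- mk_hp(a5b, a3b)
    seq_a <- paste0(hp_a$ls1, hp_a$arm5, hp_a$loop, hp_a$arm3, hp_a$ls2)
    seq_b <- paste0(hp_b$ls1, hp_b$arm5, hp_b$loop, hp_b$arm3, hp_b$ls2)
    flA <- .rand_dna(1, 12); frA <- .rand_dna(1, 12)
    flB <- .rand_dna(1, 12); frB <- .rand_dna(1, 12)
    rc <- function(x) paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]),
                            collapse = "")
    contigs <- c(chrP = paste0(flA, seq_a, frA),
                 chrM = paste0(flB, rc(seq_b), frB))
    loci <- data.frame(
      name = c("syn-a", "syn-b"), contig = c("chrP", "chrM"),
      strand = c("+", "-"), hp_start = c(12L, 12L), hp_end = c(87L, 87L),
      m5_start = c(20L, 57L), m5_end = c(42L, 79L),
      m3_start = c(57L, 20L), m3_end = c(79L, 42L),
      cluster_id = NA_character_, intronic = FALSE, idr1_sensitive = FALSE,
      base_abundance = 1, stringsAsFactors = FALSE)
    if (dup_arm) {
      hp_c <- mk_hp(a5a, .rand_dna(1, 22))  # shares syn-a's 5p arm
      seq_c <- paste0(hp_c$ls1, hp_c$arm5, hp_c$loop, hp_c$arm3, hp_c$ls2)
      contigs <- c(contigs, chrC = paste0(.rand_dna(1, 12), seq_c,
                                          .rand_dna(1, 12)))
      loci <- rbind(loci, data.frame(
        name = "syn-c", contig = "chrC", strand = "+",
        hp_start = 12L, hp_end = 87L, m5_start = 20L, m5_end = 42L,
        m3_start = 57L, m3_end = 79L, cluster_id = NA_character_,
        intronic = FALSE, idr1_sensitive = FALSE, base_abundance = 1,
        stringsAsFactors = FALSE))
    }
    b <- structure(list(contigs = contigs, mirna_loci = loci,
                        pirna_loci = .empty_pirna(),
                        spikeins = .empty_spike()),
                   class = "ref_bundle", flank = 12L, arm_len = 22L,
                   loop_len = 15L, lower_stem = 8L, seed = NA)
    attr(b, "arms") <- list(a5a = a5a, a3a = a3a, a5b = a5b, a3b = a3b)
    b
  })
}

# simulate a count matrix for DE calibration: n_null null miRNA arms,
# n_true arms at the given true log2FC, plus piRNA features for size factors;
# multinomial sampling at `depth` with mild lognormal replicate jitter
simulate_de_counts <- function(n_null = 100, n_true = 10, true_lfc = -2,
                               n_rep = 3, depth = 1e5, jitter_sd = 0.1,
                               n_pirna = 20, seed = 1) {
  withr::with_seed(seed, {
    n_mir <- n_null + n_true
    base <- exp(rnorm(n_mir, 0, 0.6))
    pir <- exp(rnorm(n_pirna, 0, 0.3)) * mean(base) * 2
    feats <- c(sprintf("arm%03d", seq_len(n_mir)),
               sprintf("pir%03d", seq_len(n_pirna)))
    cls <- setNames(c(rep("miRNA", n_mir), rep("piRNA", n_pirna)), feats)
    fc <- rep(1, n_mir + n_pirna)
    fc[n_null + seq_len(n_true)] <- 2^true_lfc
    draw <- function(mult) {
      w <- c(base, pir) * mult * exp(rnorm(n_mir + n_pirna, 0, jitter_sd))
      as.numeric(rmultinom(1, depth, w))
    }
    ctrl <- vapply(seq_len(n_rep), function(i) draw(rep(1, n_mir + n_pirna)),
                   numeric(n_mir + n_pirna))
    trt <- vapply(seq_len(n_rep), function(i) draw(fc),
                  numeric(n_mir + n_pirna))
    counts <- cbind(ctrl, trt)
    dimnames(counts) <- list(feats, c(paste0("C", seq_len(n_rep)),
                                      paste0("T", seq_len(n_rep))))
    list(counts = counts, feature_class = cls,
         groups = rep(c("ctrl", "trt"), each = n_rep),
         true_down = feats[n_null + seq_len(n_true)],
         null_feats = feats[seq_len(n_null)])
  })
}
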