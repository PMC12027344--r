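mb <- manual_bundle()
arms <- attr(mb, "arms")

test_that("length filter is inclusive at 16 and 30 nt", {
  reads <- data.frame(id = paste0("r", 1:4),
                      sequence = c(strrep("A", 15), strrep("C", 16),
                                   strrep("G", 30), strrep("T", 31)),
                      stringsAsFactors = FALSE)
  out <- preprocess_reads(reads)
  expect_equal(out$id, c("r2", "r3"))
})

test_that("UMI collapsing keeps one record per (sequence, UMI)", {
  reads <- data.frame(id = paste0("r", 1:3),
                      sequence = rep(strrep("ACGT", 5), 3),
                      umi = c("AAAA", "AAAA", "CCCC"),
                      stringsAsFactors = FALSE)
  out <- preprocess_reads(reads, collapse_umi = TRUE)
  expect_equal(nrow(out), 2)
  out2 <- preprocess_reads(reads, collapse_umi = FALSE)
  expect_equal(nrow(out2), 3)
})

test_that("malformed reads raise errors naming the record", {
  reads <- data.frame(id = c("a", "b"),
                      sequence = c(strrep("A", 20), "ACGUACGUACGUACGUACGU"),
                      stringsAsFactors = FALSE)
  expect_error(preprocess_reads(reads), "record 2")
})

test_that("an exact mature-arm read aligns uniquely with the right arm", {
  a <- align_read(arms$a5a, mb, read_id = "r1")
  expect_equal(nrow(a), 1)
  expect_equal(a$target, "syn-a")
  expect_equal(a$arm, "5p")
  expect_equal(a$tail, "")
  expect_equal(a$start, 8)   # lower stem is 8 nt
  expect_equal(a$end, 30)
  expect_equal(a$weight, 1)
  # minus-strand locus: mature-sense read aligns the same way
  b <- align_read(arms$a3b, mb, read_id = "r2")
  expect_equal(b$target, "syn-b")
  expect_equal(b$arm, "3p")
  expect_equal(b$start, 45)
})

test_that("multi-locus matches split weight fractionally", {
  dup <- manual_bundle(dup_arm = TRUE)
  a <- align_read(attr(dup, "arms")$a5a, dup)
  expect_equal(nrow(a), 2)
  expect_setequal(a$target, c("syn-a", "syn-c"))
  expect_equal(a$weight, c(0.5, 0.5))
})

test_that("3' soft-clip is bounded at 3 nt and picks the minimal tail", {
  r_tail3 <- paste0(arms$a5a, "GGG")  # G's chosen to mismatch any genome run?
  a3 <- align_read(r_tail3, mb)
  # minimal-tail rule: report the smallest t that yields a placement
  expect_equal(nrow(a3) >= 1, TRUE)
  expect_lte(nchar(a3$tail[1]), 3)
  r_tail4 <- paste0(arms$a5a, "GGGG")
  ext <- hairpin_sense_seq(mb, "syn-a", 12)
  if (!grepl(substr(r_tail4, 1, nchar(r_tail4) - 3), ext, fixed = TRUE)) {
    expect_equal(nrow(align_read(r_tail4, mb)), 0)
  }
})

test_that("alignment equals the brute-force oracle on generator reads", {
  b <- make_reference(n_mirna = 5, n_pirna = 6, n_spikein = 2, seed = 77)
  gt <- genotype_spec("WT", b$mirna_loci$name, tail_rate = 0.2)
  s <- simulate_reads(b, gt, 300, seed = 78)
  idx <- mirproc:::build_alignment_index(b)
  tg <- oracle_targets(b, 10)
  for (sq in unique(s$reads$sequence)) {
    mine <- align_read(sq, idx)
    mine <- mine[order(mine$target, mine$start),
                 c("target", "class", "arm", "start", "end", "tail",
                   "n_hits", "weight")]
    rownames(mine) <- NULL
    theirs <- oracle_align(sq, tg)
    rownames(theirs) <- NULL
    expect_equal(mine, theirs)
  }
})

test_that("fractional counting conserves aligned-read totals", {
  b <- make_reference(n_mirna = 4, n_pirna = 5, n_spikein = 2, seed = 81)
  gt <- genotype_spec("WT", b$mirna_loci$name)
  s <- simulate_reads(b, gt, 2000, seed = 82)
  al <- align_reads(s$reads, b)
  cf <- count_features(al, b)
  expect_equal(sum(cf$count), length(unique(al$read_id)), tolerance = 1e-9)
  # ten unique-mapping copies of one arm count 10
  reads10 <- data.frame(id = paste0("x", 1:10),
                        sequence = rep(attr(mb, "arms")$a5a, 10),
                        stringsAsFactors = FALSE)
  cf10 <- count_features(align_reads(reads10, mb), mb)
  expect_equal(cf10$count[cf10$feature == "syn-a-5p"], 10)
  # one read mapping two loci contributes 0.5 to each
  dup <- manual_bundle(dup_arm = TRUE)
  read1 <- data.frame(id = "y", sequence = attr(dup, "arms")$a5a,
                      stringsAsFactors = FALSE)
  cfd <- count_features(align_reads(read1, dup), dup)
  expect_equal(cfd$count[cfd$feature %in% c("syn-a-5p", "syn-c-5p")],
               c(0.5, 0.5))
})

test_that("size factors follow the two-sample geometric normalization", {
  counts <- matrix(c(1e6, 5, 2e6, 5), nrow = 2,
                   dimnames = list(c("pi1", "m1"), c("s1", "s2")))
  fc <- c(pi1 = "piRNA", m1 = "miRNA")
  s <- compute_size_factors(counts, "pirna_total", feature_class = fc)
  expect_equal(unname(s), c(1 / sqrt(2), sqrt(2)), ignore_attr = TRUE)
  expect_equal(exp(mean(log(s))), 1, tolerance = 1e-9)
  counts2 <- matrix(c(1e6, 5, 1e6, 5), nrow = 2,
                    dimnames = dimnames(counts))
  expect_equal(unname(compute_size_factors(counts2, "pirna_total",
                                           feature_class = fc)), c(1, 1),
               ignore_attr = TRUE)
  counts3 <- matrix(c(0, 5, 1e6, 5), nrow = 2, dimnames = dimnames(counts))
  expect_error(compute_size_factors(counts3, "pirna_total",
                                    feature_class = fc), "zero piRNA total")
})

test_that("size factors recover known depth ratios from simulated reads", {
  b <- make_reference(n_mirna = 4, n_pirna = 10, n_spikein = 3, seed = 91)
  gt <- genotype_spec("WT", b$mirna_loci$name)
  depths <- c(s1 = 200000, s2 = 100000, s3 = 400000)
  idx <- mirproc:::build_alignment_index(b)
  sc <- lapply(seq_along(depths), function(i) {
    s <- simulate_reads(b, gt, depths[i], replicate_id = i, seed = 91 + i)
    count_features(align_reads(s$reads, idx), b)
  })
  names(sc) <- names(depths)
  cm <- count_matrix(sc)
  for (m in c("pirna_total", "spikein")) {
    s <- compute_size_factors(cm, m)
    rel <- s / s[1]
    expect_equal(unname(rel), unname(depths / depths[1]), tolerance = 0.02,
                 ignore_attr = TRUE)
  }
})

test_that("scaling one sample's counts rescales its factor, leaving relative normalized values intact", {
  sim <- simulate_de_counts(n_null = 30, n_true = 0, seed = 5)
  cm <- sim$counts
  n <- ncol(cm)
  fc <- sim$feature_class
  s0 <- compute_size_factors(cm, "pirna_total", feature_class = fc)
  cm2 <- cm
  cm2[, 3] <- cm2[, 3] * 2.5
  s1 <- compute_size_factors(cm2, "pirna_total", feature_class = fc)
  # scaled sample's factor grows by c up to the re-geomean constant c^(1/n)
  expect_equal(unname(s1[3] / s0[3]), 2.5^((n - 1) / n), tolerance = 1e-12)
  expect_equal(unname(s1[1] / s0[1]), 2.5^(-1 / n), tolerance = 1e-12)
  # every normalized count changes only by the same global constant
  n0 <- normalize_counts(cm, s0)
  n1 <- normalize_counts(cm2, s1)
  pos <- n0 > 0
  expect_equal(unname(range(n1[pos] / n0[pos])),
               rep(2.5^(1 / n), 2), tolerance = 1e-12)
})
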