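mb <- manual_bundle()
arms <- attr(mb, "arms")

test_that("tail status calls follow the genomic continuation", {
  expect_equal(call_tail_status("", "ACGT"), "none")
  expect_equal(call_tail_status("T", "TACG"), "templated_ambiguous")
  expect_equal(call_tail_status("TT", "TAGG"), "untemplated_unambiguous")
  expect_equal(call_tail_status("ACG", "ACGT"), "templated_ambiguous")
  expect_error(call_tail_status("TT", "T"), "shorter than tail")
  expect_error(call_tail_status("TTTT", "TTTTT"), "longer than 3")
})

test_that("a canonical read has zero offsets and no tail", {
  a <- align_read(arms$a5a, mb, read_id = "r")
  rec <- classify_isomir(a, mb, flank = 12)
  expect_equal(rec$offset5, 0)
  expect_equal(rec$offset3, 0)
  expect_equal(rec$tail_status, "none")
})

test_that("basal-junction shifts map to -1 (5p 5' end) and +1 (3p 3' end)", {
  ext <- hairpin_sense_seq(mb, "syn-a", 12)
  # 5p read starting 1 nt upstream, toward the basal junction: local [7, 30)
  r5 <- substr(ext, 12 + 7 + 1, 12 + 30)
  a5 <- align_read(r5, mb)
  rec5 <- classify_isomir(a5, mb, flank = 12)
  expect_equal(rec5$arm, "5p")
  expect_equal(rec5$offset5, -1)
  # 3p read ending 1 nt downstream, toward the basal junction: local [45, 68)
  r3 <- substr(ext, 12 + 45 + 1, 12 + 68)
  a3 <- align_read(r3, mb)
  rec3 <- classify_isomir(a3, mb, flank = 12)
  expect_equal(rec3$arm, "3p")
  expect_equal(rec3$offset3, 1)
})

test_that("offsets round-trip through construct -> align -> classify on both strands", {
  for (locus in c("syn-a", "syn-b")) {
    ext <- hairpin_sense_seq(mb, locus, 12)
    for (arm in c("5p", "3p")) {
      bounds <- if (arm == "5p") c(8, 30) else c(45, 67)
      for (o5 in -3:3) for (o3 in -3:3) {
        s <- bounds[1] + o5; e <- bounds[2] + o3
        read <- substr(ext, 12 + s + 1, 12 + e)
        a <- align_read(read, mb)
        a <- a[a$target == locus, , drop = FALSE]
        expect_equal(nrow(a), 1)
        rec <- classify_isomir(a, mb, flank = 12)
        expect_equal(rec$arm, arm)
        expect_equal(rec$offset5, o5)
        expect_equal(rec$offset3, o3)
      }
    }
  }
})

test_that("end distributions aggregate weight and apply the baseMean filter", {
  rec <- data.frame(locus = "syn-a", arm = "5p",
                    offset5 = c(0, 0, -1, -1), offset3 = 0,
                    tail = "", tail_status = "none",
                    weight = c(25, 25, 25, 25), stringsAsFactors = FALSE)
  d <- end_distribution(rec, base_mean = 100)
  expect_equal(d$offsets[["0"]], 0.5)
  expect_equal(d$offsets[["-1"]], 0.5)
  expect_equal(d$pct_canonical, 50)
  expect_equal(d$end_of_interest, "five_prime")
  expect_null(end_distribution(rec, base_mean = 25))  # threshold exclusive
  rec$tail_status <- c("none", "none", "untemplated_unambiguous",
                       "untemplated_unambiguous")
  d2 <- end_distribution(rec, base_mean = 100)
  expect_equal(d2$pct_canonical, 100)  # untemplated reads removed
  recx <- rec; recx$locus <- c("syn-a", "syn-a", "syn-b", "syn-b")
  expect_error(end_distribution(recx, 100), "mix")
})

test_that("all-canonical records give 100% canonical", {
  rec <- data.frame(locus = "syn-a", arm = "3p", offset5 = 0, offset3 = 0,
                    tail = "", tail_status = "none", weight = 1,
                    stringsAsFactors = FALSE)
  d <- end_distribution(rec, base_mean = 1000)
  expect_equal(d$pct_canonical, 100)
  expect_equal(d$end_of_interest, "three_prime")
})

test_that("end-distribution recovery matches the generator truth at depth", {
  b1 <- make_reference(n_mirna = 1, n_pirna = 0, n_spikein = 0, seed = 55)
  truth5 <- c(`-1` = 0.15, `0` = 0.80, `1` = 0.05)
  gt <- genotype_spec("WT", b1$mirna_loci$name, tail_rate = 0,
                      offset5p = truth5, offset3p = truth5)
  s <- simulate_reads(b1, gt, 40000, seed = 56,
                      class_props = c(miRNA = 1, piRNA = 0, spikein = 0))
  al <- align_reads(s$reads, b1)
  iso <- classify_isomirs(al, b1)
  for (arm in c("5p", "3p")) {
    d <- end_distribution(iso[iso$arm == arm, ], base_mean = 1000)
    expect_lt(max(abs(d$offsets[names(truth5)] - truth5)), 0.01)
  }
})

test_that("untemplated-only tailing leaves pct_canonical unchanged in expectation", {
  b1 <- make_reference(n_mirna = 1, n_pirna = 0, n_spikein = 0, seed = 57)
  mk <- function(rate, seed) {
    gt <- genotype_spec("WT", b1$mirna_loci$name, tail_rate = rate)
    s <- simulate_reads(b1, gt, 20000, seed = seed,
                        class_props = c(miRNA = 1, piRNA = 0, spikein = 0))
    iso <- classify_isomirs(align_reads(s$reads, b1), b1)
    d <- end_distribution(iso[iso$arm == "5p", ], base_mean = 1000)
    c(pct = d$pct_canonical, n = d$total_weight)
  }
  lo <- mk(0, 58); hi <- mk(0.4, 59)
  p <- 0.9
  se <- 100 * sqrt(p * (1 - p) * (1 / lo[["n"]] + 1 / hi[["n"]]))
  expect_lt(abs(hi[["pct"]] - lo[["pct"]]), 3 * se)
})

test_that("identical fidelity tables give p = 1; Fisher p matches enumeration", {
  mk_dist <- function(can, non, locus = "syn-a", arm = "5p") {
    off <- c(`0` = can, `-1` = non) / (can + non)
    structure(list(locus = locus, arm = arm, end_of_interest = "five_prime",
                   offsets = off, total_weight = can + non,
                   pct_canonical = 100 * can / (can + non)),
              class = "end_distribution")
  }
  same <- compare_fidelity(mk_dist(80, 20), mk_dist(80, 20))
  expect_equal(same$p, 1)
  cmp <- compare_fidelity(mk_dist(90, 10), mk_dist(60, 40))
  expect_equal(cmp$p, oracle_fisher2x2(90, 10, 60, 40), tolerance = 1e-12)
  expect_equal(cmp$shift_direction, -1)
  expect_equal(cmp$delta_pct, -30)
})

test_that("a single shifted locus is the only significant fidelity hit", {
  b <- make_reference(n_mirna = 6, n_pirna = 4, n_spikein = 0, seed = 61)
  loci <- b$mirna_loci$name
  shifted <- loci[3]
  wt <- genotype_spec("WT", loci, tail_rate = 0.05)
  mut <- genotype_spec("dIDR1", loci, tail_rate = 0.05,
                       offset_overrides = setNames(list(list(
                         `5p` = c(`-1` = 0.45, `0` = 0.50, `1` = 0.05),
                         `3p` = c(`-1` = 0.05, `0` = 0.50, `1` = 0.45))),
                         shifted))
  run <- function(gt, seed) {
    s <- simulate_reads(b, gt, 12000, seed = seed)
    al <- align_reads(s$reads, b)
    iso <- classify_isomirs(al, b)
    bm <- data.frame(feature = unique(paste0(iso$locus, "-", iso$arm)),
                     baseMean = 1000)
    end_distributions(iso, bm)
  }
  fc <- fidelity_comparison(run(wt, 62), run(mut, 63))
  hits <- fc[fc$significant, ]
  expect_true(all(hits$locus == shifted))
  expect_setequal(hits$arm, c("5p", "3p"))
  # the mutant's modal non-canonical offset points toward the basal junction
  expect_equal(hits$shift_direction[hits$arm == "5p"], -1)
  expect_equal(hits$shift_direction[hits$arm == "3p"], 1)
})
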