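test_that("focus measurement returns the injected excess exactly at zero noise", {
  img <- simulate_nucleus_image(noise_sd = 0, seed = 3)
  m <- measure_foci(img)
  expect_equal(nrow(m), 4)
  expect_equal(sort(m$intensity), sort(img$truth$focus_excess),
               tolerance = 1e-6)
  expect_equal(attr(m, "n_excluded_negative"), 0L)
  # ranked descending
  expect_equal(m$intensity, sort(m$intensity, decreasing = TRUE))
  expect_equal(m$rank, seq_len(nrow(m)))
})

test_that("negative-intensity foci are excluded and counted", {
  img <- simulate_nucleus_image(noise_sd = 0, seed = 4)
  # add a bogus focus ROI over empty nucleoplasm with a small depression
  fake <- data.frame(x = img$foci$x[1], y = 2 * (dim(img$nucleus)[2] + 1) / 2 -
                       img$foci$y[1], plane = 1)
  # carve a dip so the fake focus measures negative
  d <- dim(img$nucleus)
  roi <- mirproc:::circle_mask(d, c(fake$x, fake$y), img$roi_radius)
  img$data[, , 1][roi] <- img$data[, , 1][roi] - 5
  all_foci <- rbind(img$foci, fake)
  m <- measure_foci(img, focus_rois = all_foci)
  expect_equal(attr(m, "n_excluded_negative"), 1L)
  expect_equal(nrow(m), 4)
})

test_that("nucleus totals and focus fraction match construction at zero noise", {
  img <- simulate_nucleus_image(focus_fraction = 0.02, noise_sd = 0, seed = 5)
  ns <- nucleus_totals(img)
  expect_equal(ns$total, img$truth$nuclear_total, tolerance = 1e-6)
  expect_equal(ns$fraction_in_foci, 2, tolerance = 1e-6)
  # truth identity: focus excesses over nuclear total equals f by construction
  expect_equal(sum(img$truth$focus_excess) / img$truth$nuclear_total, 0.02,
               tolerance = 1e-12)
})

test_that("f = 0 gives a focus-free nucleus", {
  img <- simulate_nucleus_image(focus_fraction = 0, n_foci = 0,
                                noise_sd = 0, seed = 6)
  diffuse <- img$truth$diffuse_level + 20  # + extranuclear background
  inside <- img$nucleus & !img$nucleolus
  for (z in seq_len(dim(img$data)[3]))
    expect_lt(max(img$data[, , z][inside]), diffuse + 1e-9)
  ns <- nucleus_totals(img)
  expect_equal(ns$fraction_in_foci, 0)
  expect_error(simulate_nucleus_image(focus_fraction = 0.02, n_foci = 0),
               "requires n_foci")
})

test_that("image integral over the nucleus equals truth plus background", {
  img <- simulate_nucleus_image(noise_sd = 0, seed = 7)
  sumproj <- apply(img$data, c(1, 2), sum)
  n_planes <- dim(img$data)[3]
  lhs <- sum(sumproj[img$nucleus])
  rhs <- img$truth$nuclear_total + sum(img$nucleus) * n_planes * 20
  expect_lt(abs(lhs - rhs) / rhs, 0.001)
})

test_that("intensity scaling scales totals but not the focus fraction", {
  img1 <- simulate_nucleus_image(noise_sd = 0, seed = 8)
  for (sc in c(0.1, 0.6, 10)) {
    img2 <- img1
    img2$data <- img1$data * sc
    n1 <- nucleus_totals(img1)
    n2 <- nucleus_totals(img2)
    expect_equal(n2$total / n1$total, sc, tolerance = 1e-9)
    expect_equal(n2$fraction_in_foci, n1$fraction_in_foci, tolerance = 1e-9)
  }
  # hemizygous dosage: 0.6x concentration gives 0.6x truth total
  h <- simulate_nucleus_image(nuclear_concentration = 0.6, noise_sd = 0,
                              seed = 8)
  expect_equal(h$truth$nuclear_total / img1$truth$nuclear_total, 0.6,
               tolerance = 1e-9)
})

test_that("all-foci sum is additive over the individual foci", {
  img <- simulate_nucleus_image(n_foci = 3, noise_sd = 0, seed = 9)
  m <- measure_foci(img, projection = "sum")
  ns <- nucleus_totals(img)
  expect_equal(ns$allfoci, sum(m$intensity), tolerance = 1e-9)
  expect_equal(ns$allfoci, sum(img$truth$focus_excess), tolerance = 1e-6)
})

test_that("session normalization divides by same-session control means only", {
  mk <- function(session, genotype, conc, seed, gain)
    nucleus_totals(simulate_nucleus_image(
      nuclear_concentration = conc, session_id = session, genotype = genotype,
      seed = seed, gain = gain, noise_sd = 0))
  s <- do.call(rbind, list(
    mk("A", "WT", 1, 1, 1), mk("A", "WT", 1, 2, 1), mk("A", "mut", 0.6, 3, 1),
    mk("B", "WT", 1, 4, 2.0), mk("B", "mut", 0.6, 5, 2.0)))
  n <- normalize_to_control(s, "WT")
  expect_equal(mean(n$norm_total[n$genotype == "WT" & n$session == "A"]), 1)
  expect_equal(mean(n$norm_total[n$genotype == "WT" & n$session == "B"]), 1)
  # gain cancels within session: both mutants sit near 0.6
  expect_equal(n$norm_total[n$genotype == "mut"], rep(0.6, 2),
               tolerance = 0.02)
  # permuting another session's rows leaves a session's outputs unchanged
  s2 <- s[c(4, 5, 1, 2, 3), ]
  n2 <- normalize_to_control(s2, "WT")
  expect_equal(sort(n2$norm_total[n2$session == "A"]),
               sort(n$norm_total[n$session == "A"]))
  expect_error(normalize_to_control(s[s$genotype == "mut", ], "WT"),
               "no control")
})

test_that("colocalization rate follows the center-distance rule", {
  a <- cbind(x = seq_len(10) * 10, y = 0)
  expect_equal(colocalization_rate(a, a, 1)$percent, 100)
  expect_equal(colocalization_rate(a, a[0, , drop = FALSE], 1)$percent, 0)
  expect_error(colocalization_rate(a[0, , drop = FALSE], a, 1), "empty")
  b <- cbind(x = c(10, 20.4), y = c(0.3, 0))
  r <- colocalization_rate(a, b, 0.5)
  expect_equal(r$n_colocalized, 2)
  expect_equal(r$percent, 20)
})
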