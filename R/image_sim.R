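# circular pixel mask over a h x w grid; center in pixel units
circle_mask <- function(dim, center, radius) {
  x <- matrix(rep(seq_len(dim[2]), each = dim[1]), nrow = dim[1])
  y <- matrix(rep(seq_len(dim[1]), times = dim[2]), nrow = dim[1])
  (x - center[1])^2 + (y - center[2])^2 <= radius^2
}

#' Simulate a hypodermal nucleus image stack with foci
#'
#' Builds a small z-stack in which pixel intensity is extranuclear background
#' everywhere, plus a diffuse nuclear level inside the nucleus mask (zero
#' inside the central nucleolus, which excludes the tagged protein), plus
#' `n_foci` Gaussian-profile foci, each confined to a single plane. Focus
#' amplitudes are scaled so the summed focus excess equals
#' `f / (1 - f)` times the diffuse nuclear total, i.e. the foci hold exactly
#' fraction `f` of the total nuclear signal. Focus kernels are truncated at
#' `roi_radius` so each focus's excess lies entirely within its measurement
#' ROI. Per-pixel Gaussian noise approximates shot noise; a per-session
#' `gain` multiplies the whole image (and the noise) to emulate
#' session-to-session acquisition differences.
#'
#' @param nuclear_concentration relative diffuse nuclear level (1 = control;
#'   a hemizygous nucleus uses 0.6).
#' @param focus_fraction f in [0, 1): fraction of total nuclear signal held in
#'   foci; f > 0 requires n_foci > 0.
#' @param n_foci number of foci (>= 0).
#' @param nucleolus_radius radius (px) of the central nucleolus; 0 disables.
#' @param extranuclear_background flat background level added everywhere.
#' @param noise_sd per-pixel Gaussian noise SD (pre-gain units).
#' @param session_id,genotype labels carried into summaries.
#' @param seed integer seed.
#' @param dim image height/width (px).
#' @param n_planes number of z planes.
#' @param nucleus_radius nucleus mask radius (px).
#' @param focus_sigma Gaussian sigma of focus profiles (px).
#' @param roi_radius focus measurement ROI radius (px).
#' @param gain session gain multiplying the recorded image.
#' @return a `nucleus_image` list: `data` (h x w x z array), `nucleus`,
#'   `nucleolus` (logical matrices), `foci` (data.frame x, y, plane),
#'   `roi_radius`, `session_id`, `genotype`, and `truth` (nuclear_total,
#'   focus_excess, focus_fraction, diffuse_level, gain; pre-gain units).
#' @export
simulate_nucleus_image <- function(nuclear_concentration = 1,
                                   focus_fraction = 0.02, n_foci = 4,
                                   nucleolus_radius = 6,
                                   extranuclear_background = 20,
                                   noise_sd = 3,
                                   session_id = "S1", genotype = "WT",
                                   seed = 1, dim = c(64, 64), n_planes = 5,
                                   nucleus_radius = 20, focus_sigma = 1.5,
                                   roi_radius = 5, gain = 1) {
  stopifnot(focus_fraction >= 0, focus_fraction < 1, n_foci >= 0,
            nuclear_concentration > 0, gain > 0)
  if (focus_fraction > 0 && n_foci == 0)
    stop("focus_fraction > 0 requires n_foci > 0")
  withr::with_seed(seed, {
    ctr <- (dim + 1) / 2
    nucleus <- circle_mask(dim, ctr, nucleus_radius)
    nucleolus <- if (nucleolus_radius > 0)
      circle_mask(dim, ctr, nucleolus_radius) else
      matrix(FALSE, dim[1], dim[2])

    diffuse_level <- 100 * nuclear_concentration
    diffuse_mask <- nucleus & !nucleolus
    diffuse_total <- diffuse_level * sum(diffuse_mask) * n_planes

    # focus placement: annulus clear of the nucleolus and the nucleus rim
    foci <- data.frame(x = numeric(0), y = numeric(0), plane = integer(0))
    excess <- numeric(0)
    if (n_foci > 0) {
      r_lo <- nucleolus_radius + roi_radius + 0.5
      r_hi <- nucleus_radius - roi_radius - 0.5
      if (r_lo >= r_hi) stop("no room to place foci inside the nucleus")
      base <- 2 * pi * (seq_len(n_foci) - 1) / n_foci
      ang <- base + runif(1, 0, 2 * pi) + runif(n_foci, -0.2, 0.2)
      rad <- runif(n_foci, r_lo, r_hi)
      fx <- ctr[1] + rad * cos(ang)
      fy <- ctr[2] + rad * sin(ang)
      plane <- sample.int(n_planes, n_foci, replace = TRUE)
      ok <- sqrt((fx - ctr[1])^2 + (fy - ctr[2])^2) + roi_radius <=
        nucleus_radius
      if (!all(ok)) stop("focus placed outside the nucleus")
      foci <- data.frame(x = fx, y = fy, plane = plane)
      total_excess <- focus_fraction / (1 - focus_fraction) * diffuse_total
      w <- runif(n_foci, 0.5, 1.5)
      excess <- total_excess * w / sum(w)
    }

    img <- array(extranuclear_background, c(dim[1], dim[2], n_planes))
    for (z in seq_len(n_planes))
      img[, , z][diffuse_mask] <- img[, , z][diffuse_mask] + diffuse_level
    if (n_foci > 0) {
      xg <- matrix(rep(seq_len(dim[2]), each = dim[1]), nrow = dim[1])
      yg <- matrix(rep(seq_len(dim[1]), times = dim[2]), nrow = dim[1])
      for (i in seq_len(n_foci)) {
        d2 <- (xg - foci$x[i])^2 + (yg - foci$y[i])^2
        k <- exp(-d2 / (2 * focus_sigma^2))
        k[d2 > roi_radius^2] <- 0          # confine excess to the ROI
        k <- k / sum(k) * excess[i]        # exact injected excess
        img[, , foci$plane[i]] <- img[, , foci$plane[i]] + k
      }
    }
    if (noise_sd > 0)
      img <- img + array(rnorm(length(img), 0, noise_sd), dim(img))
    img <- img * gain

    structure(list(
      data = img, nucleus = nucleus, nucleolus = nucleolus, foci = foci,
      roi_radius = roi_radius, nucleus_radius = nucleus_radius,
      session_id = session_id, genotype = genotype,
      truth = list(nuclear_total = diffuse_total + sum(excess),
                   focus_excess = excess,
                   focus_fraction = if (diffuse_total + sum(excess) > 0)
                     sum(excess) / (diffuse_total + sum(excess)) else 0,
                   diffuse_level = diffuse_level, gain = gain)),
      class = "nucleus_image")
  })
}

#' Default parameters of the packaged hypodermal nucleus fixture
#'
#' Control nuclei hold 2\% of their total nuclear signal in foci
#' (`focus_fraction = 0.02`); the hemizygous variant carries a single
#' functional tagged allele and is generated at 0.6x nuclear concentration.
#'
#' @param hemizygous if TRUE, return the hemizygous (0.6x dosage) variant.
#' @return named list of [simulate_nucleus_image()] arguments.
#' @export
nucleus_fixture_defaults <- function(hemizygous = FALSE) {
  list(nuclear_concentration = if (hemizygous) 0.6 else 1,
       focus_fraction = 0.02, n_foci = 4, nucleolus_radius = 6,
       extranuclear_background = 20, noise_sd = 3,
       genotype = if (hemizygous) "hemi" else "WT")
}

#' Write / read a nucleus image stack as 16-bit TIFF
#'
#' Intensities are scaled by 1/65535 on write (the `tiff` package stores
#' [0, 1] floats) and rescaled on read; masks are written alongside as
#' `<prefix>_nucleus.tif` and `<prefix>_nucleolus.tif`.
#'
#' @param image a `nucleus_image`.
#' @param prefix output path prefix.
#' @return invisible vector of written paths.
#' @export
write_nucleus_tiff <- function(image, prefix) {
  planes <- lapply(seq_len(dim(image$data)[3]), function(z)
    pmin(pmax(image$data[, , z] / 65535, 0), 1))
  p1 <- paste0(prefix, ".tif")
  tiff::writeTIFF(planes, p1, bits.per.sample = 16)
  p2 <- paste0(prefix, "_nucleus.tif")
  tiff::writeTIFF(image$nucleus * 1, p2, bits.per.sample = 16)
  p3 <- paste0(prefix, "_nucleolus.tif")
  tiff::writeTIFF(image$nucleolus * 1, p3, bits.per.sample = 16)
  invisible(c(p1, p2, p3))
}

#' @rdname write_nucleus_tiff
#' @param prefix path prefix used at write time.
#' @param foci data.frame of focus centers (x, y, plane) to attach.
#' @param roi_radius,session_id,genotype metadata to attach.
#' @export
read_nucleus_tiff <- function(prefix, foci, roi_radius = 5,
                              session_id = "S1", genotype = "WT") {
  planes <- tiff::readTIFF(paste0(prefix, ".tif"), all = TRUE)
  img <- array(0, c(dim(planes[[1]]), length(planes)))
  for (z in seq_along(planes)) img[, , z] <- planes[[z]] * 65535
  nuc <- tiff::readTIFF(paste0(prefix, "_nucleus.tif")) > 0.5
  nol <- tiff::readTIFF(paste0(prefix, "_nucleolus.tif")) > 0.5
  structure(list(data = img, nucleus = nuc, nucleolus = nol, foci = foci,
                 roi_radius = roi_radius, nucleus_radius = NA,
                 session_id = session_id, genotype = genotype, truth = NULL),
            class = "nucleus_image")
}
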