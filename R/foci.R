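# nearest-valid-ring background: the n nearest pixels to `center` that are
# inside the nucleus, outside the nucleolus and outside every focus ROI
ring_background_pixels <- function(image, center, n, roi_masks) {
  d <- dim(image$nucleus)
  x <- matrix(rep(seq_len(d[2]), each = d[1]), nrow = d[1])
  y <- matrix(rep(seq_len(d[1]), times = d[2]), nrow = d[1])
  eligible <- image$nucleus & !image$nucleolus
  for (m in roi_masks) eligible <- eligible & !m
  if (sum(eligible) < n)
    stop("not enough eligible background pixels adjacent to focus")
  dist2 <- (x - center[1])^2 + (y - center[2])^2
  ord <- order(dist2 + ifelse(eligible, 0, Inf))
  ord[seq_len(n)]
}

#' Measure background-subtracted focus intensities
#'
#' For each focus, the integrated intensity of a circular ROI around the
#' focus center is measured on the focus's own plane (or on the sum
#' projection), and an equal-area adjacent nuclear background region -- the
#' nearest valid pixels outside all focus ROIs and the nucleolus -- is
#' subtracted. Foci whose background-subtracted intensity is negative are
#' excluded from the ranked output and counted in `n_excluded_negative`.
#'
#' @param image a `nucleus_image`.
#' @param focus_rois data.frame of focus centers (x, y, plane); defaults to
#'   the image's own foci.
#' @param background_rois optional list of logical background masks, one per
#'   focus; each must be area-matched to the focus ROI and disjoint from it.
#'   When NULL the nearest-valid-ring rule above is used.
#' @param projection "single_plane" (each focus on its plane, the convention
#'   for ranked focus brightness) or "sum" (sum projection, the convention
#'   for the fraction-of-nuclear-signal calculation).
#' @return data.frame (focus_id, x, y, plane, intensity, rank) of surviving
#'   foci sorted brightest-first, with attribute `n_excluded_negative`.
#' @export
measure_foci <- function(image, focus_rois = NULL, background_rois = NULL,
                         projection = c("single_plane", "sum")) {
  projection <- match.arg(projection)
  foci <- focus_rois %||% image$foci
  r <- image$roi_radius
  d <- dim(image$nucleus)
  n_f <- nrow(foci)
  if (n_f == 0) {
    out <- data.frame(focus_id = integer(0), x = numeric(0), y = numeric(0),
                      plane = integer(0), intensity = numeric(0),
                      rank = integer(0))
    attr(out, "n_excluded_negative") <- 0L
    return(out)
  }
  roi_masks <- lapply(seq_len(n_f), function(i)
    circle_mask(d, c(foci$x[i], foci$y[i]), r))
  for (i in seq_len(n_f))
    if (!all(image$nucleus[roi_masks[[i]]]))
      stop("focus ROI extends outside the nucleus mask")
  sumproj <- apply(image$data, c(1, 2), sum)

  vals <- numeric(n_f)
  for (i in seq_len(n_f)) {
    plane_img <- if (projection == "sum") sumproj else
      image$data[, , foci$plane[i]]
    roi_px <- which(roi_masks[[i]])
    if (is.null(background_rois)) {
      bg_px <- ring_background_pixels(image, c(foci$x[i], foci$y[i]),
                                      length(roi_px), roi_masks)
    } else {
      bg <- background_rois[[i]]
      bg_px <- which(bg)
      if (length(bg_px) != length(roi_px))
        stop("background ROI area does not match focus ROI area")
      if (any(bg & roi_masks[[i]]))
        stop("focus and background ROIs overlap")
    }
    vals[i] <- sum(plane_img[roi_px]) - sum(plane_img[bg_px])
  }
  keep <- vals >= 0
  out <- data.frame(focus_id = seq_len(n_f), x = foci$x, y = foci$y,
                    plane = foci$plane, intensity = vals)[keep, , drop = FALSE]
  out <- out[order(-out$intensity), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "n_excluded_negative") <- sum(!keep)
  out
}

#' Summarize total nuclear signal and the fraction residing in foci
#'
#' The total nuclear signal is the sum-projection integral over the nucleus
#' mask minus an area-scaled extranuclear background estimated from an
#' adjacent ring just outside the nucleus (within the same cell). Focus
#' excesses for the fraction are re-measured on the sum projection; the
#' ranked single-plane measurements give the brightest / second-brightest
#' focus intensities.
#'
#' @param image a `nucleus_image`.
#' @return one-row data.frame (`nucleus_summary`): session, genotype, total,
#'   brightest, second_brightest, allfoci, fraction_in_foci (percent),
#'   n_excluded_negative.
#' @export
nucleus_totals <- function(image) {
  sumproj <- apply(image$data, c(1, 2), sum)
  d <- dim(image$nucleus)
  ctr <- (d + 1) / 2
  x <- matrix(rep(seq_len(d[2]), each = d[1]), nrow = d[1])
  y <- matrix(rep(seq_len(d[1]), times = d[2]), nrow = d[1])
  dist <- sqrt((x - ctr[1])^2 + (y - ctr[2])^2)
  R <- image$nucleus_radius
  if (is.na(R)) R <- max(dist[image$nucleus])
  ring <- !image$nucleus & dist <= R + 4
  if (!any(ring)) stop("no extranuclear background ring available")
  bg_per_px <- mean(sumproj[ring])
  total <- sum(sumproj[image$nucleus]) - bg_per_px * sum(image$nucleus)
  if (total <= 0) stop("non-positive background-subtracted nuclear total")

  single <- measure_foci(image, projection = "single_plane")
  proj <- measure_foci(image, projection = "sum")
  allfoci <- sum(proj$intensity)
  out <- data.frame(
    session = image$session_id, genotype = image$genotype,
    total = total,
    brightest = if (nrow(single) >= 1) single$intensity[1] else NA_real_,
    second_brightest = if (nrow(single) >= 2) single$intensity[2] else NA_real_,
    allfoci = allfoci,
    fraction_in_foci = 100 * allfoci / total,
    n_excluded_negative = attr(single, "n_excluded_negative"),
    stringsAsFactors = FALSE)
  class(out) <- c("nucleus_summary", "data.frame")
  out
}

#' Normalize nucleus summaries to the session control mean
#'
#' Each quantity (total, brightest, second-brightest, all-foci sum) is
#' divided by the mean of the same quantity over the control-genotype nuclei
#' of the *same imaging session*; sessions never share a denominator.
#'
#' @param summaries data.frame of rows from [nucleus_totals()].
#' @param control_genotype genotype label of the control nuclei.
#' @return `summaries` with added norm_total, norm_brightest,
#'   norm_second_brightest, norm_allfoci columns.
#' @export
normalize_to_control <- function(summaries, control_genotype = "WT") {
  qs <- c("total", "brightest", "second_brightest", "allfoci")
  out <- summaries
  for (q in qs) out[[paste0("norm_", q)]] <- NA_real_
  for (s in unique(summaries$session)) {
    in_s <- summaries$session == s
    ctrl <- in_s & summaries$genotype == control_genotype
    if (!any(ctrl)) stop("session ", s, " has no control (",
                         control_genotype, ") nuclei")
    for (q in qs) {
      denom <- mean(summaries[[q]][ctrl], na.rm = TRUE)
      out[[paste0("norm_", q)]][in_s] <- summaries[[q]][in_s] / denom
    }
  }
  out
}

#' Center-distance colocalization rate between two focus sets
#'
#' A focus in set A counts as colocalized when any focus center in set B lies
#' within `max_distance`. The default threshold corresponds to the
#' diffraction limit (~250 nm) expressed in pixels.
#'
#' @param foci_a,foci_b matrices or data.frames of focus center coordinates
#'   (columns = dimensions, same frame for both sets).
#' @param max_distance colocalization distance threshold (> 0).
#' @return list: n_colocalized, n_total, percent.
#' @export
colocalization_rate <- function(foci_a, foci_b, max_distance) {
  a <- as.matrix(foci_a); b <- as.matrix(foci_b)
  if (nrow(a) == 0) stop("colocalization rate undefined for empty focus set A")
  stopifnot(max_distance > 0)
  n_col <- if (nrow(b) == 0) 0L else {
    hits <- vapply(seq_len(nrow(a)), function(i) {
      d2 <- colSums((t(b) - a[i, ])^2)
      any(d2 <= max_distance^2)
    }, logical(1))
    sum(hits)
  }
  list(n_colocalized = n_col, n_total = nrow(a),
       percent = 100 * n_col / nrow(a))
}
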