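#' Simulate a FRAP trace with acquisition photobleaching and noise
#'
#' The underlying focus signal is a constant baseline over `n_pre` pre-bleach
#' frames, a bleach-pulse frame, then
#' `baseline * (bleach_floor + (1 - bleach_floor) * P * (1 - exp(-k t)))`
#' with t = 0 at the first post-bleach frame. The recorded focus and
#' background ROI channels are both attenuated frame-wise by
#' `exp(-acq_bleach_rate * frame)` (imaging-laser photobleaching) and carry
#' additive Gaussian noise; the whole-image channel decays by the same
#' acquisition factor, noise-free. After [normalize_trace()] the noise-free
#' trace equals `P * (1 - exp(-k t))` exactly.
#'
#' @param plateau P, mobile-fraction plateau of the one-phase association,
#'   in (0, 1].
#' @param rate k (1/s), > 0; half-time of recovery is log(2)/k.
#' @param n_pre number of pre-bleach frames (>= 1).
#' @param n_post number of post-bleach frames (>= 3).
#' @param frame_dt frame interval (s).
#' @param acq_bleach_rate per-frame acquisition photobleaching rate.
#' @param noise_sd per-frame noise level, expressed as the SD it produces on
#'   the *normalized* recovery trace (the scale FRAP curves are reported on);
#'   the corresponding additive channel noise is applied to both the focus
#'   and background ROI channels.
#' @param seed integer seed.
#' @param baseline,background,whole_image0 raw intensity levels.
#' @param bleach_floor fraction of baseline remaining immediately after the
#'   bleach pulse.
#' @return a `frap_trace` data.frame with columns frame, time_s, focus,
#'   background, whole_image, is_bleach_frame; `n_pre` stored as attribute.
#' @export
simulate_frap_trace <- function(plateau, rate, n_pre = 10, n_post = 60,
                                frame_dt = 1, acq_bleach_rate = 0,
                                noise_sd = 0, seed = 1,
                                baseline = 1000, background = 100,
                                whole_image0 = 50000, bleach_floor = 0.3) {
  if (plateau <= 0 || plateau > 1) stop("plateau must be in (0, 1]")
  if (rate <= 0) stop("rate must be positive")
  stopifnot(n_pre >= 1, n_post >= 3)
  withr::with_seed(seed, {
    n_frames <- n_pre + 1L + n_post
    frame <- seq_len(n_frames) - 1L
    time_s <- frame * frame_dt
    is_bleach <- frame == n_pre
    signal <- numeric(n_frames)
    signal[frame < n_pre] <- baseline
    signal[is_bleach] <- baseline * (bleach_floor + 0.4 * (1 - bleach_floor))
    post <- frame > n_pre
    t_post <- (frame[post] - n_pre - 1L) * frame_dt
    signal[post] <- baseline *
      (bleach_floor + (1 - bleach_floor) * plateau * (1 - exp(-rate * t_post)))
    acq <- exp(-acq_bleach_rate * frame)
    # channel noise calibrated so the *normalized* trace has per-frame sd =
    # noise_sd: two independent channels are subtracted and the result is
    # rescaled by the recovery amplitude baseline * (1 - bleach_floor)
    ch_sd <- noise_sd * baseline * (1 - bleach_floor) / sqrt(2)
    focus <- (signal + background) * acq + rnorm(n_frames, 0, ch_sd)
    bg <- background * acq + rnorm(n_frames, 0, ch_sd)
    tr <- data.frame(frame = frame, time_s = time_s, focus = focus,
                     background = bg, whole_image = whole_image0 * acq,
                     is_bleach_frame = is_bleach)
    attr(tr, "n_pre") <- as.integer(n_pre)
    attr(tr, "truth") <- list(plateau = plateau, rate = rate,
                              t_half = log(2) / rate)
    class(tr) <- c("frap_trace", "data.frame")
    tr
  })
}

#' Default FRAP simulation parameters for the packaged recovery fixture
#'
#' Plateau 0.5 and half-time 4 s (rate log(2)/4 per second), 10 pre-bleach and
#' 60 post-bleach frames at 1 s, frame noise SD 0.05 and a mild acquisition
#' photobleaching rate; these are the study conditions the parameter-recovery
#' checks are run under.
#'
#' @return named list of [simulate_frap_trace()] arguments.
#' @export
frap_fixture_defaults <- function() {
  list(plateau = 0.5, rate = log(2) / 4, n_pre = 10, n_post = 60,
       frame_dt = 1, acq_bleach_rate = 0.002, noise_sd = 0.05)
}

#' Write / read a FRAP trace CSV
#'
#' Columns: frame, time_s, focus, background, whole_image, is_bleach_frame.
#' The pre-bleach frame count is recovered from the bleach-frame index.
#'
#' @param trace a `frap_trace`.
#' @param path CSV path.
#' @return `write_frap_csv`: invisible path; `read_frap_csv`: a `frap_trace`.
#' @export
write_frap_csv <- function(trace, path) {
  write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_frap_csv
#' @export
read_frap_csv <- function(path) {
  tr <- read.csv(path)
  need <- c("frame", "time_s", "focus", "background", "whole_image",
            "is_bleach_frame")
  if (!all(need %in% names(tr))) stop("malformed FRAP CSV: ", path)
  tr$is_bleach_frame <- as.logical(tr$is_bleach_frame)
  attr(tr, "n_pre") <- which(tr$is_bleach_frame)[1] - 1L
  class(tr) <- c("frap_trace", "data.frame")
  tr
}
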