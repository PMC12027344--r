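#' Normalize a FRAP trace
#'
#' Applies, in order: background subtraction (equal-area adjacent nuclear
#' ROI), multiplicative correction for acquisition photobleaching (divide by
#' the whole-image intensity relative to its pre-bleach mean), then an affine
#' rescale pinning the mean of the pre-bleach frames to 1 and the first
#' post-bleach frame to 0. The bleach-pulse frame is dropped, and post-bleach
#' time is re-zeroed at the first post-bleach frame, which is the time origin
#' of the one-phase-association fit.
#'
#' @param trace a `frap_trace` (see [simulate_frap_trace()],
#'   [read_frap_csv()]).
#' @return data.frame with columns frame, time_s, t_post (NA pre-bleach),
#'   value, phase ("pre"/"post").
#' @export
normalize_trace <- function(trace) {
  n_pre <- attr(trace, "n_pre")
  if (is.null(n_pre)) n_pre <- which(trace$is_bleach_frame)[1] - 1L
  stopifnot(n_pre >= 1)
  if (any(diff(trace$frame) <= 0)) stop("frames must be strictly increasing")
  if (!all(is.finite(trace$focus)) || !all(is.finite(trace$whole_image)))
    stop("non-finite intensities in trace")
  pre <- trace$frame < n_pre
  bleach <- which(trace$is_bleach_frame)[1]
  post <- seq_len(nrow(trace)) > bleach
  if (sum(post) < 3) stop("need at least 3 post-bleach frames")

  pb_factor <- trace$whole_image / mean(trace$whole_image[pre])
  v <- (trace$focus - trace$background) / pb_factor
  v_pre <- mean(v[pre])
  v0 <- v[which(post)[1]]
  if (abs(v_pre - v0) < .Machine$double.eps * 100 * max(abs(v_pre), 1))
    stop("degenerate normalization scale: pre-bleach mean equals first ",
         "post-bleach value")
  y <- (v - v0) / (v_pre - v0)

  keep <- !trace$is_bleach_frame
  t0 <- trace$time_s[which(post)[1]]
  out <- data.frame(frame = trace$frame[keep], time_s = trace$time_s[keep],
                    t_post = ifelse(post[keep], trace$time_s[keep] - t0, NA),
                    value = y[keep],
                    phase = ifelse(post[keep], "post", "pre"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Fit the one-phase association recovery model
#'
#' Fits `y(t) = P * (1 - exp(-k t))` to the post-bleach points of a
#' normalized trace by bounded least squares (P in (0, 1.5], k > 0), with the
#' deterministic initialization P0 = last observed value and
#' k0 = log(2) / (time to reach half of the last value), plus a fixed ladder
#' of restart perturbations if the first fit does not converge. Reports the
#' half-time t1/2 = log(2)/k and the immobile fraction 1 - P; a fitted
#' immobile fraction below -0.1 is flagged.
#'
#' @param normalized output of [normalize_trace()], or any data.frame with
#'   `t_post` and `value` columns (post-bleach rows used).
#' @return a `frap_fit` list: plateau, rate, t_half, immobile_fraction, rss,
#'   n_points, flagged.
#' @export
fit_recovery <- function(normalized) {
  d <- normalized[!is.na(normalized$t_post), c("t_post", "value")]
  names(d) <- c("t", "y")
  if (nrow(d) < 3) stop("need at least 3 post-bleach points")
  if (!all(is.finite(d$y))) stop("non-finite values in normalized trace")

  y_last <- d$y[nrow(d)]
  p0 <- min(max(y_last, 0.05), 1.5)
  i_half <- which(d$y >= y_last / 2 & d$t > 0)[1]
  k0 <- if (is.na(i_half)) log(2) / max(d$t) else log(2) / d$t[i_half]
  k0 <- max(k0, 1e-4)

  fit <- NULL
  for (mult in list(c(1, 1), c(1, 0.5), c(1, 2), c(0.7, 1.5))) {
    st <- list(P = min(max(p0 * mult[1], 1e-3), 1.5), k = k0 * mult[2])
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ P * (1 - exp(-k * t)), data = d, start = st,
                        lower = c(P = 1e-6, k = 1e-6),
                        upper = c(P = 1.5, k = 1e3),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit))
    stop("one-phase association fit failed to converge (n = ", nrow(d),
         " points, init P0 = ", signif(p0, 3), ", k0 = ", signif(k0, 3), ")")
  cf <- coef(fit)
  structure(list(plateau = unname(cf["P"]), rate = unname(cf["k"]),
                 t_half = log(2) / unname(cf["k"]),
                 immobile_fraction = 1 - unname(cf["P"]),
                 rss = sum(resid(fit)^2), n_points = nrow(d),
                 flagged = (1 - unname(cf["P"])) < -0.1),
            class = "frap_fit")
}

#' Summarize a set of FRAP fits
#'
#' Arithmetic mean, sample SD (n - 1 denominator) and SEM = SD/sqrt(n) for
#' the half-time and immobile fraction across fits. With a single fit, SD and
#' SEM are reported as NA.
#'
#' @param fits list of `frap_fit` objects.
#' @return data.frame with one row per quantity (t_half, immobile_fraction)
#'   and columns mean, sd, sem, n.
#' @export
summarize_fits <- function(fits) {
  if (length(fits) < 1) stop("no fits to summarize")
  stopifnot(all(vapply(fits, inherits, logical(1), "frap_fit")))
  one <- function(x) {
    n <- length(x)
    s <- if (n > 1) sd(x) else NA_real_
    data.frame(mean = mean(x), sd = s,
               sem = if (n > 1) s / sqrt(n) else NA_real_, n = n)
  }
  out <- rbind(one(vapply(fits, `[[`, numeric(1), "t_half")),
               one(vapply(fits, `[[`, numeric(1), "immobile_fraction")))
  out <- cbind(quantity = c("t_half", "immobile_fraction"), out)
  rownames(out) <- NULL
  out
}
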