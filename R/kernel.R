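# Temporal response function and the minimal linear encoding model.
#
# The minimal model says: the membrane potential of an ON-region is the
# pixel luminance contrast convolved with the unit's temporal response
# function; for an OFF-region the kernel is sign-inverted; the encoded
# image is ON minus OFF.  With a biphasic (adapted) kernel the encoded
# image right after a transition approximates the difference between the
# current and the previous image, and only later the current image.

#' Biphasic temporal response function
#'
#' Difference of two gamma-shaped lobes: a fast positive (depolarizing for
#' an ON region) lobe and a slower, broader undershoot.  The kernel is
#' sampled on a regular lag grid and scaled to unit peak.  The undershoot
#' area ratio sets the net integral: at ratio 1 the kernel integrates to
#' zero and a sustained stimulus leaves no late representation; the
#' default 0.9 leaves a modestly positive integral so the current image
#' retains a sustained (if weak) representation late in the period.
#'
#' @param peak_ms Lag of the positive lobe's peak (default 40 ms).
#' @param undershoot_ms Lag of the undershoot's (negative) peak (60 ms).
#' @param shape,undershoot_shape Gamma shape parameters of the two lobes.
#' @param undershoot_ratio Undershoot area divided by positive-lobe area.
#' @param dt_ms Sampling interval of the lag grid (default 1 ms).
#' @param t_max_ms Kernel support (default 250 ms, one stimulus period).
#' @return Object of class `"trp_kernel"`: list with `lag_ms`, `value`
#'   (unit peak), `dt_ms`.
#' @examples
#' k <- trp_kernel()
#' k$lag_ms[which.max(k$value)]   # ~40 ms
#' @export
trp_kernel <- function(peak_ms = 40, undershoot_ms = 60,
                       shape = 5, undershoot_shape = 4,
                       undershoot_ratio = 0.9,
                       dt_ms = 1, t_max_ms = 250) {
  stopifnot(peak_ms > 0, undershoot_ms > 0, shape > 1,
            undershoot_shape > 1, dt_ms > 0, t_max_ms >= dt_ms)
  lag <- seq(dt_ms, t_max_ms, by = dt_ms)
  pos <- stats::dgamma(lag, shape = shape, scale = peak_ms / (shape - 1))
  neg <- stats::dgamma(lag, shape = undershoot_shape,
                       scale = undershoot_ms / (undershoot_shape - 1))
  v <- pos - undershoot_ratio * neg
  v <- v / max(abs(v))
  structure(list(lag_ms = lag, value = v, dt_ms = dt_ms),
            class = "trp_kernel")
}

# wrap raw samples as a kernel object
.as_kernel <- function(value, dt_ms) {
  stopifnot(length(value) >= 1, all(is.finite(value)))
  structure(list(lag_ms = seq_along(value) * dt_ms - dt_ms,
                 value = value, dt_ms = dt_ms),
            class = "trp_kernel")
}

#' @export
print.trp_kernel <- function(x, ...) {
  cat(sprintf(
    "Temporal response function: %d samples at %.3g ms, peak at %.3g ms, net integral %.3g (peak-normalized)\n",
    length(x$value), x$dt_ms, x$lag_ms[which.max(x$value)], sum(x$value)))
  invisible(x)
}

#' @export
plot.trp_kernel <- function(x, ...) {
  graphics::plot(x$lag_ms, x$value, type = "l", xlab = "lag (ms)",
                 ylab = "kernel (unit peak)", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Serialize a kernel as two-column delimited text
#' @param kernel A `"trp_kernel"`.
#' @param path File path (columns `lag_ms`, `value`).
#' @export
write_kernel <- function(kernel, path) {
  stopifnot(inherits(kernel, "trp_kernel"))
  utils::write.table(data.frame(lag_ms = kernel$lag_ms, value = kernel$value),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_kernel
#' @export
read_kernel <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  stopifnot(all(c("lag_ms", "value") %in% names(df)), nrow(df) >= 1)
  dt <- if (nrow(df) > 1) diff(df$lag_ms[1:2]) else 1
  structure(list(lag_ms = df$lag_ms, value = df$value, dt_ms = dt),
            class = "trp_kernel")
}

# causal discrete convolution with zero-padded history; y[t] depends on
# x[t], x[t-1], ...
.conv_causal <- function(x, k) {
  n <- length(x); L <- length(k)
  y <- stats::filter(c(rep(0, L - 1), x), filter = k,
                     method = "convolution", sides = 1)
  as.numeric(y[(L - 1 + 1):(L - 1 + n)])
}

#' Encode one pixel's luminance time course
#'
#' Causal discrete convolution of a pixel's luminance-contrast time course
#' with the temporal response function: the model membrane potential of an
#' ON-region covering that pixel.  The history before the first sample is
#' taken as zero contrast (gray screen before the session).
#'
#' @param sis Numeric vector: luminance contrast over time, sampled at the
#'   kernel's `dt_ms`.
#' @param kernel A `"trp_kernel"`.
#' @return Numeric vector, same length as `sis`; entry `t` depends only on
#'   `sis[1..t]`.
#' @export
encode_pixel <- function(sis, kernel) {
  if (!inherits(kernel, "trp_kernel") || length(kernel$value) == 0L)
    stop("'kernel' must be a non-empty trp_kernel")
  if (!is.numeric(sis) || any(!is.finite(sis)))
    stop("'sis' must be a finite numeric vector")
  .conv_causal(sis, kernel$value)
}

#' Scalar drive of a unit from encoded pixels
#'
#' Sums the encoded contrast over the unit's ON pixels and subtracts the
#' sum over its OFF pixels (where the response function is inverted).
#'
#' @param eis Matrix of encoded contrast, time x pixels (or a vector for a
#'   single pixel).
#' @param on_weights,off_weights Non-negative weight vectors, one entry
#'   per pixel column of `eis`.
#' @return Numeric vector: drive over time.
#' @export
unit_drive <- function(eis, on_weights, off_weights) {
  if (is.null(dim(eis))) eis <- matrix(eis, ncol = 1)
  npx <- ncol(eis)
  if (length(on_weights) != npx || length(off_weights) != npx)
    stop("weight length must match the number of pixel columns (", npx, ")")
  if (any(on_weights < 0) || any(off_weights < 0))
    stop("weights must be non-negative")
  if (all(on_weights == 0) && all(off_weights == 0))
    stop("at least one region must be non-empty")
  as.numeric(eis %*% (on_weights - off_weights))
}

# For a step from image A (shown for period_ms) to image B, the encoded
# image at lag t after the step is cur_coef(t) * B + prev_coef(t) * A:
# cur_coef = cumulative kernel sum up to t, prev_coef = kernel mass on
# lags (t, t + period_ms].
.step_coefficients <- function(kernel, period_ms = 250) {
  k <- kernel$value
  n_prev <- round(period_ms / kernel$dt_ms)
  cur <- cumsum(k)
  total <- c(cumsum(k), rep(sum(k), n_prev))  # cumsum padded past support
  idx_hi <- pmin(seq_along(k) + n_prev, length(total))
  prev <- total[idx_hi] - cur
  list(cur = cur, prev = prev, t_ms = kernel$lag_ms)
}

#' Model correlation time course over all pattern transitions
#'
#' For every ordered pair (A, B) of stimulus patterns, computes the 2x2
#' image encoded by the minimal model after the A-to-B transition (A shown
#' for one 250 ms period, then B), correlates the encoded image at each
#' time bin with the normalized previous pattern A, current pattern B and
#' difference pattern B - A, and averages across all P x P transitions.
#' Identity transitions have a zero difference vector and contribute 0 to
#' the difference-pattern average.
#'
#' @param kernel A `"trp_kernel"`.
#' @param patterns Pattern set (default full 81).
#' @param bin_ms Output bin width in ms (default 10).
#' @param period_ms Duration each pattern is shown (250 ms).
#' @return A `"correlation_trace"` data.frame: `time_ms` (bin start),
#'   mean and SEM of the three correlations, `n` transitions per bin.
#' @examples
#' tr <- model_correlation_timecourse(trp_kernel())
#' crossover_time(tr)
#' @export
model_correlation_timecourse <- function(kernel, patterns = enumerate_patterns(),
                                         bin_ms = 10, period_ms = 250) {
  stopifnot(inherits(kernel, "trp_kernel"))
  pm <- pattern_matrix(patterns)
  P <- nrow(pm$raw)
  pairs <- expand.grid(a = seq_len(P), b = seq_len(P))
  A <- pm$raw[pairs$a, , drop = FALSE]
  B <- pm$raw[pairs$b, , drop = FALSE]
  An <- .normalize_rows(A); Bn <- .normalize_rows(B)
  Dn <- .normalize_rows(B - A)

  co <- .step_coefficients(kernel, period_ms)
  keep <- co$t_ms <= period_ms
  t_ms <- co$t_ms[keep]
  bins <- split(seq_along(t_ms), floor((t_ms - kernel$dt_ms / 2) / bin_ms))

  rows <- lapply(bins, function(ii) {
    # average encoded image over the samples of this bin
    cur_c <- mean(co$cur[keep][ii]); prev_c <- mean(co$prev[keep][ii])
    En <- .normalize_rows(cur_c * B + prev_c * A)
    cp <- rowSums(En * An); cc <- rowSums(En * Bn); cd <- rowSums(En * Dn)
    n <- length(cp)
    data.frame(time_ms = floor(t_ms[ii[1]] - kernel$dt_ms / 2),
               corr_previous = mean(cp), corr_current = mean(cc),
               corr_difference = mean(cd),
               sem_previous = stats::sd(cp) / sqrt(n),
               sem_current = stats::sd(cc) / sqrt(n),
               sem_difference = stats::sd(cd) / sqrt(n),
               n = n)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("correlation_trace", "data.frame"),
            bin_ms = bin_ms, source = "minimal_model")
}

#' Estimate a temporal response function by reverse correlation
#'
#' Spike-triggered average of a white-noise stimulus: for each lag, the
#' spike-count-weighted mean of the stimulus frames preceding the spikes,
#' per pixel; pixel kernels are then averaged over the unit's driving
#' pixels with OFF pixels sign-flipped, and scaled to unit peak magnitude.
#'
#' @param stimulus Matrix pixels x frames of luminance contrast; each
#'   pixel should be (close to) zero-mean over frames.
#' @param counts Integer vector of spike counts per frame.
#' @param frame_ms Frame duration in ms (default 8.3).
#' @param max_lag_ms Largest lag of the estimated kernel (default 200 ms).
#' @param on_pixels,off_pixels Integer indices of the unit's ON and OFF
#'   pixels (default: all pixels ON).
#' @param normalize Scale the estimate to unit peak magnitude (default);
#'   with `FALSE` the raw spike-triggered average is returned, whose
#'   fluctuations shrink as 1/sqrt(number of spikes) for stimulus-independent
#'   spiking.
#' @return A `"trp_kernel"` sampled at `frame_ms`.
#' @export
reverse_correlate <- function(stimulus, counts, frame_ms = 8.3,
                              max_lag_ms = 200,
                              on_pixels = seq_len(nrow(stimulus)),
                              off_pixels = integer(0),
                              normalize = TRUE) {
  stimulus <- as.matrix(stimulus)
  nf <- ncol(stimulus)
  if (length(counts) != nf)
    stop("'counts' must have one entry per stimulus frame")
  total <- sum(counts)
  if (total == 0)
    stop("no spikes: kernel is unestimable")
  n_lags <- max(1L, floor(max_lag_ms / frame_ms) + 1L)
  px <- c(on_pixels, off_pixels)
  sgn <- c(rep(1, length(on_pixels)), rep(-1, length(off_pixels)))
  sta <- matrix(0, length(px), n_lags)
  for (l in seq_len(n_lags) - 1L) {
    tt <- seq_len(nf - l) + l              # frame of the spike
    w <- counts[tt]
    sta[, l + 1L] <- (stimulus[px, tt - l, drop = FALSE] %*% w) / total
  }
  kern <- as.numeric(crossprod(sgn, sta)) / length(px)
  if (normalize) {
    peak <- max(abs(kern))
    if (peak > 0) kern <- kern / peak
  }
  .as_kernel(kern, frame_ms)
}
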