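# Synthetic multiunit population: minimal-model drive, rectified-linear
# rate, Poisson spike counts.  Stands in for a 16-site laminar probe.

#' Generate a heterogeneous synthetic multiunit population
#'
#' Each unit is simple-cell-like over the four tiles of the miniature
#' image: a signed weight vector over tiles (positive entries = ON
#' sub-region, negative = OFF), a shared biphasic temporal response
#' function, a gain mapping drive to firing rate, an additive baseline
#' rate and a response latency.  Units are generated in sign-opposite
#' pairs (w, -w) so that the population covers both contrast polarities,
#' the way ON- and OFF-dominated multiunits do; together with random
#' directions this makes the population span all four tiles.
#'
#' @param n_units Number of units (default 16, one laminar probe).
#' @param kernel A `"trp_kernel"` shared across the population.
#' @param gain_range Uniform range of gains (spikes/s per unit drive).
#' @param baseline_range Uniform range of baseline rates (spikes/s).
#' @param latency_ms Response latency (default 25 ms).
#' @param seed Optional seed; the population is reproducible given it.
#' @return Object of class `"unit_population"`: list of units, each with
#'   `weights` (signed, unit norm), `on_weights`, `off_weights`, `gain`,
#'   `baseline`, `latency_ms`; the kernel is stored as attribute
#'   `kernel`.
#' @export
make_population <- function(n_units = 16, kernel = trp_kernel(),
                            gain_range = c(80, 200),
                            baseline_range = c(2, 8),
                            latency_ms = 25, seed = NULL) {
  stopifnot(n_units >= 1, inherits(kernel, "trp_kernel"))
  units <- .with_seed(seed, {
    n_half <- ceiling(n_units / 2)
    ws <- lapply(seq_len(n_half), function(i) {
      w <- stats::rnorm(4)
      while (sqrt(sum(w^2)) < 1e-8) w <- stats::rnorm(4)
      w / sqrt(sum(w^2))
    })
    ws <- do.call(c, lapply(ws, function(w) list(w, -w)))[seq_len(n_units)]
    gains <- stats::runif(n_units, gain_range[1], gain_range[2])
    bases <- stats::runif(n_units, baseline_range[1], baseline_range[2])
    lapply(seq_len(n_units), function(i) {
      w <- ws[[i]]
      list(weights = w,
           on_weights = pmax(w, 0), off_weights = pmax(-w, 0),
           gain = gains[i], baseline = bases[i], latency_ms = latency_ms)
    })
  })
  if (all(vapply(units, `[[`, 0, "gain") == 0))
    warning("degenerate population: all gains are zero")
  structure(units, class = "unit_population", kernel = kernel, seed = seed)
}

#' @export
print.unit_population <- function(x, ...) {
  g <- vapply(x, `[[`, 0, "gain")
  cat(sprintf(
    "Synthetic multiunit population: %d units, gain %.3g-%.3g spk/s, latency %g ms\n",
    length(x), min(g), max(g), x[[1]]$latency_ms))
  invisible(x)
}

# 4 x n_t tile contrast time course of a schedule at resolution dt_ms
.schedule_contrast <- function(schedule, patterns, dt_ms) {
  total_ms <- max(schedule$onset_ms + schedule$duration_ms)
  n_t <- round(total_ms / dt_ms)
  cc <- matrix(0, 4, n_t)
  for (i in seq_len(nrow(schedule))) {
    pid <- schedule$pattern_id[i]
    if (is.na(pid)) next
    j <- match(pid, patterns$ids)
    a <- round(schedule$onset_ms[i] / dt_ms) + 1L
    b <- round((schedule$onset_ms[i] + schedule$duration_ms[i]) / dt_ms)
    cc[, a:b] <- patterns$contrast[j, ]
  }
  cc
}

#' Simulate spike-count responses to a schedule
#'
#' Runs the minimal model for every unit over the whole session: tile
#' contrast is convolved with the temporal response function, combined
#' with the unit's signed tile weights, delayed by the latency, rectified
#' and scaled, `rate(t) = baseline + gain * max(0, drive(t - latency))`,
#' and spike counts are drawn per time bin as independent Poisson with
#' mean `rate * bin`.  With `noise = FALSE` the "counts" are the Poisson
#' means themselves (a real-valued noiseless tensor for oracle tests).
#'
#' @param schedule A `"trial_schedule"`.
#' @param population A `"unit_population"`.
#' @param bin_ms Bin width in ms, in 1..50 (default 10).  Bin 0 starts at
#'   period onset; bins cover `[t, t + bin_ms)` relative to onset.
#' @param seed Optional seed for the Poisson draws.
#' @param noise If `FALSE`, return expected counts (no Poisson noise).
#' @param patterns Pattern set referenced by the schedule.
#' @return A `"spike_count_tensor"`: numeric array units x bins x periods
#'   with attributes `bin_ms`, `noise`.
#' @export
simulate_responses <- function(schedule, population, bin_ms = 10,
                               seed = NULL, noise = TRUE,
                               patterns = enumerate_patterns()) {
  stopifnot(inherits(schedule, "trial_schedule"),
            inherits(population, "unit_population"))
  if (!is.numeric(bin_ms) || bin_ms <= 0)
    stop("'bin_ms' must be positive")
  if (bin_ms < 1 || bin_ms > 50)
    stop("'bin_ms' must lie in [1, 50] ms")
  kernel <- attr(population, "kernel")
  dt <- kernel$dt_ms
  cc <- .schedule_contrast(schedule, patterns, dt)
  n_t <- ncol(cc)
  # scale so a unit-contrast step reaches peak drive 1: gain then reads
  # "evoked spikes/s per unit contrast at the transient peak"
  drive_scale <- max(abs(cumsum(kernel$value)))
  eis <- t(apply(cc, 1, .conv_causal, k = kernel$value)) / drive_scale

  n_units <- length(population)
  n_bins <- floor(schedule$duration_ms[1] / bin_ms)
  n_periods <- nrow(schedule)
  samples_per_bin <- bin_ms / dt
  if (abs(samples_per_bin - round(samples_per_bin)) > 1e-9)
    stop("'bin_ms' must be a multiple of the kernel sampling interval")
  samples_per_bin <- round(samples_per_bin)

  expected <- array(0, dim = c(n_units, n_bins, n_periods))
  onset_idx <- round(schedule$onset_ms / dt)
  for (u in seq_len(n_units)) {
    un <- population[[u]]
    drive <- as.numeric(crossprod(eis, un$weights))
    lat <- round(un$latency_ms / dt)
    drive <- c(rep(0, lat), drive)[seq_len(n_t)]
    rate <- un$baseline + un$gain * pmax(0, drive)       # spikes/s
    mean_count <- rate * dt / 1000                       # per dt sample
    for (p in seq_len(n_periods)) {
      seg <- mean_count[onset_idx[p] + seq_len(n_bins * samples_per_bin)]
      expected[u, , p] <- colSums(matrix(seg, samples_per_bin))
    }
  }
  counts <- if (noise) {
    .with_seed(seed, array(stats::rpois(length(expected), expected),
                           dim = dim(expected)))
  } else expected
  structure(counts, class = "spike_count_tensor",
            bin_ms = bin_ms, noise = noise)
}

#' @export
print.spike_count_tensor <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "Spike count tensor: %d sites x %d bins (%g ms) x %d periods%s\n",
    d[1], d[2], attr(x, "bin_ms"), d[3],
    if (isTRUE(attr(x, "noise"))) "" else " [noiseless]"))
  invisible(x)
}
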