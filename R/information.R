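# Mutual information between spike counts and stimulus identity, with
# shuffle bias correction.  Counts in one time bin are discretized into
# four equal-width intervals spanning the observed range; the empirical
# joint distribution over (count interval, stimulus) gives the
# information, and the mean information under random stimulus-label
# permutations is subtracted to remove the limited-sampling bias.

#' Discretize spike counts into four range-relative intervals
#'
#' Computes the minimum and maximum count across all trials of all
#' stimuli, partitions `[min, max + 1)` into four equal-width intervals,
#' and assigns each count the index of the interval containing it.  For
#' the range 0..7 this gives the intervals 0-1, 2-3, 4-5, 6-7 spikes; the
#' continuous equal-width construction generalizes to ranges not
#' divisible by four.  A degenerate range (all counts equal) puts all
#' trials in interval 0 and carries no information.
#'
#' @param counts Integer vector of spike counts (all trials, all stimuli,
#'   one time bin).
#' @return Integer vector of interval labels 0..3 with attributes
#'   `edges` (the 5 interval boundaries) and `degenerate`.
#' @export
bin_counts <- function(counts) {
  stopifnot(is.numeric(counts), length(counts) >= 1, all(is.finite(counts)))
  lo <- min(counts); hi <- max(counts)
  if (hi == lo) {
    return(structure(rep(0L, length(counts)),
                     edges = lo + 0:4 * 0.25, degenerate = TRUE))
  }
  width <- (hi - lo + 1) / 4
  lab <- pmin(3L, as.integer(floor((counts - lo) / width)))
  structure(lab, edges = lo + 0:4 * width, degenerate = FALSE)
}

#' Mutual information of a joint distribution (bits)
#'
#' `I = sum_{r,s} P(r,s) log2( P(r,s) / (P(r) P(s)) )`, with `0 log 0 = 0`.
#'
#' @param joint Numeric matrix of probabilities (rows = response
#'   intervals, columns = stimuli); must be non-negative and sum to 1.
#' @return Information in bits (non-negative).
#' @examples
#' mutual_information(diag(4) / 4)        # 2 bits
#' mutual_information(outer(c(.5, .5), c(.25, .25, .25, .25)))  # 0 bits
#' @export
mutual_information <- function(joint) {
  joint <- as.matrix(joint)
  if (any(joint < 0)) stop("probabilities must be non-negative")
  if (abs(sum(joint) - 1) > 1e-8)
    stop("joint distribution must sum to 1")
  pr <- rowSums(joint); ps <- colSums(joint)
  ratio <- joint / outer(pr, ps)
  terms <- joint * log2(ratio)
  sum(terms[joint > 0])
}

# raw (uncorrected) information between stimulus labels and counts
.info_raw <- function(counts, labels) {
  lab <- bin_counts(counts)
  if (isTRUE(attr(lab, "degenerate"))) return(0)
  joint <- table(factor(lab, levels = 0:3), factor(labels)) / length(counts)
  mutual_information(unclass(joint))
}

# counts and stimulus labels for one site/time-bin, optionally reading
# the counts `lag_periods` pattern periods after the labelled one
.bin_samples <- function(tensor, schedule, site, bin, paradigm,
                         lag_periods = 0) {
  idx <- which(schedule$paradigm == paradigm & !is.na(schedule$pattern_id))
  labels <- schedule$pattern_id[idx]
  if (lag_periods > 0) {
    # successor must be the immediately following contiguous period of
    # the same paradigm (block boundaries are dropped)
    succ <- match(idx + lag_periods, idx)
    contiguous <- !is.na(succ) &
      (schedule$onset_ms[idx + lag_periods] - schedule$onset_ms[idx]) ==
        lag_periods * schedule$duration_ms[1]
    labels <- labels[contiguous]
    idx <- idx[contiguous] + lag_periods
  }
  list(counts = as.numeric(tensor[site, bin, idx]), labels = labels)
}

#' Shuffle-corrected stimulus information of one site and time bin
#'
#' Raw information between the stimulus label and the discretized spike
#' count, minus the mean information over `n_shuffles` random
#' stimulus-label permutations.  The correction removes the positive
#' limited-sampling bias and can leave slightly negative values for
#' uninformative sites.
#'
#' @param tensor A `"spike_count_tensor"`.
#' @param schedule Its `"trial_schedule"`.
#' @param site Site index.
#' @param bin Time-bin index (1-based; bin `b` covers
#'   `[(b-1) bin_ms, b bin_ms)` after period onset).
#' @param n_shuffles Number of label permutations (default 20).
#' @param seed Optional seed for the permutations.
#' @param paradigm Paradigm whose periods are used (default relay).
#' @param lag_periods Read counts this many periods after the labelled
#'   one (0 = current stimulus, 1 = spikes at t + 250 ms).
#' @return Bias-corrected information in bits.
#' @export
corrected_information <- function(tensor, schedule, site, bin,
                                  n_shuffles = 20, seed = NULL,
                                  paradigm = "relay", lag_periods = 0) {
  if (n_shuffles < 1) stop("'n_shuffles' must be >= 1")
  smp <- .bin_samples(tensor, schedule, site, bin, paradigm, lag_periods)
  raw <- .info_raw(smp$counts, smp$labels)
  bias <- .with_seed(seed, mean(vapply(seq_len(n_shuffles), function(i)
    .info_raw(smp$counts, sample(smp$labels)), numeric(1))))
  raw - bias
}

#' Information about the previous stimulus
#'
#' Identical to [corrected_information()] but pairing each stimulus label
#' with the spike counts observed one full 250 ms period later (counting
#' spikes at `t + 250 ms`), so the estimate asks what the current firing
#' still conveys about the preceding pattern.  Periods without a
#' contiguous successor (block boundaries) are dropped.
#'
#' @inheritParams corrected_information
#' @export
previous_stimulus_information <- function(tensor, schedule, site, bin,
                                          n_shuffles = 20, seed = NULL,
                                          paradigm = "relay") {
  corrected_information(tensor, schedule, site, bin,
                        n_shuffles = n_shuffles, seed = seed,
                        paradigm = paradigm, lag_periods = 1)
}

#' Information time course averaged over significant sites
#'
#' Computes shuffle-corrected information about the current and the
#' previous stimulus for every time bin, averaged across the included
#' sites (by default the sites passing [significance_mask()]).
#'
#' @param tensor,schedule As above.
#' @param sites Integer site indices; default the significance mask.
#' @param n_shuffles,seed Passed to [corrected_information()].
#' @param paradigm Paradigm decoded (default relay).
#' @return An `"information_trace"` data.frame with columns `time_ms`,
#'   `info_current_bits`, `info_previous_bits`, `n_sites`.
#' @export
information_trace <- function(tensor, schedule, sites = NULL,
                              n_shuffles = 20, seed = NULL,
                              paradigm = "relay") {
  if (is.null(sites)) sites <- which(significance_mask(tensor, schedule))
  if (length(sites) == 0) stop("no sites included")
  bin_ms <- attr(tensor, "bin_ms")
  n_bins <- dim(tensor)[2]
  seeds <- if (is.null(seed)) rep(list(NULL), n_bins) else
    as.list(seed + seq_len(n_bins))
  rows <- lapply(seq_len(n_bins), function(b) {
    cur <- vapply(sites, function(s)
      corrected_information(tensor, schedule, s, b, n_shuffles,
                            seeds[[b]], paradigm, 0), numeric(1))
    prev <- vapply(sites, function(s)
      corrected_information(tensor, schedule, s, b, n_shuffles,
                            seeds[[b]], paradigm, 1), numeric(1))
    data.frame(time_ms = (b - 1) * bin_ms,
               info_current_bits = mean(cur),
               info_previous_bits = mean(prev),
               n_sites = length(sites))
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("information_trace", "data.frame"),
            bin_ms = bin_ms)
}

#' @export
print.information_trace <- function(x, ...) {
  cat(sprintf(
    "Information trace: %d bins of %g ms, %d sites; peak current %.3g bits at %g ms\n",
    nrow(x), attr(x, "bin_ms"), x$n_sites[1],
    max(x$info_current_bits), x$time_ms[which.max(x$info_current_bits)]))
  invisible(x)
}

#' @export
plot.information_trace <- function(x, ...) {
  graphics::matplot(x$time_ms, cbind(x$info_current_bits, x$info_previous_bits),
                    type = "l", lty = c(1, 2), col = c("black", "gray40"),
                    xlab = "time after transition (ms)",
                    ylab = "information (bits)", ...)
  graphics::legend("topright", c("current", "previous"), lty = c(1, 2),
                   col = c("black", "gray40"), bty = "n")
  invisible(x)
}
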