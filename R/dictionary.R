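# Population-code dictionary and correlation-weighted decoding.
#
# The dictionary RR holds each pattern's mean population firing rate
# vector (rows = patterns, columns = recording sites) measured in the
# blank-separated dictionary paradigm.  Row-normalizing RR gives R, so
# that multiplying R with a normalized instantaneous population vector r
# yields the vector c of Pearson correlations between r and every
# pattern's code.  The decoded image is the correlation-weighted average
# of all (normalized) stimulus patterns.

#' Build the population-code dictionary
#'
#' Averages each site's firing rate over a window after pattern onset and
#' over all repetitions of each pattern in the dictionary paradigm, giving
#' the P x N rate matrix `RR`; `R` is its row-normalized form (see
#' [normalize_vector()]).  Supported windows include 0-90, 90-250 and
#' 0-250 ms.  A site with no rate variation across patterns normalizes to
#' a zero column contribution rather than erroring.
#'
#' @param tensor A `"spike_count_tensor"` covering the schedule.
#' @param schedule The `"trial_schedule"` the tensor was recorded under.
#' @param window Length-2 numeric, ms after pattern onset (default
#'   `c(0, 90)`); must align with the tensor's bin grid.
#' @param patterns Pattern set.
#' @return Object of class `"pattern_dictionary"`: list with `RR`
#'   (spikes/s), `R`, `window`, `bin_ms`, `pattern_ids`, `n_repeats`.
#' @export
build_dictionary <- function(tensor, schedule, window = c(0, 90),
                             patterns = enumerate_patterns()) {
  stopifnot(inherits(tensor, "spike_count_tensor"),
            inherits(schedule, "trial_schedule"),
            length(window) == 2, window[1] < window[2],
            window[1] >= 0, window[2] <= schedule$duration_ms[1])
  bin_ms <- attr(tensor, "bin_ms")
  idx <- which(schedule$paradigm == "dictionary" & !is.na(schedule$pattern_id))
  if (length(idx) == 0) stop("schedule contains no dictionary-paradigm periods")
  pids <- schedule$pattern_id[idx]
  missing <- setdiff(patterns$ids, pids)
  if (length(missing))
    stop("patterns missing from the dictionary schedule: ",
         paste(utils::head(missing, 5), collapse = ", "))
  starts <- (seq_len(dim(tensor)[2]) - 1) * bin_ms
  inwin <- starts >= window[1] & (starts + bin_ms) <= window[2]
  if (!any(inwin)) stop("window contains no complete bins")
  win_s <- sum(inwin) * bin_ms / 1000

  n_sites <- dim(tensor)[1]
  rate <- apply(tensor[, inwin, idx, drop = FALSE], c(1, 3), sum) / win_s
  RR <- t(vapply(patterns$ids, function(p)
    rowMeans(rate[, pids == p, drop = FALSE]), numeric(n_sites)))
  dimnames(RR) <- list(pattern = patterns$ids, site = seq_len(n_sites))
  structure(list(RR = RR, R = .normalize_rows(RR), window = window,
                 bin_ms = bin_ms, pattern_ids = patterns$ids,
                 n_repeats = sum(pids == patterns$ids[1])),
            class = "pattern_dictionary")
}

#' @export
print.pattern_dictionary <- function(x, ...) {
  cat(sprintf(
    "Population-code dictionary: %d patterns x %d sites, window %g-%g ms, %d repetitions averaged\n",
    nrow(x$RR), ncol(x$RR), x$window[1], x$window[2], x$n_repeats))
  invisible(x)
}

#' @export
coef.pattern_dictionary <- function(object, ...) object$RR

#' Export / import a dictionary as a delimited table
#' @param dictionary A `"pattern_dictionary"`.
#' @param path File path; the window is stored in a comment header line.
#' @export
write_dictionary <- function(dictionary, path) {
  stopifnot(inherits(dictionary, "pattern_dictionary"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# window_ms: %g %g", dictionary$window[1],
                     dictionary$window[2]), con)
  df <- data.frame(pattern_id = dictionary$pattern_ids, dictionary$RR,
                   check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Significant-response mask over recording sites
#'
#' A site is significant if its mean evoked firing rate, averaged across
#' all dictionary-paradigm pattern periods and time bins, strictly exceeds
#' the mean plus two standard deviations of its baseline PSTH: the
#' trial-averaged firing rate in the `baseline_ms` of blank screen
#' immediately preceding pattern presentations (-100 to 0 ms), with mean
#' and standard deviation taken across those baseline time bins.
#'
#' @param tensor,schedule As in [build_dictionary()].
#' @param baseline_ms Length of the pre-onset baseline window taken from
#'   the end of each blank period (default 100 ms).
#' @return Logical vector, one entry per site.
#' @export
significance_mask <- function(tensor, schedule, baseline_ms = 100) {
  stopifnot(inherits(tensor, "spike_count_tensor"))
  bin_ms <- attr(tensor, "bin_ms")
  blanks <- which(schedule$paradigm == "dictionary" & is.na(schedule$pattern_id))
  if (length(blanks) == 0)
    stop("schedule has no blank periods: no pre-onset baseline bins")
  starts <- (seq_len(dim(tensor)[2]) - 1) * bin_ms
  base_bins <- which(starts >= (schedule$duration_ms[1] - baseline_ms))
  if (length(base_bins) < 2) stop("need at least two baseline bins")
  pat <- which(schedule$paradigm == "dictionary" & !is.na(schedule$pattern_id))

  vapply(seq_len(dim(tensor)[1]), function(s) {
    # trial-averaged baseline rate per bin position (the PSTH tail)
    base <- rowMeans(matrix(tensor[s, base_bins, blanks],
                            nrow = length(base_bins))) / (bin_ms / 1000)
    evoked <- mean(tensor[s, , pat]) / (bin_ms / 1000)
    evoked > mean(base) + 2 * stats::sd(base)
  }, logical(1))
}

#' Decode one instantaneous population vector
#'
#' Normalizes the population spike-count vector `rr` to `r`, correlates it
#' with every dictionary row (`c = R r`), and forms the decoded image as
#' the correlation-weighted average of all normalized patterns,
#' `d_l = sum_p c_p S_pl`, itself normalized.  Also reports the
#' maximum-correlation pattern (the argmax decoding variant).
#'
#' @param rr Numeric vector of spike counts, one per site.
#' @param dictionary A `"pattern_dictionary"`.
#' @param patterns A `"pattern_matrix"` (default: the full set).
#' @return List with `c` (P correlations, each in `[-1, 1]`), `d`
#'   (normalized decoded 4-vector), `best_id` (argmax pattern id).
#' @examples
#' # toy 2-site, 2-pattern dictionary
#' @export
decode_instant <- function(rr, dictionary, patterns = pattern_matrix()) {
  stopifnot(inherits(dictionary, "pattern_dictionary"),
            inherits(patterns, "pattern_matrix"))
  if (length(rr) != ncol(dictionary$R))
    stop("'rr' must have one entry per dictionary site (",
         ncol(dictionary$R), ")")
  r <- normalize_vector(rr)
  cvec <- as.numeric(dictionary$R %*% r)
  S <- patterns$S[match(dictionary$pattern_ids, patterns$ids), , drop = FALSE]
  d <- normalize_vector(as.numeric(crossprod(S, cvec)))
  list(c = cvec, d = d, best_id = dictionary$pattern_ids[which.max(cvec)])
}

# decode many population vectors at once: rr_mat is sites x m
.decode_matrix <- function(rr_mat, dictionary, patterns) {
  r <- .normalize_cols(rr_mat)
  C <- dictionary$R %*% r                              # P x m
  S <- patterns$S[match(dictionary$pattern_ids, patterns$ids), , drop = FALSE]
  D <- .normalize_cols(crossprod(S, C))                # 4 x m, normalized
  list(C = C, D = D)
}

# normalized contrast (4 x m) for a vector of pattern ids; NA = gray blank
.contrast_for_ids <- function(ids, patterns) {
  M <- matrix(0, 4, length(ids))
  known <- !is.na(ids)
  M[, known] <- t(patterns$raw[match(ids[known], patterns$ids), , drop = FALSE])
  M
}

#' Correlation time course of the decoded pattern
#'
#' Decodes the single-trial population vector of every pattern period at
#' every time bin and correlates the decoded image with the normalized
#' previous pattern, current pattern and difference pattern (current minus
#' previous, un-normalized subtraction then normalization).  Means and
#' standard errors (sd / sqrt(n)) are taken across transitions.
#' Transitions from a gray blank have a zero-vector previous pattern and
#' identity transitions a zero difference vector; both contribute 0 to
#' the respective average, the correlation-with-a-constant-image
#' convention.
#'
#' @param tensor A `"spike_count_tensor"`.
#' @param schedule Its `"trial_schedule"`.
#' @param dictionary A `"pattern_dictionary"` (typically built from the
#'   dictionary paradigm of the same session).
#' @param patterns A `"pattern_matrix"`.
#' @param paradigm Which paradigm's transitions to decode (default relay).
#' @return A `"correlation_trace"` data.frame with columns `time_ms` (bin
#'   start), `corr_previous`, `corr_current`, `corr_difference`, the
#'   three SEMs, and `n`.
#' @export
correlation_timecourse <- function(tensor, schedule, dictionary,
                                   patterns = pattern_matrix(),
                                   paradigm = "relay") {
  stopifnot(inherits(tensor, "spike_count_tensor"))
  bin_ms <- attr(tensor, "bin_ms")
  tr <- transitions(schedule, paradigm)
  An <- .normalize_cols(.contrast_for_ids(tr$prev_id, patterns))
  Bn <- .normalize_cols(.contrast_for_ids(tr$cur_id, patterns))
  Dn <- .normalize_cols(.contrast_for_ids(tr$cur_id, patterns) -
                          .contrast_for_ids(tr$prev_id, patterns))
  n_bins <- dim(tensor)[2]
  rows <- lapply(seq_len(n_bins), function(b) {
    dec <- .decode_matrix(tensor[, b, tr$period, drop = TRUE], dictionary,
                          patterns)
    cp <- colSums(dec$D * An); cc <- colSums(dec$D * Bn)
    cd <- colSums(dec$D * Dn)
    n <- length(cp)
    data.frame(time_ms = (b - 1) * bin_ms,
               corr_previous = mean(cp), corr_current = mean(cc),
               corr_difference = mean(cd),
               sem_previous = stats::sd(cp) / sqrt(n),
               sem_current = stats::sd(cc) / sqrt(n),
               sem_difference = stats::sd(cd) / sqrt(n),
               n = n)
  })
  out <- do.call(rbind, rows)
  structure(out, class = c("correlation_trace", "data.frame"),
            bin_ms = bin_ms, source = paradigm)
}

#' @export
print.correlation_trace <- function(x, ...) {
  cat(sprintf(
    "Correlation trace: %d bins of %g ms, n = %d transitions (%s)\n",
    nrow(x), attr(x, "bin_ms"), x$n[1], attr(x, "source")))
  invisible(x)
}

#' @export
plot.correlation_trace <- function(x, ...) {
  graphics::matplot(x$time_ms,
                    cbind(x$corr_previous, x$corr_current, x$corr_difference),
                    type = "l", lty = c(2, 1, 4), col = c("gray40", "black", "red"),
                    xlab = "time after transition (ms)", ylab = "correlation", ...)
  graphics::abline(h = 0, lty = 3)
  graphics::legend("topright", c("previous", "current", "difference"),
                   lty = c(2, 1, 4), col = c("gray40", "black", "red"),
                   bty = "n")
  invisible(x)
}

#' Write / read a correlation trace as delimited text
#' @param trace A `"correlation_trace"`.
#' @param path File path.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "correlation_trace"))
  utils::write.table(as.data.frame(trace), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  bin <- if (nrow(df) > 1) diff(df$time_ms[1:2]) else NA_real_
  structure(df, class = c("correlation_trace", "data.frame"),
            bin_ms = bin, source = "file")
}

#' Crossover time of the Difference-Current characteristic
#'
#' The crossover is the moment the decoded image stops resembling the
#' difference pattern more than the current pattern.  Operationally: after
#' the first bin in which the mean difference-pattern correlation exceeds
#' the mean current-pattern correlation (the difference-dominated epoch
#' must exist), the first bin at which the current-pattern correlation is
#' larger and remains larger for `k` consecutive bins.
#'
#' @param trace A `"correlation_trace"`.
#' @param k Persistence requirement in bins (default 3).
#' @return Time in ms (bin start), or `NA_real_` if there is no
#'   difference-dominated epoch or no persistent re-crossing.
#' @export
crossover_time <- function(trace, k = 3) {
  stopifnot(inherits(trace, "correlation_trace"), k >= 1)
  above <- trace$corr_current > trace$corr_difference
  onset <- which(!above)[1]           # difference epoch begins
  if (is.na(onset)) return(NA_real_)
  n <- length(above)
  for (j in seq(onset, n)) {
    if (all(above[j:min(n, j + k - 1)]) && (j + k - 1) <= n)
      return(trace$time_ms[j])
  }
  NA_real_
}

#' Consistency of decoding under window-split dictionaries
#'
#' Builds one dictionary from the 0-90 ms response and one from the
#' 90-250 ms response, decodes the same relay data with both, and
#' correlates the two difference-minus-current time courses.  A high
#' correlation means the population code is the same before and after the
#' crossover (the message changes, not the code).
#'
#' @param tensor,schedule,patterns As in [correlation_timecourse()].
#' @param windows List of two dictionary windows.
#' @return List of class `"window_split"` with `trace_early`,
#'   `trace_late`, and `consistency` (Pearson correlation of the two
#'   difference-minus-current curves).
#' @export
window_split_consistency <- function(tensor, schedule,
                                     patterns = pattern_matrix(),
                                     windows = list(c(0, 90), c(90, 250))) {
  d1 <- build_dictionary(tensor, schedule, window = windows[[1]])
  d2 <- build_dictionary(tensor, schedule, window = windows[[2]])
  t1 <- correlation_timecourse(tensor, schedule, d1, patterns)
  t2 <- correlation_timecourse(tensor, schedule, d2, patterns)
  consistency <- stats::cor(t1$corr_difference - t1$corr_current,
                            t2$corr_difference - t2$corr_current)
  structure(list(trace_early = t1, trace_late = t2,
                 consistency = consistency, windows = windows),
            class = "window_split")
}

#' @export
print.window_split <- function(x, ...) {
  cat(sprintf(
    "Window-split decoding: dictionaries %g-%g ms vs %g-%g ms; difference-minus-current consistency r = %.3f\n",
    x$windows[[1]][1], x$windows[[1]][2], x$windows[[2]][1],
    x$windows[[2]][2], x$consistency))
  invisible(x)
}
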