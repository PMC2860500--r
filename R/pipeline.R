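# End-to-end pipeline: simulate -> dictionary -> decode -> information ->
# orientation.  A run is reproducible from its config; all stage seeds are
# derived from the single config seed.

#' Default pipeline configuration
#'
#' Nested list describing one run of the full analysis on synthetic data:
#' the stimulus section (repetitions, bin size), the population section
#' (units, kernel parameters, gains), and the analysis section
#' (dictionary window, shuffle count, crossover persistence).
#'
#' @param seed Master seed; every stage derives its own seed from it.
#' @return Named nested list.
#' @export
default_config <- function(seed = 1) {
  list(seed = seed,
       stimulus = list(n_repeats = 10, bin_ms = 10),
       population = list(n_units = 16,
                         gain_range = c(80, 200),
                         baseline_range = c(2, 8),
                         latency_ms = 25,
                         kernel = list(peak_ms = 40, undershoot_ms = 60,
                                       shape = 5, undershoot_shape = 4,
                                       undershoot_ratio = 0.9, dt_ms = 1,
                                       t_max_ms = 250)),
       analysis = list(window = c(0, 90), n_shuffles = 20,
                       crossover_k = 3,
                       orientation_units = 17))
}

#' Run the full decoding pipeline on synthetic data
#'
#' Executes every stage in order: build the interleaved relay/dictionary
#' schedule, generate the synthetic population, simulate spike counts,
#' compute the significance mask, build the dictionary, decode the relay
#' transitions into a correlation trace, find the crossover time, check
#' window-split consistency, estimate the information trace, and run the
#' model orientation-shift analysis.  With `out_dir` set, the authoritative
#' delimited tables (schedule, dictionary, correlation trace, information
#' trace, kernel, report) are written there.
#'
#' @param config Configuration list as from [default_config()].
#' @param out_dir Optional output directory for the tables.
#' @param quiet Suppress stage progress messages.
#' @return A `"run_report"` list with the fitted objects and headline
#'   numbers (crossover time, early/late window correlations, information
#'   peaks, orientation shift).
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL,
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    say(sprintf("[%s] done in %.1f s", name,
                as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    out
  }
  seed <- config$seed
  kp <- config$population$kernel
  kernel <- do.call(trp_kernel, kp)
  patterns <- enumerate_patterns()
  pm <- pattern_matrix(patterns)

  schedule <- stage("schedule", build_schedule(
    "interleaved", config$stimulus$n_repeats, seed = seed + 1L,
    patterns = patterns))
  population <- stage("population", make_population(
    config$population$n_units, kernel = kernel,
    gain_range = config$population$gain_range,
    baseline_range = config$population$baseline_range,
    latency_ms = config$population$latency_ms, seed = seed + 2L))
  tensor <- stage("simulate", simulate_responses(
    schedule, population, bin_ms = config$stimulus$bin_ms,
    seed = seed + 3L, patterns = patterns))
  mask <- stage("mask", significance_mask(tensor, schedule))
  dictionary <- stage("dictionary", build_dictionary(
    tensor, schedule, window = config$analysis$window, patterns = patterns))
  trace <- stage("decode", correlation_timecourse(
    tensor, schedule, dictionary, pm))
  crossover <- crossover_time(trace, k = config$analysis$crossover_k)
  split <- stage("window-split", window_split_consistency(
    tensor, schedule, pm))
  info <- stage("information", information_trace(
    tensor, schedule, n_shuffles = config$analysis$n_shuffles,
    seed = seed + 4L))
  orientation <- stage("orientation", model_orientation_shift(
    kernel, n_units = config$analysis$orientation_units, noise = TRUE,
    seed = seed + 5L))

  early <- trace$time_ms >= 50 & trace$time_ms < 90
  late <- trace$time_ms >= 150 & trace$time_ms < 250
  report <- structure(list(
    config = config,
    n_transitions = trace$n[1],
    n_significant_sites = sum(mask),
    crossover_time_ms = crossover,
    early_mean = c(previous = mean(trace$corr_previous[early]),
                   current = mean(trace$corr_current[early]),
                   difference = mean(trace$corr_difference[early])),
    late_mean = c(previous = mean(trace$corr_previous[late]),
                  current = mean(trace$corr_current[late]),
                  difference = mean(trace$corr_difference[late])),
    window_split_consistency = split$consistency,
    info_peak_current_ms = info$time_ms[which.max(info$info_current_bits)],
    info_peak_current_bits = max(info$info_current_bits),
    orientation_shift_deg = orientation$shift_deg,
    schedule = schedule, population = population, tensor = tensor,
    mask = mask, dictionary = dictionary, trace = trace, split = split,
    info = info, orientation = orientation),
    class = "run_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_schedule(schedule, file.path(out_dir, "schedule.tsv"))
    write_dictionary(dictionary, file.path(out_dir, "dictionary.tsv"))
    write_trace(trace, file.path(out_dir, "correlation_trace.tsv"))
    utils::write.table(as.data.frame(info),
                       file.path(out_dir, "information_trace.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_kernel(kernel, file.path(out_dir, "kernel.tsv"))
    write_counts(tensor, file.path(out_dir, "counts.tsv"))
    writeLines(utils::capture.output(print(report)),
               file.path(out_dir, "report.txt"))
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Stimulus-transition decoding run (seed ", x$config$seed, ")\n",
      sep = "")
  cat(sprintf("  transitions decoded: %d; significant sites: %d/%d\n",
              x$n_transitions, x$n_significant_sites,
              x$config$population$n_units))
  cat(sprintf("  early window (50-90 ms) mean corr: prev %.3f, cur %.3f, diff %.3f\n",
              x$early_mean["previous"], x$early_mean["current"],
              x$early_mean["difference"]))
  cat(sprintf("  late window (150-250 ms) mean corr: prev %.3f, cur %.3f, diff %.3f\n",
              x$late_mean["previous"], x$late_mean["current"],
              x$late_mean["difference"]))
  cat(sprintf("  crossover (current > difference): %s ms\n",
              format(x$crossover_time_ms)))
  cat(sprintf("  window-split consistency r = %.3f\n",
              x$window_split_consistency))
  cat(sprintf("  information peak (current): %.3g bits at %g ms\n",
              x$info_peak_current_bits, x$info_peak_current_ms))
  cat(sprintf("  model orientation shift: %.1f deg\n",
              x$orientation_shift_deg))
  invisible(x)
}

#' Export / import a spike-count tensor as a long-format table
#'
#' Plain TSV with columns `site`, `period`, `bin`, `count` and a comment
#' header line carrying the bin size, so a round trip is lossless.
#'
#' @param tensor A `"spike_count_tensor"`.
#' @param path File path.
#' @export
write_counts <- function(tensor, path) {
  stopifnot(inherits(tensor, "spike_count_tensor"))
  d <- dim(tensor)
  df <- data.frame(site = rep(seq_len(d[1]), times = d[2] * d[3]),
                   bin = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
                   period = rep(seq_len(d[3]), each = d[1] * d[2]),
                   count = as.vector(tensor))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# bin_ms: %g", attr(tensor, "bin_ms")), con)
  utils::write.table(df[, c("site", "period", "bin", "count")], con,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a spike-count tensor from a long-format table
#'
#' @param path TSV with header columns `site`, `period`, `bin`, `count`
#'   (optionally a `# bin_ms:` comment line first).
#' @param schedule The `"trial_schedule"` the counts belong to; period
#'   ids are validated against it.
#' @param bin_ms Bin size, overridden by the file's comment header.
#' @return A `"spike_count_tensor"`.
#' @export
load_counts <- function(path, schedule, bin_ms = 10) {
  first <- readLines(path, n = 1)
  if (startsWith(first, "#")) {
    m <- regmatches(first, regexec("bin_ms:\\s*([0-9.]+)", first))[[1]]
    if (length(m) == 2) bin_ms <- as.numeric(m[2])
  }
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  need <- c("site", "period", "bin", "count")
  if (!all(need %in% names(df)))
    stop("counts file must have columns: ", paste(need, collapse = ", "))
  if (any(df$count < 0)) stop("negative spike counts in file")
  unknown <- setdiff(unique(df$period), schedule$period)
  if (length(unknown))
    stop("unknown period ids: ", paste(utils::head(unknown, 5), collapse = ", "))
  sites <- sort(unique(df$site)); bins <- sort(unique(df$bin))
  periods <- schedule$period
  full <- expand.grid(site = sites, bin = bins, period = periods)
  key <- function(d) paste(d$site, d$bin, d$period)
  miss <- setdiff(key(full), key(df))
  if (length(miss))
    stop("missing entries for (site bin period): ",
         paste(utils::head(miss, 5), collapse = "; "))
  arr <- array(0, dim = c(length(sites), length(bins), length(periods)))
  arr[cbind(match(df$site, sites), match(df$bin, bins),
            match(df$period, periods))] <- df$count
  structure(arr, class = "spike_count_tensor", bin_ms = bin_ms,
            noise = TRUE)
}
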