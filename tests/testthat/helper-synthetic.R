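# Shared fixtures, all built in code.

# hand-built schedule: one period per element of `ids` (NA = gray blank)
manual_schedule <- function(ids, paradigm = "relay") {
  df <- data.frame(period = seq_along(ids), block = 1L,
                   paradigm = paradigm, pattern_id = as.integer(ids),
                   onset_ms = (seq_along(ids) - 1L) * 250, duration_ms = 250)
  structure(df, class = c("trial_schedule", "data.frame"),
            n_permutations = NA_integer_, seed = NULL, n_patterns = 81L)
}

# hand-built single-unit (or multi-unit) population
manual_population <- function(weights_list, gain = 100, baseline = 5,
                              latency_ms = 25, kernel = trp_kernel()) {
  units <- lapply(weights_list, function(w)
    list(weights = w, on_weights = pmax(w, 0), off_weights = pmax(-w, 0),
         gain = gain, baseline = baseline, latency_ms = latency_ms))
  structure(units, class = "unit_population", kernel = kernel, seed = NULL)
}

# wrap a plain array as a spike-count tensor
manual_tensor <- function(counts, bin_ms = 10) {
  structure(counts, class = "spike_count_tensor", bin_ms = bin_ms,
            noise = TRUE)
}

# hand-built dictionary over an arbitrary pattern subset
manual_dictionary <- function(RR, pattern_ids, window = c(0, 250)) {
  R <- t(apply(RR, 1, normalize_vector))
  structure(list(RR = RR, R = R, window = window, bin_ms = 10,
                 pattern_ids = pattern_ids, n_repeats = 1L),
            class = "pattern_dictionary")
}

# pattern-matrix object for an arbitrary contrast matrix
manual_patterns <- function(raw, ids = seq_len(nrow(raw)) - 1L) {
  S <- t(apply(raw, 1, normalize_vector))
  structure(list(S = S, raw = raw, ids = ids), class = "pattern_matrix")
}

# default small-footprint session shared by decoder tests (built once)
session_cache <- new.env()
default_session <- function(noise = TRUE) {
  key <- if (noise) "noisy" else "clean"
  if (is.null(session_cache[[key]])) {
    kernel <- trp_kernel()
    schedule <- build_schedule("interleaved", n_repeats = 10, seed = 11)
    population <- make_population(16, kernel = kernel, seed = 12)
    tensor <- simulate_responses(schedule, population, bin_ms = 10,
                                 seed = 13, noise = noise)
    session_cache[[key]] <- list(kernel = kernel, schedule = schedule,
                                 population = population, tensor = tensor)
  }
  session_cache[[key]]
}
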