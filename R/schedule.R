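# Trial schedules for the relay and dictionary paradigms.
#
# A schedule is a data.frame of 250 ms stimulus periods.  In the relay
# paradigm the 81 patterns are shown back-to-back in a fresh random
# permutation per repetition; in the dictionary paradigm a 250 ms gray
# blank precedes every pattern.  Interleaving both paradigms for
# n_repeats repetitions consumes 2 * n_repeats permutations.

.PERIOD_MS <- 250

# Evaluate expr under a temporary RNG state seeded with `seed` (NULL =
# use the current stream).
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Build a trial schedule
#'
#' Constructs the ordered list of 250 ms stimulus periods for one
#' recording session.  Every repetition uses a new random permutation of
#' the full pattern set.  Relay repetitions additionally start with a
#' single 250 ms gray adaptation period so that the first pattern of a
#' repetition has a well-defined (gray) predecessor; these adaptation
#' blanks are not counted as transitions.
#'
#' @param paradigm `"relay"`, `"dictionary"`, or `"interleaved"` (relay
#'   and dictionary repetitions alternating, as in a recording session).
#' @param n_repeats Number of repetitions per paradigm (default 10).
#' @param seed Optional integer seed; schedules are reproducible given it.
#' @param patterns Pattern set to schedule.
#' @return A data.frame of class `"trial_schedule"` with columns
#'   `period` (1-based index), `block` (repetition), `paradigm`,
#'   `pattern_id` (`NA` for gray blanks), `onset_ms`, `duration_ms`.
#'   Attribute `n_permutations` records how many random permutations were
#'   drawn.
#' @examples
#' sch <- build_schedule("relay", n_repeats = 10, seed = 1)
#' sum(!is.na(sch$pattern_id))   # 810 pattern periods
#' @export
build_schedule <- function(paradigm = c("relay", "dictionary", "interleaved"),
                           n_repeats = 10, seed = NULL,
                           patterns = enumerate_patterns()) {
  paradigm <- match.arg(paradigm)
  if (!is.numeric(n_repeats) || n_repeats < 1)
    stop("'n_repeats' must be >= 1")
  n_repeats <- as.integer(n_repeats)
  P <- length(patterns$ids)

  n_perm <- 0L
  block_rows <- function(kind, block) {
    perm <- sample(patterns$ids)
    n_perm <<- n_perm + 1L
    if (kind == "relay") {
      data.frame(block = block, paradigm = "relay",
                 pattern_id = c(NA_integer_, perm))
    } else {
      data.frame(block = block, paradigm = "dictionary",
                 pattern_id = as.integer(rbind(NA_integer_, perm)))
    }
  }

  rows <- .with_seed(seed, {
    out <- list()
    for (b in seq_len(n_repeats)) {
      if (paradigm %in% c("relay", "interleaved"))
        out[[length(out) + 1L]] <- block_rows("relay", b)
      if (paradigm %in% c("dictionary", "interleaved"))
        out[[length(out) + 1L]] <- block_rows("dictionary", b)
    }
    do.call(rbind, out)
  })

  rows$period <- seq_len(nrow(rows))
  rows$duration_ms <- .PERIOD_MS
  rows$onset_ms <- (rows$period - 1L) * .PERIOD_MS
  rows <- rows[, c("period", "block", "paradigm", "pattern_id",
                   "onset_ms", "duration_ms")]
  structure(rows, class = c("trial_schedule", "data.frame"),
            n_permutations = n_perm, seed = seed, n_patterns = P)
}

#' Pattern transitions of a schedule
#'
#' Every pattern period counts as one transition from the pattern shown in
#' the immediately preceding period.  A preceding gray blank (dictionary
#' inter-stimulus blank or relay adaptation period) gives `prev_id = NA`,
#' meaning the contrast-free gray screen; its normalized contrast is the
#' zero vector.
#'
#' @param schedule A `"trial_schedule"`.
#' @param paradigm Which paradigm's pattern periods to list.
#' @return data.frame with columns `period`, `prev_id`, `cur_id`.
#' @export
transitions <- function(schedule, paradigm = c("relay", "dictionary")) {
  stopifnot(inherits(schedule, "trial_schedule"))
  paradigm <- match.arg(paradigm)
  idx <- which(schedule$paradigm == paradigm & !is.na(schedule$pattern_id))
  prev <- idx - 1L
  prev_id <- ifelse(prev >= 1L & prev %in% schedule$period,
                    schedule$pattern_id[prev], NA_integer_)
  # a predecessor from the other paradigm is still just whatever was on
  # screen; blanks are NA already
  data.frame(period = schedule$period[idx],
             prev_id = as.integer(prev_id),
             cur_id = schedule$pattern_id[idx])
}

#' Write / read a schedule as a delimited table
#'
#' @param schedule A `"trial_schedule"`.
#' @param path File path.
#' @return `read_schedule` returns the `"trial_schedule"` (attributes
#'   `n_permutations`/`seed` are not preserved in the file).
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "trial_schedule"))
  utils::write.table(as.data.frame(schedule), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("period", "block", "paradigm", "pattern_id", "onset_ms",
            "duration_ms")
  if (!all(need %in% names(df)))
    stop("schedule file must have columns: ", paste(need, collapse = ", "))
  structure(df[, need], class = c("trial_schedule", "data.frame"),
            n_permutations = NA_integer_, seed = NULL,
            n_patterns = length(unique(stats::na.omit(df$pattern_id))))
}

#' @export
print.trial_schedule <- function(x, ...) {
  np <- sum(!is.na(x$pattern_id))
  cat("Trial schedule:", nrow(x), "periods (", np, "pattern,",
      nrow(x) - np, "blank ),",
      "paradigms:", paste(unique(x$paradigm), collapse = "+"),
      "| permutations drawn:", attr(x, "n_permutations"), "\n")
  invisible(x)
}
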