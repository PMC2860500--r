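#' Tile luminance levels used by the decoding stimulus set
#'
#' The decoding stimuli are 2x2 "miniature images" tiled across the screen.
#' Each tile takes one of three luminances: black (0.01 Cd/m2), gray
#' (6 Cd/m2) or white (60 Cd/m2).  In the contrast code a tile is 1 (black),
#' 0 (gray) or -1 (white).
#'
#' @format Named numeric vector of length 3 (Cd/m2).
#' @export
tile_luminances <- c(black = 0.01, gray = 6, white = 60)

# contrast code per luminance level: black = 1, gray = 0, white = -1
.contrast_levels <- c(black = 1, gray = 0, white = -1)

#' Enumerate all 2x2 three-level luminance patterns
#'
#' Generates the complete stimulus set of 3^4 = 81 patterns obtained by
#' assigning each of the four tiles (upper-left, upper-right, lower-left,
#' lower-right) one of three luminances.  Pattern ids are the base-3
#' encoding of the tile levels in the order UL, UR, LL, LR with digit
#' mapping black = 0, gray = 1, white = 2, so id 0 is all-black and id 40
#' is the all-gray pattern.  This ordering is stable across runs, which
#' keeps dictionaries comparable.
#'
#' @return An object of class `"tile_patterns"`: a list with elements
#'   `ids` (integer 0..80), `contrast` (81 x 4 matrix, values in
#'   \{1, 0, -1\}) and `luminance` (81 x 4 matrix, Cd/m2).  Row `i`
#'   corresponds to id `ids[i]`; columns are named UL, UR, LL, LR.
#' @examples
#' pats <- enumerate_patterns()
#' length(pats$ids)              # 81
#' pats$contrast[pats$ids == 40, ]  # the all-gray pattern
#' @export
enumerate_patterns <- function() {
  digits <- as.matrix(expand.grid(LR = 0:2, LL = 0:2, UR = 0:2, UL = 0:2))
  digits <- digits[, c("UL", "UR", "LL", "LR")]
  ids <- as.integer(digits %*% c(27L, 9L, 3L, 1L))
  ord <- order(ids)
  digits <- digits[ord, , drop = FALSE]
  ids <- ids[ord]
  contrast <- 1 - digits                 # 0 -> 1 (black), 1 -> 0, 2 -> -1
  lum <- matrix(tile_luminances[digits + 1L], nrow = nrow(digits),
                dimnames = dimnames(digits))
  structure(list(ids = ids,
                 contrast = `dimnames<-`(contrast, list(NULL, colnames(digits))),
                 luminance = lum),
            class = "tile_patterns")
}

#' @export
print.tile_patterns <- function(x, ...) {
  cat("Tile pattern set:", length(x$ids),
      "patterns of 2x2 tiles, luminances {0.01, 6, 60} Cd/m2\n")
  invisible(x)
}

#' Normalize a vector so that dot products are Pearson correlations
#'
#' Subtracts the mean and divides by the Euclidean norm of the centered
#' vector.  For two vectors normalized this way the plain dot product
#' equals their Pearson correlation coefficient, which is what lets the
#' decoder compute correlations by multiplication and summation.  A
#' constant vector has no spatial contrast and is mapped to the zero
#' vector; any correlation with it is 0 by convention.
#'
#' @param v Numeric vector with finite entries.
#' @return Numeric vector of the same length: zero-mean, unit-norm if `v`
#'   is non-constant, all zeros otherwise.
#' @examples
#' normalize_vector(c(1, 0, 0, -1))   # c(1, 0, 0, -1) / sqrt(2)
#' normalize_vector(c(5, 5, 5, 5))    # zero vector
#' @export
normalize_vector <- function(v) {
  if (!is.numeric(v) || length(v) == 0L)
    stop("'v' must be a non-empty numeric vector")
  if (any(!is.finite(v)))
    stop("'v' contains non-finite values")
  centered <- v - mean(v)
  nrm <- sqrt(sum(centered^2))
  if (nrm == 0) return(centered * 0)
  centered / nrm
}

# Row-wise version of normalize_vector() for a matrix of vectors.
.normalize_rows <- function(M) {
  M <- as.matrix(M)
  centered <- M - rowMeans(M)
  nrm <- sqrt(rowSums(centered^2))
  nz <- nrm > 0
  centered[nz, ] <- centered[nz, , drop = FALSE] / nrm[nz]
  centered[!nz, ] <- 0
  centered
}

# Column-wise version (population vectors come in as columns).
.normalize_cols <- function(M) t(.normalize_rows(t(M)))

#' Stimulus pattern matrix S
#'
#' Arranges the contrast codes of all patterns into a P x 4 matrix and
#' row-normalizes it (see [normalize_vector()]).  The normalized matrix
#' `S` is the target basis of the decoder: the decoded image is a
#' correlation-weighted average of its rows.  Constant patterns
#' (all-black, all-gray, all-white) carry no spatial contrast and
#' normalize to zero rows.
#'
#' @param patterns A `"tile_patterns"` object, by default the full set.
#' @return An object of class `"pattern_matrix"`: list with `S` (P x 4
#'   row-normalized), `raw` (P x 4 un-normalized contrast codes) and
#'   `ids`.
#' @export
pattern_matrix <- function(patterns = enumerate_patterns()) {
  stopifnot(inherits(patterns, "tile_patterns"))
  raw <- patterns$contrast
  structure(list(S = .normalize_rows(raw), raw = raw, ids = patterns$ids),
            class = "pattern_matrix")
}

#' @export
print.pattern_matrix <- function(x, ...) {
  cat("Pattern matrix S:", nrow(x$S), "x", ncol(x$S),
      "(row-normalized contrast codes)\n")
  invisible(x)
}

#' Difference pattern between two stimulus patterns
#'
#' The difference pattern of a transition from pattern `a` to pattern `b`
#' is the element-wise subtraction `b - a` of the *un-normalized* contrast
#' codes, so the entries lie in \{-2, -1, 0, 1, 2\}.  It is the candidate
#' image for what the early transient response encodes.
#'
#' @param a,b Either pattern ids (integers 0..80) or contrast 4-vectors.
#' @param patterns Pattern set used to resolve ids.
#' @return List of class `"difference_pattern"` with `values` (integer
#'   4-vector) and `normalized` (per [normalize_vector()]; the zero vector
#'   for an identity transition).
#' @examples
#' difference_pattern(c(1, 1, -1, -1), c(1, -1, 1, -1))$values  # 0 -2 2 0
#' @export
difference_pattern <- function(a, b, patterns = enumerate_patterns()) {
  resolve <- function(x) {
    if (length(x) == 1L && is.numeric(x)) {
      i <- match(as.integer(x), patterns$ids)
      if (is.na(i)) stop("unknown pattern id: ", x)
      patterns$contrast[i, ]
    } else if (length(x) == 4L && is.numeric(x)) {
      as.numeric(x)
    } else stop("patterns must be ids or contrast 4-vectors")
  }
  ca <- resolve(a); cb <- resolve(b)
  values <- unname(cb - ca)
  structure(list(values = values, normalized = normalize_vector(values)),
            class = "difference_pattern")
}

#' @export
print.difference_pattern <- function(x, ...) {
  cat("Difference pattern (B - A):", paste(x$values, collapse = " "), "\n")
  invisible(x)
}
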