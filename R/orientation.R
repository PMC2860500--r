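# Orientation preference and the preference shift after a pattern ->
# grating transition.
#
# The orientation test shows a stationary square grating (5 and 35
# Cd/m2, background 20 Cd/m2) either after a gray blank or after a fixed
# checker pattern (0, 10, 10, 60 Cd/m2).  The luminance of the checker is
# arranged so that along the grating's own orientation the average
# luminance does not change at the transition; all the luminance change
# is orthogonal to the grating.  A linear transient encoder should
# therefore prefer the orthogonal orientation right after the transition.

#' Orientation-test stimulus set
#'
#' Describes, for each of 16 orientations in 22.5 degree steps, the
#' blank-to-grating and checker-pattern-to-grating transitions, together
#' with the analytic orientation of the difference image (orthogonal to
#' the grating).  Tile luminances are given in the frame co-rotating with
#' the stimulus, where the checker is always (UL, UR, LL, LR) =
#' (0, 10, 10, 60) Cd/m2 and the grating (5, 35, 5, 35) Cd/m2.
#'
#' @param orientations Grating orientations in degrees.
#' @param grating_luminance Dark/light grating luminances (Cd/m2).
#' @param background Blank-screen luminance (Cd/m2).
#' @param checker_luminance The four checker tile luminances (Cd/m2).
#' @return A data.frame of class `"orientation_stimuli"` with columns
#'   `orientation_deg` and `difference_orientation_deg`; the tile
#'   luminances are stored as attributes `checker_tiles`,
#'   `grating_tiles`, `background`.
#' @examples
#' st <- orientation_test_stimuli()
#' mean(attr(st, "checker_tiles")[c(1, 3)])   # left column before: 5 Cd/m2
#' mean(attr(st, "grating_tiles")[c(1, 3)])   # left column after:  5 Cd/m2
#' @export
orientation_test_stimuli <- function(orientations = seq(0, 337.5, by = 22.5),
                                     grating_luminance = c(5, 35),
                                     background = 20,
                                     checker_luminance = c(0, 10, 10, 60)) {
  df <- data.frame(orientation_deg = orientations,
                   difference_orientation_deg = (orientations + 90) %% 180)
  structure(df, class = c("orientation_stimuli", "data.frame"),
            checker_tiles = checker_luminance,
            grating_tiles = grating_luminance[c(1, 2, 1, 2)],
            grating_luminance = grating_luminance,
            background = background)
}

#' Preferred orientation from a tuning curve
#'
#' Estimates the preferred orientation as half the circular mean angle of
#' the rate-weighted doubled orientations.  On a uniform grid covering
#' the full circle this equals the phase of a least-squares cosine fit
#' with period 180 degrees, but needs no optimizer and is invariant to
#' additive offsets and multiplicative scaling of the rates.
#'
#' @param rates Non-negative firing rates, one per orientation.
#' @param orientations_deg Orientations (degrees), default the 16-point
#'   22.5-degree grid.
#' @return Preferred orientation in `[0, 180)`, or `NA_real_` (with a
#'   warning) when the tuning carries no orientation signal (all rates
#'   equal, e.g. all zero).
#' @examples
#' th <- seq(0, 337.5, by = 22.5)
#' fit_preference(10 + 5 * cospi(2 * (th - 45) / 180), th)   # 45
#' @export
fit_preference <- function(rates, orientations_deg = seq(0, 337.5, by = 22.5)) {
  stopifnot(length(rates) == length(orientations_deg), length(rates) >= 4)
  if (any(rates < 0)) stop("rates must be non-negative")
  z <- sum(rates * exp(2i * orientations_deg * pi / 180))
  if (Mod(z) <= 1e-9 * max(sum(rates), 1)) {
    warning("orientation preference undefined: no modulation in rates")
    return(NA_real_)
  }
  p <- (Arg(z) * 90 / pi) %% 180
  if (180 - p < 1e-6) p <- 0     # wrap the boundary onto 0
  p
}

#' Shift between two orientation preferences
#'
#' Absolute orientation difference wrapped to `[0, 90]` degrees (0 means
#' the same preference, 90 means orthogonal).
#'
#' @param pref_a_deg,pref_b_deg Preferred orientations in degrees; `NA`
#'   propagates.
#' @return Shift in degrees in `[0, 90]`.
#' @examples
#' preference_shift(30, 120)   # 90
#' preference_shift(170, 5)    # 15
#' @export
preference_shift <- function(pref_a_deg, pref_b_deg) {
  d <- abs(pref_a_deg - pref_b_deg) %% 180
  pmin(d, 180 - d)
}

# -- pixel-level stimulus/receptive-field machinery -----------------------

# square-wave sign along the axis at `axis_deg` (degrees), phase aligned
# at the grid center; coords are pixel offsets from the center
.square_axis <- function(X, Y, axis_deg, period_px) {
  u <- X * cospi(axis_deg / 180) + Y * sinpi(axis_deg / 180)
  ifelse(cospi(2 * u / period_px) >= 0, 1, -1)
}

# Luminance-contrast images (relative to the gray background) for a
# grating at `theta` and its preceding checker, on an npx x npx grid.
# The checker-to-grating alignment across stripes (what fixes "the
# average luminance along the grating orientation does not change") is
# preserved exactly; the checker's phase ALONG the stripes, which the
# tiled full-screen stimulus leaves free relative to any one receptive
# field, is chosen so that the difference image is in phase with the
# canonical unit's receptive field rather than in anti-phase (a real
# unit samples this phase at random; the opposite phase merely swaps the
# roles of sign-opposite units).
.orientation_images <- function(theta, npx, period_px, stim) {
  off <- (seq_len(npx) - (npx + 1) / 2)
  X <- matrix(off, npx, npx); Y <- t(X)
  su <- .square_axis(X, Y, theta + 90, period_px)  # modulation across stripes
  sv <- -.square_axis(X, Y, theta, period_px)      # along stripes, offset phase
  gl <- attr(stim, "grating_luminance"); bg <- attr(stim, "background")
  ck <- attr(stim, "checker_tiles")
  gmid <- mean(gl); gamp <- diff(gl) / 2
  # checker in the su/sv sign basis: mean + a su + b sv + c su sv
  a <- (ck[4] + ck[2] - ck[3] - ck[1]) / 4   # along su (UR/LR bright side)
  b <- (ck[4] + ck[3] - ck[2] - ck[1]) / 4
  cc <- (ck[1] + ck[4] - ck[2] - ck[3]) / 4
  m <- mean(ck)
  list(grating = (gmid - bg) + gamp * su,
       checker = (m - bg) + a * su + b * sv + cc * su * sv)
}

# Gabor receptive field at preferred orientation psi (degrees)
.gabor_rf <- function(psi, npx, period_px, sigma_px) {
  off <- (seq_len(npx) - (npx + 1) / 2)
  X <- matrix(off, npx, npx); Y <- t(X)
  u <- X * cospi((psi + 90) / 180) + Y * sinpi((psi + 90) / 180)
  exp(-(X^2 + Y^2) / (2 * sigma_px^2)) * cospi(2 * u / period_px)
}

#' Orientation-preference shift predicted by the minimal model
#'
#' Simulates minimal-model responses to the orientation test: for each of
#' the 16 grating orientations, a unit's drive after the transition is
#' `B(t) * <w, grating> + P(t) * <w, preceding image>`, where `B`/`P` are
#' the kernel's current/previous step coefficients, `w` a Gabor receptive
#' field at the unit's preferred orientation, and the preceding image is
#' either the gray blank or the co-rotating checker.  Firing rates are
#' averaged in the 25-90 ms window, rectified, optionally Poisson-sampled,
#' the preference fitted per condition with [fit_preference()], and the
#' wrapped shift between conditions returned.
#'
#' @param kernel A `"trp_kernel"` (default biphasic).
#' @param stimuli An `"orientation_stimuli"` description.
#' @param n_units Number of simulated units (default 1; the single
#'   noiseless unit gives the model's deterministic prediction).
#' @param noise If `TRUE`, draw Poisson spike counts over `n_repeats`
#'   presentations per orientation instead of using exact rates.
#' @param n_repeats Repetitions per orientation when `noise = TRUE`.
#' @param window_ms Averaging window after grating onset (default 25-90).
#' @param peak_rate Evoked rate scale in spikes/s (default 50).
#' @param seed Optional seed (noise and unit preferences).
#' @param npx,tile_px,sigma_px Pixel grid size, tile size and Gabor
#'   envelope SD in pixels.
#' @return List of class `"orientation_shift"` with `shift_deg` (mean
#'   across units), `shifts` (per unit), `pref_blank`, `pref_pattern`,
#'   and the blank/pattern tuning curves of the first unit.
#' @examples
#' model_orientation_shift(trp_kernel())$shift_deg   # 90
#' @export
model_orientation_shift <- function(kernel = trp_kernel(),
                                    stimuli = orientation_test_stimuli(),
                                    n_units = 1, noise = FALSE,
                                    n_repeats = 10,
                                    window_ms = c(25, 90),
                                    peak_rate = 50, seed = NULL,
                                    npx = 48, tile_px = 8, sigma_px = 10) {
  stopifnot(inherits(kernel, "trp_kernel"))
  period_px <- 2 * tile_px
  thetas <- stimuli$orientation_deg
  co <- .step_coefficients(kernel, period_ms = 250)
  win <- co$t_ms >= window_ms[1] & co$t_ms <= window_ms[2]
  Bw <- co$cur[win]; Pw <- co$prev[win]
  win_s <- sum(win) * kernel$dt_ms / 1000

  .with_seed(seed, {
    psis <- if (n_units == 1) 0 else stats::runif(n_units, 0, 180)
    res <- lapply(seq_len(n_units), function(u) {
      w <- .gabor_rf(psis[u], npx, period_px, sigma_px)
      proj <- vapply(thetas, function(th) {
        im <- .orientation_images(th, npx, period_px, stimuli)
        c(g = sum(w * im$grating), ck = sum(w * im$checker))
      }, numeric(2))
      scale <- max(abs(proj["g", ]))
      rate_for <- function(prev_proj, cur_proj) {
        drive <- (Bw * cur_proj + Pw * prev_proj) / scale
        mean(pmax(0, drive)) * peak_rate       # spikes/s in the window
      }
      tune <- function(prev_projs) {
        r <- vapply(seq_along(thetas), function(i)
          rate_for(prev_projs[i], proj["g", i]), numeric(1))
        if (noise) {
          mean_counts <- r * win_s
          r <- vapply(mean_counts, function(mc)
            mean(stats::rpois(n_repeats, mc)) / win_s, numeric(1))
        }
        r
      }
      tb <- tune(rep(0, length(thetas)))       # blank -> grating
      tp <- tune(proj["ck", ])                 # checker -> grating
      list(pref_blank = fit_preference(tb, thetas),
           pref_pattern = fit_preference(tp, thetas),
           tuning_blank = tb, tuning_pattern = tp)
    })
    pb <- vapply(res, `[[`, 0, "pref_blank")
    pp <- vapply(res, `[[`, 0, "pref_pattern")
    shifts <- preference_shift(pb, pp)
    structure(list(shift_deg = mean(shifts, na.rm = TRUE), shifts = shifts,
                   pref_blank = pb, pref_pattern = pp,
                   orientations_deg = thetas,
                   tuning_blank = res[[1]]$tuning_blank,
                   tuning_pattern = res[[1]]$tuning_pattern),
              class = "orientation_shift")
  })
}

#' @export
print.orientation_shift <- function(x, ...) {
  cat(sprintf(
    "Orientation-preference shift: %.1f deg (n = %d unit%s; 90 deg = preference follows the difference pattern)\n",
    x$shift_deg, length(x$shifts), if (length(x$shifts) > 1) "s" else ""))
  invisible(x)
}
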