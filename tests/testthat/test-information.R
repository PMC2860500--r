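test_that("count discretization reproduces the four equal sub-intervals", {
  lab <- bin_counts(c(0, 1, 2, 3, 4, 5, 6, 7))
  expect_equal(as.integer(lab), c(0, 0, 1, 1, 2, 2, 3, 3))
  expect_equal(attr(lab, "edges"), c(0, 2, 4, 6, 8))
  # range not divisible by four: continuous edges, floor assignment
  lab2 <- bin_counts(c(1, 2, 3, 4, 5, 6, 7, 8, 9))
  expect_equal(as.integer(lab2), c(0, 0, 0, 1, 1, 2, 2, 3, 3))
  expect_equal(attr(lab2, "edges"), 1 + 0:4 * 2.25)
  # degenerate range
  lab3 <- bin_counts(rep(4, 6))
  expect_equal(as.integer(lab3), rep(0, 6))
  expect_true(attr(lab3, "degenerate"))
  # binning is range-relative: adding a constant changes nothing
  set.seed(8)
  x <- rpois(50, 4)
  expect_equal(as.integer(bin_counts(x)), as.integer(bin_counts(x + 11)))
})

test_that("mutual information matches closed forms and direct summation", {
  # independence
  expect_equal(mutual_information(outer(c(.5, .5), c(.25, .25, .25, .25))), 0)
  # 4 equiprobable stimuli, deterministic mapping: log2(4) bits
  expect_equal(mutual_information(diag(4) / 4), 2)
  # direct-summation oracle for a 2x2 joint
  j <- rbind(c(0.4, 0.1), c(0.1, 0.4))
  manual <- sum(j * log2(j / outer(rowSums(j), colSums(j))))
  expect_equal(mutual_information(j), manual)
  expect_equal(mutual_information(j), 0.278072, tolerance = 1e-6)
  # zero cells contribute zero
  expect_equal(mutual_information(rbind(c(.5, 0), c(0, .5))), 1)
  expect_error(mutual_information(rbind(c(.5, .2), c(.1, .1))), "sum to 1")
  expect_error(mutual_information(rbind(c(.7, -.1), c(.2, .2))),
               "non-negative")
  # raw information is bounded by the 4-interval response entropy
  set.seed(9)
  for (i in 1:20) {
    J <- matrix(rexp(4 * 9), 4); J <- J / sum(J)
    I <- mutual_information(J)
    expect_gte(I, 0)
    expect_lte(I, 2)
  }
})

test_that("shuffle correction removes the limited-sampling bias", {
  sch <- build_schedule("relay", n_repeats = 2, seed = 61)
  idx <- which(!is.na(sch$pattern_id))
  n_per <- nrow(sch)
  # counts carry no stimulus signal: corrected information centers on 0,
  # while raw information stays positive (the bias)
  set.seed(62)
  counts <- array(rpois(1 * 25 * n_per, 3), dim = c(1, 25, n_per))
  ten <- manual_tensor(counts)
  corr <- corrected_information(ten, sch, site = 1, bin = 5,
                                n_shuffles = 40, seed = 63)
  raw <- popdecode:::.info_raw(as.numeric(ten[1, 5, idx]),
                               sch$pattern_id[idx])
  expect_gt(raw, 0.1)            # the bias itself is substantial
  expect_lt(abs(corr), 0.05)
  # deterministic stimulus -> count mapping with many repetitions:
  # the correction barely changes the estimate (bias ~ 1/N)
  sch20 <- build_schedule("relay", n_repeats = 20, seed = 61)
  idx20 <- which(!is.na(sch20$pattern_id))
  counts2 <- array(0, dim = c(1, 25, nrow(sch20)))
  counts2[1, , idx20] <- rep(sch20$pattern_id[idx20] %% 8, each = 25)
  ten2 <- manual_tensor(counts2)
  corr2 <- corrected_information(ten2, sch20, 1, 5, n_shuffles = 20,
                                 seed = 64)
  raw2 <- popdecode:::.info_raw(as.numeric(ten2[1, 5, idx20]),
                                sch20$pattern_id[idx20])
  # 8 count values fold into 4 near-equiprobable intervals: ~2 bits
  expect_equal(raw2, 2, tolerance = 1e-3)
  expect_gt(corr2, 0.9 * raw2)
  expect_lt(corr2, raw2)         # the shuffle bias is strictly positive
  expect_error(corrected_information(ten, sch, 1, 5, n_shuffles = 0),
               "n_shuffles")
})

test_that("corrected information of stimulus-independent sites centers on zero", {
  sch <- build_schedule("relay", n_repeats = 10, seed = 65)
  n_per <- nrow(sch)
  set.seed(66)
  n_sites <- 50
  counts <- array(rpois(n_sites * 25 * n_per, 4),
                  dim = c(n_sites, 25, n_per))
  ten <- manual_tensor(counts)
  vals <- vapply(seq_len(n_sites), function(s)
    corrected_information(ten, sch, s, 3, n_shuffles = 20, seed = 66 + s),
    numeric(1))
  expect_lt(abs(mean(vals)), 3 * sd(vals) / sqrt(n_sites))
  st <- binom.test(sum(vals > 0), sum(vals != 0))
  expect_gt(st$p.value, 0.01)
})

test_that("previous-stimulus information lags the current by one period", {
  ses <- default_session(noise = TRUE)
  mask <- which(significance_mask(ses$tensor, ses$schedule))
  s <- mask[1]
  # early bins: firing still reflects the previous pattern
  early_prev <- previous_stimulus_information(ses$tensor, ses$schedule, s,
                                              bin = 2, seed = 71)
  early_cur <- corrected_information(ses$tensor, ses$schedule, s,
                                     bin = 2, seed = 71)
  expect_gt(early_prev, early_cur)
  # late bins: the current pattern dominates
  late_prev <- previous_stimulus_information(ses$tensor, ses$schedule, s,
                                             bin = 22, seed = 72)
  late_cur <- corrected_information(ses$tensor, ses$schedule, s,
                                    bin = 22, seed = 72)
  expect_gt(late_cur, late_prev)
  # two periods back (500 ms) the memory is gone
  lag2 <- corrected_information(ses$tensor, ses$schedule, s, bin = 2,
                                seed = 73, lag_periods = 2)
  expect_lt(lag2, early_prev)
  expect_lt(abs(lag2), 0.05)
})

test_that("the information trace averages masked sites for both stimuli", {
  ses <- default_session(noise = TRUE)
  info <- information_trace(ses$tensor, ses$schedule, n_shuffles = 5,
                            seed = 81)
  expect_equal(nrow(info), 25)
  expect_true(all(c("info_current_bits", "info_previous_bits", "n_sites")
                  %in% names(info)))
  # early: previous-stimulus information dominates; later the reverse
  expect_gt(mean(info$info_previous_bits[info$time_ms < 30]),
            mean(info$info_current_bits[info$time_ms < 30]))
  expect_gt(mean(info$info_current_bits[info$time_ms >= 60]),
            mean(info$info_previous_bits[info$time_ms >= 60]))
  # current information peaks while the difference pattern still dominates
  # the decoded image (compare with the session's crossover)
  dict <- build_dictionary(ses$tensor, ses$schedule, window = c(0, 90))
  cx <- crossover_time(correlation_timecourse(ses$tensor, ses$schedule, dict))
  expect_lt(info$time_ms[which.max(info$info_current_bits)], cx)
})
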