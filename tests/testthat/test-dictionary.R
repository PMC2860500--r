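test_that("noiseless dictionaries equal the generator's windowed mean rates", {
  ses <- default_session(noise = FALSE)
  for (win in list(c(0, 90), c(90, 250), c(0, 250))) {
    dict <- build_dictionary(ses$tensor, ses$schedule, window = win)
    expect_equal(dim(dict$RR), c(81, 16))
    # direct recomputation for a handful of patterns
    idx <- which(ses$schedule$paradigm == "dictionary" &
                   !is.na(ses$schedule$pattern_id))
    bins <- which((seq_len(25) - 1) * 10 >= win[1] &
                    seq_len(25) * 10 <= win[2])
    for (p in c(0, 13, 80)) {
      per <- idx[ses$schedule$pattern_id[idx] == p]
      manual <- rowMeans(apply(ses$tensor[, bins, per, drop = FALSE],
                               c(1, 3), sum)) / (length(bins) * 0.01)
      expect_equal(unname(dict$RR[p + 1, ]), unname(manual),
                   tolerance = 1e-12)
    }
    # row normalization contract
    nonconst <- apply(dict$RR, 1, function(r) length(unique(r)) > 1)
    expect_lt(max(abs(rowMeans(dict$R[nonconst, ]))), 1e-12)
    expect_lt(max(abs(sqrt(rowSums(dict$R[nonconst, ]^2)) - 1)), 1e-12)
  }
  expect_error(build_dictionary(ses$tensor, ses$schedule, window = c(0, 5)),
               "complete bins")
  # a schedule missing patterns is rejected
  short <- manual_schedule(c(NA, 0, NA, 1), paradigm = "dictionary")
  pop <- make_population(2, seed = 1)
  tshort <- simulate_responses(short, pop, seed = 1)
  expect_error(build_dictionary(tshort, short), "missing")
})

test_that("the significance criterion is mean + 2 sd with strict inequality", {
  # 2 sites x 25 bins x 4 periods (blank, pattern, blank, pattern)
  sch <- manual_schedule(c(NA, 3, NA, 7), paradigm = "dictionary")
  counts <- array(0, dim = c(2, 25, 4))
  # site 1: baseline PSTH mean 2 spk/s sd ~1, evoked 5 spk/s -> significant
  base_rates <- rep(c(1, 3), 5)                          # last 10 bins
  counts[1, , c(1, 3)] <- rep(c(rep(0.02, 15), base_rates * 0.01), 2)
  counts[1, , c(2, 4)] <- 0.05                           # 5 spk/s evoked
  # site 2: evoked exactly mean + 2 sd -> NOT significant (strict)
  counts[2, , c(1, 3)] <- rep(c(rep(0.02, 15), base_rates * 0.01), 2)
  thr <- mean(base_rates) + 2 * sd(base_rates)
  counts[2, , c(2, 4)] <- thr * 0.01
  ten <- manual_tensor(counts)
  expect_equal(significance_mask(ten, sch), c(TRUE, FALSE))
  expect_error(significance_mask(ten, manual_schedule(c(3, 7))),
               "no blank")
})

test_that("stimulus-blind units pass the significance criterion at a low false-positive rate", {
  sch <- build_schedule("dictionary", n_repeats = 3, seed = 31)
  pop <- suppressWarnings(
    make_population(40, gain_range = c(0, 0), baseline_range = c(5, 5),
                    seed = 32))
  ten <- suppressWarnings(simulate_responses(sch, pop, seed = 33))
  expect_lt(mean(significance_mask(ten, sch)), 0.2)
})

test_that("decoding matches the hand-computed toy example", {
  raw <- rbind(c(1, 1, -1, -1), c(1, -1, 1, -1))
  pats <- manual_patterns(raw, ids = 0:1)
  dict <- manual_dictionary(rbind(c(2, 0), c(0, 2)), pattern_ids = 0:1)
  out <- decode_instant(c(2, 0), dict, pats)
  expect_equal(out$c, c(1, -1))
  expect_equal(out$d, normalize_vector(c(0, 1, -1, 0)))
  expect_equal(out$best_id, 0)
  # constant population vector decodes to nothing
  flat <- decode_instant(c(3, 3), dict, pats)
  expect_equal(flat$c, c(0, 0))
  expect_equal(flat$d, rep(0, 4))
  expect_error(decode_instant(1:3, dict, pats), "per dictionary site")
})

test_that("decode_instant agrees with a brute-force pairwise-Pearson decoder", {
  pm <- pattern_matrix()
  set.seed(44)
  for (i in 1:100) {
    n_sites <- sample(4:12, 1)
    RR <- matrix(rexp(81 * n_sites), 81)
    dict <- manual_dictionary(RR, pattern_ids = 0:80)
    rr <- rpois(n_sites, 5) + runif(n_sites)
    got <- decode_instant(rr, dict, pm)
    cvec <- apply(RR, 1, function(row)
      if (sd(row) == 0 || sd(rr) == 0) 0 else cor(row, rr))
    expect_equal(got$c, unname(cvec), tolerance = 1e-10)
    d_brute <- unname(normalize_vector(colSums(pm$S * cvec)))
    expect_equal(got$d, d_brute, tolerance = 1e-10)
    expect_true(all(abs(got$c) <= 1 + 1e-12))
  }
})

test_that("the dictionary paradigm decodes itself perfectly without noise", {
  ses <- default_session(noise = FALSE)
  dict <- build_dictionary(ses$tensor, ses$schedule, window = c(0, 250))
  idx <- which(ses$schedule$paradigm == "dictionary" &
                 !is.na(ses$schedule$pattern_id))
  rr <- apply(ses$tensor[, , idx], c(1, 3), sum)       # 0-250 ms counts
  best <- vapply(seq_along(idx), function(j)
    decode_instant(rr[, j], dict)$best_id, numeric(1))
  expect_equal(mean(best == ses$schedule$pattern_id[idx]), 1)
  # with Poisson noise at default gains, a large majority still wins
  noisy <- default_session(noise = TRUE)
  dict2 <- build_dictionary(noisy$tensor, noisy$schedule, window = c(0, 250))
  rr2 <- apply(noisy$tensor[, , idx], c(1, 3), sum)
  best2 <- vapply(seq_along(idx), function(j)
    decode_instant(rr2[, j], dict2)$best_id, numeric(1))
  expect_gt(mean(best2 == noisy$schedule$pattern_id[idx]), 0.6)
})

test_that("relay decoding shows the difference-then-current time course", {
  ses <- default_session(noise = TRUE)
  dict <- build_dictionary(ses$tensor, ses$schedule, window = c(0, 90))
  tr <- correlation_timecourse(ses$tensor, ses$schedule, dict)
  expect_equal(tr$n[1], 810)
  expect_true(all(abs(tr$corr_previous) <= 1) &&
                all(abs(tr$corr_current) <= 1) &&
                all(abs(tr$corr_difference) <= 1))
  # before the response latency: previous pattern only
  pre <- tr$time_ms < 20
  expect_gt(mean(tr$corr_previous[pre]), 3 * max(tr$sem_previous[pre]))
  expect_lt(abs(mean(tr$corr_current[pre])), 0.1)
  # difference epoch then current epoch
  expect_gt(mean(tr$corr_difference[tr$time_ms >= 60 & tr$time_ms < 120]),
            mean(tr$corr_current[tr$time_ms >= 60 & tr$time_ms < 120]))
  expect_gt(mean(tr$corr_current[tr$time_ms >= 200]),
            mean(tr$corr_difference[tr$time_ms >= 200]))
  cx <- crossover_time(tr)
  expect_true(!is.na(cx) && cx > 0 && cx < 250)
  # serialization round trip
  path <- tempfile(fileext = ".tsv")
  write_trace(tr, path)
  expect_equal(as.data.frame(read_trace(path)), as.data.frame(tr),
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("label shuffling destroys the decoded correlations", {
  # a single permutation leaves O(1/sqrt(P)) accidental structure in the
  # shuffled dictionary, so the null is the average over permutations
  ses <- default_session(noise = TRUE)
  idx <- which(ses$schedule$paradigm == "dictionary" &
                 !is.na(ses$schedule$pattern_id))
  set.seed(55)
  n_perm <- 10
  traces <- lapply(seq_len(n_perm), function(i) {
    sch2 <- ses$schedule
    sigma <- sample(0:80)                  # pattern-level label permutation
    sch2$pattern_id[idx] <- sigma[sch2$pattern_id[idx] + 1]
    dict <- build_dictionary(ses$tensor, sch2, window = c(0, 90))
    correlation_timecourse(ses$tensor, ses$schedule, dict)
  })
  null_cur <- rowMeans(sapply(traces, `[[`, "corr_current"))
  null_dif <- rowMeans(sapply(traces, `[[`, "corr_difference"))
  true_dict <- build_dictionary(ses$tensor, ses$schedule, window = c(0, 90))
  true_tr <- correlation_timecourse(ses$tensor, ses$schedule, true_dict)
  expect_lt(max(abs(null_cur)), 0.1)
  expect_lt(max(abs(null_dif)), 0.1)
  expect_lt(max(abs(null_cur)), max(true_tr$corr_current) / 3)
  expect_lt(max(abs(null_dif)), max(true_tr$corr_difference) / 3)
})

test_that("crossover detection needs persistence and a difference epoch", {
  mk <- function(cur, dif) {
    structure(data.frame(time_ms = seq(0, by = 10, length.out = length(cur)),
                         corr_previous = 0, corr_current = cur,
                         corr_difference = dif,
                         sem_previous = 0, sem_current = 0,
                         sem_difference = 0, n = 10),
              class = c("correlation_trace", "data.frame"), bin_ms = 10)
  }
  # current always below difference: no crossover
  expect_true(is.na(crossover_time(mk(rep(0, 10), rep(0.5, 10)))))
  # clean single crossing at bin 6 (60 ms)
  tr <- mk(c(0, 0, 1, 1, 1, 1, 3, 3, 3, 3), c(1, 1, 2, 2, 2, 2, 2, 2, 2, 2))
  expect_equal(crossover_time(tr), 60)
  # a 1-bin blip does not count with k = 3
  blip <- mk(c(0, 0, 3, 1, 1, 1, 3, 3, 3, 3), c(1, 1, 2, 2, 2, 2, 2, 2, 2, 2))
  expect_equal(crossover_time(blip, k = 3), 60)
  expect_equal(crossover_time(blip, k = 1), 20)
  # never entering a difference epoch means nothing to cross
  expect_true(is.na(crossover_time(mk(rep(1, 10), rep(0, 10)))))
})

test_that("window-split dictionaries give consistent difference-minus-current curves", {
  ses <- default_session(noise = TRUE)
  ws <- window_split_consistency(ses$tensor, ses$schedule)
  expect_gt(ws$consistency, 0.8)
  # equal windows: identical traces by construction
  same <- window_split_consistency(ses$tensor, ses$schedule,
                                   windows = list(c(0, 90), c(0, 90)))
  expect_equal(same$trace_early, same$trace_late)
  expect_equal(same$consistency, 1)
})
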