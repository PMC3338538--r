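test_that("DCT basis size follows the cutoff", {
  expect_equal(ncol(dct_basis(300, 2.04, 1 / 128)), 9L)
  expect_equal(ncol(dct_basis(10, 1, 0.001)), 0L)
  # independent frequency count: cosines with period >= 128 s
  n <- 300; tr <- 2.04
  k_max <- 0
  for (k in 1:50) if (k / (2 * n * tr) <= 1 / 128) k_max <- k
  expect_equal(ncol(dct_basis(n, tr)), k_max)
})

test_that("confound regression removes drift and is orthogonal to confounds", {
  n <- 200; tr <- 2.04
  # drift lying in the cosine span is removed exactly
  dct <- dct_basis(n, tr)
  in_span <- dct %*% diag(c(5, -2, 1, 0.5, 2, -1)[seq_len(ncol(dct))])
  res0 <- regress_confounds(in_span, motion = NULL, tr = tr)
  expect_lt(max(abs(res0)), 1e-8 * max(abs(in_span)))
  # a strictly linear trend is strongly attenuated (it is approximated,
  # not spanned, by the low-frequency cosines)
  drift <- matrix(seq_len(n) / n, n, 3) %*% diag(c(5, -2, 1))
  res <- regress_confounds(drift, motion = NULL, tr = tr)
  expect_lt(max(abs(res)), 0.05 * max(abs(drift)))
  expect_lt(sum(res^2) / sum(scale(drift, scale = FALSE)^2), 0.01)
  set.seed(1)
  series <- matrix(rnorm(n * 4), n, 4)
  motion <- matrix(rnorm(n * 6), n, 6)
  res2 <- regress_confounds(series, motion, tr = tr)
  X <- cbind(1, motion, dct_basis(n, tr))
  expect_lt(max(abs(crossprod(X, res2))) / max(abs(series)), 1e-8)
})

test_that("rank-deficient confounds fall back to a pseudo-inverse fit", {
  n <- 50
  motion <- cbind(1:n, 2 * (1:n))  # collinear
  set.seed(2)
  series <- matrix(rnorm(n * 2), n, 2)
  expect_warning(res <- regress_confounds(series, motion, tr = 2),
                 "rank-deficient")
  X <- cbind(1, motion, dct_basis(n, 2))
  expect_lt(max(abs(crossprod(X, res))) / max(abs(series)), 1e-6)
})

test_that("exploration window selects scans by acquisition midpoint", {
  # oracle: midpoints 1.02 + 2.04 (k - 1); window [16, 19) contains only
  # scan 9 (midpoint 17.34)
  tr <- 2.04
  mids <- (seq_len(40) - 0.5) * tr
  oracle <- which(mids >= 16 & mids < 19)
  expect_equal(oracle, 9L)
  ev <- mvpadecode:::new_event_table(
    data.frame(onset = 10, duration = 3, category = "faces", block = 1L,
               path = NA_integer_, keypress_time = NA_real_),
    session = "exploration")
  series <- matrix(seq_len(40), 40, 1)
  ss <- extract_exploration_samples(series, ev, tr = tr)
  expect_equal(ss$scans[[1]], oracle)
  expect_equal(ss$X[1, 1], 9)
})

test_that("zero delay with a TR-wide window picks the onset scan", {
  ev <- mvpadecode:::new_event_table(
    data.frame(onset = 10, duration = 2.04, category = "animals",
               block = 1L, path = NA_integer_, keypress_time = NA_real_),
    session = "exploration")
  series <- matrix(seq_len(40), 40, 1)
  ss <- extract_exploration_samples(series, ev, tr = 2.04, hrf_delay = 0,
                                    window = 2.04)
  expect_length(ss$scans[[1]], 1L)
  k <- ss$scans[[1]]
  expect_true(10 >= (k - 1) * 2.04 - 2.04 / 2 && 10 < k * 2.04 + 2.04 / 2)
})

test_that("events past the run end are dropped with a warning", {
  ev <- mvpadecode:::new_event_table(
    data.frame(onset = c(10, 75), duration = 3,
               category = c("faces", "faces"), block = 1L,
               path = NA_integer_, keypress_time = NA_real_),
    session = "exploration")
  series <- matrix(rnorm(40), 40, 1)  # run is 81.6 s; window of 2nd event ends at 84
  expect_warning(ss <- extract_exploration_samples(series, ev, tr = 2.04),
                 "dropped")
  expect_equal(nrow(ss$X), 1L)
  expect_equal(ss$dropped$event, 2L)
})

test_that("imagery extraction averages at most max_scans and excludes shared scans", {
  tr <- 2.04
  # hand-built 3-event path: key presses at 20, 22, 30 s; delay 6 s
  ev <- mvpadecode:::new_event_table(
    data.frame(onset = c(16, 20.5, 26), duration = c(4, 1.5, 4),
               category = "buildings", block = 1L, path = 1L,
               keypress_time = c(20, 22, 30)),
    session = "imagery")
  series <- matrix(seq_len(40), 40, 1)
  ss <- extract_imagery_samples(series, ev, tr = tr)
  # event windows (delay-corrected): [22,26), [26,28), [28,36)
  mids <- (seq_len(40) - 0.5) * tr
  w1 <- which(mids >= 22 & mids < 26)
  w2 <- which(mids >= 26 & mids < 28)
  w3 <- which(mids >= 28 & mids < 36)
  w3 <- w3[(length(w3) - 1):length(w3)]  # truncated to last 2 scans
  expect_equal(ss$scans, list(w1, w2, w3))
  expect_lte(max(lengths(ss$scans)), 2L)
})

test_that("a scan claimed by two events serves neither", {
  # consecutive same-path windows are disjoint by construction, so a
  # shared scan arises across paths: last event of path 1 and first of
  # path 2 (whose window starts at its own onset).
  series <- matrix(seq_len(30), 30, 1)
  ev <- mvpadecode:::new_event_table(
    data.frame(onset = c(8, 8.6), duration = c(3, 0.7),
               category = c("faces", "buildings"), block = 1L,
               path = c(1L, 2L), keypress_time = c(11, 9.3)),
    session = "imagery")
  # delay 6, tr 2, midpoints 1, 3, ...: window 1 = [14, 17) -> scan 8
  # (midpoint 15); window 2 = [14.6, 15.3) -> scan 8 too: excluded from
  # both, leaving both events without a sample
  expect_message(ss <- extract_imagery_samples(series, ev, tr = 2),
                 "no sample")
  expect_equal(nrow(ss$X), 0L)
  expect_equal(ss$dropped$event, c(1L, 2L))
})

test_that("a sub-TR event with no scan midpoint yields no sample", {
  series <- matrix(seq_len(30), 30, 1)
  # three-event path; middle event's window [17.2, 17.6) contains no
  # midpoint (odd integers at tr = 2)
  ev <- mvpadecode:::new_event_table(
    data.frame(onset = c(8, 11.3, 11.7), duration = c(3.2, 0.3, 1.9),
               category = "animals", block = 1L, path = 1L,
               keypress_time = c(11.2, 11.6, 13.6)),
    session = "imagery")
  expect_message(ss <- extract_imagery_samples(series, ev, tr = 2),
                 "no sample")
  expect_equal(nrow(ss$X), 2L)
  expect_equal(ss$dropped$event, 2L)
})

test_that("sample provenance never shares scans across events", {
  fix <- small_imagery_samples(seed = 11, n_voxels = 60, n_informative = 10,
                               effect = 1)
  sc <- unlist(fix$samples$scans)
  expect_equal(anyDuplicated(sc), 0L)
  expect_lte(nrow(fix$samples$X), nrow(fix$events))
})

test_that("noise-free samples separate categories perfectly", {
  fix <- small_exploration_samples(
    seed = 21, n_voxels = 60, n_informative = 10, effect = 2,
    noise = list(white_sd = 0, ar1_coef = 0, drift_amp = 0,
                 motion_amp = 0),
    n_repetitions = 1)
  ss <- fix$samples
  info <- attr(fix$patterns, "informative")
  # own-category samples have the highest mean in informative voxels
  for (cc in categories()) {
    m <- tapply(rowMeans(ss$X[, info[[cc]], drop = FALSE]), ss$labels, mean)
    expect_equal(names(which.max(m)), cc)
  }
  # nearest-centroid rule reaches 100%
  cent <- sapply(categories(), function(cc)
    colMeans(ss$X[ss$labels == cc, , drop = FALSE]))
  pred <- colnames(cent)[apply(ss$X, 1, function(r)
    which.min(colSums((cent - r)^2)))]
  expect_equal(mean(pred == as.character(ss$labels)), 1)
})
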