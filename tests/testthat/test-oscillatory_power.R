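fs <- 300

test_that("epoching counts trials and enforces window preconditions", {
  sch <- make_event_schedule(utils::modifyList(default_paradigm(1),
                                               list(attend_block_s = 40)))
  n_pairs <- nrow(sch$events)
  x <- matrix(rnorm(round(sch$duration_s * fs) * 2), nrow = 2)
  ep <- segment_epochs(x, sch, c(-0.5, 0.5), NULL, fs)
  expect_equal(dim(ep$data)[1], n_pairs)
  expect_equal(dim(ep$data)[3], round(1.0 * fs))
  expect_error(segment_epochs(x, sch, c(-2, 2), NULL, fs),
               class = "oscmeg_config_error")
  expect_error(segment_epochs(x, sch, c(0.5, -0.5), NULL, fs),
               class = "oscmeg_config_error")
})

test_that("EOG rejection keeps a trial at exactly the threshold and is monotone", {
  ntr <- 6; nsamp <- 100
  eog <- array(0, c(ntr, 1, nsamp))
  pp <- c(40, 100, 100.01, 150, 99.99, 20)  # peak-to-peak per trial
  for (i in seq_len(ntr)) { eog[i, 1, 1] <- -pp[i] / 2; eog[i, 1, 2] <- pp[i] / 2 }
  dat <- epochs_from_array(array(rnorm(ntr * 2 * nsamp), c(ntr, 2, nsamp)),
                           c(-1, -1 + nsamp / fs), fs)
  eog_ep <- epochs_from_array(eog, dat$window, fs)
  r100 <- reject_artifacts(dat, eog_ep, 100)
  expect_identical(r100$rejected, c(3L, 4L))   # only strictly > 100 discarded
  expect_true(2L %in% r100$kept)               # exactly 100 uV is kept
  rInf <- reject_artifacts(dat, eog_ep, Inf)
  expect_identical(rInf$kept, seq_len(ntr))
  # monotonicity: lowering the threshold never increases the kept count
  kept_counts <- sapply(c(Inf, 150, 100, 99, 30, 10), function(th)
    length(reject_artifacts(dat, eog_ep, th)$kept))
  expect_true(all(diff(kept_counts) <= 0))
  expect_error(reject_artifacts(dat, epochs_from_array(eog[1:3, , , drop = FALSE],
                                                       dat$window, fs), 100),
               class = "oscmeg_data_error")
})

test_that("sustained power concentrates a sinusoid and is flat for white noise", {
  nsamp <- round(1.75 * fs)
  t <- (seq_len(nsamp) - 1) / fs
  # unit 10 Hz sinusoid: spectral energy concentrates in the Hanning main
  # lobe around 10 Hz (10 Hz sits halfway between the 4/7 Hz-spaced bins,
  # so the two nearest bins share the power)
  dat <- array(0, c(1, 1, nsamp))
  dat[1, 1, ] <- sin(2 * pi * 10 * t)
  pw <- sustained_power(epochs_from_array(dat, c(-2, -0.25), fs))
  df <- diff(pw$freqs_hz[1:2])
  peak <- which.max(pw$values[1, ])
  expect_lte(abs(pw$freqs_hz[peak] - 10), df)
  lobe <- abs(pw$freqs_hz - pw$freqs_hz[peak]) <= 2 * df + 1e-9
  expect_gt(sum(pw$values[1, lobe]) / sum(pw$values[1, ]), 0.9)
  # closed-form Hanning-leakage oracle: bin amplitudes from the analytic
  # DTFT of the tapered sinusoid
  dirichlet <- function(th, N) {
    out <- exp(-1i * th * (N - 1) / 2) * sin(N * th / 2) / sin(th / 2)
    out[abs(th %% (2 * pi)) < 1e-12] <- N
    out
  }
  W_han <- function(th, N) 0.5 * dirichlet(th, N) -
    0.25 * (dirichlet(th - 2 * pi / (N - 1), N) + dirichlet(th + 2 * pi / (N - 1), N))
  N <- nsamp; w0 <- 2 * pi * 10 / fs
  wsum2 <- sum(oscmeg:::hanning_taper(N)^2)
  dc <- mean(dat[1, 1, ])   # epoch demeaning shifts every bin by -dc * W(theta)
  for (k in (peak - 3):(peak + 3)) {
    thk <- 2 * pi * pw$freqs_hz[k] / fs
    Xk <- (W_han(thk - w0, N) - W_han(thk + w0, N)) / (2i) - dc * W_han(thk, N)
    expected <- 2 * Mod(Xk)^2 / (fs * wsum2)
    expect_equal(pw$values[1, k], expected, tolerance = 1e-6)
  }
  # quadratic amplitude scaling, exactly
  dat2 <- dat; dat2[1, 1, ] <- 2 * dat[1, 1, ]
  pw2 <- sustained_power(epochs_from_array(dat2, c(-2, -0.25), fs))
  expect_equal(pw2$values, 4 * pw$values, tolerance = 1e-12)
  # white noise: alpha vs gamma band means within [0.8, 1.25] over 50 trials
  set.seed(8)
  wn <- array(rnorm(50 * 1 * nsamp), c(50, 1, nsamp))
  pwn <- sustained_power(epochs_from_array(wn, c(-2, -0.25), fs))
  ratio <- mean(pwn$values[1, pwn$freqs_hz >= 7 & pwn$freqs_hz <= 13]) /
    mean(pwn$values[1, pwn$freqs_hz >= 35 & pwn$freqs_hz <= 80])
  expect_gt(ratio, 0.8); expect_lt(ratio, 1.25)
  # trial-order invariance
  perm <- sample(50)
  pwp <- sustained_power(epochs_from_array(wn[perm, , , drop = FALSE],
                                           c(-2, -0.25), fs))
  expect_equal(pwn$values, pwp$values, tolerance = 1e-12)
  expect_error(sustained_power(structure(list(data = wn, window = c(-2, -0.25),
                                              fs = fs, kept = integer(0),
                                              rejected = 1:50),
                                         class = "epoch_set")),
               class = "oscmeg_estimation_error")
})

test_that("tapered FFT power satisfies Parseval under the chosen scaling", {
  set.seed(3)
  for (n in c(524, 525)) {   # even and odd lengths
    x <- rnorm(n)
    w <- oscmeg:::hanning_taper(n)
    p <- oscmeg:::taper_psd(x, fs, w)
    lhs <- sum(p$psd) * fs / n
    rhs <- sum((x * w)^2) / sum(w^2)
    expect_lt(abs(lhs - rhs) / rhs, 1e-8)
  }
})

test_that("band averaging matches bin enumeration and handles support", {
  nsamp <- round(1.75 * fs)
  set.seed(4)
  dat <- array(rnorm(5 * 2 * nsamp), c(5, 2, nsamp))
  pw <- sustained_power(epochs_from_array(dat, c(-2, -0.25), fs))
  # flat synthetic spectrum: every band mean equals the constant
  flat <- pw; flat$values[] <- 3.5
  for (b in seq_len(nrow(band_definitions())))
    expect_equal(band_average(flat, band_definitions()[b, ]), c(3.5, 3.5))
  # support: power only at the 10 Hz bin
  solo <- pw; solo$values[] <- 0
  solo$values[, which.min(abs(pw$freqs_hz - 10))] <- 1
  expect_gt(band_average(solo, c(7, 13))[1], 0)
  expect_equal(band_average(solo, c(35, 80)), c(0, 0))
  # brute-force enumeration oracle for the alpha band
  sel <- which(pw$freqs_hz >= 7 & pw$freqs_hz <= 13)
  manual <- sapply(1:2, function(ch) mean(sapply(sel, function(k) pw$values[ch, k])))
  expect_equal(band_average(pw, c(7, 13)), manual, tolerance = 1e-12)
  expect_error(band_average(pw, c(5.0, 5.1)), class = "oscmeg_config_error")
})

test_that("evoked subtraction zeroes the trial average and removes the locked response", {
  nsamp <- round(2.5 * fs)
  t <- (seq_len(nsamp) - 1) / fs
  tmpl <- 3 * sin(2 * pi * 9 * t) * exp(-t / 0.2)
  set.seed(5)
  dat <- array(0, c(20, 1, nsamp))
  for (i in 1:20) dat[i, 1, ] <- tmpl + rnorm(nsamp, 0, 0.5)
  ep <- epochs_from_array(dat, c(-0.75, 1.75), fs)
  out <- subtract_evoked(ep)
  avg_after <- apply(out$data[out$kept, 1, ], 2, mean)
  expect_lt(max(abs(avg_after)), 1e-10)
  # stimulus-locked average power drops by > 90%
  avg_before <- apply(ep$data[, 1, ], 2, mean)
  expect_lt(mean(avg_after^2) / mean(avg_before^2), 0.1)
  # identical trials produce all-zero output
  same <- array(rep(tmpl, each = 3), c(3, 1, nsamp))
  zeroed <- subtract_evoked(epochs_from_array(same, c(-0.75, 1.75), fs))
  expect_lt(max(abs(zeroed$data)), 1e-10)
  expect_error(subtract_evoked(epochs_from_array(same[1, , , drop = FALSE],
                                                 c(-0.75, 1.75), fs)),
               class = "oscmeg_estimation_error")
})

test_that("adaptive TFR windows define exactly the reachable center span", {
  expect_equal(tfr_defined_span(4), c(-0.375, 1.375))
  expect_equal(tfr_defined_span(12), c(-0.625, 1.625))
  nsamp <- round(2.5 * fs)
  set.seed(6)
  dat <- array(rnorm(3 * 1 * nsamp), c(3, 1, nsamp))
  ep <- epochs_from_array(dat, c(-0.75, 1.75), fs)
  freqs <- c(4, 7, 12, 25, 60)
  tp <- tfr_power(ep, freqs)
  for (fi in seq_along(freqs)) {
    defined <- which(!is.na(tp$values[1, fi, ]))
    # brute-force window-fit scan: a center is defined iff a window of
    # n_cycles/f fits inside the epoch around it
    half <- 3 / (2 * freqs[fi])
    fit <- which(tp$times_s >= -0.75 + half - 0.5 / fs &
                   tp$times_s <= 1.75 - half + 0.5 / fs)
    expect_identical(defined, fit)
  }
  expect_error(tfr_power(ep, c(1, 10)), class = "oscmeg_config_error")
})

test_that("TFR power of a stationary sinusoid is constant over defined centers", {
  nsamp <- round(2.5 * fs)
  t <- (seq_len(nsamp) - 1) / fs
  dat <- array(0, c(1, 1, nsamp))
  dat[1, 1, ] <- sin(2 * pi * 10 * t)
  tp <- tfr_power(epochs_from_array(dat, c(-0.75, 1.75), fs), c(10))
  vals <- tp$values[1, 1, !is.na(tp$values[1, 1, ])]
  expect_lt(stats::sd(vals) / mean(vals), 0.05)
  # trial-order invariance
  set.seed(9)
  multi <- array(rnorm(6 * 1 * nsamp), c(6, 1, nsamp))
  t1 <- tfr_power(epochs_from_array(multi, c(-0.75, 1.75), fs), c(8, 20))
  t2 <- tfr_power(epochs_from_array(multi[sample(6), , , drop = FALSE],
                                    c(-0.75, 1.75), fs), c(8, 20))
  expect_equal(t1$values, t2$values, tolerance = 1e-12)
})

test_that("decibel normalization reproduces its closed-form identities", {
  nsamp <- round(1.75 * fs)
  set.seed(10)
  dat <- array(abs(rnorm(2 * 2 * nsamp)) + 0.5, c(2, 2, nsamp))
  pw <- sustained_power(epochs_from_array(dat, c(-2, -0.25), fs))
  expect_true(all(db_normalize(pw, pw)$values == 0))
  ref <- pw; ref$values <- pw$values / 10
  expect_equal(db_normalize(pw, ref)$values,
               matrix(10, nrow(pw$values), ncol(pw$values)), tolerance = 1e-12)
  ref2 <- pw; ref2$values <- pw$values / 2
  expect_equal(unique(round(as.vector(db_normalize(pw, ref2)$values), 6)),
               round(10 * log10(2), 6))
  bad <- pw; bad$values[1, 1] <- -1
  expect_error(db_normalize(pw, bad), class = "oscmeg_numerical_error")
  # TFR baseline normalization: baseline cells average to ~0 dB
  nsamp2 <- round(2.5 * fs)
  tdat <- array(abs(rnorm(4 * 1 * nsamp2)) + 0.5, c(4, 1, nsamp2))
  tp <- tfr_power(epochs_from_array(tdat, c(-0.75, 1.75), fs), c(10, 20))
  dbn <- db_normalize(tp, "baseline")
  base <- dbn$times_s < -0.1
  for (fi in 1:2) {
    cells <- dbn$values[1, fi, base]
    expect_lt(abs(mean(10^(cells[!is.na(cells)] / 10)) - 1), 1e-9)
  }
})
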