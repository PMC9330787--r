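make_rec <- function(m, fs = 500, labs = NULL) {
  if (is.null(labs)) labs <- paste0("ch", seq_len(ncol(m)))
  recording(m, fs = fs, labels = labs)
}

eog_rec <- function(m, fs = 500)
  recording(m, fs = fs, labels = eog_channel_names())

test_that("H-infinity removes linearly mixed EOG after warm-up", {
  withr::with_seed(3, {
    fs <- 500; n <- 20 * fs
    clean <- matrix(rnorm(n * 27, 0, 10), n, 27)
    eog <- matrix(rnorm(n * 4, 0, 30), n, 4,
                  dimnames = list(NULL, eog_channel_names()))
    mixing <- turnintent:::default_eog_mixing() * 4
    mixed <- clean + eog %*% t(mixing)
    out <- hinf_filter(make_rec(mixed), eog_rec(eog))
    post <- (15 * fs):n
    veog <- eog[, "VU"] - eog[, "VD"]
    heog <- eog[, "HR"] - eog[, "HL"]
    for (ref in list(veog, heog)) {
      cc <- vapply(1:27, function(j)
        abs(cor(out$samples[post, j], ref[post])), numeric(1))
      expect_lt(max(cc), 0.1)
    }
  })
})

test_that("H-infinity is near-identity on clean data and tracks drift", {
  withr::with_seed(4, {
    # the adaptive gain anneals like 1/t, so the identity check uses a long
    # warm-up (the rate is irrelevant: only the sample count matters)
    fs <- 250; n <- 160 * fs
    clean <- matrix(rnorm(n * 8, 0, 10), n, 8)
    zeros <- matrix(0, n, 4, dimnames = list(NULL, eog_channel_names()))
    out <- hinf_filter(make_rec(clean, fs), eog_rec(zeros, fs))
    post <- (140 * fs):n
    rel <- sqrt(mean((out$samples[post, ] - clean[post, ])^2)) /
      sqrt(mean(clean[post, ]^2))
    expect_lt(rel, 0.01)

    fs2 <- 500; n2 <- 20 * fs2
    post2 <- (15 * fs2):n2
    zeros2 <- matrix(0, n2, 4, dimnames = list(NULL, eog_channel_names()))
    ramp <- matrix(seq(0, 100, length.out = n2), n2, 8)
    outr <- hinf_filter(make_rec(ramp, fs2), eog_rec(zeros2, fs2))
    expect_lt(sqrt(mean(outr$samples[post2, ]^2)),
              0.3 * sqrt(mean(ramp[post2, ]^2)))

    expect_error(hinf_filter(make_rec(ramp, fs2), eog_rec(zeros2, fs2),
                             gamma = 1),
                 class = "turnintent_param_error")
  })
})

test_that("H-infinity weights stay bounded on long bounded inputs", {
  withr::with_seed(5, {
    fs <- 100; n <- 600 * fs  # ten minutes at reduced rate
    x <- matrix(rnorm(n * 2, 0, 10), n, 2)
    eog <- matrix(rnorm(n * 4, 0, 20), n, 4,
                  dimnames = list(NULL, eog_channel_names()))
    out <- hinf_filter(make_rec(x, fs), eog_rec(eog, fs))
    expect_true(all(is.finite(out$samples)))
    expect_lt(max(abs(attr(out, "weights"))), 100)
  })
})

test_that("ASR calibration validates its baseline and is deterministic", {
  withr::with_seed(6, {
    fs <- 250
    sigma <- make_spd_pair(5, 1, seed = 1)$a * 100
    base <- matrix(rnorm(61 * fs * 5), ncol = 5) %*% chol(sigma)
    m1 <- asr_calibrate(make_rec(base, fs))
    m2 <- asr_calibrate(make_rec(base, fs))
    expect_identical(m1$thresholds, m2$thresholds)

    short <- make_rec(base[1:(59 * fs), ], fs)
    expect_error(asr_calibrate(short), class = "turnintent_data_error")

    t5 <- asr_calibrate(make_rec(base, fs), cutoff_k = 5)$thresholds
    t20 <- asr_calibrate(make_rec(base, fs), cutoff_k = 20)$thresholds
    expect_true(all(t20 > t5))
  })
})

test_that("ASR suppresses bursts at least 10x with small clean distortion", {
  withr::with_seed(7, {
    fs <- 500
    sigma <- make_spd_pair(27, 1, seed = 2)$a * 100
    ch <- chol(sigma)
    base <- matrix(rnorm(61 * fs * 27), ncol = 27) %*% ch
    model <- asr_calibrate(make_rec(base, fs))

    clean <- matrix(rnorm(6 * fs * 27), ncol = 27) %*% ch
    out_c <- asr_process(make_rec(clean, fs), model)
    expect_lt(sqrt(mean((out_c$samples - clean)^2)) / sqrt(mean(clean^2)),
              0.05)

    dirty <- clean
    idx <- (2 * fs):(2.5 * fs)
    for (c3 in c(4, 11, 20))
      dirty[idx, c3] <- dirty[idx, c3] + 500 * rnorm(length(idx))
    out_d <- asr_process(make_rec(dirty, fs), model)
    err_in <- sqrt(mean((dirty[idx, ] - clean[idx, ])^2))
    err_out <- sqrt(mean((out_d$samples[idx, ] - clean[idx, ])^2))
    expect_gt(err_in / err_out, 10)

    zero <- matrix(0, 2 * fs, 27)
    expect_equal(asr_process(make_rec(zero, fs), model)$samples, zero,
                 ignore_attr = TRUE)
    expect_error(asr_process(make_rec(zero[, 1:5], fs), model),
                 class = "turnintent_data_error")
  })
})

test_that("band-pass is causal, stateful and frequency-selective", {
  fs <- 500; n <- 10 * fs
  tt <- (1:n) / fs
  tone <- matrix(sin(2 * pi * 11 * tt), ncol = 1)
  ss <- (5 * fs):n
  in_band <- bandpass(make_rec(tone, fs), "8-14")$samples
  out_band <- bandpass(make_rec(tone, fs), "23-30")$samples
  expect_gt(sd(in_band[ss, 1]) / sd(tone[ss, 1]), 0.7)
  expect_lt(sd(out_band[ss, 1]) / sd(tone[ss, 1]), 0.2)

  dc <- matrix(1, 2 * fs, 1)
  dc_out <- bandpass(make_rec(dc, fs), "8-40")$samples
  expect_lt(max(abs(tail(dc_out, 100))), 1e-4)

  withr::with_seed(8, x <- matrix(rnorm(3000 * 3), ncol = 3))
  one <- bandpass(make_rec(x, fs), "8-40")$samples
  st <- NULL; chunks <- list()
  for (i in seq(1, 3000, by = 100)) {  # 0.2 s chunks
    res <- bandpass(make_rec(x[i:(i + 99), , drop = FALSE], fs), "8-40",
                    state = st)
    st <- attr(res, "state")
    chunks[[length(chunks) + 1]] <- res$samples
  }
  expect_lt(max(abs(do.call(rbind, chunks) - one)), 1e-9)

  # causality: a prefix of the input yields a prefix of the output
  pre <- bandpass(make_rec(x[1:1000, , drop = FALSE], fs), "8-40")$samples
  expect_equal(pre, one[1:1000, ], tolerance = 1e-12)

  expect_error(bandpass(make_rec(x, 60), "8-40"),
               class = "turnintent_config_error")
})

test_that("preprocessing cascade filters artifacts before band isolation", {
  ses <- small_session(seed = 13, n_trials = 1)
  cfg <- run_config(artifact_filter = "hinf", band = "8-40",
                    classifier = "mdm")
  tr <- preprocess_trial(ses$trials[[1]], cfg)
  expect_s3_class(tr$eeg, "recording")
  expect_equal(dim(tr$eeg$samples), dim(ses$trials[[1]]$eeg$samples))
  cfg_asr <- run_config(artifact_filter = "asr", band = "8-40",
                        classifier = "mdm")
  ses2 <- preprocess_session(small_session(seed = 13, n_trials = 1), cfg_asr)
  expect_equal(length(ses2$trials), 1)
})
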