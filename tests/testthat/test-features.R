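empty_frames <- function() {
  data.frame(t_ms = numeric(0), class = character(0), area = numeric(0),
             yaw = numeric(0), roll = numeric(0), pitch = numeric(0),
             mouth_open_conf = numeric(0), eyes_open_conf = numeric(0))
}

empty_utt <- function() {
  data.frame(start = numeric(0), end = numeric(0),
             speaker_class = character(0), mean_confidence = numeric(0),
             loudness = numeric(0))
}

test_that("rasterization produces the right grid and half-open bin coverage", {
  fs <- rasterize_features(empty_frames(), empty_utt(), 60000)
  expect_equal(nrow(fs$channels), 240)
  expect_equal(ncol(fs$channels), 15)

  u <- data.frame(start = 1000, end = 1600, speaker_class = "adult",
                  mean_confidence = 0.8, loudness = 7)
  fs <- rasterize_features(empty_frames(), u, 2000)
  sa <- fs$channels[, "speech_active"]
  expect_equal(which(sa == 1), 5:7)
  expect_equal(as.numeric(fs$channels[6, "word_conf"]), 0.8)
  expect_equal(as.numeric(fs$channels[6, "loudness"]), 7)
  expect_equal(as.numeric(fs$channels[8, "word_conf"]), 0)
  expect_error(rasterize_features(empty_frames(), empty_utt(), 0),
               "session_ms")
})

test_that("face samples fill the bins their native window covers; absent bins are gaps", {
  ff <- data.frame(t_ms = 500, class = "adult", area = 0.1, yaw = 1,
                   roll = 2, pitch = 3, mouth_open_conf = 60,
                   eyes_open_conf = 90)
  fs <- rasterize_features(ff, empty_utt(), 2000)
  a <- fs$channels[, "adult_area"]
  expect_equal(a, c(NA, NA, 0.1, 0.1, NA, NA, NA, NA))
  expect_true(all(is.na(fs$channels[, "peer_area"])))
})

test_that("speech_active covers at least the utterance interiors", {
  set.seed(71)
  for (i in 1:10) {
    n <- sample(3:10, 1)
    st <- sort(runif(n, 0, 50000))
    u <- data.frame(start = st, end = st + runif(n, 300, 2000),
                    speaker_class = "adult", mean_confidence = 0.9,
                    loudness = 5)
    fs <- rasterize_features(empty_frames(), u, 60000)
    covered <- sum(fs$channels[, "speech_active"]) * 250
    expect_gte(covered, sum(u$end - u$start) - 2 * 250 * n)
  }
})

test_that("infilling repairs short gaps by windowed means and zeroes long absences", {
  m <- matrix(c(1, NA, 3), ncol = 1, dimnames = list(NULL, "adult_area"))
  expect_equal(as.numeric(infill_moving_average(m, 3)), c(1, 2, 3))

  full <- matrix(1:6, ncol = 1, dimnames = list(NULL, "adult_area"))
  expect_equal(infill_moving_average(full, 3), full)

  long_gap <- matrix(c(2, rep(NA, 7), 4), ncol = 1,
                     dimnames = list(NULL, "adult_area"))
  out <- as.numeric(infill_moving_average(long_gap, 5))
  expect_equal(out, c(2, rep(0, 7), 4))

  expect_error(infill_moving_average(full, 4), "odd")
  expect_warning(
    filled <- infill_moving_average(
      matrix(NA_real_, 5, 1, dimnames = list(NULL, "x")), 3),
    "all-gap")
  expect_equal(as.numeric(filled), rep(0, 5))
})

test_that("infilling equals an independent brute-force implementation", {
  brute <- function(x, w) {
    half <- w %/% 2
    isna <- is.na(x)
    runs <- rle(isna)
    hi <- cumsum(runs$lengths)
    lo <- hi - runs$lengths + 1
    out <- x
    for (k in seq_along(runs$values)) {
      if (!runs$values[k]) next
      if (runs$lengths[k] > w) {
        out[lo[k]:hi[k]] <- 0
      } else {
        for (i in lo[k]:hi[k]) {
          nb <- x[max(1, i - half):min(length(x), i + half)]
          nb <- nb[!is.na(nb)]
          out[i] <- if (length(nb)) mean(nb) else
            x[which(!isna)[which.min(abs(which(!isna) - i))]]
        }
      }
    }
    out
  }
  set.seed(72)
  for (i in 1:50) {
    x <- rnorm(60)
    x[runif(60) < 0.4] <- NA
    if (all(is.na(x))) x[1] <- 1
    m <- matrix(x, ncol = 1, dimnames = list(NULL, "ch"))
    expect_equal(as.numeric(infill_moving_average(m, 5)), brute(x, 5))
  }
})

test_that("outlier clipping caps the upper tail only and skips boolean channels", {
  x <- c(rep(0, 100), 1e9)
  m <- matrix(x, ncol = 1, dimnames = list(NULL, "loudness"))
  out <- clip_outliers(m, 0.99)
  expect_equal(max(out), quantile(x, 0.99, names = FALSE))
  expect_equal(out[1:100], rep(0, 100))

  const <- matrix(5, 10, 1, dimnames = list(NULL, "x"))
  expect_equal(clip_outliers(const), const)

  bool <- matrix(rep(c(0, 1), 50), ncol = 1,
                 dimnames = list(NULL, "speech_active"))
  expect_equal(clip_outliers(bool, 0.5), bool)

  set.seed(73)
  for (i in 1:20) {
    x <- rlnorm(200, 0, 2)
    m <- matrix(x, ncol = 1, dimnames = list(NULL, "ch"))
    expect_equal(as.numeric(clip_outliers(m, 0.99)),
                 pmin(x, quantile(x, 0.99, names = FALSE)))
  }
})

test_that("normalization z-scores with pooled training statistics, constants pass through", {
  set.seed(74)
  m1 <- matrix(rnorm(100, 10, 2), ncol = 1, dimnames = list(NULL, "ch"))
  m2 <- matrix(rnorm(100, 10, 2), ncol = 1, dimnames = list(NULL, "ch"))
  st <- fit_normalize(list(m1, m2))
  pooled <- c(m1, m2)
  expect_equal(as.numeric(st$center), mean(pooled))
  expect_equal(as.numeric(st$scale), sd(pooled))
  probe <- matrix(st$center + 2 * st$scale, 1, 1,
                  dimnames = list(NULL, "ch"))
  expect_equal(as.numeric(apply_normalize(probe, st)), 2)

  const <- matrix(7, 10, 1, dimnames = list(NULL, "ch"))
  stc <- fit_normalize(list(const))
  expect_equal(apply_normalize(const, stc), const)
  expect_error(fit_normalize(list()), "non-empty")
})

test_that("training channels are standard after normalization and clip/normalize do not commute", {
  set.seed(75)
  mats <- lapply(1:3, function(i) {
    matrix(rlnorm(200, 1, 1), ncol = 2, dimnames = list(NULL, c("a", "b")))
  })
  st <- fit_normalize(mats)
  normed <- do.call(rbind, lapply(mats, apply_normalize, stats = st))
  expect_lt(abs(mean(normed[, "a"])), 1e-9)
  expect_equal(sd(normed[, "a"]), 1, tolerance = 1e-9)

  m <- mats[[1]]
  a <- apply_normalize(clip_outliers(m, 0.9), fit_normalize(list(clip_outliers(m, 0.9))))
  b <- clip_outliers(apply_normalize(m, fit_normalize(list(m))), 0.9)
  expect_false(isTRUE(all.equal(a, b)))
})

test_that("the built feature series for a session has no gaps and a coherent grid", {
  cfg <- sim_config(session_minutes = 3, seed = 76)
  s <- generate_session(cfg)
  fs <- build_feature_series(s)
  expect_false(anyNA(fs$channels))
  expect_equal(nrow(fs$channels), ceiling(s$session_ms / 250))
  expect_true(all(fs$channels[, "speech_active"] %in% c(0, 1)))
})
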