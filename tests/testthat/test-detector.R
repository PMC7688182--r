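small_spec <- function(partner = "adult", feature_set = "full", ...) {
  detector_spec(partner, feature_set, hidden_units = 6, epochs = 2,
                learn_rate = 0.05, seed = 9, ...)
}

test_that("detector specs pin the input width to the feature set", {
  expect_length(detector_channels(detector_spec("adult", "full")), 15)
  reduced <- detector_channels(detector_spec("peer", "reduced"))
  expect_equal(reduced, c("peer_area", "speech_active"))
  # the reduced detector uses its own partner's face-area channel
  expect_equal(detector_channels(detector_spec("adult", "reduced"))[1],
               "adult_area")
  expect_error(detector_spec("adult", hidden_units = 0), "hidden_units")
  m <- build_detector(small_spec())
  expect_equal(dim(m$params$Wx_f), c(4 * 6, 15))
  m2 <- build_detector(small_spec("peer", "reduced"))
  expect_equal(dim(m2$params$Wx_f), c(4 * 6, 2))
})

test_that("initialization is deterministic and does not disturb the caller RNG", {
  expect_identical(build_detector(small_spec())$params,
                   build_detector(small_spec())$params)
  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(build_detector(small_spec()))
  expect_identical(runif(1), before)
})

test_that("forward pass yields a valid probability simplex per timestep", {
  m <- build_detector(small_spec())
  x <- matrix(0, nrow = 15, ncol = 20,
              dimnames = list(feature_channels(), NULL))
  p <- predict_probs(m, t(x))
  expect_length(p, 20)
  expect_true(all(p >= 0 & p <= 1))
  full <- classtalk:::cpp_bilstm_forward(
    m$params$Wx_f, m$params$Wh_f, m$params$b_f, m$params$Wx_b,
    m$params$Wh_b, m$params$b_b, m$params$Wo, m$params$bo, x)
  expect_equal(colSums(full), rep(1, 20))
})

test_that("analytic gradients match finite differences", {
  set.seed(55)
  D <- 3; H <- 4; Tt <- 9
  p <- list(Wx_f = matrix(rnorm(4 * H * D, 0, 0.4), 4 * H, D),
            Wh_f = matrix(rnorm(4 * H * H, 0, 0.4), 4 * H, H),
            b_f = rnorm(4 * H, 0, 0.4),
            Wx_b = matrix(rnorm(4 * H * D, 0, 0.4), 4 * H, D),
            Wh_b = matrix(rnorm(4 * H * H, 0, 0.4), 4 * H, H),
            b_b = rnorm(4 * H, 0, 0.4),
            Wo = matrix(rnorm(4 * H, 0, 0.4), 2, 2 * H),
            bo = rnorm(2, 0, 0.4))
  X <- matrix(rnorm(D * Tt), D, Tt)
  y <- as.integer(rbinom(Tt, 1, 0.5))
  g <- classtalk:::cpp_bilstm_grad(p$Wx_f, p$Wh_f, p$b_f, p$Wx_b, p$Wh_b,
                                   p$b_b, p$Wo, p$bo, X, y)
  lossfn <- function(q) {
    classtalk:::cpp_bilstm_grad(q$Wx_f, q$Wh_f, q$b_f, q$Wx_b, q$Wh_b,
                                q$b_b, q$Wo, q$bo, X, y)$loss
  }
  eps <- 1e-6
  for (nm in names(p)) {
    for (i in sample(length(p[[nm]]), min(4, length(p[[nm]])))) {
      pp <- p; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- p; pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (lossfn(pp) - lossfn(pm)) / (2 * eps)
      expect_equal(g[[nm]][i], num, tolerance = 1e-4)
    }
  }
})

sep_fixture <- function(n = 3, minutes = 6, seed = 21) {
  cfg <- separable_config(minutes, seed = seed)
  coh <- generate_cohort(cfg, n)
  # peer face channels are legitimately all-gap in short separable sessions
  fs <- suppressWarnings(lapply(coh, build_feature_series))
  list(cohort = coh, fs = fs, refs = lapply(coh, `[[`, "truth_adult"))
}

test_that("training reduces the loss and changes parameters on a separable fixture", {
  fx <- sep_fixture()
  spec <- detector_spec("adult", "full", hidden_units = 8, epochs = 10,
                        learn_rate = 0.05, seed = 2)
  sub <- lapply(fx$fs, function(s) {
    s$channels <- s$channels[, detector_channels(spec)]
    s
  })
  st <- fit_normalize(sub)
  normed <- lapply(sub, apply_normalize, stats = st)
  labs <- lapply(seq_along(fx$cohort), function(i) {
    rasterize_track(fx$refs[[i]], fx$cohort[[i]]$session_ms)
  })
  m0 <- build_detector(spec)
  m <- train_detector(m0, normed, labs)
  expect_false(identical(m0$params, m$params))
  expect_lt(tail(m$loss_history, 1), m$loss_history[1])

  # training-set F1 on the separable fixture is essentially perfect
  f1 <- vapply(seq_along(normed), function(i) {
    pred <- smooth_track(predict_track(m, normed[[i]]))
    detection_metrics(pred, fx$refs[[i]], fx$cohort[[i]]$session_ms)$f1
  }, numeric(1))
  expect_true(all(f1 >= 99))

  # deterministic retrain
  m_again <- train_detector(build_detector(spec), normed, labs)
  expect_identical(m$params, m_again$params)

  expect_error(train_detector(m0, normed, labs[-1]), "equal length")
  short <- labs
  short[[1]] <- short[[1]][-1]
  expect_error(train_detector(m0, normed, short), "mismatch")
})

test_that("all-negative labels collapse predictions to the empty track", {
  fx <- sep_fixture(n = 2, minutes = 3, seed = 23)
  spec <- detector_spec("adult", "full", hidden_units = 6, epochs = 3,
                        learn_rate = 0.05, seed = 3)
  sub <- lapply(fx$fs, function(s) {
    s$channels <- s$channels[, detector_channels(spec)]
    s
  })
  st <- fit_normalize(sub)
  normed <- lapply(sub, apply_normalize, stats = st)
  zero_labs <- lapply(normed, function(s) integer(nrow(s$channels)))
  m <- train_detector(build_detector(spec), normed, zero_labs)
  pred <- smooth_track(predict_track(m, normed[[1]]))
  expect_equal(nrow(pred$intervals), 0)
})

test_that("LOSO folds never use the held-out child's data for normalization", {
  fx <- sep_fixture(n = 3, minutes = 4, seed = 25)
  spec <- detector_spec("adult", "reduced", hidden_units = 6, epochs = 2,
                        learn_rate = 0.05, seed = 4)
  # tiny sessions can yield empty predictions, whose precision is undefined
  res <- suppressWarnings(loso_detect(fx$fs, fx$refs, spec))
  expect_equal(nrow(res$metrics), 3)

  # perturb child 1's features: its own fold statistics must be unchanged,
  # every other fold's statistics must move
  fs2 <- fx$fs
  fs2[[1]]$channels[, "adult_area"] <- fs2[[1]]$channels[, "adult_area"] + 50
  res2 <- suppressWarnings(loso_detect(fs2, fx$refs, spec))
  expect_identical(res$fold_stats[[1]], res2$fold_stats[[1]])
  expect_false(identical(res$fold_stats[[2]], res2$fold_stats[[2]]))
  expect_error(loso_detect(fx$fs[1], fx$refs[1], spec), "at least 2")
})

test_that("prediction requires the channels the spec was built for", {
  m <- build_detector(small_spec())
  bad <- matrix(0, 10, 2, dimnames = list(NULL, c("adult_area", "speech_active")))
  expect_error(predict_probs(m, bad), "lacks channel")
})
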