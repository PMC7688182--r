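test_that("config validation rejects impossible parameter regimes", {
  expect_error(sim_config(adult_rate = -1), "adult_rate")
  expect_error(sim_config(occlusion_prob = 1.2), "probability")
  expect_error(sim_config(wer_del = 0.7, wer_sub = 0.5), "wer_del \\+ wer_sub")
  expect_error(sim_config(session_minutes = 0), "session_minutes")
  expect_error(sim_config(adult_rate = 5000), "250 ms")
  expect_error(sim_config(peer_dur_logmean = log(60)), "peer median")
})

test_that("a zero-rate process yields an empty session", {
  cfg <- sim_config(session_minutes = 5, adult_rate = 0, peer_rate = 0,
                    bg_speech_rate = 0, false_face_rate = 0,
                    staff_face_rate = 0, seed = 2)
  s <- generate_session(cfg)
  expect_equal(nrow(s$truth_adult$intervals), 0)
  expect_equal(nrow(s$truth_peer$intervals), 0)
  expect_equal(nrow(s$reference), 0)
  expect_equal(s$bookkeeping$cds$adult$tnu, 0)
  expect_equal(s$bookkeeping$cds$peer$tnw, 0)
  expect_equal(s$bookkeeping$interaction$adult$frequency, 0)
})

test_that("sessions and cohorts are deterministic given the seed", {
  cfg <- sim_config(session_minutes = 4, seed = 5)
  expect_identical(generate_session(cfg, "kid", seed = 9),
                   generate_session(cfg, "kid", seed = 9))
  expect_identical(generate_cohort(cfg, 3), generate_cohort(cfg, 3))
  s1 <- generate_session(cfg, "kid", seed = 9)
  s2 <- generate_session(cfg, "kid", seed = 10)
  expect_false(identical(s1$faces, s2$faces))
})

test_that("cohort generation produces distinct children and requires at least two", {
  cfg <- sim_config(session_minutes = 2, seed = 3)
  coh <- generate_cohort(cfg, 13)
  expect_length(coh, 13)
  ids <- vapply(coh, `[[`, "", "child_id")
  expect_equal(length(unique(ids)), 13)
  expect_error(generate_cohort(cfg, 1), ">= 2")
})

test_that("realized interaction counts follow the configured point-process rate", {
  # short durations so that same-class merging is negligible
  cfg <- sim_config(session_minutes = 40, adult_rate = 2,
                    adult_dur_logmean = log(2), adult_dur_logsd = 0.3,
                    peer_rate = 0, peer_dur_logmean = log(1),
                    bg_speech_rate = 0, false_face_rate = 0,
                    staff_face_rate = 0, occlusion_prob = 1, seed = 6)
  counts <- vapply(1:200, function(i) {
    s <- generate_session(cfg, seed = 1000 + i)
    nrow(s$truth_adult$intervals)
  }, numeric(1))
  lambda <- 2 * 40 / 10  # 8 expected onsets
  se <- sqrt(lambda / 200)
  expect_lt(abs(mean(counts) - lambda), 3 * se)

  # chi-square goodness of fit against the Poisson law, alpha = 0.01
  brk <- c(-0.5, 3.5, 5.5, 7.5, 9.5, 11.5, Inf)
  obs <- table(cut(counts, brk))
  pr <- diff(ppois(c(-1, 3, 5, 7, 9, 11, Inf), lambda))
  chi2 <- sum((as.numeric(obs) - 200 * pr)^2 / (200 * pr))
  expect_lt(chi2, qchisq(0.99, df = length(pr) - 1))
})

test_that("peer interactions are shorter than adult interactions under defaults", {
  cfg <- sim_config(seed = 8)
  coh <- generate_cohort(cfg, 6)
  adult_dur <- unlist(lapply(coh, function(s) {
    s$truth_adult$intervals$offset - s$truth_adult$intervals$onset
  }))
  peer_dur <- unlist(lapply(coh, function(s) {
    s$truth_peer$intervals$offset - s$truth_peer$intervals$onset
  }))
  expect_lt(median(peer_dur), median(adult_dur))
})

test_that("transcript corruption preserves identity at zero rates and deletes everything at one", {
  cfg <- separable_config(5, seed = 12)
  s <- generate_session(cfg)
  same <- corrupt_transcript(s$reference, 0, 0, seed = 1)
  expect_equal(unlist(same$words), unlist(s$reference$words))
  expect_equal(same$start, s$reference$start)
  gone <- corrupt_transcript(s$reference, 1, 0, seed = 1)
  expect_equal(nrow(gone), 0)
  expect_error(corrupt_transcript(s$reference, 0.8, 0.5, seed = 1), "sum")
})

test_that("word deletion thins word counts binomially", {
  # ~10,000 reference words, 50 corruption replicates
  words <- replicate(2500, paste(sample(letters, 4, TRUE), collapse = ""))
  utt <- data.frame(
    start = seq(0, by = 3000, length.out = 250),
    end = seq(2000, by = 3000, length.out = 250),
    speaker_class = "adult", text = NA_character_, loudness = 5,
    words = I(split(words, rep(1:250, each = 10))),
    confs = I(replicate(250, runif(10, .8, 1), simplify = FALSE)),
    wstart = I(replicate(250, seq(0, 1800, by = 200), simplify = FALSE)),
    wend = I(replicate(250, seq(200, 2000, by = 200), simplify = FALSE))
  )
  n_ref <- 2500
  ratios <- vapply(1:50, function(r) {
    cr <- corrupt_transcript(utt, wer_del = 0.3, wer_sub = 0, seed = r)
    length(unlist(cr$words)) / n_ref
  }, numeric(1))
  se <- sqrt(0.3 * 0.7 / n_ref) / sqrt(50)
  expect_lt(abs(mean(ratios) - 0.7), 3 * se + 1e-3)
})

test_that("bookkeeping equals measures recomputed from the reference transcript", {
  set.seed(13)
  for (i in 1:12) {
    cfg <- sim_config(
      session_minutes = runif(1, 2, 6),
      adult_rate = runif(1, 1, 4), peer_rate = runif(1, 2, 6),
      occlusion_prob = runif(1, 0, 0.4),
      bg_speech_rate = runif(1, 0, 3),
      focal_speech_prob = runif(1, 0.1, 0.5),
      seed = 100 + i)
    s <- generate_session(cfg, seed = 200 + i)
    ref <- s$reference
    focal <- ref$speaker_class == "focal"
    for (sp in c("adult", "peer", "focal")) {
      sel <- if (sp == "focal") focal & ref$directed != "none"
             else !focal & ref$cds_label == paste0(sp, "_cds")
      uu <- ref[sel, , drop = FALSE]
      uu$tokens <- lapply(uu$text, tokenize_utterance)
      recomputed <- cds_measures(uu, cfg$session_minutes, norm = TRUE)
      expect_equal(unclass(recomputed), unclass(s$bookkeeping$cds[[sp]]))
    }
  }
})

test_that("reference CDS labels always lie inside a truth interval of their class", {
  cfg <- sim_config(session_minutes = 6, seed = 77)
  s <- generate_session(cfg)
  ref <- s$reference
  a <- ref[!is.na(ref$cds_label) & ref$cds_label == "adult_cds", ]
  p <- ref[!is.na(ref$cds_label) & ref$cds_label == "peer_cds", ]
  expect_true(all(classtalk:::overlaps_track(a$start, a$end, s$truth_adult)))
  expect_true(all(classtalk:::overlaps_track(p$start, p$end, s$truth_peer)))
})
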