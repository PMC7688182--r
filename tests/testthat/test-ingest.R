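make_det <- function(t_ms, x = 0.1, y = 0.1, w = 0.2, h = 0.3, yaw = 0,
                     roll = 0, pitch = 0, mouth = 50, eyes = 80) {
  data.frame(t_ms = t_ms, x = x, y = y, w = w, h = h, yaw = yaw,
             roll = roll, pitch = pitch, mouth_open_conf = mouth,
             eyes_open_conf = eyes)
}

test_that("face-detection parsing keeps well-formed records and counts skips", {
  d <- rbind(make_det(500), make_det(0), make_det(1000, w = 0.95, x = 0.2))
  d$pitch[2] <- NA  # missing pose -> skipped
  expect_message(out <- parse_face_detections(d), "skipped 2")
  expect_equal(attr(out, "skipped"), 2L)
  expect_equal(out$t_ms, 500)
  expect_equal(out$w * out$h, 0.06)

  empty <- d[0, ]
  expect_warning(out0 <- parse_face_detections(empty), "empty")
  expect_equal(nrow(out0), 0)
})

test_that("parsed detection count round-trips with the simulator face stream", {
  cfg <- sim_config(session_minutes = 3, seed = 55)
  s <- generate_session(cfg)
  out <- parse_face_detections(s$faces)
  expect_equal(nrow(out), nrow(s$faces))
  expect_equal(attr(out, "skipped"), 0L)
})

id_map <- data.frame(face_id = c("teacher_1", "staff_1"),
                     participant_id = c("t", "s"),
                     class = c("teacher", "other_adult"))

test_that("identity resolution enforces the similarity threshold and removes staff", {
  det <- make_det(c(1000, 2000, 3000))
  matches <- data.frame(
    t_ms = c(1000, 2000, 3000),
    face_id = c("teacher_1", "teacher_1", "staff_1"),
    similarity = c(91.9, 100, 99),
    x = 0.1, y = 0.1, w = 0.2, h = 0.3)
  out <- resolve_identities(det, matches, id_map)
  # 91.9 is below the 92 threshold -> unmatched -> default peer
  expect_equal(out$class[out$t_ms == 1000], "peer")
  # identical bbox and timestamp, similarity 100 -> labeled adult (IoU = 1)
  expect_equal(out$class[out$t_ms == 2000], "adult")
  # staff detections are removed entirely
  expect_false(3000 %in% out$t_ms)
  expect_false(any(out$class == "other_adult"))
})

test_that("identity resolution respects time and IoU tolerances", {
  det <- make_det(1000)
  far_time <- data.frame(t_ms = 1400, face_id = "teacher_1",
                         similarity = 99, x = 0.1, y = 0.1, w = 0.2, h = 0.3)
  expect_equal(resolve_identities(det, far_time, id_map)$class, "peer")
  near_time <- far_time
  near_time$t_ms <- 1200
  expect_equal(resolve_identities(det, near_time, id_map)$class, "adult")
  poor_iou <- data.frame(t_ms = 1000, face_id = "teacher_1",
                         similarity = 99, x = 0.7, y = 0.7, w = 0.2, h = 0.3)
  expect_equal(resolve_identities(det, poor_iou, id_map)$class, "peer")
})

test_that("representative-face selection takes the largest box per class, earliest on ties", {
  det <- rbind(make_det(1000, w = 0.2, h = 0.2),   # area 0.04
               make_det(1000, w = 0.3, h = 0.3),   # area 0.09
               make_det(1000, w = 0.1, h = 0.1))
  det$class <- c("adult", "adult", "peer")
  det$yaw <- c(1, 2, 3)
  rep_faces <- select_representative_faces(det)
  expect_equal(rep_faces$area[rep_faces$class == "adult"], 0.09)
  expect_equal(rep_faces$yaw[rep_faces$class == "adult"], 2)

  tie <- rbind(make_det(500, w = 0.2, h = 0.2), make_det(500, w = 0.2, h = 0.2))
  tie$class <- "peer"
  tie$yaw <- c(10, 20)
  expect_equal(select_representative_faces(tie)$yaw, 10)
})

test_that("representative selection equals brute-force argmax on random frames", {
  set.seed(61)
  for (i in 1:40) {
    n <- sample(1:6, 1)
    det <- make_det(rep(1000, n), w = runif(n, 0.05, 0.4),
                    h = runif(n, 0.05, 0.4))
    det$class <- sample(c("adult", "peer"), n, replace = TRUE)
    det$yaw <- seq_len(n)
    out <- select_representative_faces(det)
    for (cls in unique(det$class)) {
      sub <- det[det$class == cls, ]
      best <- sub[which.max(sub$w * sub$h), ]
      expect_equal(out$area[out$class == cls], best$w * best$h)
      expect_equal(out$yaw[out$class == cls], best$yaw)
    }
  }
})

seg <- function(text, words, speaker = "adult", t0 = 0, conf = 0.9) {
  n <- length(words)
  list(start_ms = t0, end_ms = t0 + 400 * n, speaker_class = speaker,
       punctuated_text = text, loudness = 10,
       words = data.frame(w = words, conf = conf,
                          start_ms = t0 + 400 * (seq_len(n) - 1),
                          end_ms = t0 + 400 * seq_len(n)))
}

test_that("utterance segmentation splits at sentence-final punctuation only", {
  asr <- list(segments = list(
    seg("you are here. sit down.", c("you", "are", "here", "sit", "down"))))
  u <- segment_utterances(asr)
  expect_equal(nrow(u), 2)
  expect_equal(u$n_tokens, c(3, 2))
  expect_equal(u$start, c(0, 1200))
  expect_equal(u$end, c(1200, 2000))

  nosplit <- list(segments = list(
    seg("well, you are here", c("well", "you", "are", "here"))))
  expect_equal(nrow(segment_utterances(nosplit)), 1)

  broken <- list(segments = list(seg("", c("you", "are"))))
  expect_error(segment_utterances(broken), "inconsistent")
})

test_that("splitting preserves the total token count", {
  set.seed(62)
  cfg <- sim_config(session_minutes = 4, seed = 63)
  s <- generate_session(cfg)
  u <- segment_utterances(s$asr)
  total_seg <- sum(vapply(s$asr$segments, function(sg) {
    length(tokenize_utterance(sg$punctuated_text))
  }, numeric(1)))
  expect_equal(sum(u$n_tokens), total_seg)
})

test_that("utterance count round-trips with bookkeeping when ASR is uncorrupted", {
  cfg <- separable_config(5, seed = 64, focal_speech_prob = 0.3)
  s <- generate_session(cfg)
  u <- segment_utterances(s$asr)
  expect_equal(nrow(u), nrow(s$reference))
})

test_that("loudness passes through when present and the proxy is monotone", {
  segs <- list(seg("hi there.", c("hi", "there")))
  expect_equal(compute_segment_loudness(segs), 10)

  no_loud <- segs
  no_loud[[1]]$loudness <- NULL
  expect_error(compute_segment_loudness(no_loud), "loudness")
  x <- rnorm(1000)
  l1 <- compute_segment_loudness(no_loud, samples = list(x))
  l2 <- compute_segment_loudness(no_loud, samples = list(2 * x))
  expect_gt(l2, l1)
  expect_equal(compute_segment_loudness(no_loud, samples = list(rep(0, 10))),
               0)
})
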