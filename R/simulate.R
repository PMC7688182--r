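# Synthetic classroom-session simulator. Generates ground-truth interaction
# tracks, a raw face-detection stream with identity matches, reference
# transcripts with generative CDS labels, and corrupted ASR output, so that
# every downstream stage of the pipeline can be trained and validated without
# recordings or cloud featurization.
#
# Generative model: interaction onsets follow a homogeneous Poisson process
# per partner class (adults less frequent but longer; peers sparse and
# short), durations are log-normal, and same-class overlaps are merged.
# Event boundaries are aligned to the 500 ms native face-frame grid so the
# feature stream can represent them exactly. Partner faces are emitted every
# 500 ms during true intervals (subject to occlusion dropouts) with bounding
# boxes stochastically larger than background false faces, encoding the
# proximity proxy. Speech is placed inside intervals (CDS and focal-child
# speech) and outside (background, non-CDS); ASR output is derived from the
# reference transcript by word deletion/substitution corruption.

.frame_ms <- 500  # native face-frame period

derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + stream) %% 2147483647)
}

#' Configuration for the classroom-session simulator
#'
#' Defaults encode a 40-minute employed recording with adult interactions
#' that are longer and less frequent than the sparse, short peer
#' interactions, face occlusion dropouts during interactions, background
#' false-face detections, and ASR word-level corruption that makes raw
#' automatic counts underestimate the reference.
#'
#' @param session_minutes employed recording time (minutes).
#' @param adult_rate,peer_rate interaction onsets per 10 minutes.
#' @param adult_dur_logmean,adult_dur_logsd log-normal duration parameters
#'   (log seconds) for adult interactions.
#' @param peer_dur_logmean,peer_dur_logsd same for peer interactions; the
#'   default peer median duration must stay below the adult median.
#' @param occlusion_prob probability a partner face frame is dropped during
#'   a true interaction.
#' @param false_face_rate background (non-partner) face detections per minute
#'   outside interactions.
#' @param staff_face_rate research-staff face detections per minute; these are
#'   matched to an \code{other_adult} identity and must be removed at ingest.
#' @param bg_speech_rate background (non-CDS) utterances per minute.
#' @param focal_speech_prob probability an utterance slot inside an
#'   interaction belongs to the focal child rather than the partner.
#' @param word_rate words per second of speech.
#' @param wer_del,wer_sub per-word deletion and substitution probabilities
#'   applied when deriving ASR output from the reference transcript.
#' @param vocab_size vocabulary size for word sampling.
#' @param seed master seed; all randomness is derived from it.
#' @return validated list of class \code{sim_config}.
#' @export
sim_config <- function(session_minutes = 40,
                       adult_rate = 2,
                       adult_dur_logmean = log(30),
                       adult_dur_logsd = 0.6,
                       peer_rate = 3,
                       peer_dur_logmean = log(8),
                       peer_dur_logsd = 0.7,
                       occlusion_prob = 0.2,
                       false_face_rate = 2,
                       staff_face_rate = 0.3,
                       bg_speech_rate = 2,
                       focal_speech_prob = 0.35,
                       word_rate = 2.5,
                       wer_del = 0.3,
                       wer_sub = 0.1,
                       vocab_size = 200,
                       seed = 1L) {
  cfg <- list(
    session_minutes = session_minutes,
    adult_rate = adult_rate,
    adult_dur_logmean = adult_dur_logmean,
    adult_dur_logsd = adult_dur_logsd,
    peer_rate = peer_rate,
    peer_dur_logmean = peer_dur_logmean,
    peer_dur_logsd = peer_dur_logsd,
    occlusion_prob = occlusion_prob,
    false_face_rate = false_face_rate,
    staff_face_rate = staff_face_rate,
    bg_speech_rate = bg_speech_rate,
    focal_speech_prob = focal_speech_prob,
    word_rate = word_rate,
    wer_del = wer_del,
    wer_sub = wer_sub,
    vocab_size = as.integer(vocab_size),
    seed = as.integer(seed)
  )
  rates <- c("adult_rate", "peer_rate", "false_face_rate", "staff_face_rate",
             "bg_speech_rate", "word_rate")
  for (f in rates) {
    if (!is.finite(cfg[[f]]) || cfg[[f]] < 0) {
      stop(sprintf("invalid config field '%s': must be finite and >= 0", f))
    }
  }
  probs <- c("occlusion_prob", "false_face_prob" = NA, "focal_speech_prob",
             "wer_del", "wer_sub")
  for (f in c("occlusion_prob", "focal_speech_prob", "wer_del", "wer_sub")) {
    if (!is.finite(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1) {
      stop(sprintf("invalid config field '%s': must be a probability", f))
    }
  }
  if (cfg$wer_del + cfg$wer_sub > 1) {
    stop("invalid config: wer_del + wer_sub must be <= 1")
  }
  if (!is.finite(cfg$session_minutes) || cfg$session_minutes <= 0) {
    stop("invalid config field 'session_minutes': must be > 0")
  }
  if (cfg$adult_rate > 2400 || cfg$peer_rate > 2400) {
    stop("interaction rate implies > 1 onset per 250 ms bin; unsupported regime")
  }
  if (cfg$vocab_size < 1) stop("invalid config field 'vocab_size'")
  if (exp(cfg$peer_dur_logmean) >= exp(cfg$adult_dur_logmean)) {
    stop("peer median duration must be shorter than adult median duration")
  }
  structure(cfg, class = "sim_config")
}

# Core child-directed vocabulary; recycled or extended to vocab_size.
# Contains a few contractions so tokenization expansion is exercised.
.base_vocab <- c(
  "you", "i", "it", "the", "a", "to", "and", "that", "this", "is",
  "look", "see", "go", "come", "put", "get", "want", "like", "play", "make",
  "here", "there", "up", "down", "in", "out", "on", "off", "now", "again",
  "ball", "block", "book", "car", "truck", "doll", "baby", "dog", "cat",
  "house", "table", "chair", "door", "window", "paper", "crayon", "paint",
  "water", "snack", "apple", "milk", "juice", "cup", "plate", "spoon",
  "red", "blue", "green", "yellow", "big", "little", "good", "nice", "fast",
  "slow", "hot", "cold", "one", "two", "three", "four", "five", "more",
  "all", "some", "my", "your", "his", "her", "we", "they", "what", "where",
  "who", "why", "how", "yes", "no", "please", "thank", "okay", "friend",
  "teacher", "help", "share", "turn", "wait", "sit", "stand", "walk", "run",
  "jump", "clean", "wash", "hands", "story", "song", "sing", "dance",
  "circle", "line", "time", "day", "outside", "inside", "don't", "it's",
  "you're", "that's", "let's", "can't", "what's", "i'm"
)

build_vocab <- function(vocab_size) {
  if (vocab_size <= length(.base_vocab)) {
    .base_vocab[seq_len(vocab_size)]
  } else {
    c(.base_vocab,
      sprintf("word%03d", seq_len(vocab_size - length(.base_vocab))))
  }
}

# Zipf-like sampling weights over the vocabulary.
vocab_weights <- function(n) 1 / seq_len(n)

# --- interval generation -----------------------------------------------------

sample_truth_track <- function(rate, dur_logmean, dur_logsd, session_ms,
                               partner) {
  grid_end <- floor(session_ms / .frame_ms) * .frame_ms
  n <- rpois(1, rate * (session_ms / 60000) / 10)
  if (n == 0 || grid_end < 2 * .frame_ms) {
    return(interval_track(partner = partner, source = "reference"))
  }
  onset <- round(runif(n, 0, grid_end - .frame_ms) / .frame_ms) * .frame_ms
  dur <- round(rlnorm(n, dur_logmean, dur_logsd) * 1000 / .frame_ms) * .frame_ms
  dur <- pmax(dur, .frame_ms)
  offset <- pmin(onset + dur, grid_end)
  keep <- offset > onset
  interval_track(onset[keep], offset[keep], partner = partner,
                 source = "reference")
}

# --- speech generation -------------------------------------------------------

empty_utterances <- function() {
  data.frame(
    start = numeric(0), end = numeric(0), speaker_class = character(0),
    text = character(0), loudness = numeric(0),
    words = I(list()), confs = I(list()),
    wstart = I(list()), wend = I(list())
  )
}

make_utterance <- function(start, speaker, vocab, wts, word_rate) {
  nw <- 1 + rpois(1, 2.2)
  wdur <- round(1000 / word_rate)
  words <- sample(vocab, nw, replace = TRUE, prob = wts)
  wstart <- start + (seq_len(nw) - 1) * wdur
  data.frame(
    start = start, end = start + nw * wdur, speaker_class = speaker,
    text = paste(words, collapse = " "),
    loudness = NA_real_,
    words = I(list(words)),
    confs = I(list(round(runif(nw, 0.85, 1), 4))),
    wstart = I(list(wstart)),
    wend = I(list(wstart + wdur))
  )
}

gen_interval_speech <- function(track, partner, cfg, vocab, wts) {
  iv <- track_intervals(track)
  out <- list()
  for (i in seq_len(nrow(iv))) {
    t <- iv$onset[i] + round(rexp(1, 1 / 600))
    while (t < iv$offset[i]) {
      speaker <- if (runif(1) < cfg$focal_speech_prob) "focal" else partner
      u <- make_utterance(t, speaker, vocab, wts, cfg$word_rate)
      if (u$end > iv$offset[i]) break
      out[[length(out) + 1]] <- u
      t <- u$end + round(rexp(1, 1 / 900))
    }
  }
  if (length(out) == 0) empty_utterances() else do.call(rbind, out)
}

gen_background_speech <- function(cfg, session_ms, busy, vocab, wts) {
  n <- rpois(1, cfg$bg_speech_rate * session_ms / 60000)
  out <- list()
  for (i in seq_len(n)) {
    for (attempt in 1:25) {
      start <- round(runif(1, 0, max(0, session_ms - 4000)))
      speaker <- sample(c("adult", "peer"), 1)
      u <- make_utterance(start, speaker, vocab, wts, cfg$word_rate)
      if (u$end <= session_ms &&
          !any(pmin(u$end, busy$offset) - pmax(u$start, busy$onset) > 0)) {
        out[[length(out) + 1]] <- u
        break
      }
    }
  }
  if (length(out) == 0) empty_utterances() else do.call(rbind, out)
}

# --- face generation ---------------------------------------------------------

empty_faces <- function() {
  data.frame(t_ms = numeric(0), x = numeric(0), y = numeric(0),
             w = numeric(0), h = numeric(0), yaw = numeric(0),
             roll = numeric(0), pitch = numeric(0),
             mouth_open_conf = numeric(0), eyes_open_conf = numeric(0))
}

make_faces <- function(ts, w_range, pose_sd, mouth) {
  n <- length(ts)
  if (n == 0) return(empty_faces())
  w <- runif(n, w_range[1], w_range[2])
  h <- runif(n, w_range[1], w_range[2])
  data.frame(
    t_ms = ts,
    x = round(runif(n, 0, 1 - w), 4), y = round(runif(n, 0, 1 - h), 4),
    w = round(w, 4), h = round(h, 4),
    yaw = round(rnorm(n, 0, pose_sd), 2),
    roll = round(rnorm(n, 0, pose_sd), 2),
    pitch = round(rnorm(n, 0, pose_sd), 2),
    mouth_open_conf = round(mouth, 2),
    eyes_open_conf = round(runif(n, 60, 100), 2)
  )
}

gen_partner_faces <- function(track, cfg, utterances, partner) {
  iv <- track_intervals(track)
  ts <- unlist(lapply(seq_len(nrow(iv)), function(i) {
    if (iv$offset[i] - iv$onset[i] < .frame_ms) return(numeric(0))
    seq(iv$onset[i], iv$offset[i] - .frame_ms, by = .frame_ms)
  }))
  if (length(ts) == 0) return(empty_faces())
  ts <- ts[runif(length(ts)) >= cfg$occlusion_prob]
  if (length(ts) == 0) return(empty_faces())
  spk <- utterances[utterances$speaker_class == partner, , drop = FALSE]
  talking <- vapply(ts, function(t) {
    any(pmin(t + .frame_ms, spk$end) - pmax(t, spk$start) > 0)
  }, logical(1))
  mouth <- ifelse(talking, runif(length(ts), 55, 100),
                  runif(length(ts), 10, 70))
  make_faces(ts, c(0.25, 0.45), pose_sd = 8, mouth = mouth)
}

gen_scatter_faces <- function(rate, cfg, session_ms, w_range) {
  n <- rpois(1, rate * session_ms / 60000)
  grid_end <- floor(session_ms / .frame_ms) * .frame_ms
  if (n == 0 || grid_end < .frame_ms) return(empty_faces())
  ts <- round(runif(n, 0, grid_end - .frame_ms) / .frame_ms) * .frame_ms
  make_faces(ts, w_range, pose_sd = 30, mouth = runif(n, 0, 100))
}

match_rows <- function(faces, face_id) {
  if (nrow(faces) == 0) {
    return(data.frame(t_ms = numeric(0), face_id = character(0),
                      similarity = numeric(0), x = numeric(0), y = numeric(0),
                      w = numeric(0), h = numeric(0)))
  }
  data.frame(t_ms = faces$t_ms, face_id = face_id,
             similarity = round(runif(nrow(faces), 93, 100), 2),
             x = faces$x, y = faces$y, w = faces$w, h = faces$h)
}

# --- ASR corruption ----------------------------------------------------------

#' Corrupt a reference transcript into simulated ASR output
#'
#' Each word is independently deleted with probability \code{wer_del} or
#' substituted by a random vocabulary word with probability \code{wer_sub};
#' substituted words get a lower confidence. Utterances emptied of all words
#' are dropped; surviving utterances keep their punctuation boundary and the
#' timings of their surviving words.
#'
#' @param utterances reference utterance data frame (as produced by
#'   \code{\link{generate_session}}).
#' @param wer_del,wer_sub word deletion / substitution probabilities, with
#'   \code{wer_del + wer_sub <= 1}.
#' @param vocab character vector to draw substitutions from.
#' @param seed optional seed; when given, corruption is deterministic and the
#'   caller's RNG state is untouched.
#' @return corrupted utterance data frame in the same layout.
#' @export
corrupt_transcript <- function(utterances, wer_del, wer_sub,
                               vocab = build_vocab(200), seed = NULL) {
  if (!is.finite(wer_del) || wer_del < 0 || wer_del > 1 ||
      !is.finite(wer_sub) || wer_sub < 0 || wer_sub > 1 ||
      wer_del + wer_sub > 1) {
    stop("wer_del and wer_sub must be probabilities with sum <= 1")
  }
  run <- function() {
    if (nrow(utterances) == 0) return(utterances)
    nw <- lengths(utterances$words)
    uidx <- rep(seq_len(nrow(utterances)), nw)
    words <- unlist(utterances$words, use.names = FALSE)
    confs <- unlist(utterances$confs, use.names = FALSE)
    ws <- unlist(utterances$wstart, use.names = FALSE)
    we <- unlist(utterances$wend, use.names = FALSE)
    u <- runif(length(words))
    deleted <- u < wer_del
    substituted <- !deleted & u < wer_del + wer_sub
    if (any(substituted)) {
      words[substituted] <- sample(vocab, sum(substituted), replace = TRUE)
      confs[substituted] <- round(runif(sum(substituted), 0.2, 0.6), 4)
    }
    keep <- !deleted
    if (!any(keep)) return(empty_utterances())
    uidx <- uidx[keep]
    words <- words[keep]
    confs <- confs[keep]
    ws <- ws[keep]
    we <- we[keep]
    survivors <- unique(uidx)
    f <- factor(uidx, levels = survivors)
    words_l <- split(words, f)
    confs_l <- split(confs, f)
    ws_l <- split(ws, f)
    we_l <- split(we, f)
    out <- data.frame(
      start = vapply(ws_l, `[[`, numeric(1), 1),
      end = vapply(we_l, function(v) v[length(v)], numeric(1)),
      speaker_class = utterances$speaker_class[survivors],
      text = vapply(words_l, paste, character(1), collapse = " "),
      loudness = utterances$loudness[survivors],
      words = I(unname(words_l)), confs = I(unname(confs_l)),
      wstart = I(unname(ws_l)), wend = I(unname(we_l))
    )
    rownames(out) <- NULL
    out
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# Group corrupted utterances into ASR segments: consecutive utterances of the
# same speaker separated by less than `gap_ms` share one segment, their texts
# joined with sentence-final periods (the boundaries the utterance segmenter
# later splits on).
assemble_asr_segments <- function(utterances, gap_ms = 800) {
  if (nrow(utterances) == 0) {
    return(list(segments = list()))
  }
  utterances <- utterances[order(utterances$start), , drop = FALSE]
  grp <- integer(nrow(utterances))
  g <- 1L
  grp[1] <- g
  if (nrow(utterances) > 1) {
    for (i in 2:nrow(utterances)) {
      same <- utterances$speaker_class[i] == utterances$speaker_class[i - 1]
      close <- utterances$start[i] - utterances$end[i - 1] < gap_ms
      if (!(same && close)) g <- g + 1L
      grp[i] <- g
    }
  }
  segments <- lapply(split(seq_len(nrow(utterances)), grp), function(idx) {
    uu <- utterances[idx, , drop = FALSE]
    words <- data.frame(
      w = unlist(uu$words, use.names = FALSE),
      conf = unlist(uu$confs, use.names = FALSE),
      start_ms = unlist(uu$wstart, use.names = FALSE),
      end_ms = unlist(uu$wend, use.names = FALSE)
    )
    list(
      start_ms = uu$start[1],
      end_ms = uu$end[nrow(uu)],
      speaker_class = uu$speaker_class[1],
      punctuated_text = paste0(paste(uu$text, collapse = ". "), "."),
      loudness = round(mean(uu$loudness), 3),
      words = words
    )
  })
  names(segments) <- NULL
  list(segments = segments)
}

# --- session assembly --------------------------------------------------------

label_reference <- function(utterances, truth_adult, truth_peer) {
  focal <- utterances$speaker_class == "focal"
  utterances$cds_label <- rep(NA_character_, nrow(utterances))
  utterances$directed <- rep(NA_character_, nrow(utterances))
  if (any(!focal)) {
    lab <- assign_utterances(utterances[!focal, , drop = FALSE],
                             truth_adult, truth_peer)
    utterances$cds_label[!focal] <- lab$cds_label
  }
  if (any(focal)) {
    dd <- collect_focal_speech(utterances[focal, , drop = FALSE],
                               truth_adult, truth_peer)
    utterances$directed[focal] <- dd$directed
  }
  utterances
}

session_bookkeeping <- function(reference, truth_adult, truth_peer, minutes) {
  focal <- reference$speaker_class == "focal"
  sel <- list(
    adult = !focal & reference$cds_label == "adult_cds",
    peer = !focal & reference$cds_label == "peer_cds",
    focal = focal & reference$directed != "none"
  )
  cds <- lapply(sel, function(s) {
    uu <- reference[s, , drop = FALSE]
    uu$tokens <- lapply(uu$text, tokenize_utterance)
    cds_measures(uu, minutes, norm = TRUE)
  })
  list(
    cds = cds,
    interaction = list(
      adult = interaction_measures(truth_adult, minutes, norm = TRUE),
      peer = interaction_measures(truth_peer, minutes, norm = TRUE)
    )
  )
}

#' Generate one synthetic classroom session
#'
#' @param config a \code{\link{sim_config}}.
#' @param child_id identifier for the focal child.
#' @param seed seed for this session (default the config's master seed).
#' @return object of class \code{synthetic_session}: ground-truth tracks
#'   (\code{truth_adult}, \code{truth_peer}), raw face detections
#'   (\code{faces}), identity matches (\code{matches}, \code{identity_map}),
#'   simulated ASR output (\code{asr}), the reference transcript
#'   (\code{reference}, with generative CDS labels) and \code{bookkeeping}
#'   (exact reference measure sets computed at generation time).
#' @export
generate_session <- function(config, child_id = "child01",
                             seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  session_ms <- round(config$session_minutes * 60000)
  if (session_ms <= 0) stop("zero-duration session")
  vocab <- build_vocab(config$vocab_size)
  wts <- vocab_weights(length(vocab))

  truth_adult <- with_seed(derive_seed(seed, 1), {
    sample_truth_track(config$adult_rate, config$adult_dur_logmean,
                       config$adult_dur_logsd, session_ms, "adult")
  })
  truth_peer <- with_seed(derive_seed(seed, 2), {
    sample_truth_track(config$peer_rate, config$peer_dur_logmean,
                       config$peer_dur_logsd, session_ms, "peer")
  })

  reference <- with_seed(derive_seed(seed, 3), {
    busy <- merge_intervals(
      c(truth_adult$intervals$onset, truth_peer$intervals$onset),
      c(truth_adult$intervals$offset, truth_peer$intervals$offset)
    )
    utt <- rbind(
      gen_interval_speech(truth_adult, "adult", config, vocab, wts),
      gen_interval_speech(truth_peer, "peer", config, vocab, wts),
      gen_background_speech(config, session_ms, busy, vocab, wts)
    )
    utt <- utt[order(utt$start), , drop = FALSE]
    rownames(utt) <- NULL
    utt <- label_reference(utt, truth_adult, truth_peer)
    # loudness encodes acoustic proximity: talk within an interaction is
    # closer to the head-mounted microphone than background talk
    in_int <- overlaps_track(utt$start, utt$end, truth_adult) |
      overlaps_track(utt$start, utt$end, truth_peer)
    utt$loudness <- round(pmax(0.1, rnorm(nrow(utt),
                                          ifelse(in_int, 12, 4),
                                          ifelse(in_int, 2, 1))), 3)
    utt
  })

  face_parts <- with_seed(derive_seed(seed, 4), {
    teacher <- gen_partner_faces(truth_adult, config, reference, "adult")
    peer <- gen_partner_faces(truth_peer, config, reference, "peer")
    false_f <- gen_scatter_faces(config$false_face_rate, config, session_ms,
                                 c(0.04, 0.12))
    staff <- gen_scatter_faces(config$staff_face_rate, config, session_ms,
                               c(0.15, 0.35))
    list(teacher = teacher, peer = peer, false_f = false_f, staff = staff,
         matches = rbind(match_rows(teacher, "teacher_1"),
                         match_rows(staff, "staff_1")))
  })
  faces <- rbind(face_parts$teacher, face_parts$peer, face_parts$false_f,
                 face_parts$staff)
  faces <- faces[order(faces$t_ms), , drop = FALSE]
  rownames(faces) <- NULL
  matches <- face_parts$matches[order(face_parts$matches$t_ms), , drop = FALSE]
  rownames(matches) <- NULL

  corrupted <- corrupt_transcript(reference, config$wer_del, config$wer_sub,
                                  vocab, seed = derive_seed(seed, 5))
  asr <- with_seed(derive_seed(seed, 6), assemble_asr_segments(corrupted))

  structure(
    list(
      child_id = child_id,
      session_ms = session_ms,
      config = config,
      seed = seed,
      truth_adult = truth_adult,
      truth_peer = truth_peer,
      faces = faces,
      matches = matches,
      identity_map = data.frame(
        face_id = c("teacher_1", "staff_1"),
        participant_id = c("teacher_a", "staff_a"),
        class = c("teacher", "other_adult")
      ),
      asr = asr,
      reference = reference,
      bookkeeping = session_bookkeeping(reference, truth_adult, truth_peer,
                                        config$session_minutes)
    ),
    class = "synthetic_session"
  )
}

#' @export
print.synthetic_session <- function(x, ...) {
  cat(sprintf(
    "<synthetic_session> %s: %.1f min, %d adult / %d peer interactions, %d utterances\n",
    x$child_id, x$session_ms / 60000, nrow(x$truth_adult$intervals),
    nrow(x$truth_peer$intervals), nrow(x$reference)))
  invisible(x)
}

#' Generate a cohort of independent synthetic sessions
#'
#' Child seeds are derived deterministically from the config's master seed,
#' so the same config reproduces the same cohort.
#'
#' @param config a \code{\link{sim_config}}.
#' @param n_children number of focal children (at least 2; leave-one-subject-out
#'   validation needs two or more subjects).
#' @return list of \code{synthetic_session} objects, class
#'   \code{synthetic_cohort}.
#' @export
generate_cohort <- function(config, n_children = 13) {
  stopifnot(inherits(config, "sim_config"))
  if (n_children < 2) stop("n_children must be >= 2")
  sessions <- lapply(seq_len(n_children), function(i) {
    generate_session(config, child_id = sprintf("child%02d", i),
                     seed = derive_seed(config$seed, 100 + i))
  })
  structure(sessions, class = "synthetic_cohort")
}
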