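# Shared fixtures: configs, small cohorts and independent oracles used
# across test files. Everything is generated in code under fixed seeds.

# A noiseless, fully separable simulator configuration: no occlusion, no
# background faces or speech, uncorrupted transcripts.
separable_config <- function(session_minutes = 10, seed = 1L, ...) {
  args <- list(session_minutes = session_minutes, occlusion_prob = 0,
               false_face_rate = 0, staff_face_rate = 0, bg_speech_rate = 0,
               wer_del = 0, wer_sub = 0, seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

# Random interval track on [0, session_ms) for property tests.
random_track <- function(session_ms = 60000, max_n = 8,
                         partner = "adult", source = "predicted") {
  n <- sample(0:max_n, 1)
  if (n == 0) return(interval_track(partner = partner, source = source))
  onset <- sort(runif(n, 0, session_ms - 300))
  offset <- pmin(onset + rexp(n, 1 / 1500) + 50, session_ms)
  keep <- offset > onset
  interval_track(onset[keep], offset[keep], partner = partner,
                 source = source)
}

# Brute-force per-bin rasterization: literal definition, independent of
# rasterize_track's index arithmetic.
brute_rasterize <- function(track, session_ms, dt = 250) {
  iv <- if (inherits(track, "interval_track")) track$intervals else track
  n_bins <- ceiling(session_ms / dt)
  vapply(seq_len(n_bins), function(b) {
    lo <- (b - 1) * dt
    hi <- b * dt
    any(pmin(hi, iv$offset) - pmax(lo, iv$onset) > 0)
  }, logical(1)) |> as.integer()
}

# Utterance data frame from bare texts; tokens computed by the package
# tokenizer unless supplied.
utt_df <- function(texts, start = NULL, end = NULL, speaker = "adult") {
  n <- length(texts)
  start <- start %||% seq(0, by = 2000, length.out = n)
  end <- end %||% (start + 1000)
  data.frame(start = start, end = end,
             speaker_class = rep_len(speaker, n), text = texts,
             tokens = I(lapply(texts, tokenize_utterance)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# The fixed end-to-end study behind the golden-report regression test:
# 5 children, 6-minute sessions, default noise, desk-scale detectors, with
# every session round-tripped through the on-disk schemas.
golden_study <- function(io_dir) {
  cfg <- sim_config(session_minutes = 6, seed = 20260927L)
  spec_a <- detector_spec("adult", "full", hidden_units = 8, epochs = 6,
                          learn_rate = 0.05, seed = 101L)
  spec_p <- detector_spec("peer", "reduced", hidden_units = 8, epochs = 6,
                          learn_rate = 0.05, seed = 102L)
  suppressWarnings(
    run_study(cfg, n_children = 5, spec_adult = spec_a, spec_peer = spec_p,
              io_dir = io_dir)
  )
}
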