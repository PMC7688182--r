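# Interaction detector: bi-directional LSTM sequence classifiers labeling
# every 250 ms bin as interaction / not-interaction, trained separately per
# partner class (adult vs peer) on whole-session sequences, with a
# full-feature (15-channel) and a reduced-feature (partner face area +
# speech activity) variant, interval post-processing, and a
# leave-one-subject-out harness.

#' Specification of an interaction detector
#'
#' The default architecture is a bi-directional LSTM with 200 hidden units
#' per direction, a per-timestep softmax over (not-interaction, interaction),
#' trained for 30 epochs. The reduced feature set uses only the detector's
#' own partner-class face bounding-box area and the speech-activity channel,
#' mimicking what a non-invasive proximity sensor would provide.
#'
#' @param partner \code{"adult"} or \code{"peer"}.
#' @param feature_set \code{"full"} (all 15 channels) or \code{"reduced"}.
#' @param hidden_units LSTM hidden units per direction.
#' @param epochs training passes over the training sessions.
#' @param learn_rate Adam learning rate (one update per training sequence).
#' @param seed seed for parameter initialization.
#' @return list of class \code{detector_spec}.
#' @export
detector_spec <- function(partner = c("adult", "peer"),
                          feature_set = c("full", "reduced"),
                          hidden_units = 200, epochs = 30,
                          learn_rate = 0.02, seed = 1L) {
  partner <- match.arg(partner)
  feature_set <- match.arg(feature_set)
  if (hidden_units <= 0) stop("hidden_units must be > 0")
  if (epochs <= 0) stop("epochs must be > 0")
  structure(
    list(partner = partner, feature_set = feature_set,
         hidden_units = as.integer(hidden_units),
         epochs = as.integer(epochs),
         learn_rate = learn_rate, seed = as.integer(seed)),
    class = "detector_spec"
  )
}

#' Channels consumed by a detector
#' @param spec a \code{detector_spec}.
#' @return character vector of channel names (15 for full, 2 for reduced).
#' @export
detector_channels <- function(spec) {
  if (spec$feature_set == "full") {
    feature_channels()
  } else {
    c(paste0(spec$partner, "_area"), "speech_active")
  }
}

#' Build an untrained detector with seeded initial parameters
#'
#' Weights are drawn uniformly from \code{[-1/sqrt(H), 1/sqrt(H)]}; the
#' forget-gate bias starts at 1 (standard practice so memory persists early
#' in training).
#'
#' @param spec a \code{detector_spec}.
#' @return list of class \code{bilstm_detector} with \code{params},
#'   \code{spec}, and a NULL \code{norm_stats} slot filled at training time.
#' @export
build_detector <- function(spec) {
  stopifnot(inherits(spec, "detector_spec"))
  d <- length(detector_channels(spec))
  h <- spec$hidden_units
  r <- 1 / sqrt(h)
  init <- function(nr, nc) matrix(runif(nr * nc, -r, r), nr, nc)
  params <- with_seed(spec$seed, {
    gate_bias <- rep(c(0, 1, 0, 0), each = h)  # forget gate biased open
    list(
      Wx_f = init(4 * h, d), Wh_f = init(4 * h, h), b_f = gate_bias,
      Wx_b = init(4 * h, d), Wh_b = init(4 * h, h), b_b = gate_bias,
      Wo = init(2, 2 * h), bo = rep(0, 2)
    )
  })
  structure(
    list(spec = spec, params = params, norm_stats = NULL,
         loss_history = numeric(0)),
    class = "bilstm_detector"
  )
}

#' @export
print.bilstm_detector <- function(x, ...) {
  cat(sprintf(
    "<bilstm_detector> partner=%s features=%s H=%d epochs=%d%s\n",
    x$spec$partner, x$spec$feature_set, x$spec$hidden_units, x$spec$epochs,
    if (length(x$loss_history)) " (trained)" else " (untrained)"))
  invisible(x)
}

series_matrix <- function(series, spec) {
  m <- if (inherits(series, "feature_series")) series$channels else series
  ch <- detector_channels(spec)
  missing_ch <- setdiff(ch, colnames(m))
  if (length(missing_ch) > 0) {
    stop(sprintf("series lacks channel(s): %s",
                 paste(missing_ch, collapse = ", ")))
  }
  t(m[, ch, drop = FALSE])  # D x T for the C++ core
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, clip = 5) {
  gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  sc <- if (gn > clip) clip / gn else 1
  state$t <- state$t + 1
  for (nm in names(params)) {
    g <- grads[[nm]] * sc
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Train a detector on labeled feature sequences
#'
#' One Adam update per training sequence per epoch, sequences visited in a
#' fixed order, so training is deterministic given the spec seed. Inputs must
#' already be normalized (the LOSO harness normalizes with training-fold
#' statistics; see \code{\link{loso_detect}}).
#'
#' @param model an untrained (or partially trained) \code{bilstm_detector}.
#' @param series_list list of normalized \code{feature_series} (or matrices).
#' @param labels_list list of 0/1 integer vectors, one per series, aligned to
#'   its bins.
#' @return the trained model, with per-epoch mean loss in
#'   \code{loss_history}.
#' @export
train_detector <- function(model, series_list, labels_list) {
  stopifnot(inherits(model, "bilstm_detector"))
  if (length(series_list) != length(labels_list)) {
    stop("series_list and labels_list must have equal length")
  }
  xs <- lapply(series_list, series_matrix, spec = model$spec)
  for (i in seq_along(xs)) {
    if (ncol(xs[[i]]) != length(labels_list[[i]])) {
      stop(sprintf("label/series length mismatch for sequence %d", i))
    }
  }
  params <- model$params
  state <- list(
    t = 0,
    m = lapply(params, function(p) p * 0),
    v = lapply(params, function(p) p * 0)
  )
  loss_hist <- model$loss_history
  for (epoch in seq_len(model$spec$epochs)) {
    losses <- numeric(length(xs))
    for (i in seq_along(xs)) {
      g <- cpp_bilstm_grad(params$Wx_f, params$Wh_f, params$b_f,
                           params$Wx_b, params$Wh_b, params$b_b,
                           params$Wo, params$bo,
                           xs[[i]], as.integer(labels_list[[i]]))
      losses[i] <- g$loss
      upd <- adam_step(params, g[names(params)], state,
                       lr = model$spec$learn_rate)
      params <- upd$params
      state <- upd$state
    }
    loss_hist <- c(loss_hist, mean(losses))
  }
  model$params <- params
  model$loss_history <- loss_hist
  model
}

#' Per-bin interaction probabilities for a normalized series
#' @param model a trained \code{bilstm_detector}.
#' @param series a normalized \code{feature_series} or matrix.
#' @return numeric vector of P(interaction) per bin.
#' @export
predict_probs <- function(model, series) {
  x <- series_matrix(series, model$spec)
  p <- cpp_bilstm_forward(model$params$Wx_f, model$params$Wh_f,
                          model$params$b_f, model$params$Wx_b,
                          model$params$Wh_b, model$params$b_b,
                          model$params$Wo, model$params$bo, x)
  p[2, ]
}

#' Predict an interval track from a normalized series
#'
#' Takes the per-bin argmax class and merges consecutive interaction bins
#' into intervals with bin-edge timestamps. Smoothing
#' (\code{\link{smooth_track}}) is a separate step.
#'
#' @inheritParams predict_probs
#' @param dt bin width in ms.
#' @return an \code{interval_track} (source \code{"predicted"}).
#' @export
predict_track <- function(model, series, dt = 250) {
  p <- predict_probs(model, series)
  bins_to_track(as.integer(p > 0.5), dt = dt, partner = model$spec$partner,
                source = "predicted")
}

#' Leave-one-subject-out training and evaluation of a detector
#'
#' For each held-out child: normalization statistics are fitted on the other
#' children only, a fresh detector is trained on those children, and the
#' held-out child's series (normalized with the training statistics) is
#' predicted and smoothed; sample-level metrics are computed against the
#' child's reference track.
#'
#' @param series_list list of clipped, un-normalized \code{feature_series},
#'   one per child (at least 2).
#' @param ref_tracks list of reference \code{interval_track}s, same order.
#' @param spec a \code{detector_spec}.
#' @param child_ids optional child identifiers.
#' @param min_dur_ms smoothing threshold passed to
#'   \code{\link{smooth_track}}.
#' @param dt bin width in ms.
#' @return list with \code{metrics} (one row per held-out child),
#'   \code{tracks} (smoothed predicted tracks), \code{fold_stats}
#'   (per-fold \code{norm_stats}, for leakage auditing) and \code{spec}.
#' @export
loso_detect <- function(series_list, ref_tracks, spec, child_ids = NULL,
                        min_dur_ms = 1000, dt = 250) {
  n <- length(series_list)
  if (n < 2) stop("LOSO needs at least 2 children")
  stopifnot(length(ref_tracks) == n)
  if (is.null(child_ids)) {
    child_ids <- vapply(seq_len(n), function(i) {
      series_list[[i]]$child_id %||% sprintf("child%02d", i)
    }, character(1))
  }
  session_ms <- vapply(series_list, function(s) s$session_ms, numeric(1))
  labels <- lapply(seq_len(n), function(i) {
    rasterize_track(ref_tracks[[i]], session_ms[i], dt)
  })
  sub <- lapply(series_list, function(s) {
    s$channels <- s$channels[, detector_channels(spec), drop = FALSE]
    s
  })
  metrics <- NULL
  tracks <- vector("list", n)
  fold_stats <- vector("list", n)
  for (j in seq_len(n)) {
    tr <- setdiff(seq_len(n), j)
    stats <- fit_normalize(sub[tr])
    fold_stats[[j]] <- stats
    model <- build_detector(spec)
    model$norm_stats <- stats
    model <- train_detector(model,
                            lapply(sub[tr], apply_normalize, stats = stats),
                            labels[tr])
    held <- apply_normalize(sub[[j]], stats)
    pred <- smooth_track(predict_track(model, held, dt = dt), min_dur_ms)
    tracks[[j]] <- pred
    dm <- detection_metrics(pred, ref_tracks[[j]], session_ms[j], dt)
    metrics <- rbind(metrics, data.frame(
      child_id = child_ids[j], accuracy = dm$accuracy,
      precision = dm$precision, recall = dm$recall, f1 = dm$f1
    ))
  }
  names(tracks) <- child_ids
  names(fold_stats) <- child_ids
  list(metrics = metrics, tracks = tracks, fold_stats = fold_stats,
       spec = spec)
}
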