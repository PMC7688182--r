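# Validation machinery: sample-level detection metrics, relative-error
# agreement metrics between predicted and reference measures, and
# ordinary-least-products (type II) calibration applied inside the
# leave-one-subject-out loop.

#' Sample-level detection metrics for a predicted track
#'
#' Both tracks are rasterized to \code{dt}-ms bins; accuracy is the
#' percentage of bins correctly labeled as interaction or not-interaction,
#' precision the percentage of predicted-interaction bins that are true
#' interaction, recall the percentage of true interaction bins detected, and
#' F1 their harmonic mean. All reported on a 0-100 scale.
#'
#' @param pred_track,ref_track \code{interval_track}s.
#' @param session_ms session length in ms.
#' @param dt bin width in ms (default 250).
#' @return list of class \code{detection_metrics} with confusion counts
#'   (\code{tp}, \code{fp}, \code{tn}, \code{fn}) and \code{accuracy},
#'   \code{precision}, \code{recall}, \code{f1} percentages. Undefined ratios
#'   (zero denominators) are NA with a warning.
#' @export
detection_metrics <- function(pred_track, ref_track, session_ms, dt = 250) {
  p <- rasterize_track(pred_track, session_ms, dt)
  r <- rasterize_track(ref_track, session_ms, dt)
  tp <- sum(p == 1 & r == 1)
  fp <- sum(p == 1 & r == 0)
  tn <- sum(p == 0 & r == 0)
  fn <- sum(p == 0 & r == 1)
  total <- tp + fp + tn + fn
  safe_pct <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined (zero denominator)", what), call. = FALSE)
      return(NA_real_)
    }
    100 * num / den
  }
  precision <- safe_pct(tp, tp + fp, "precision")
  recall <- safe_pct(tp, tp + fn, "recall")
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    NA_real_
  } else {
    2 * precision * recall / (precision + recall)
  }
  structure(
    list(tp = tp, fp = fp, tn = tn, fn = fn,
         accuracy = safe_pct(tp + tn, total, "accuracy"),
         precision = precision, recall = recall, f1 = f1),
    class = "detection_metrics"
  )
}

#' @export
print.detection_metrics <- function(x, ...) {
  cat(sprintf("<detection_metrics> acc=%.1f prec=%.1f rec=%.1f f1=%.1f\n",
              x$accuracy, x$precision, x$recall, x$f1))
  invisible(x)
}

#' Relative error between reference and predicted measures, in percent
#'
#' Unsigned: \code{|x_ref - x_pred| / x_ref * 100} (the absolute relative
#' error, ARE). Signed: \code{(x_pred - x_ref) / x_ref * 100}, so negative
#' values indicate underestimation. Children with a zero reference value get
#' NA and are excluded from summaries.
#'
#' @param x_ref,x_pred numeric vectors (per child).
#' @param signed return the signed version (default FALSE).
#' @return numeric vector of percentages; NA where \code{x_ref == 0} or
#'   either input is NA.
#' @export
relative_error <- function(x_ref, x_pred, signed = FALSE) {
  stopifnot(length(x_ref) == length(x_pred))
  out <- (x_pred - x_ref) / x_ref * 100
  out[!is.finite(out) | x_ref == 0] <- NA_real_
  if (signed) out else abs(out)
}

#' Summarize per-child agreement between predicted and reference measures
#'
#' @param x_ref,x_pred numeric vectors of reference and predicted values per
#'   child.
#' @return list of class \code{agreement_metrics}: \code{are} (per-child
#'   absolute relative error, percent), \code{mare} (its median), \code{mre}
#'   (mean signed relative error), \code{r} (Pearson correlation, NA with
#'   fewer than 2 complete pairs), and \code{n} (children contributing).
#' @export
agreement_summary <- function(x_ref, x_pred) {
  are <- relative_error(x_ref, x_pred)
  sre <- relative_error(x_ref, x_pred, signed = TRUE)
  ok <- !is.na(are)
  cc <- is.finite(x_ref) & is.finite(x_pred)
  r <- if (sum(cc) >= 2 && sd(x_ref[cc]) > 0 && sd(x_pred[cc]) > 0) {
    cor(x_ref[cc], x_pred[cc])
  } else {
    NA_real_
  }
  structure(
    list(are = are,
         mare = if (any(ok)) median(are[ok]) else NA_real_,
         mre = if (any(ok)) mean(sre[ok]) else NA_real_,
         r = r,
         n = sum(ok)),
    class = "agreement_metrics"
  )
}

#' Ordinary least products (type II) calibration
#'
#' Fits the geometric-mean (reduced major axis) regression of reference
#' values on raw predicted values: slope = sign(r) * sd(y)/sd(x), intercept =
#' mean(y) - slope * mean(x). Symmetric in x and y up to inversion. Used to
#' adapt raw automatic measures to the reference scale; inside LOSO the fit
#' uses training-fold children only.
#'
#' @param x raw predicted values (training children).
#' @param y reference values (training children).
#' @param measure optional measure name stored in the model.
#' @return list of class \code{olp_model} with \code{slope}, \code{intercept},
#'   \code{n}, \code{measure}. With fewer than 3 complete pairs an error; with
#'   degenerate variance an identity calibration with a warning.
#' @export
olp_fit <- function(x, y, measure = NA_character_) {
  cc <- is.finite(x) & is.finite(y)
  x <- x[cc]
  y <- y[cc]
  if (length(x) < 3) stop("olp_fit needs at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    warning("degenerate variance in OLP fit; using identity calibration",
            call. = FALSE)
    return(structure(list(slope = 1, intercept = 0, n = length(x),
                          measure = measure), class = "olp_model"))
  }
  r <- cor(x, y)
  s <- if (is.na(r) || r == 0) 1 else sign(r)
  slope <- s * sd(y) / sd(x)
  structure(
    list(slope = slope, intercept = mean(y) - slope * mean(x),
         n = length(x), measure = measure),
    class = "olp_model"
  )
}

#' Apply an OLP calibration model to raw values
#' @param model an \code{olp_model} from \code{\link{olp_fit}}.
#' @param raw numeric vector of raw predicted values.
#' @export
olp_apply <- function(model, raw) {
  model$intercept + model$slope * raw
}

#' Leave-one-subject-out evaluation of measures with OLP adaptation
#'
#' For each speaker class and measure, computes per-child absolute relative
#' errors of the raw automatic values against reference values, then adapts
#' each held-out child's raw value with an OLP model fitted on the remaining
#' children, and summarizes both raw and adapted results (mARE, MRE, Pearson
#' r).
#'
#' @param raw,ref data frames with columns \code{child_id}, \code{speaker},
#'   and one column per measure; rows keyed by (child_id, speaker).
#' @param measures character vector of measure column names (default the five
#'   CDS measures).
#' @return list with \code{report} (one row per speaker x measure x
#'   adaptation: \code{mare}, \code{mre}, \code{r}, \code{n},
#'   \code{olp_slope}), \code{per_child} (raw, adapted and reference values
#'   with per-child ARE) and \code{models} (per speaker/measure/fold OLP
#'   models, for leakage auditing).
#' @export
loso_measure_eval <- function(raw, ref,
                              measures = c("tnu", "tnw", "ndw", "mlu", "ttr")) {
  key <- function(d) paste(d$child_id, d$speaker, sep = "\r")
  ref_idx <- match(key(raw), key(ref))
  if (anyNA(ref_idx)) stop("every (child_id, speaker) in raw needs a reference row")
  report <- NULL
  per_child <- NULL
  models <- list()
  for (sp in unique(raw$speaker)) {
    sel <- raw$speaker == sp
    children <- raw$child_id[sel]
    for (m in measures) {
      x <- raw[[m]][sel]
      y <- ref[[m]][ref_idx[sel]]
      usable <- is.finite(x) & is.finite(y)
      if (sum(usable) < 3) {
        message(sprintf("skipping %s/%s: fewer than 3 usable children", sp, m))
        next
      }
      adapted <- rep(NA_real_, length(x))
      fold_models <- vector("list", length(x))
      for (j in seq_along(x)) {
        tr <- usable
        tr[j] <- FALSE
        if (sum(tr) < 3 || !usable[j]) next
        mod <- olp_fit(x[tr], y[tr], measure = m)
        fold_models[[j]] <- mod
        adapted[j] <- olp_apply(mod, x[j])
      }
      names(fold_models) <- children
      models[[paste(sp, m, sep = ".")]] <- fold_models
      raw_sum <- agreement_summary(y, x)
      ad_sum <- agreement_summary(y, adapted)
      slopes <- vapply(fold_models,
                       function(f) if (is.null(f)) NA_real_ else f$slope,
                       numeric(1))
      report <- rbind(report, data.frame(
        speaker = sp, measure = m,
        adaptation = c("raw", "adapted"),
        mare = c(raw_sum$mare, ad_sum$mare),
        mre = c(raw_sum$mre, ad_sum$mre),
        r = c(raw_sum$r, ad_sum$r),
        n = c(raw_sum$n, ad_sum$n),
        olp_slope = c(NA_real_, mean(slopes, na.rm = TRUE))
      ))
      per_child <- rbind(per_child, data.frame(
        child_id = children, speaker = sp, measure = m,
        reference = y, raw = x, adapted = adapted,
        are_raw = raw_sum$are, are_adapted = ad_sum$are
      ))
    }
  }
  rownames(report) <- NULL
  list(report = report, per_child = per_child, models = models)
}
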