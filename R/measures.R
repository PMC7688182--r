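# Transcript measures: tokenization with contraction expansion, the five CDS
# measures (TNU, TNW, NDW, MLU, TTR), and interaction measures, with optional
# norming of count measures to a 10-minute basis.

# Irregular contractions expanded as whole tokens, following the transcript
# convention of splitting contractions before counting words.
.contraction_table <- c(
  "won't"   = "will not",
  "can't"   = "can not",
  "cannot"  = "can not",
  "shan't"  = "shall not",
  "ain't"   = "is not",
  "let's"   = "let us",
  "gonna"   = "going to",
  "wanna"   = "want to",
  "gotta"   = "got to",
  "y'all"   = "you all",
  "it's"    = "it is",
  "that's"  = "that is",
  "what's"  = "what is",
  "who's"   = "who is",
  "there's" = "there is",
  "here's"  = "here is",
  "he's"    = "he is",
  "she's"   = "she is",
  "where's" = "where is",
  "how's"   = "how is"
)

#' The contraction table used by the tokenizer
#'
#' Irregular forms are listed explicitly; regular suffixes (n't, 're, 've,
#' 'll, 'm, 'd) are expanded by rule. A trailing \code{'s} not covered by the
#' irregular table is treated as a possessive and stripped.
#' @return named character vector mapping contraction to expansion.
#' @export
contraction_table <- function() .contraction_table

expand_token <- function(tok) {
  hit <- .contraction_table[tok]
  if (!is.na(hit)) {
    return(strsplit(hit, " ", fixed = TRUE)[[1]])
  }
  if (grepl("n't$", tok)) {
    return(c(sub("n't$", "", tok), "not"))
  }
  if (grepl("'re$", tok)) return(c(sub("'re$", "", tok), "are"))
  if (grepl("'ve$", tok)) return(c(sub("'ve$", "", tok), "have"))
  if (grepl("'ll$", tok)) return(c(sub("'ll$", "", tok), "will"))
  if (grepl("'m$", tok))  return(c(sub("'m$", "", tok), "am"))
  if (grepl("'d$", tok))  return(c(sub("'d$", "", tok), "would"))
  if (grepl("'s$", tok))  return(sub("'s$", "", tok))  # possessive
  gsub("'", "", tok)
}

#' Tokenize an utterance for word counting
#'
#' Lowercases, strips punctuation, and expands language contractions (e.g.
#' "you're" to "you are") so that automatic word counts are comparable with
#' manual transcription conventions.
#'
#' @param text a character string (one utterance).
#' @return character vector of tokens; empty vector for empty or
#'   whitespace-only input.
#' @examples
#' tokenize_utterance("You're going home.")  # "you" "are" "going" "home"
#' @export
tokenize_utterance <- function(text) {
  if (length(text) != 1 || is.na(text)) stop("text must be a single string")
  x <- tolower(text)
  x <- gsub("[‘’‛]", "'", x)
  raw <- strsplit(x, "[^a-z0-9']+")[[1]]
  raw <- raw[nzchar(raw)]
  raw <- gsub("^'+|'+$", "", raw)
  raw <- raw[nzchar(raw)]
  if (length(raw) == 0) return(character(0))
  out <- unlist(lapply(raw, expand_token), use.names = FALSE)
  out[nzchar(out)]
}

utterance_token_list <- function(utterances) {
  if (!is.null(utterances$tokens)) {
    return(utterances$tokens)
  }
  if (!is.null(utterances$text)) {
    return(lapply(utterances$text, tokenize_utterance))
  }
  stop("utterances must carry a 'tokens' list column or a 'text' column")
}

#' Child-directed speech measures for one partner class
#'
#' Computes total number of utterances (TNU), total number of words (TNW),
#' number of different words (NDW), mean length of utterance (MLU = TNW/TNU)
#' and type-token ratio (TTR = NDW/TNW). MLU and TTR are always computed from
#' raw counts; when \code{norm} is TRUE the three count measures are scaled
#' by \code{10 / recording_minutes} to a per-10-minute basis.
#'
#' @param utterances data frame of utterances (one class), with a
#'   \code{tokens} list column or a \code{text} column.
#' @param recording_minutes employed recording time in minutes (> 0).
#' @param norm norm count measures by 10 minutes (default TRUE).
#' @return object of class \code{measure_set}: list with \code{tnu},
#'   \code{tnw}, \code{ndw}, \code{mlu}, \code{ttr}, \code{recording_minutes},
#'   \code{normed}. With zero utterances the counts are 0 and MLU/TTR are NA.
#' @export
cds_measures <- function(utterances, recording_minutes, norm = TRUE) {
  if (!is.numeric(recording_minutes) || recording_minutes <= 0) {
    stop("recording_minutes must be > 0")
  }
  n_utt <- if (is.null(utterances)) 0L else nrow(utterances)
  if (n_utt == 0) {
    return(structure(
      list(tnu = 0, tnw = 0, ndw = 0, mlu = NA_real_, ttr = NA_real_,
           recording_minutes = recording_minutes, normed = norm),
      class = "measure_set"
    ))
  }
  toks <- utterance_token_list(utterances)
  if (any(lengths(toks) == 0)) stop("utterances must have non-empty tokens")
  all_tok <- unlist(toks, use.names = FALSE)
  tnu <- n_utt
  tnw <- length(all_tok)
  ndw <- length(unique(all_tok))
  scale <- if (norm) 10 / recording_minutes else 1
  structure(
    list(
      tnu = tnu * scale,
      tnw = tnw * scale,
      ndw = ndw * scale,
      mlu = tnw / tnu,
      ttr = ndw / tnw,
      recording_minutes = recording_minutes,
      normed = norm
    ),
    class = "measure_set"
  )
}

#' @export
print.measure_set <- function(x, ...) {
  cat(sprintf(
    "<measure_set%s> TNU=%.3g TNW=%.3g NDW=%.3g MLU=%.3g TTR=%.3g (%.3g min)\n",
    if (x$normed) " per 10 min" else "",
    x$tnu, x$tnw, x$ndw, x$mlu, x$ttr, x$recording_minutes))
  invisible(x)
}

#' @export
as.data.frame.measure_set <- function(x, ...) {
  data.frame(tnu = x$tnu, tnw = x$tnw, ndw = x$ndw, mlu = x$mlu,
             ttr = x$ttr, recording_minutes = x$recording_minutes,
             normed = x$normed)
}

#' Interaction measures for one partner class
#'
#' Interaction frequency (normed by 10 minutes when requested), median and
#' standard deviation of interaction duration, and total duration of
#' interactions (TDI). Durations are in seconds and are never normed (they
#' are lengths, not counts).
#'
#' @param track an \code{interval_track}.
#' @inheritParams cds_measures
#' @return list of class \code{interaction_measures} with \code{frequency},
#'   \code{median_dur}, \code{sd_dur}, \code{total_dur}, seconds-based;
#'   empty track gives frequency 0, NA median/sd, total 0.
#' @export
interaction_measures <- function(track, recording_minutes, norm = TRUE) {
  if (!is.numeric(recording_minutes) || recording_minutes <= 0) {
    stop("recording_minutes must be > 0")
  }
  iv <- track_intervals(track)
  scale <- if (norm) 10 / recording_minutes else 1
  if (nrow(iv) == 0) {
    return(structure(
      list(frequency = 0, median_dur = NA_real_, sd_dur = NA_real_,
           total_dur = 0, recording_minutes = recording_minutes,
           normed = norm),
      class = "interaction_measures"
    ))
  }
  dur_s <- (iv$offset - iv$onset) / 1000
  structure(
    list(
      frequency = nrow(iv) * scale,
      median_dur = median(dur_s),
      sd_dur = if (length(dur_s) == 1) 0 else sd(dur_s),
      total_dur = sum(dur_s),
      recording_minutes = recording_minutes,
      normed = norm
    ),
    class = "interaction_measures"
  )
}
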