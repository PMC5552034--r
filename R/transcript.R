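#' Transcripts
#'
#' A transcript is a pre-tokenized utterance: an ordered character vector of
#' tokens plus the speaking duration in seconds. Tokenization (for Japanese,
#' morphological analysis) happens upstream; the package consumes tokens as
#' given.
#'
#' @param tokens Character vector (may be empty).
#' @param duration_s Duration in seconds, > 0.
#' @param lang BCP-47 language tag (default `"ja"`).
#' @return An object of class `transcript`.
#' @export
transcript <- function(tokens, duration_s, lang = "ja") {
  if (!is.character(tokens)) abort("tokens must be a character vector")
  if (!is.numeric(duration_s) || length(duration_s) != 1 || duration_s <= 0) {
    abort("duration_s must be a single positive number")
  }
  structure(list(tokens = tokens, duration_s = duration_s, lang = lang),
            class = "transcript")
}

#' @export
print.transcript <- function(x, ...) {
  cat(sprintf("<transcript> %d tokens over %.1f s [%s]\n",
              length(x$tokens), x$duration_s, x$lang))
  invisible(x)
}

#' Read a transcript from JSON or plain text
#'
#' JSON form: `{"tokens": [...], "duration_s": float, "lang": "ja"}`.
#' Plain-text form: whitespace-tokenized file plus an explicit `duration_s`.
#'
#' @param path File path.
#' @param duration_s Required for plain text; ignored for JSON.
#' @param lang Language tag for plain text.
#' @return A [transcript()].
#' @export
read_transcript <- function(path, duration_s = NULL, lang = "ja") {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    transcript(as.character(obj$tokens), obj$duration_s, obj$lang %||% lang)
  } else {
    if (is.null(duration_s)) abort("plain-text transcripts need `duration_s`")
    txt <- paste(readLines(path, warn = FALSE, encoding = "UTF-8"), collapse = " ")
    tokens <- strsplit(trimws(txt), "\\s+")[[1]]
    tokens <- tokens[nzchar(tokens)]
    transcript(tokens, duration_s, lang)
  }
}

#' Speaking rate in words per minute
#'
#' @param tr A [transcript()].
#' @return `60 * length(tokens) / duration_s`.
#' @export
words_per_minute <- function(tr) {
  stopifnot(inherits(tr, "transcript"))
  60 * length(tr$tokens) / tr$duration_s
}

#' Count of words longer than a character threshold
#'
#' A token counts when its character length is strictly greater than
#' `threshold` ("words over six letters" with the default 6). For Japanese
#' input the character count is over the tokens as delivered by the
#' tokenizer.
#'
#' @param tr A [transcript()].
#' @param threshold Positive integer, default 6.
#' @return Integer count.
#' @export
long_word_count <- function(tr, threshold = 6) {
  stopifnot(inherits(tr, "transcript"))
  if (threshold < 1) abort("threshold must be >= 1")
  sum(nchar(tr$tokens, type = "chars") > threshold)
}

#' Default Japanese filler lexicon
#'
#' Common lexicalized hesitation tokens (romanized). Fully replaceable:
#' pass any character vector to [filler_count()].
#' @return Character vector.
#' @export
default_filler_lexicon <- function() {
  c("eto", "etto", "eeto", "ano", "anou", "maa", "nanka", "sono", "un", "uun")
}

#' Count filler tokens
#'
#' Number of tokens exactly matching a lexicon entry after normalization
#' (lower-casing and whitespace trimming by default). Repeated occurrences
#' all count.
#'
#' @param tr A [transcript()].
#' @param lexicon Non-empty character vector of filler forms.
#' @param normalize Function applied to both tokens and lexicon before
#'   matching.
#' @return Integer count.
#' @export
filler_count <- function(tr, lexicon = default_filler_lexicon(),
                         normalize = function(x) tolower(trimws(x))) {
  stopifnot(inherits(tr, "transcript"))
  if (length(lexicon) == 0) abort("filler lexicon must be non-empty")
  sum(normalize(tr$tokens) %in% normalize(lexicon))
}

#' Extract the linguistic narrative features from a transcript
#'
#' @param tr A [transcript()].
#' @param long_word_threshold See [long_word_count()].
#' @param lexicon See [filler_count()].
#' @return A one-row tibble: `words_per_minute`, `long_word_count`,
#'   `filler_count`.
#' @export
extract_linguistic <- function(tr, long_word_threshold = 6,
                               lexicon = default_filler_lexicon()) {
  tibble::tibble(
    words_per_minute = words_per_minute(tr),
    long_word_count = long_word_count(tr, long_word_threshold),
    filler_count = filler_count(tr, lexicon)
  )
}
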