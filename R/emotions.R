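#' Canonical emotion vocabulary
#'
#' The package works over a fixed eight-way-minus-one codomain: the seven
#' labels used throughout — the six Ekman universal emotions with anger and
#' contempt merged into a single `angry` class, plus a `neutral` class.
#' Every label entering the system (rater vocabulary, provider score keys,
#' prompt emotions) is canonicalized onto this set or discarded.
#'
#' @return Character vector of the 7 canonical emotion labels, in the fixed
#'   display order used for confusion matrices and reports.
#' @export
#' @examples
#' emotion_levels()
emotion_levels <- function() {
  c("neutral", "happy", "sad", "surprised", "scared", "disgusted", "angry")
}

#' Sentinel for labels that are dropped on canonicalization
#'
#' Vocabulary terms mapped to `DISCARD` (e.g. `confusion`, which not every
#' classifier supports and for which no prompts exist) are treated as absent
#' labels: annotations become unlabeled, provider score keys are dropped.
#'
#' @format A length-one character constant.
#' @export
DISCARD <- "__discard__"

#' Default label mapping
#'
#' Maps rater/provider vocabulary onto the canonical emotion set. Contains
#' the identity on the 7 canonical values plus the merges the curation
#' protocol prescribes: `anger` and `contempt` collapse into `angry`,
#' `calm` is read as `neutral`, and `confusion` is discarded. Common
#' provider spellings (`happiness`, `sadness`, `surprise`, `fear`,
#' `disgust`) are included so the same mapping serves raters and dialects.
#'
#' @return Named character vector: names are vocabulary terms (lower case),
#'   values are canonical labels or [DISCARD].
#' @export
#' @examples
#' default_label_map()[["contempt"]]
default_label_map <- function() {
  canon <- emotion_levels()
  c(
    stats::setNames(canon, canon),
    anger     = "angry",
    contempt  = "angry",
    calm      = "neutral",
    confusion = DISCARD,
    confused  = DISCARD,
    happiness = "happy",
    sadness   = "sad",
    surprise  = "surprised",
    fear      = "scared",
    afraid    = "scared",
    disgust   = "disgusted"
  )
}

#' Canonicalize emotion labels
#'
#' Applies a vocabulary mapping to a character vector of raw labels.
#' Matching is case-insensitive and whitespace-trimmed. Empty strings and
#' `NA` pass through as `NA` (an absent label); terms mapped to [DISCARD]
#' also become `NA`. Canonicalization is idempotent: applying it twice is
#' the same as applying it once.
#'
#' @param x Character vector of raw labels.
#' @param mapping Named character vector as from [default_label_map()].
#' @param on_unknown One of `"error"` (default), `"na"`, or `"warn"`:
#'   what to do with a term absent from the mapping. `"warn"` drops the
#'   term to `NA` with a warning.
#' @return Character vector of canonical labels, `NA` where absent/discarded.
#' @export
#' @examples
#' canonicalize_labels(c("Contempt", "happy", "", "confusion"))
canonicalize_labels <- function(x, mapping = default_label_map(),
                                on_unknown = c("error", "na", "warn")) {
  on_unknown <- match.arg(on_unknown)
  stopifnot(is.character(mapping), !is.null(names(mapping)))
  key <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(key))
  absent <- is.na(key) | key == ""
  hit <- !absent & key %in% names(mapping)
  out[hit] <- unname(mapping[key[hit]])
  unknown <- !absent & !hit
  if (any(unknown)) {
    terms <- unique(key[unknown])
    msg <- paste0("unknown emotion label(s): ", paste(terms, collapse = ", "))
    if (on_unknown == "error") stop(msg, call. = FALSE)
    if (on_unknown == "warn") warning(msg, call. = FALSE)
  }
  out[out == DISCARD] <- NA_character_
  bad <- !is.na(out) & !out %in% emotion_levels()
  if (any(bad)) {
    stop("mapping targets outside the canonical emotion set: ",
         paste(unique(out[bad]), collapse = ", "), call. = FALSE)
  }
  out
}

assert_emotion <- function(emotion) {
  if (!(is.character(emotion) && length(emotion) == 1L &&
        emotion %in% emotion_levels())) {
    stop("`emotion` must be one of: ", paste(emotion_levels(), collapse = ", "),
         call. = FALSE)
  }
  invisible(emotion)
}
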