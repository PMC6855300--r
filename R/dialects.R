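#' @name dialects
#' @title Provider score dialects
#'
#' @description
#' Commercial emotion classifiers return per-emotion confidence scores in
#' provider-specific shapes: different emotion vocabularies and different
#' score scales (0–1 or 0–100). A *dialect* declares, for one provider, the
#' maximum of its score scale and the vocabulary mapping onto the canonical
#' emotion set. Readers normalize every dialect to scores in \[0, 1\] over
#' canonical labels, so downstream code never sees provider quirks.
#'
#' Built-in dialects:
#' \describe{
#'   \item{`azure`}{0–1 scale; keys such as `happiness`, `sadness`, `anger`,
#'     `contempt`, `surprise`, `fear`, `disgust`, `neutral`.}
#'   \item{`sighthound`}{0–100 scale, same key family.}
#'   \item{`rekognition`}{0–100 scale; upper-case keys (`HAPPY`, `CALM`,
#'     `CONFUSED`, ...). `CALM` maps to neutral; `CONFUSED` is discarded.}
#'   \item{`unit`}{generic 0–1 scale with canonical keys (used by the
#'     synthetic generator).}
#'   \item{`percent`}{generic 0–100 scale with canonical keys.}
#' }
#'
#' Keys the mapping does not know are dropped with a warning, not an error:
#' provider APIs add categories over time. Keys that map to the same
#' canonical label (e.g. `anger` and `contempt`) have their scores summed
#' and capped at 1, treating them as probabilities of a union event.
NULL

.dialect_registry <- new.env(parent = emptyenv())

#' Register a provider score dialect
#'
#' @param name Dialect name (string).
#' @param scale_max Declared maximum of the provider's score scale
#'   (typically 1 or 100); scores are divided by this on read and any score
#'   outside \[0, scale_max\] is an error.
#' @param emotion_map Named character vector mapping provider emotion keys
#'   (lower-cased on lookup) to canonical labels or [DISCARD].
#' @return The dialect definition, invisibly.
#' @export
register_dialect <- function(name, scale_max, emotion_map = default_label_map()) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  stopifnot(is.numeric(scale_max), length(scale_max) == 1L, scale_max > 0)
  d <- list(name = name, scale_max = as.numeric(scale_max),
            emotion_map = emotion_map)
  assign(name, d, envir = .dialect_registry)
  invisible(d)
}

#' Look up a registered dialect
#'
#' @param name Dialect name.
#' @return A list with `name`, `scale_max`, `emotion_map`.
#' @export
get_dialect <- function(name) {
  if (!exists(name, envir = .dialect_registry, inherits = FALSE)) {
    stop("unknown provider dialect: ", name,
         " (registered: ", paste(list_dialects(), collapse = ", "), ")",
         call. = FALSE)
  }
  get(name, envir = .dialect_registry, inherits = FALSE)
}

#' @rdname get_dialect
#' @export
list_dialects <- function() sort(ls(envir = .dialect_registry))

register_builtin_dialects <- function() {
  register_dialect("unit", 1)
  register_dialect("percent", 100)
  register_dialect("azure", 1)
  register_dialect("sighthound", 100)
  register_dialect("rekognition", 100)
}
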