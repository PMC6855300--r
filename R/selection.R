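#' Frame sets
#'
#' A *frame set* is a tibble of retained frames for one target emotion,
#' carrying a provenance attribute that records which filters produced it:
#' the target emotion, the sub-bound trim (`alpha`, `beta`), the confidence
#' threshold (`lambda`), the fusion method and provider set if scores were
#' fused. Selection functions return frame sets; [write_frameset()]
#' serializes provenance alongside the rows.
#'
#' @param x Tibble of frames (`session_id`, `frame_id`, `timestamp`,
#'   `region_index`, optionally `true_label`).
#' @param provenance Named list of filter provenance.
#' @return A `frame_set` (tibble subclass).
#' @keywords internal
#' @export
new_frame_set <- function(x, provenance = list()) {
  out <- tibble::as_tibble(x)
  attr(out, "provenance") <- provenance
  class(out) <- c("frame_set", class(out))
  out
}

#' @rdname new_frame_set
#' @param fs A frame set.
#' @export
frameset_provenance <- function(fs) attr(fs, "provenance") %||% list()

#' Select frames inside matching prompt regions
#'
#' Boundary selection: retain every frame lying inside a region whose prompt
#' emotion equals the target label. Intervals are left-closed/right-open
#' (`t_start <= t < t_end`), so a frame at a shared boundary belongs to
#' exactly one region — the prompt that is on screen at that instant.
#' Equivalent to [frames_in_subbound()] with `alpha = beta = 0`.
#'
#' @param meta Session meta tibble (one or more sessions pooled).
#' @param frames Frame tibble (`session_id`, `frame_id`, `timestamp`,
#'   optionally `true_label`).
#' @param emotion Target canonical emotion label.
#' @return A `frame_set`; empty (zero rows) when no region matches.
#' @export
frames_in_region <- function(meta, frames, emotion) {
  frames_in_subbound(meta, frames, emotion, alpha = 0, beta = 0)
}

#' Select frames inside trimmed sub-bounds
#'
#' Sub-bound selection: within each matching region, crop `alpha` seconds at
#' the start (the child's interpretation lag after a prompt change) and
#' `beta` seconds at the end (the trailing period when the face relaxes or
#' leaves the frame as the phone is tilted). A frame is retained when
#' `t_start + alpha <= t < t_end - beta`. A region whose trimmed interval is
#' empty contributes no frames; that is not an error.
#'
#' @inheritParams frames_in_region
#' @param alpha,beta Leading/trailing crop in seconds, `>= 0`.
#' @return A `frame_set` with provenance `(emotion, alpha, beta)`.
#' @export
frames_in_subbound <- function(meta, frames, emotion, alpha, beta) {
  assert_emotion(emotion)
  if (!is.numeric(alpha) || !is.numeric(beta) || alpha < 0 || beta < 0) {
    stop("`alpha` and `beta` must be non-negative seconds", call. = FALSE)
  }
  regions <- dplyr::filter(meta, .data$emotion == !!emotion)
  cols <- intersect(c("session_id", "frame_id", "timestamp", "true_label"),
                    names(frames))
  if (nrow(regions) == 0L) {
    out <- dplyr::mutate(frames[0, cols, drop = FALSE],
                         region_index = integer())
  } else {
    out <- frames[cols] |>
      dplyr::inner_join(
        dplyr::select(regions, "session_id", "region_index",
                      "t_start_s", "t_end_s"),
        by = "session_id", relationship = "many-to-many") |>
      dplyr::filter(.data$timestamp >= .data$t_start_s + alpha,
                    .data$timestamp < .data$t_end_s - beta) |>
      dplyr::select(-"t_start_s", -"t_end_s") |>
      dplyr::arrange(.data$session_id, .data$timestamp)
  }
  new_frame_set(out, provenance = list(emotion = emotion, alpha = alpha,
                                       beta = beta, lambda = 0,
                                       fusion = NULL, providers = NULL))
}

#' Fuse provider confidence scores
#'
#' Combines per-emotion confidence scores from several classifiers into one
#' score per frame, before thresholding. Only providers that returned a
#' score vector for the frame participate; a provider's vector that lacks
#' the target emotion contributes a score of 0 for it. Frames for which no
#' provider returned a vector are absent from the result. Methods:
#' `min` (suits classifiers tuned for high recall), `max` (high precision),
#' `average` (smooths provider biases without characterizing them).
#'
#' @param scores Long score tibble (`frame_id`, `provider`, `emotion`,
#'   `score`), as from [read_provider_scores()] or [simulate_scores()].
#' @param emotion Target canonical emotion.
#' @param method One of `"average"`, `"min"`, `"max"`.
#' @return Tibble `frame_id`, `score` — the fused score in \[0, 1\].
#' @export
fuse_scores <- function(scores, emotion, method = c("average", "min", "max")) {
  assert_emotion(emotion)
  method <- match.arg(method)
  fun <- switch(method, average = mean, min = min, max = max)
  scores |>
    dplyr::group_by(.data$frame_id, .data$provider) |>
    dplyr::summarise(
      score = sum(.data$score[.data$emotion == !!emotion]),
      .groups = "drop") |>
    dplyr::group_by(.data$frame_id) |>
    dplyr::summarise(score = fun(.data$score), .groups = "drop")
}

#' Filter a frame set by minimum classifier confidence
#'
#' Retains frames whose (fused or single-provider) confidence for the frame
#' set's target emotion strictly exceeds `lambda`. `lambda = 0` means no
#' filtering: the input set passes through unchanged, including frames with
#' no score at all. For `lambda > 0`, unscored frames are dropped — absence
#' of a score (no face found) cannot exceed a positive threshold.
#'
#' @param fs A `frame_set`.
#' @param frame_scores Tibble `frame_id`, `score` (e.g. from
#'   [fuse_scores()]); frames missing from it are treated as unscored.
#' @param lambda Threshold in \[0, 1\].
#' @param fusion Optional fusion-method string recorded in provenance.
#' @return A `frame_set` (subset of `fs`) with `lambda` (and `fusion`)
#'   recorded in provenance.
#' @export
confidence_filter <- function(fs, frame_scores, lambda, fusion = NULL) {
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda < 0 || lambda > 1) {
    stop("`lambda` must be a number in [0, 1]", call. = FALSE)
  }
  prov <- frameset_provenance(fs)
  prov$lambda <- lambda
  if (!is.null(fusion)) prov$fusion <- fusion
  if (lambda == 0) {
    return(new_frame_set(fs, provenance = prov))
  }
  sc <- frame_scores$score[match(fs$frame_id, frame_scores$frame_id)]
  keep <- !is.na(sc) & sc > lambda
  new_frame_set(fs[keep, , drop = FALSE], provenance = prov)
}

#' Density of a frame set
#'
#' Fraction of retained ground-truth frames whose true label matches the
#' target emotion — the quantity the trims and thresholds are tuned to
#' raise. Frames without ground truth are excluded from both numerator and
#' denominator.
#'
#' @param fs A `frame_set` whose rows carry `true_label`.
#' @param emotion Target emotion; defaults to the set's provenance emotion.
#' @return One-row tibble `emotion`, `retained`, `matching`, `density`
#'   (`density` is `NA` when no ground-truth frame is retained).
#' @export
frameset_density <- function(fs, emotion = NULL) {
  emotion <- emotion %||% frameset_provenance(fs)$emotion
  assert_emotion(emotion)
  truth <- fs$true_label[!is.na(fs$true_label)]
  n <- length(truth)
  m <- sum(truth == emotion)
  tibble::tibble(emotion = emotion, retained = n, matching = m,
                 density = if (n > 0) m / n else NA_real_)
}
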