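# In-code fixture builders shared across test files.

# A single-session region table. `spec` is a list of c(t_start, t_end)
# intervals with an emotion each, e.g. list(happy = c(0, 4), sad = c(4, 7)).
make_meta <- function(spec, session_id = "s1", duration = NULL, fps = 5) {
  starts <- unname(vapply(spec, `[[`, numeric(1), 1))
  ends <- unname(vapply(spec, `[[`, numeric(1), 2))
  tibble::tibble(
    session_id = session_id,
    duration_s = duration %||% max(ends),
    fps = fps,
    region_index = seq_along(spec),
    emotion = names(spec),
    t_start_s = starts,
    t_end_s = ends,
    point_awarded = NA
  )
}

# Frames on the i/fps grid of a session, optionally with truth labels.
make_frames <- function(meta, true_label = NA_character_) {
  fr <- session_frames(meta)
  fr$true_label <- rep_len(true_label, nrow(fr))
  fr
}

# Frames with truth assigned from the region structure: frames whose
# region-relative offset is below `lag` or within `decay` of the end get
# `junk_label`; interior frames get the region's emotion.
make_labeled_frames <- function(meta, lag = 0, decay = 0,
                                junk_label = "neutral") {
  fr <- session_frames(meta)
  idx <- findInterval(fr$timestamp, meta$t_start_s)
  ok <- idx >= 1 & fr$timestamp < meta$t_end_s[pmax(idx, 1)]
  lab <- rep(NA_character_, nrow(fr))
  off_s <- fr$timestamp - meta$t_start_s[pmax(idx, 1)]
  off_e <- meta$t_end_s[pmax(idx, 1)] - fr$timestamp
  lab[ok] <- ifelse(off_s[ok] < lag | off_e[ok] <= decay,
                    junk_label, meta$emotion[idx[ok]])
  fr$true_label <- lab
  fr
}

# Annotation table from per-frame label pairs: a named list
# frame_id -> c(rater1_label, rater2_label); NA for an absent label.
make_annotations <- function(pairs, raters = c("r1", "r2")) {
  tibble::tibble(
    frame_id = rep(names(pairs), each = 2),
    rater_id = rep(raters, length(pairs)),
    label = unlist(pairs, use.names = FALSE)
  )
}

# Long score table from a named list frame_id -> named score vector,
# replicated for each provider (or a list provider -> such a list).
make_scores <- function(by_frame, provider = "p1") {
  purrr::imap_dfr(by_frame, function(sc, fid) {
    tibble::tibble(frame_id = fid, provider = provider,
                   emotion = names(sc), score = unname(sc))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Config for the "stated world" recovery experiments: onset lag 0.6 s,
# trailing decay 1.0 s, near-perfect interior expression, no invalid frames.
recovery_config <- function(...) {
  simulation_config(onset_lag = 0.6, decay = 1.0, p_express = 1,
                    p_invalid = 0, ...)
}
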