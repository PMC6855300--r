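#' Read session meta-information
#'
#' A game session's meta file records how the recording is delimited into
#' prompt regions: for each region, the target emotion of the prompt shown,
#' its start/end time in seconds from session start, and whether a point was
#' awarded. The schema is a JSON document:
#'
#' ```
#' {"session_id": "s1", "duration_s": 90, "fps": 5,
#'  "regions": [{"index": 1, "emotion": "happy",
#'               "t_start_s": 0, "t_end_s": 4.2, "point_awarded": true}, ...]}
#' ```
#'
#' Region emotions are canonicalized (so `contempt` becomes `angry`);
#' regions are sorted by start time and validated: positive fps, every
#' interval inside `[0, duration]`, `t_start < t_end`, no overlaps.
#'
#' @param path Path to a session meta JSON file.
#' @param mapping Label mapping for region emotions; see [default_label_map()].
#' @return A tibble with one row per region and columns `session_id`,
#'   `duration_s`, `fps`, `region_index`, `emotion`, `t_start_s`, `t_end_s`,
#'   `point_awarded`. Multiple sessions can be pooled with
#'   [dplyr::bind_rows()]; every function in the package accepts the pooled
#'   form.
#' @export
read_session_meta <- function(path, mapping = default_label_map()) {
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  req <- c("session_id", "duration_s", "fps", "regions")
  if (!all(req %in% names(doc))) {
    stop("session meta is missing field(s): ",
         paste(setdiff(req, names(doc)), collapse = ", "), call. = FALSE)
  }
  regions <- tibble::as_tibble(doc$regions)
  req_r <- c("index", "emotion", "t_start_s", "t_end_s")
  if (!all(req_r %in% names(regions))) {
    stop("session meta regions are missing field(s): ",
         paste(setdiff(req_r, names(regions)), collapse = ", "), call. = FALSE)
  }
  if (!"point_awarded" %in% names(regions)) regions$point_awarded <- NA
  meta <- tibble::tibble(
    session_id = as.character(doc$session_id),
    duration_s = as.numeric(doc$duration_s),
    fps = as.numeric(doc$fps),
    region_index = as.integer(regions$index),
    emotion = canonicalize_labels(regions$emotion, mapping),
    t_start_s = as.numeric(regions$t_start_s),
    t_end_s = as.numeric(regions$t_end_s),
    point_awarded = as.logical(regions$point_awarded)
  )
  if (any(is.na(meta$emotion))) {
    stop("session meta contains regions with discarded/absent emotions",
         call. = FALSE)
  }
  validate_session_meta(meta)
}

validate_session_meta <- function(meta) {
  stopifnot(is.data.frame(meta))
  meta <- dplyr::arrange(meta, .data$session_id, .data$t_start_s)
  by_sess <- split(meta, meta$session_id)
  for (m in by_sess) {
    sid <- m$session_id[[1]]
    if (any(m$fps <= 0) || any(m$duration_s <= 0)) {
      stop("session ", sid, ": fps and duration must be positive", call. = FALSE)
    }
    if (any(m$t_start_s >= m$t_end_s)) {
      stop("session ", sid, ": every region needs t_start < t_end", call. = FALSE)
    }
    if (any(m$t_start_s < 0) || any(m$t_end_s > m$duration_s[[1]] + 1e-9)) {
      stop("session ", sid, ": regions must lie within [0, duration]",
           call. = FALSE)
    }
    if (nrow(m) > 1L && any(m$t_start_s[-1] < m$t_end_s[-nrow(m)] - 1e-9)) {
      stop("session ", sid, ": regions overlap", call. = FALSE)
    }
  }
  meta
}

#' Write session meta-information
#'
#' Inverse of [read_session_meta()]; one session per file.
#'
#' @param meta Session meta tibble for a single session.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_session_meta <- function(meta, path) {
  stopifnot(length(unique(meta$session_id)) == 1L)
  doc <- list(
    session_id = meta$session_id[[1]],
    duration_s = meta$duration_s[[1]],
    fps = meta$fps[[1]],
    regions = lapply(seq_len(nrow(meta)), function(i) {
      list(index = meta$region_index[[i]], emotion = meta$emotion[[i]],
           t_start_s = meta$t_start_s[[i]], t_end_s = meta$t_end_s[[i]],
           point_awarded = meta$point_awarded[[i]])
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Enumerate the frame grid of a session
#'
#' Frame `i` of a session sits at time `i / fps`, 0-based, for
#' `floor(duration * fps)` frames — the subsampled representation of the
#' recording (default sessions: 90 s at 5 frames/s, 450 frames).
#'
#' @param meta Session meta tibble (one or more sessions).
#' @return Tibble `session_id`, `frame_id`, `timestamp`, `true_label`
#'   (all `NA`; join ground truth on later).
#' @export
session_frames <- function(meta) {
  sess <- dplyr::distinct(meta, .data$session_id, .data$duration_s, .data$fps)
  purrr::pmap_dfr(sess, function(session_id, duration_s, fps) {
    n <- floor(duration_s * fps)
    i <- seq_len(n) - 1L
    tibble::tibble(
      session_id = session_id,
      frame_id = sprintf("%s_f%04d", session_id, i),
      timestamp = i / fps,
      true_label = NA_character_
    )
  })
}

#' Read rater annotations
#'
#' CSV with header `frame_id,rater_id,label`; one row per (frame, rater).
#' Raw labels pass through the vocabulary mapping: empty labels and labels
#' mapped to [DISCARD] (e.g. `confusion`) become `NA`, meaning the rater
#' assigned no usable label to that frame.
#'
#' @param path Path to the CSV.
#' @param mapping Label mapping; see [default_label_map()].
#' @return Tibble `frame_id`, `rater_id`, `label` (canonical or `NA`).
#' @export
read_annotations <- function(path, mapping = default_label_map()) {
  ann <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  req <- c("frame_id", "rater_id", "label")
  if (!all(req %in% names(ann))) {
    stop("annotation file needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(ann[c("frame_id", "rater_id")])) {
    stop("duplicate (frame_id, rater_id) rows in annotation file", call. = FALSE)
  }
  tibble::tibble(
    frame_id = ann$frame_id,
    rater_id = ann$rater_id,
    label = canonicalize_labels(ann$label, mapping)
  )
}

#' @rdname read_annotations
#' @param annotations Annotation tibble to write (NA labels become empty).
#' @export
write_annotations <- function(annotations, path) {
  out <- annotations
  out$label[is.na(out$label)] <- ""
  readr::write_csv(out, path)
  invisible(path)
}

#' Read per-frame provider confidence scores
#'
#' JSON-lines, one record per frame per provider:
#' `{"frame_id": "...", "provider": "...", "scores": {"<emotion>": <num>}}`.
#' Scores are validated against the dialect's declared scale and rescaled
#' to \[0, 1\]; emotion keys are canonicalized via the dialect's mapping.
#' Keys mapping to the same canonical label are summed and capped at 1
#' (a union-event probability); unknown keys are dropped with a warning;
#' frames with no record (no face found) simply yield no rows.
#'
#' @param path Path to a JSON-lines score file.
#' @param dialect Registered dialect name; see [get_dialect()].
#' @return Long tibble `frame_id`, `provider`, `emotion`, `score` with all
#'   scores in \[0, 1\].
#' @export
read_provider_scores <- function(path, dialect) {
  d <- get_dialect(dialect)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  recs <- lapply(lines, jsonlite::fromJSON)
  rows <- purrr::map_dfr(recs, function(r) {
    if (is.null(r$scores) || length(r$scores) == 0L) return(NULL)
    sc <- unlist(r$scores)
    if (any(sc < 0 | sc > d$scale_max)) {
      stop("score outside the '", d$name, "' dialect range [0, ", d$scale_max,
           "] for frame ", r$frame_id, call. = FALSE)
    }
    tibble::tibble(
      frame_id = as.character(r$frame_id),
      provider = as.character(r$provider %||% d$name),
      emotion = names(sc),
      score = as.numeric(sc) / d$scale_max
    )
  })
  if (nrow(rows) == 0L) {
    return(tibble::tibble(frame_id = character(), provider = character(),
                          emotion = character(), score = numeric()))
  }
  rows$emotion <- canonicalize_labels(rows$emotion, d$emotion_map,
                                      on_unknown = "warn")
  rows <- dplyr::filter(rows, !is.na(.data$emotion))
  # merge keys mapped to one canonical label (anger + contempt): sum, cap at 1
  rows |>
    dplyr::group_by(.data$frame_id, .data$provider, .data$emotion) |>
    dplyr::summarise(score = min(sum(.data$score), 1), .groups = "drop")
}

#' Write provider confidence scores
#'
#' Inverse of [read_provider_scores()]: emits JSON-lines on the dialect's
#' declared scale (so a 0–100 dialect writes percentages).
#'
#' @param scores Long score tibble (`frame_id`, `provider`, `emotion`,
#'   `score` in \[0, 1\]).
#' @param path Output path.
#' @param dialect Registered dialect name.
#' @return `path`, invisibly.
#' @export
write_provider_scores <- function(scores, path, dialect = "unit") {
  d <- get_dialect(dialect)
  recs <- scores |>
    dplyr::arrange(.data$provider, .data$frame_id, .data$emotion) |>
    dplyr::group_by(.data$provider, .data$frame_id) |>
    dplyr::group_map(function(g, key) {
      jsonlite::toJSON(
        list(frame_id = key$frame_id, provider = key$provider,
             scores = as.list(stats::setNames(g$score * d$scale_max, g$emotion))),
        auto_unbox = TRUE, digits = NA)
    })
  writeLines(unlist(recs), path, useBytes = TRUE)
  invisible(path)
}

#' Write / read a selected frame set
#'
#' A frame set is the output of the selection pipeline: the retained frames
#' for one target emotion, with full provenance of the filters that produced
#' it (the trim parameters alpha/beta, the confidence threshold lambda, and
#' the fusion method, if any). Written as CSV with one row per retained
#' frame; a round trip reproduces the frame set.
#'
#' @param fs A frame set, as returned by [frames_in_subbound()] or
#'   [confidence_filter()].
#' @param path Output path.
#' @return `path` invisibly for the writer; the frame set for the reader.
#' @export
write_frameset <- function(fs, path) {
  prov <- frameset_provenance(fs)
  out <- tibble::tibble(
    session_id = fs$session_id,
    frame_id = fs$frame_id,
    timestamp = fs$timestamp,
    label = prov$emotion %||% NA_character_,
    region_index = fs$region_index,
    alpha = prov$alpha %||% NA_real_,
    beta = prov$beta %||% NA_real_,
    lambda = prov$lambda %||% NA_real_,
    fusion = prov$fusion %||% NA_character_
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_frameset
#' @export
read_frameset <- function(path) {
  tbl <- readr::read_csv(path, col_types = readr::cols(
    session_id = readr::col_character(), frame_id = readr::col_character(),
    timestamp = readr::col_double(), label = readr::col_character(),
    region_index = readr::col_integer(), alpha = readr::col_double(),
    beta = readr::col_double(), lambda = readr::col_double(),
    fusion = readr::col_character()
  ))
  prov <- list(
    emotion = if (nrow(tbl)) tbl$label[[1]] else NA_character_,
    alpha = if (nrow(tbl)) tbl$alpha[[1]] else NA_real_,
    beta = if (nrow(tbl)) tbl$beta[[1]] else NA_real_,
    lambda = if (nrow(tbl)) tbl$lambda[[1]] else NA_real_,
    fusion = if (nrow(tbl)) tbl$fusion[[1]] else NA_character_
  )
  new_frame_set(
    dplyr::select(tbl, "session_id", "frame_id", "timestamp", "region_index"),
    provenance = prov
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
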