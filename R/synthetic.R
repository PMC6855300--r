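#' Simulation configuration
#'
#' The synthetic generator emulates the statistical structure the selection
#' framework assumes: a 90-second session at 5 frames/s, tiled by prompt
#' regions of random duration; a per-class interpretation lag `onset_lag`
#' after each prompt change during which the child has not yet adopted the
#' prompted expression (the face carries over the previous region's emotion
#' with probability 0.5, else rests at neutral); a per-class trailing
#' `decay` window before the region ends, when the face returns to neutral
#' (relaxation, or leaving the frame as the phone is tilted); an interior
#' in which the target emotion is shown with probability `p_express` and
#' otherwise a confusion-weighted off-target label; and invalid frames
#' (no usable face) with probability `p_invalid` anywhere. Synthetic
#' classifier providers emit confidence vectors whose expected score for
#' the true label strictly dominates every other label (for
#' `concentration > 0`), with a miss rate for frames where no face is
#' found by that provider.
#'
#' @param duration Session length, seconds.
#' @param fps Frames per second.
#' @param region_duration_range Length-2 numeric, uniform region-duration
#'   range in seconds.
#' @param emotion_weights Named non-negative sampling weights over
#'   [emotion_levels()] for region prompts.
#' @param onset_lag,decay Per-class lag/decay seconds: scalar or named
#'   vector over emotions. Must satisfy `onset_lag + decay <
#'   min(region_duration_range)`.
#' @param p_express Probability an interior frame shows the target emotion.
#' @param confusion_weights Named weights for the off-target label drawn
#'   when the child fails to express the target (the target's own weight is
#'   zeroed at draw time).
#' @param p_invalid Probability a frame has no usable face (absent truth).
#' @param providers List of [provider_profile()]s.
#' @param carryover_prob Probability a lag frame carries the previous
#'   region's emotion (else neutral).
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(duration = 90, fps = 5,
                              region_duration_range = c(2, 10),
                              emotion_weights = NULL,
                              onset_lag = 0.6, decay = 1.0,
                              p_express = 0.75,
                              confusion_weights = NULL,
                              p_invalid = 0.12,
                              providers = default_providers(),
                              carryover_prob = 0.5) {
  lv <- emotion_levels()
  full_weights <- function(w, default) {
    if (is.null(w)) return(stats::setNames(rep(default, length(lv)), lv))
    stopifnot(!is.null(names(w)), all(names(w) %in% lv))
    out <- stats::setNames(rep(0, length(lv)), lv)
    out[names(w)] <- w
    out
  }
  per_class <- function(x) {
    if (length(x) == 1L && is.null(names(x))) {
      return(stats::setNames(rep(x, length(lv)), lv))
    }
    stopifnot(all(lv %in% names(x)))
    x[lv]
  }
  if (is.null(confusion_weights)) {
    # default: resting neutral twice as likely as any single wrong emotion
    confusion_weights <- stats::setNames(c(2, rep(1, 6)), lv)
  }
  cfg <- list(
    duration = duration, fps = fps,
    region_duration_range = region_duration_range,
    emotion_weights = full_weights(emotion_weights, 1),
    onset_lag = per_class(onset_lag), decay = per_class(decay),
    p_express = p_express,
    confusion_weights = full_weights(confusion_weights, 0),
    p_invalid = p_invalid, providers = providers,
    carryover_prob = carryover_prob)
  validate_simulation_config(cfg)
}

validate_simulation_config <- function(cfg) {
  stopifnot(cfg$duration > 0, cfg$fps > 0)
  stopifnot(length(cfg$region_duration_range) == 2L,
            cfg$region_duration_range[[1]] > 0,
            cfg$region_duration_range[[1]] <= cfg$region_duration_range[[2]])
  probs <- c(cfg$p_express, cfg$p_invalid, cfg$carryover_prob)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (any(cfg$emotion_weights < 0) || sum(cfg$emotion_weights) == 0) {
    stop("emotion weights must be non-negative and not all zero", call. = FALSE)
  }
  bad <- cfg$onset_lag + cfg$decay >= cfg$region_duration_range[[1]]
  if (any(bad)) {
    stop("infeasible config: onset_lag + decay must be below the minimum ",
         "region duration (violated for: ",
         paste(names(cfg$onset_lag)[bad], collapse = ", "), ")",
         call. = FALSE)
  }
  structure(cfg, class = "simulation_config")
}

#' Synthetic classifier provider profile
#'
#' @param name Provider id.
#' @param concentration Sharpness of score vectors around the true label:
#'   scores are a Dirichlet draw with parameter `1 + concentration` on the
#'   true label and 1 elsewhere, so the true label's expected score
#'   `(1 + c) / (7 + c)` strictly exceeds every other label's
#'   `1 / (7 + c)` whenever `concentration > 0` (the calibration
#'   contract). `Inf` gives one-hot vectors.
#' @param miss_rate Probability the provider returns no vector for a frame.
#' @param dialect Registered dialect the provider's files are written in.
#' @return A `provider_profile` list.
#' @export
provider_profile <- function(name, concentration = 8, miss_rate = 0.05,
                             dialect = "unit") {
  stopifnot(concentration >= 0, miss_rate >= 0, miss_rate <= 1)
  structure(list(name = name, concentration = concentration,
                 miss_rate = miss_rate, dialect = dialect),
            class = "provider_profile")
}

#' @rdname provider_profile
#' @export
default_providers <- function() {
  list(provider_profile("azure_sim", concentration = 10, miss_rate = 0.05,
                        dialect = "unit"),
       provider_profile("sighthound_sim", concentration = 6, miss_rate = 0.08,
                        dialect = "percent"),
       provider_profile("rekognition_sim", concentration = 8, miss_rate = 0.05,
                        dialect = "percent"))
}

# Deterministic per-stream seed derivation: one global seed fans out into
# independent sub-seeds per (stream name, index), so e.g. adding a provider
# never perturbs session structure. Kept below 2^31.
derive_seed <- function(seed, stream, index = 0L) {
  h <- sum(utf8ToInt(stream) * seq_len(nchar(stream)))
  (as.double(seed) * 2654435761 + h * 97 + as.double(index) * 7919) %% 2147483647
}

#' Simulate one game session
#'
#' Generates a session's region structure and ground-truth frame labels
#' under the model described in [simulation_config()]. Fully deterministic
#' given `(cfg, seed, session_id)`.
#'
#' @param cfg A [simulation_config()].
#' @param seed Integer seed for this session's random stream.
#' @param session_id Session identifier used in frame ids.
#' @return List with `meta` (region tibble as from [read_session_meta()])
#'   and `frames` (tibble `session_id`, `frame_id`, `timestamp`,
#'   `true_label`; `NA` truth marks invalid frames).
#' @export
simulate_session <- function(cfg, seed, session_id = "sim1") {
  cfg <- validate_simulation_config(cfg)
  lv <- emotion_levels()
  withr::local_seed(derive_seed(seed, "session"))

  # tile [0, duration] with regions
  starts <- c()
  ends <- c()
  t <- 0
  while (t < cfg$duration - 1e-9) {
    d <- stats::runif(1, cfg$region_duration_range[[1]],
                      cfg$region_duration_range[[2]])
    e <- min(t + d, cfg$duration)
    starts <- c(starts, t)
    ends <- c(ends, e)
    t <- e
  }
  emo <- sample(lv, length(starts), replace = TRUE,
                prob = cfg$emotion_weights)
  meta <- tibble::tibble(
    session_id = session_id, duration_s = cfg$duration, fps = cfg$fps,
    region_index = seq_along(starts), emotion = emo,
    t_start_s = starts, t_end_s = ends, point_awarded = NA)

  frames <- session_frames(meta)
  n <- nrow(frames)
  reg <- findInterval(frames$timestamp, starts) # 1-based; frames lie in [0,dur)
  target <- emo[reg]
  lag <- cfg$onset_lag[target]
  dec <- cfg$decay[target]
  off_start <- frames$timestamp - starts[reg]
  off_end <- ends[reg] - frames$timestamp

  lab <- character(n)
  in_lag <- off_start < lag
  in_decay <- !in_lag & off_end <= dec
  interior <- !in_lag & !in_decay

  prev_emo <- ifelse(reg > 1, emo[pmax(reg - 1L, 1L)], NA_character_)
  carry <- stats::runif(n) < cfg$carryover_prob & !is.na(prev_emo)
  lab[in_lag] <- ifelse(carry[in_lag], prev_emo[in_lag], "neutral")

  lab[in_decay] <- "neutral"

  express <- stats::runif(n) < cfg$p_express
  conf <- vapply(which(interior & !express), function(i) {
    w <- cfg$confusion_weights
    w[target[[i]]] <- 0
    sample(lv, 1, prob = w)
  }, character(1))
  lab[interior & express] <- target[interior & express]
  lab[interior & !express] <- conf

  lab[stats::runif(n) < cfg$p_invalid] <- NA_character_
  frames$true_label <- lab
  list(meta = meta, frames = frames)
}

#' Simulate provider confidence scores
#'
#' Draws per-frame, per-provider confidence vectors over the canonical
#' emotions. For a frame with true label `e`, scores are a Dirichlet draw
#' concentrated on `e` (see [provider_profile()]); for invalid frames
#' (absent truth) the draw is symmetric, so scores are exchangeable across
#' labels. Each provider independently misses frames at its `miss_rate`.
#' Deterministic given `(cfg, seed)`; each provider has its own derived
#' random stream, so adding providers never changes existing ones.
#'
#' @param frames Frame tibble with `true_label` (as from
#'   [simulate_session()]).
#' @param cfg A [simulation_config()] with at least one provider.
#' @param seed Integer seed.
#' @return Long tibble `frame_id`, `provider`, `emotion`, `score` with
#'   scores in \[0, 1\].
#' @export
simulate_scores <- function(frames, cfg, seed) {
  cfg <- validate_simulation_config(cfg)
  if (length(cfg$providers) == 0L) {
    stop("config declares no providers", call. = FALSE)
  }
  lv <- emotion_levels()
  k <- length(lv)
  purrr::map_dfr(cfg$providers, function(p) {
    withr::local_seed(derive_seed(seed, paste0("scores/", p$name)))
    n <- nrow(frames)
    emit <- stats::runif(n) >= p$miss_rate
    idx <- which(emit)
    if (length(idx) == 0L) {
      return(tibble::tibble(frame_id = character(), provider = character(),
                            emotion = character(), score = numeric()))
    }
    truth <- frames$true_label[idx]
    if (is.infinite(p$concentration)) {
      sc <- matrix(0, nrow = length(idx), ncol = k,
                   dimnames = list(NULL, lv))
      has <- !is.na(truth)
      sc[cbind(which(has), match(truth[has], lv))] <- 1
      if (any(!has)) sc[!has, ] <- 1 / k
    } else {
      shape <- matrix(1, nrow = length(idx), ncol = k)
      has <- !is.na(truth)
      shape[cbind(which(has), match(truth[has], lv))] <- 1 + p$concentration
      g <- matrix(stats::rgamma(length(idx) * k, shape = as.vector(shape)),
                  nrow = length(idx), ncol = k)
      sc <- g / rowSums(g)
      colnames(sc) <- lv
    }
    tibble::tibble(
      frame_id = rep(frames$frame_id[idx], each = k),
      provider = p$name,
      emotion = rep(lv, times = length(idx)),
      score = as.vector(t(sc)))
  })
}

#' Simulate a complete session bundle
#'
#' Convenience wrapper producing everything the pipeline consumes for
#' `n_sessions` sessions: pooled meta, ground-truth frames, a perfect-rater
#' annotation pair derived from the truth (both raters report the true
#' label; invalid frames are unlabeled), and provider scores. One global
#' seed drives derived per-session and per-provider streams.
#'
#' @param cfg A [simulation_config()].
#' @param n_sessions Number of sessions.
#' @param seed Global integer seed.
#' @return List `meta`, `frames`, `annotations`, `scores`.
#' @export
simulate_bundle <- function(cfg, n_sessions = 1, seed = 1) {
  sessions <- lapply(seq_len(n_sessions), function(i) {
    simulate_session(cfg, derive_seed(seed, "bundle", i),
                     session_id = sprintf("sim%03d", i))
  })
  meta <- purrr::map_dfr(sessions, "meta")
  frames <- purrr::map_dfr(sessions, "frames")
  scores <- simulate_scores(frames, cfg, derive_seed(seed, "bundle-scores"))
  annotations <- tidyr::expand_grid(
    frame_id = frames$frame_id, rater_id = c("r1", "r2")) |>
    dplyr::left_join(dplyr::select(frames, "frame_id", label = "true_label"),
                     by = "frame_id")
  list(meta = meta, frames = frames, annotations = annotations,
       scores = scores)
}

#' Write / read a session bundle on disk
#'
#' Emits exactly the interchange formats the readers consume — session meta
#' JSON per session, an annotation CSV, and one JSON-lines score file per
#' provider in that provider's dialect — so synthetic bundles are
#' indistinguishable from field data to the rest of the system.
#'
#' @param bundle As from [simulate_bundle()].
#' @param dir Output directory (created if needed).
#' @param cfg The [simulation_config()] used (for provider dialects).
#' @return `dir` invisibly for the writer; a bundle list for the reader.
#' @export
write_bundle <- function(bundle, dir, cfg = simulation_config()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sid in unique(bundle$meta$session_id)) {
    write_session_meta(dplyr::filter(bundle$meta, .data$session_id == sid),
                       file.path(dir, paste0(sid, ".meta.json")))
  }
  write_annotations(bundle$annotations, file.path(dir, "annotations.csv"))
  dialects <- stats::setNames(
    vapply(cfg$providers, `[[`, character(1), "dialect"),
    vapply(cfg$providers, `[[`, character(1), "name"))
  for (prov in unique(bundle$scores$provider)) {
    d <- if (prov %in% names(dialects)) dialects[[prov]] else "unit"
    write_provider_scores(
      dplyr::filter(bundle$scores, .data$provider == prov),
      file.path(dir, paste0("scores_", prov, ".jsonl")), dialect = d)
  }
  writeLines(jsonlite::toJSON(as.list(dialects), auto_unbox = TRUE),
             file.path(dir, "providers.json"))
  invisible(dir)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(dir) {
  meta_files <- sort(list.files(dir, pattern = "\\.meta\\.json$",
                                full.names = TRUE))
  meta <- purrr::map_dfr(meta_files, read_session_meta)
  annotations <- read_annotations(file.path(dir, "annotations.csv"))
  dialects <- jsonlite::fromJSON(file.path(dir, "providers.json"))
  scores <- purrr::imap_dfr(dialects, function(d, prov) {
    read_provider_scores(file.path(dir, paste0("scores_", prov, ".jsonl")), d)
  })
  frames <- session_frames(meta)
  truth <- consensus_labels(annotations, c("r1", "r2"))
  frames$true_label <- truth$label[match(frames$frame_id, truth$frame_id)]
  list(meta = meta, frames = frames, annotations = annotations,
       scores = scores)
}
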