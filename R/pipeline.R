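#' The five frame-curation techniques
#'
#' @return Character vector of technique names, in comparison order:
#'   `entire_video` (prevalence of the emotion over all ground-truth
#'   frames), `boundary` (all frames in matching prompt regions),
#'   `subbound` (regions trimmed by alpha/beta), `subbound_minconf`
#'   (sub-bound plus a single-provider minimum-confidence filter), and
#'   `subbound_ensemble` (sub-bound plus a fused multi-provider filter).
#' @export
techniques <- function() {
  c("entire_video", "boundary", "subbound", "subbound_minconf",
    "subbound_ensemble")
}

#' Extract frames for one emotion under a chosen technique
#'
#' Runs the selection stack for a single target emotion: region selection,
#' optional sub-bound trimming, optional minimum-confidence filtering with
#' single-provider or fused ensemble scores. Parameters `(alpha, beta,
#' lambda)` come from `params` (e.g. a row of [optimize_params()]); they
#' default to no trimming and no filtering.
#'
#' @param meta,frames Pooled session meta and frames (`true_label` may be
#'   present; it is carried through for density reporting).
#' @param emotion Target canonical emotion.
#' @param technique One of [techniques()].
#' @param params Optional one-row data frame / list with `alpha`, `beta`,
#'   `lambda` for this emotion.
#' @param scores Long provider score tibble; required for the
#'   minimum-confidence and ensemble techniques.
#' @param provider Provider id used by `subbound_minconf` (default: first
#'   provider present in `scores`).
#' @param fusion Fusion method for `subbound_ensemble`.
#' @return A `frame_set`. For `entire_video` the set contains every frame
#'   (region_index `NA`): the technique is the no-information baseline and
#'   its density is the emotion's prevalence.
#' @export
extract_frames <- function(meta, frames, emotion,
                           technique = c("boundary", "entire_video",
                                         "subbound", "subbound_minconf",
                                         "subbound_ensemble"),
                           params = NULL, scores = NULL,
                           provider = NULL,
                           fusion = c("average", "min", "max")) {
  technique <- match.arg(technique)
  fusion <- match.arg(fusion)
  assert_emotion(emotion)
  alpha <- params$alpha %||% 0
  beta <- params$beta %||% 0
  lambda <- params$lambda %||% 0

  if (technique == "entire_video") {
    out <- dplyr::mutate(
      frames[intersect(c("session_id", "frame_id", "timestamp", "true_label"),
                       names(frames))],
      region_index = NA_integer_)
    return(new_frame_set(out, provenance = list(
      emotion = emotion, alpha = NA_real_, beta = NA_real_, lambda = NA_real_,
      fusion = NULL, providers = NULL, technique = technique)))
  }

  if (technique == "boundary") {
    fs <- frames_in_region(meta, frames, emotion)
  } else {
    fs <- frames_in_subbound(meta, frames, emotion, alpha, beta)
  }

  if (technique %in% c("subbound_minconf", "subbound_ensemble")) {
    if (is.null(scores) || nrow(scores) == 0L) {
      stop("technique '", technique, "' needs provider scores", call. = FALSE)
    }
    if (technique == "subbound_minconf") {
      provider <- provider %||% scores$provider[[1]]
      sc <- fuse_scores(
        dplyr::filter(scores, .data$provider == !!provider), emotion,
        method = "average")
      fs <- confidence_filter(fs, sc, lambda)
      prov <- frameset_provenance(fs)
      prov$providers <- provider
      attr(fs, "provenance") <- prov
    } else {
      sc <- fuse_scores(scores, emotion, method = fusion)
      fs <- confidence_filter(fs, sc, lambda, fusion = fusion)
      prov <- frameset_provenance(fs)
      prov$providers <- unique(scores$provider)
      attr(fs, "provenance") <- prov
    }
  }
  prov <- frameset_provenance(fs)
  prov$technique <- technique
  attr(fs, "provenance") <- prov
  fs
}

#' Per-emotion optimal trim and confidence parameters
#'
#' Runs the sequential per-class search — sub-bound trim first, then the
#' minimum-confidence threshold at the chosen trim — for each requested
#' emotion, pooled over sessions. Mirrors the per-class optimal-parameter
#' table a study would report. Emotions with no region or no usable ground
#' truth are skipped with a warning, not an error.
#'
#' @inheritParams optimize_subbound
#' @param emotions Emotions to fit; defaults to all canonical labels.
#' @param scores Long provider score tibble; when `NULL`, the lambda search
#'   is skipped and all lambdas are 0.
#' @param provider Provider whose scores drive the lambda search (default:
#'   first in `scores`); use `fusion` instead for fused scores.
#' @param fusion When non-`NULL`, fuse all providers by this method for the
#'   lambda search instead of using a single provider.
#' @param lambda_step,lambda_max Lambda search increment and cap.
#' @return Tibble, one row per fitted emotion: `emotion`, `alpha`, `beta`,
#'   `lambda`, `baseline_density`, `final_density`, `baseline_retained`,
#'   `final_retained`. Skipped emotions are listed in attribute `skipped`.
#' @export
optimize_params <- function(meta, frames, emotions = emotion_levels(),
                            scores = NULL, provider = NULL, fusion = NULL,
                            step = 0.2, alpha_max = 2.4, beta_max = 2.4,
                            lambda_step = 0.01, lambda_max = 0.5,
                            baseline = "initial", loss_on = "matching") {
  frame_scores_for <- function(emotion) {
    if (is.null(scores)) return(NULL)
    if (!is.null(fusion)) return(fuse_scores(scores, emotion, fusion))
    prov <- provider %||% scores$provider[[1]]
    fuse_scores(dplyr::filter(scores, .data$provider == !!prov), emotion,
                method = "average")
  }
  skipped <- character()
  rows <- purrr::map_dfr(emotions, function(em) {
    fit_ab <- tryCatch(
      optimize_subbound(meta, frames, em, step = step, alpha_max = alpha_max,
                        beta_max = beta_max, baseline = baseline,
                        loss_on = loss_on),
      error = function(e) e)
    if (inherits(fit_ab, "error")) {
      warning("skipping '", em, "': ", conditionMessage(fit_ab),
              call. = FALSE)
      skipped <<- c(skipped, em)
      return(NULL)
    }
    fit <- fit_ab
    fsc <- frame_scores_for(em)
    if (!is.null(fsc)) {
      fit_l <- tryCatch(
        optimize_lambda(meta, frames, em, fit_ab$alpha, fit_ab$beta, fsc,
                        step = lambda_step, lambda_max = lambda_max,
                        baseline = baseline, loss_on = loss_on),
        error = function(e) e)
      if (!inherits(fit_l, "error")) fit <- fit_l
    }
    tibble::tibble(
      emotion = em, alpha = fit_ab$alpha, beta = fit_ab$beta,
      lambda = fit$lambda,
      baseline_density = fit_ab$baseline_density,
      final_density = fit$final_density,
      baseline_retained = fit_ab$baseline_retained,
      final_retained = fit$final_retained)
  })
  attr(rows, "skipped") <- skipped
  rows
}

#' Compare the five curation techniques
#'
#' Evaluates density (fraction of retained ground-truth frames matching the
#' target emotion) and yield for every requested emotion under each of the
#' five techniques, using a fitted parameter table for the trimmed and
#' filtered ones.
#'
#' @inheritParams optimize_params
#' @param params Parameter tibble from [optimize_params()].
#' @param fusion Fusion method for the ensemble technique.
#' @return A `technique_comparison` tibble: `emotion`, `technique`,
#'   `retained`, `matching`, `density`. Supports [ggplot2::autoplot()].
#' @export
evaluate_techniques <- function(meta, frames, scores, params,
                                emotions = params$emotion,
                                provider = NULL, fusion = "average") {
  rows <- purrr::map_dfr(emotions, function(em) {
    p <- params[params$emotion == em, ]
    if (nrow(p) == 0L) p <- list(alpha = 0, beta = 0, lambda = 0)
    purrr::map_dfr(techniques(), function(tech) {
      fs <- extract_frames(meta, frames, em, technique = tech, params = p,
                          scores = scores, provider = provider,
                          fusion = fusion)
      dplyr::mutate(frameset_density(fs, em), technique = tech,
                    .after = "emotion")
    })
  })
  rows$technique <- factor(rows$technique, levels = techniques())
  class(rows) <- c("technique_comparison", class(rows))
  rows
}

#' @method autoplot technique_comparison
#' @export
autoplot.technique_comparison <- function(object, ...) {
  df <- dplyr::filter(object, !is.na(.data$density))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$emotion,
                                   y = 100 * .data$density,
                                   fill = .data$technique)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "matching frames (%)", fill = "technique",
                  title = "Frame-labeling density by technique") +
    ggplot2::theme_minimal()
}

#' Tradeoff surface plot
#'
#' Tile plot of a [tradeoff_grid()] slice: density (or retained count) as a
#' function of alpha and beta at a fixed lambda.
#'
#' @param grid Tibble from [tradeoff_grid()].
#' @param what `"density"` or `"retained"`.
#' @param lambda Which lambda slice to show.
#' @return A ggplot object.
#' @export
plot_tradeoff_surface <- function(grid, what = c("density", "retained"),
                                  lambda = 0) {
  what <- match.arg(what)
  df <- dplyr::filter(grid, .data$lambda == !!lambda)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$alpha, y = .data$beta,
                                   fill = .data[[what]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "alpha (s)", y = "beta (s)", fill = what,
                  title = paste("Sub-bound tradeoff surface:", what)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
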