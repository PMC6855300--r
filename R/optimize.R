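#' Density-versus-yield tradeoff ratio
#'
#' The greedy searches weigh a candidate filter setting against a baseline
#' by the ratio `k = gain / loss`, where `gain` is the density improvement
#' in percentage points, `100 * (cand_density - base_density)`, and `loss`
#' is the percentage of frames given up,
#' `100 * (base_retained - cand_retained) / base_retained`. `k = 1` means
#' density improved by the same margin that the frame count shrank — the
#' boundary of an acceptable tradeoff; steps with `k < 1` are rejected.
#'
#' Conventions for the degenerate corners: a candidate with no density gain
#' (`gain <= 0`, including an undefined candidate density) has `k = 0`; a
#' candidate that gains density while giving up nothing (`loss <= 0`) has
#' `k = Inf`.
#'
#' @param base_density,cand_density Densities in \[0, 1\] (candidate may be
#'   `NA` when it retains nothing).
#' @param base_retained,cand_retained Frame counts the loss is measured on;
#'   `base_retained` must be positive.
#' @return Non-negative number, possibly `Inf`.
#' @export
#' @examples
#' tradeoff_ratio(0.35, 100, 0.40, 90) # gain 5 pp, loss 10% -> 0.5
tradeoff_ratio <- function(base_density, base_retained,
                           cand_density, cand_retained) {
  if (!is.numeric(base_retained) || base_retained <= 0) {
    stop("baseline must retain at least one frame", call. = FALSE)
  }
  gain <- 100 * (cand_density - base_density)
  if (is.na(gain) || gain <= 0) return(0)
  loss <- 100 * (base_retained - cand_retained) / base_retained
  if (loss <= 0) return(Inf)
  gain / loss
}

# Per-frame working table for one target emotion: every ground-truth frame
# inside a matching region, with its offsets from the region edges and
# whether its true label matches. All grid/greedy evaluations reduce to
# vectorized filters over this table.
subbound_worktable <- function(meta, frames, emotion, require_truth = TRUE) {
  assert_emotion(emotion)
  regions <- dplyr::filter(meta, .data$emotion == !!emotion)
  if (nrow(regions) == 0L) {
    stop("no region with emotion '", emotion, "' in the session meta",
         call. = FALSE)
  }
  wt <- frames |>
    dplyr::inner_join(
      dplyr::select(regions, "session_id", "region_index",
                    "t_start_s", "t_end_s"),
      by = "session_id", relationship = "many-to-many") |>
    dplyr::filter(.data$timestamp >= .data$t_start_s,
                  .data$timestamp < .data$t_end_s) |>
    dplyr::mutate(
      off_start = .data$timestamp - .data$t_start_s,
      off_end = .data$t_end_s - .data$timestamp,
      match = .data$true_label == !!emotion)
  if (require_truth) {
    wt <- dplyr::filter(wt, !is.na(.data$true_label))
    if (nrow(wt) == 0L) {
      stop("no ground-truth frames inside '", emotion, "' regions",
           call. = FALSE)
    }
  }
  wt
}

# Evaluate one (alpha, beta, lambda) point on a worktable. `score` column
# (may be NA) is consulted only when lambda > 0.
eval_point <- function(wt, alpha, beta, lambda = 0) {
  keep <- wt$off_start >= alpha & wt$off_end > beta
  if (lambda > 0) keep <- keep & !is.na(wt$score) & wt$score > lambda
  retained <- sum(keep)
  matching <- sum(keep & wt$match)
  list(retained = retained, matching = matching,
       density = if (retained > 0) matching / retained else NA_real_)
}

loss_count <- function(state, loss_on) {
  if (loss_on == "matching") state$matching else state$retained
}

# k of candidate vs reference state under the configured loss basis.
state_k <- function(ref, cand, loss_on) {
  n0 <- loss_count(ref, loss_on)
  if (n0 <= 0) return(0)
  tradeoff_ratio(ref$density, n0, cand$density, loss_count(cand, loss_on))
}

#' Greedy sub-bound search for one emotion class
#'
#' Tunes the leading/trailing trim `(alpha, beta)` for one emotion, pooled
#' over all supplied sessions. Starting at `alpha = beta = 0`, each
#' iteration evaluates the two single-axis increments
#' `(alpha + step, beta)` and `(alpha, beta + step)` against the untrimmed
#' baseline via [tradeoff_ratio()] and accepts the admissible candidate
#' with the larger `k`; ties go to `alpha`. A candidate is admissible when
#' its `k >= 1` *and* it strictly improves density over the current
#' accepted state (the marginal-gain guard, see Details). The search stops
#' when neither candidate is admissible or the caps are reached. Run it
#' separately per class: interpretation lag and decay differ between
#' prompts.
#'
#' @details
#' Two readings of `k` are configurable. `baseline = "initial"` (default)
#' measures gain and loss against the untrimmed `(0, 0)` state;
#' `"previous"` measures against the last accepted state. `loss_on`
#' chooses the denominator frames: `"matching"` (default) counts only
#' frames whose ground truth matches the target — the *relevant* frames
#' whose loss matters — while `"all"` counts every retained frame. Under
#' `"all"`, removing purely-mismatched frames yields `k` equal to the
#' candidate density, so `k >= 1` is unattainable below density 1 and the
#' search degenerates; `"matching"` is the reading consistent with the
#' intended behavior and is the default. The marginal-gain guard prevents
#' the baseline-relative `k` from accepting no-op or density-flat steps
#' indefinitely once a good trim is found.
#'
#' @param meta,frames Pooled session meta and ground-truth frames
#'   (`true_label` column; frames without truth are ignored).
#' @param emotion Target canonical emotion.
#' @param step Trim increment in seconds; default 0.2 s = one frame at
#'   5 frames/s.
#' @param alpha_max,beta_max Search caps in seconds.
#' @param baseline `"initial"` or `"previous"`; see Details.
#' @param loss_on `"matching"` or `"all"`; see Details.
#' @return A `trim_fit`: list with `emotion`, `alpha`, `beta`,
#'   `lambda` (0), the baseline and final [eval_point()] states, the
#'   accepted-step `path` tibble, and the search settings. Supports
#'   `tidy()` (the path) and `glance()` (one-row summary).
#' @export
optimize_subbound <- function(meta, frames, emotion, step = 0.2,
                              alpha_max = 2.4, beta_max = 2.4,
                              baseline = c("initial", "previous"),
                              loss_on = c("matching", "all")) {
  baseline <- match.arg(baseline)
  loss_on <- match.arg(loss_on)
  stopifnot(step > 0, alpha_max >= 0, beta_max >= 0)
  wt <- subbound_worktable(meta, frames, emotion)

  base <- eval_point(wt, 0, 0)
  cur <- base
  alpha <- 0
  beta <- 0
  path <- list()
  repeat {
    cands <- list()
    if (alpha + step <= alpha_max + 1e-9) {
      cands$alpha <- list(alpha = alpha + step, beta = beta)
    }
    if (beta + step <= beta_max + 1e-9) {
      cands$beta <- list(alpha = alpha, beta = beta + step)
    }
    if (length(cands) == 0L) break
    ref <- if (baseline == "initial") base else cur
    evals <- lapply(cands, function(cc) {
      st <- eval_point(wt, cc$alpha, cc$beta)
      list(point = cc, state = st,
           k = state_k(ref, st, loss_on),
           marginal_gain = (st$density %||% NA_real_) - cur$density)
    })
    admissible <- vapply(evals, function(e) {
      e$k >= 1 && !is.na(e$marginal_gain) && e$marginal_gain > 0
    }, logical(1))
    if (!any(admissible)) break
    ks <- vapply(evals, `[[`, numeric(1), "k")
    ks[!admissible] <- -Inf
    # which.max returns the first maximum; candidate order puts alpha first,
    # so ties go to incrementing alpha
    pick <- evals[[which.max(ks)]]
    alpha <- pick$point$alpha
    beta <- pick$point$beta
    cur <- pick$state
    path[[length(path) + 1L]] <- tibble::tibble(
      step = length(path) + 1L, alpha = alpha, beta = beta, lambda = 0,
      k = pick$k, retained = cur$retained, matching = cur$matching,
      density = cur$density)
  }

  new_trim_fit(emotion, alpha, beta, lambda = 0, base = base, final = cur,
               path = dplyr::bind_rows(path),
               settings = list(what = "subbound", step = step,
                               alpha_max = alpha_max, beta_max = beta_max,
                               baseline = baseline, loss_on = loss_on))
}

#' Greedy minimum-confidence search for one emotion class
#'
#' Tunes the per-class confidence threshold `lambda` at a fixed sub-bound
#' trim `(alpha, beta)`. Starting from `lambda = 0` (no filtering), the
#' threshold is raised in increments of `step` while the candidate's
#' [tradeoff_ratio()] against the `lambda = 0` state is at least 1 and the
#' step strictly improves density over the current accepted state; the
#' search stops at the first inadmissible step or at `lambda_max`.
#' Classifier sensitivities differ between classes, so `lambda` is
#' determined per emotion.
#'
#' Frames with no score cannot exceed a positive threshold and are dropped
#' for any `lambda > 0`; the `lambda = 0` baseline retains them.
#'
#' @inheritParams optimize_subbound
#' @param alpha,beta The fixed trim, typically from [optimize_subbound()].
#' @param frame_scores Tibble `frame_id`, `score`: the per-frame confidence
#'   for this emotion, single-provider or fused via [fuse_scores()].
#' @param step Threshold increment; default 0.01.
#' @param lambda_max Search cap.
#' @return A `trim_fit` with the chosen `lambda` (a multiple of `step`).
#' @export
optimize_lambda <- function(meta, frames, emotion, alpha, beta, frame_scores,
                            step = 0.01, lambda_max = 0.5,
                            baseline = c("initial", "previous"),
                            loss_on = c("matching", "all")) {
  baseline <- match.arg(baseline)
  loss_on <- match.arg(loss_on)
  stopifnot(step > 0, lambda_max >= 0, alpha >= 0, beta >= 0)
  wt <- subbound_worktable(meta, frames, emotion)
  wt$score <- frame_scores$score[match(wt$frame_id, frame_scores$frame_id)]
  in_sub <- wt$off_start >= alpha & wt$off_end > beta
  if (!any(in_sub & !is.na(wt$score))) {
    stop("no scored ground-truth frames inside the '", emotion,
         "' sub-bound; cannot search lambda", call. = FALSE)
  }

  base <- eval_point(wt, alpha, beta, 0)
  cur <- base
  lambda <- 0
  path <- list()
  while (lambda + step <= lambda_max + 1e-9) {
    cand_lambda <- round(lambda + step, 10)
    st <- eval_point(wt, alpha, beta, cand_lambda)
    ref <- if (baseline == "initial") base else cur
    k <- state_k(ref, st, loss_on)
    marginal_gain <- (st$density %||% NA_real_) - cur$density
    if (!(k >= 1 && !is.na(marginal_gain) && marginal_gain > 0)) break
    lambda <- cand_lambda
    cur <- st
    path[[length(path) + 1L]] <- tibble::tibble(
      step = length(path) + 1L, alpha = alpha, beta = beta, lambda = lambda,
      k = k, retained = cur$retained, matching = cur$matching,
      density = cur$density)
  }

  new_trim_fit(emotion, alpha, beta, lambda, base = base, final = cur,
               path = dplyr::bind_rows(path),
               settings = list(what = "lambda", step = step,
                               lambda_max = lambda_max, baseline = baseline,
                               loss_on = loss_on))
}

new_trim_fit <- function(emotion, alpha, beta, lambda, base, final, path,
                         settings) {
  if (nrow(path) == 0L) {
    path <- tibble::tibble(step = integer(), alpha = numeric(),
                           beta = numeric(), lambda = numeric(), k = numeric(),
                           retained = integer(), matching = integer(),
                           density = numeric())
  }
  structure(
    list(emotion = emotion, alpha = alpha, beta = beta, lambda = lambda,
         baseline_density = base$density, final_density = final$density,
         baseline_retained = base$retained, final_retained = final$retained,
         baseline_matching = base$matching, final_matching = final$matching,
         path = path, settings = settings),
    class = "trim_fit")
}

#' @export
print.trim_fit <- function(x, ...) {
  cat(sprintf(
    "Trim fit [%s]: alpha = %.2f s, beta = %.2f s, lambda = %.2f\n",
    x$emotion, x$alpha, x$beta, x$lambda))
  cat(sprintf("  density %.1f%% -> %.1f%%, retained %d -> %d (%d steps)\n",
              100 * x$baseline_density, 100 * x$final_density,
              x$baseline_retained, x$final_retained, nrow(x$path)))
  invisible(x)
}

#' @method tidy trim_fit
#' @export
tidy.trim_fit <- function(x, ...) x$path

#' @method glance trim_fit
#' @export
glance.trim_fit <- function(x, ...) {
  tibble::tibble(
    emotion = x$emotion, alpha = x$alpha, beta = x$beta, lambda = x$lambda,
    baseline_density = x$baseline_density, final_density = x$final_density,
    baseline_retained = x$baseline_retained,
    final_retained = x$final_retained, steps = nrow(x$path))
}

#' Exhaustive tradeoff grid (test oracle)
#'
#' Brute-force evaluation of retained/matching counts and density at every
#' point of an `(alpha, beta, lambda)` grid, for one emotion pooled over
#' sessions. Used to verify that every step the greedy searches accept is
#' legal (`k >= 1`) and to render density/yield tradeoff surfaces.
#'
#' @inheritParams optimize_subbound
#' @param alpha_values,beta_values,lambda_values Numeric grid axes
#'   (non-empty; `lambda_values` defaults to 0 only).
#' @param frame_scores Optional per-frame score tibble; required when any
#'   `lambda_values > 0`.
#' @return Tibble `alpha`, `beta`, `lambda`, `retained`, `matching`,
#'   `density` over the full grid.
#' @export
tradeoff_grid <- function(meta, frames, emotion, alpha_values, beta_values,
                          lambda_values = 0, frame_scores = NULL) {
  if (length(alpha_values) == 0L || length(beta_values) == 0L ||
      length(lambda_values) == 0L) {
    stop("empty grid", call. = FALSE)
  }
  wt <- subbound_worktable(meta, frames, emotion)
  wt$score <- if (is.null(frame_scores)) NA_real_ else
    frame_scores$score[match(wt$frame_id, frame_scores$frame_id)]
  grid <- tidyr::expand_grid(alpha = sort(alpha_values),
                             beta = sort(beta_values),
                             lambda = sort(lambda_values))
  res <- purrr::pmap_dfr(grid, function(alpha, beta, lambda) {
    st <- eval_point(wt, alpha, beta, lambda)
    tibble::tibble(retained = st$retained, matching = st$matching,
                   density = st$density)
  })
  dplyr::bind_cols(grid, res)
}
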