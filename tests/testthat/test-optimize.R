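test_that("tradeoff ratio follows the stated gain/loss arithmetic", {
  # density 0.35 -> 0.40 (gain 5 pp), retained 100 -> 90 (loss 10%)
  expect_equal(tradeoff_ratio(0.35, 100, 0.40, 90), 0.5)
  # density 0.58 -> 0.75, retained 100 -> 80 -> k = 17/20
  expect_equal(tradeoff_ratio(0.58, 100, 0.75, 80), 0.85)
  # density up, nothing lost -> infinite ratio
  expect_equal(tradeoff_ratio(0.5, 100, 0.6, 100), Inf)
  # no gain (or a regression) -> 0, regardless of loss
  expect_equal(tradeoff_ratio(0.5, 100, 0.5, 50), 0)
  expect_equal(tradeoff_ratio(0.5, 100, 0.4, 90), 0)
  expect_equal(tradeoff_ratio(0.5, 100, NA, 0), 0)
  expect_error(tradeoff_ratio(0.5, 0, 0.6, 0), "at least one")
})

test_that("sub-bound search returns (0,0) when trimming cannot help", {
  meta <- make_meta(list(happy = c(0, 3), happy = c(3, 6)))
  # every in-region frame already matches: no density gain available
  perfect <- make_frames(meta, true_label = "happy")
  fit <- optimize_subbound(meta, perfect, "happy")
  expect_equal(c(fit$alpha, fit$beta), c(0, 0))
  expect_equal(fit$final_density, 1)

  # no frame matches anywhere: density 0 at every trim
  hopeless <- make_frames(meta, true_label = "sad")
  fit0 <- optimize_subbound(meta, hopeless, "happy")
  expect_equal(c(fit0$alpha, fit0$beta), c(0, 0))

  expect_error(optimize_subbound(meta, perfect, "scared"), "no region")
  no_truth <- make_frames(meta, true_label = NA_character_)
  expect_error(optimize_subbound(meta, no_truth, "happy"), "ground-truth")
})

test_that("sub-bound search recovers a leading junk interval", {
  # frames in [0, 0.6) of each region are mismatched; the rest match
  meta <- make_meta(list(happy = c(0, 3), happy = c(3, 6), happy = c(6, 9)))
  frames <- make_labeled_frames(meta, lag = 0.6)
  fit <- optimize_subbound(meta, frames, "happy")
  expect_equal(fit$alpha, 0.6)
  expect_equal(fit$beta, 0)
  expect_equal(fit$final_density, 1)

  # every accepted step is legal against the exhaustive grid
  grid <- tradeoff_grid(meta, frames, "happy",
                        alpha_values = seq(0, 2.4, by = 0.2),
                        beta_values = seq(0, 2.4, by = 0.2))
  base <- grid[grid$alpha == 0 & grid$beta == 0, ]
  for (i in seq_len(nrow(fit$path))) {
    row <- fit$path[i, ]
    pt <- grid[grid$alpha == row$alpha & grid$beta == row$beta, ]
    expect_equal(pt$density, row$density)
    expect_equal(pt$retained, row$retained)
    k <- tradeoff_ratio(base$density, base$matching, pt$density, pt$matching)
    expect_gte(k, 1)
  }
})

test_that("lambda search: separating scores stop after one increment", {
  meta <- make_meta(list(happy = c(0, 3), happy = c(3, 6)))
  frames <- make_labeled_frames(meta, lag = 0.6)
  sc <- tibble::tibble(
    frame_id = frames$frame_id,
    score = ifelse(frames$true_label == "happy", 1, 0))

  lam <- optimize_lambda(meta, frames, "happy", 0, 0, sc)
  expect_equal(lam$lambda, 0.01)
  expect_equal(lam$final_density, 1)
  expect_equal(lam$path$k, Inf)

  # all frames already matching: no gain possible, lambda stays 0
  perfect <- make_frames(meta, true_label = "happy")
  sc1 <- tibble::tibble(frame_id = perfect$frame_id, score = 0.9)
  expect_equal(optimize_lambda(meta, perfect, "happy", 0, 0, sc1)$lambda, 0)

  # unscored sub-bound is an error
  expect_error(
    optimize_lambda(meta, frames, "happy", 0, 0,
                    tibble::tibble(frame_id = character(), score = numeric())),
    "no scored")
})

test_that("lambda search lands on multiples of its step", {
  cfg <- simulation_config()
  b <- simulate_bundle(cfg, n_sessions = 3, seed = 5)
  for (em in c("happy", "surprised", "disgusted")) {
    sc <- fuse_scores(b$scores, em, "average")
    fit <- optimize_lambda(b$meta, b$frames, em, 0, 0, sc, step = 0.01)
    expect_equal(fit$lambda * 100, round(fit$lambda * 100), tolerance = 1e-8)
  }
})

test_that("exhaustive grid oracle: baseline point and monotone retention", {
  cfg <- simulation_config()
  b <- simulate_bundle(cfg, n_sessions = 2, seed = 23)

  single <- tradeoff_grid(b$meta, b$frames, "happy", 0, 0, 0)
  boundary <- frameset_density(frames_in_region(b$meta, b$frames, "happy"))
  expect_equal(nrow(single), 1L)
  expect_equal(single$retained, boundary$retained)
  expect_equal(single$density, boundary$density)

  grid <- tradeoff_grid(b$meta, b$frames, "happy",
                        alpha_values = seq(0, 1.2, by = 0.2),
                        beta_values = seq(0, 1.2, by = 0.2))
  by_beta <- split(grid, grid$beta)
  for (g in by_beta) expect_true(all(diff(g[order(g$alpha), ]$retained) <= 0))
  by_alpha <- split(grid, grid$alpha)
  for (g in by_alpha) expect_true(all(diff(g[order(g$beta), ]$retained) <= 0))

  expect_error(tradeoff_grid(b$meta, b$frames, "happy", numeric(), 0, 0),
               "empty grid")
})

test_that("greedy results coincide with the oracle at their grid point", {
  cfg <- recovery_config()
  b <- simulate_bundle(cfg, n_sessions = 4, seed = 31)
  fit <- optimize_subbound(b$meta, b$frames, "disgusted")
  grid <- tradeoff_grid(b$meta, b$frames, "disgusted",
                        alpha_values = seq(0, 2.4, by = 0.2),
                        beta_values = seq(0, 2.4, by = 0.2))
  pt <- grid[abs(grid$alpha - fit$alpha) < 1e-9 &
               abs(grid$beta - fit$beta) < 1e-9, ]
  expect_equal(pt$density, fit$final_density)
  expect_equal(pt$retained, fit$final_retained)
})

test_that("greedy terminates within the step-budget bound", {
  cfg <- simulation_config()
  b <- simulate_bundle(cfg, n_sessions = 2, seed = 41)
  fit <- optimize_subbound(b$meta, b$frames, "sad",
                           step = 0.2, alpha_max = 1, beta_max = 1)
  expect_lte(nrow(fit$path), (1 + 1) / 0.2)
  sc <- fuse_scores(b$scores, "sad", "average")
  fl <- optimize_lambda(b$meta, b$frames, "sad", fit$alpha, fit$beta, sc,
                        step = 0.05, lambda_max = 0.3)
  expect_lte(nrow(fl$path), 0.3 / 0.05)
})

test_that("both loss denominators and baselines are available as switches", {
  meta <- make_meta(list(happy = c(0, 3), happy = c(3, 6), happy = c(6, 9)))
  frames <- make_labeled_frames(meta, lag = 0.6)

  # under the all-frames loss, k equals candidate density when trimmed
  # frames are mismatched, so no step below density 1 is ever accepted
  # from a non-degenerate start
  fit_all <- optimize_subbound(meta, frames, "happy", loss_on = "all")
  expect_equal(c(fit_all$alpha, fit_all$beta), c(0, 0))

  fit_prev <- optimize_subbound(meta, frames, "happy", baseline = "previous")
  expect_equal(fit_prev$alpha, 0.6)
})
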