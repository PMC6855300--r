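test_that("sessions conserve the frame grid and tile without overlap", {
  cfg <- simulation_config()
  s <- simulate_session(cfg, seed = 1)
  expect_equal(nrow(s$frames), floor(cfg$duration * cfg$fps)) # 450
  expect_true(all(diff(s$frames$timestamp) > 0))

  m <- s$meta
  expect_true(all(m$t_start_s[-1] >= m$t_end_s[-nrow(m)] - 1e-9))
  expect_equal(m$t_start_s[[1]], 0)
  expect_equal(m$t_end_s[[nrow(m)]], cfg$duration)
  expect_true(all(m$emotion %in% emotion_levels()))
})

test_that("generation is deterministic in the seed, stream by stream", {
  cfg <- simulation_config()
  a <- simulate_bundle(cfg, n_sessions = 2, seed = 7)
  b <- simulate_bundle(cfg, n_sessions = 2, seed = 7)
  expect_identical(a, b)
  c <- simulate_bundle(cfg, n_sessions = 2, seed = 8)
  expect_false(identical(a$meta, c$meta))

  # adding a provider must not perturb session structure or other providers
  cfg4 <- simulation_config(providers = c(
    cfg$providers, list(provider_profile("extra", dialect = "unit"))))
  d <- simulate_bundle(cfg4, n_sessions = 2, seed = 7)
  expect_identical(a$meta, d$meta)
  expect_identical(a$frames, d$frames)
  expect_equal(a$scores,
               dplyr::filter(d$scores, .data$provider != "extra"))
})

test_that("degenerate config: perfect expression gives density 1 everywhere", {
  cfg <- simulation_config(onset_lag = 0, decay = 0, p_express = 1,
                           p_invalid = 0, region_duration_range = c(2, 6))
  s <- simulate_session(cfg, seed = 3)
  for (em in unique(s$meta$emotion)) {
    d <- frameset_density(frames_in_region(s$meta, s$frames, em))
    expect_equal(d$density, 1)
  }
  expect_false(anyNA(s$frames$true_label))
})

test_that("lag, decay, and interior zones follow the generative model", {
  cfg <- recovery_config(region_duration_range = c(3, 8))
  s <- simulate_session(cfg, seed = 11)
  m <- s$meta
  idx <- findInterval(s$frames$timestamp, m$t_start_s)
  target <- m$emotion[idx]
  off_s <- s$frames$timestamp - m$t_start_s[idx]
  off_e <- m$t_end_s[idx] - s$frames$timestamp
  lab <- s$frames$true_label

  in_lag <- off_s < 0.6
  in_decay <- !in_lag & off_e <= 1.0
  interior <- !in_lag & !in_decay

  # interior frames always express the target (p_express = 1)
  expect_true(all(lab[interior] == target[interior]))
  # decay frames rest at neutral
  expect_true(all(lab[in_decay] == "neutral"))
  # lag frames carry the previous region's emotion or neutral
  prev <- c(NA_character_, m$emotion)[idx]
  ok_lag <- lab[in_lag] == "neutral" |
    lab[in_lag] == prev[in_lag]
  expect_true(all(ok_lag, na.rm = TRUE))

  # with carryover off, boundary density per non-neutral region is exactly
  # the interval-arithmetic count of interior frames over in-region frames
  cfg1 <- simulation_config(onset_lag = 0.6, decay = 1.0, p_express = 1,
                            p_invalid = 0, carryover_prob = 0,
                            region_duration_range = c(3, 8))
  for (seed in c(4, 11, 29)) {
    s1 <- simulate_session(cfg1, seed = seed)
    grid <- s1$frames$timestamp
    for (em in setdiff(unique(s1$meta$emotion), "neutral")) {
      d <- frameset_density(frames_in_region(s1$meta, s1$frames, em))
      regs <- s1$meta[s1$meta$emotion == em, ]
      exp_retained <- sum(purrr::map_int(seq_len(nrow(regs)), function(i)
        sum(grid >= regs$t_start_s[[i]] & grid < regs$t_end_s[[i]])))
      exp_matching <- sum(purrr::map_int(seq_len(nrow(regs)), function(i)
        sum(grid >= regs$t_start_s[[i]] + 0.6 &
              grid < regs$t_end_s[[i]] - 1.0)))
      expect_equal(d$retained, exp_retained)
      expect_equal(d$matching, exp_matching)
    }
  }
})

test_that("synthetic scores honor the calibration contract", {
  cfg <- simulation_config(p_invalid = 0)
  s <- simulate_session(cfg, seed = 21)
  # ~10,000 simulated frame draws: 450 frames x 3 providers x repeats
  sc <- purrr::map_dfr(1:8, function(i)
    simulate_scores(s$frames, cfg, seed = 100 + i))
  joined <- dplyr::left_join(
    sc, dplyr::select(s$frames, "frame_id", "true_label"), by = "frame_id")
  means <- joined |>
    dplyr::group_by(is_true = .data$emotion == .data$true_label) |>
    dplyr::summarise(m = mean(.data$score))
  expect_gt(means$m[means$is_true], max(0.5, means$m[!means$is_true]))

  by_emotion <- joined |>
    dplyr::group_by(.data$emotion,
                    is_true = .data$emotion == .data$true_label) |>
    dplyr::summarise(m = mean(.data$score), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "is_true", values_from = "m")
  expect_true(all(by_emotion$`TRUE` > by_emotion$`FALSE`))

  expect_true(all(sc$score >= 0 & sc$score <= 1))
})

test_that("score edge cases: one-hot limit, total miss, no providers", {
  cfg <- simulation_config(
    p_invalid = 0,
    providers = list(provider_profile("hot", concentration = Inf,
                                      miss_rate = 0)))
  s <- simulate_session(cfg, seed = 2)
  sc <- simulate_scores(s$frames, cfg, seed = 2)
  wide <- dplyr::left_join(sc, dplyr::select(s$frames, "frame_id",
                                             "true_label"), by = "frame_id")
  expect_true(all(wide$score[wide$emotion == wide$true_label] == 1))
  expect_true(all(wide$score[wide$emotion != wide$true_label] == 0))

  cfg_miss <- simulation_config(
    providers = list(provider_profile("gone", miss_rate = 1)))
  expect_equal(nrow(simulate_scores(s$frames, cfg_miss, seed = 2)), 0L)

  cfg_none <- simulation_config()
  cfg_none$providers <- list()
  expect_error(simulate_scores(s$frames, cfg_none, seed = 2), "provider")
})

test_that("infeasible configs are rejected", {
  expect_error(simulation_config(onset_lag = 1.5, decay = 0.8,
                                 region_duration_range = c(2, 10)),
               "infeasible")
  expect_error(simulation_config(p_express = 1.4), "0, 1")
  expect_error(simulation_config(emotion_weights = c(happy = 0)),
               "not all zero")
})

test_that("bundles round-trip through the interchange formats on disk", {
  cfg <- simulation_config()
  b <- simulate_bundle(cfg, n_sessions = 2, seed = 13)
  dir <- withr::local_tempdir()
  write_bundle(b, dir, cfg)
  back <- read_bundle(dir)

  expect_equal(back$meta$emotion, b$meta$emotion)
  expect_equal(back$meta$t_start_s, b$meta$t_start_s, tolerance = 1e-9)
  # perfect-rater annotations reproduce the truth map exactly
  expect_equal(back$frames$true_label, b$frames$true_label)
  # scores survive the dialect round trip (percent dialects included)
  merged <- dplyr::inner_join(
    b$scores, back$scores,
    by = c("frame_id", "provider", "emotion"), suffix = c("", ".back"))
  expect_equal(nrow(merged), nrow(b$scores))
  expect_equal(merged$score.back, merged$score, tolerance = 1e-9)
})
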