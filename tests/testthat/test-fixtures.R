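test_that("synthetic tracks are deterministic, ordered and analytically calibrated", {
  spec <- synthetic_sentence_spec(rng_seed = 41)
  a <- make_tracks(spec, "sA")
  b <- make_tracks(spec, "sA")
  expect_identical(a$f2$freqs, b$f2$freqs)
  expect_identical(a$keywords, b$keywords)

  # formant ordering and F1-F2 clearance at every frame
  expect_true(all(a$f1$freqs < a$f2$freqs))
  expect_true(all(a$f2$freqs < a$f3$freqs))
  expect_true(all(a$f2$freqs - a$f1$freqs >= 200))
  expect_true(length(a$keywords) >= 2 && length(a$keywords) <= 5)
  expect_gt(length(a$phonemes), 0)

  # F2 log-range equals the spec excursion; cycle estimate is finite
  lr <- max(log(a$f2$freqs)) - min(log(a$f2$freqs))
  expect_equal(lr, 2 * 0.22, tolerance = 0.02)
  est <- estimate_cycles(block_smooth(a$f2$freqs, 40),
                         geometric_mean(a$f2), track_duration(a$f2))
  expect_gt(est$period_T, 0)
  expect_true(is.finite(est$period_T))

  expect_error(
    make_tracks(synthetic_sentence_spec(formant_centers = c(500, 650, 2500),
                                        log_excursion = c(0.3, 0.3, 0.1),
                                        rng_seed = 1)),
    "infeasible")
})

test_that("corpus generation writes round-trippable track files with distinct contours", {
  dir <- withr::local_tempdir()
  corpus <- make_corpus(6, base_seed = 2, dir = dir)
  expect_length(corpus, 6)
  files <- list.files(dir, pattern = "\\.tsv$")
  expect_length(files, 6)

  back <- read_formant_tracks(file.path(dir, "s003.tsv"),
                              keywords = corpus[[3]]$keywords)
  expect_equal(back$f2$freqs, corpus[[3]]$f2$freqs, tolerance = 1e-6)
  expect_equal(back$f1$amps, corpus[[3]]$f1$amps, tolerance = 1e-6)
  expect_equal(back$f1$frame_period, 0.001)

  # per-sentence seeds give distinct F2 contours
  g2 <- vapply(corpus, function(s) geometric_mean(s$f2), numeric(1))
  first <- vapply(corpus, function(s) s$f2$freqs[1], numeric(1))
  expect_equal(anyDuplicated(paste(g2, first)), 0L)
})

test_that("track file reader rejects non-uniform frame spacing", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(time_s = c(0, 0.001, 0.003),
                   f1_hz = rep(500, 3), a1 = 1,
                   f2_hz = rep(1500, 3), a2 = 1,
                   f3_hz = rep(2500, 3), a3 = 1)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  expect_error(read_formant_tracks(path), "uniformly spaced")
})

test_that("simulated listeners follow the psychometric function", {
  plan <- data.frame(condition = c("a", "b"), x = c(100, 0),
                     n_keywords = c(500, 500))
  # saturated function: certain success above, certain failure at zero
  p_step <- weibull_params(0, 0, alpha = 1, beta = 2)
  out <- simulate_responses(plan, p_step, rng_seed = 4)
  expect_equal(out$n_correct[out$condition == "a"], 500)
  expect_equal(out$n_correct[out$condition == "b"], 0)

  # intermediate probability: observed rate within 3 binomial SEs
  p_mid <- weibull_params(0, 0.4, alpha = 30, beta = 1)
  plan2 <- data.frame(condition = "c", x = 30, n_keywords = 1000)
  p <- weibull_eval(30, p_mid)
  out2 <- simulate_responses(plan2, p_mid, rng_seed = 4)
  se <- sqrt(p * (1 - p) / 1000)
  expect_lt(abs(out2$n_correct / 1000 - p), 3 * se)

  # determinism and listener replication
  out3 <- simulate_responses(plan, p_mid, n_listeners = 3, rng_seed = 7)
  expect_equal(nrow(out3), 6)
  expect_identical(simulate_responses(plan, p_mid, 3, 7), out3)
})

test_that("simulated experiment recovers the generating psychometric function", {
  truth <- weibull_params(0.07, 0.28, 33, 1.5)
  conds <- build_condition_table("exp1")
  # 4 sentences x ~3 keywords per condition per listener, 20 listeners
  plan <- do.call(rbind, lapply(seq_len(nrow(conds)), function(i)
    data.frame(condition = conds$id[i],
               x = 100 * conds$target_scale_x[i],
               n_keywords = c(3, 3, 3, 4))))
  out <- simulate_responses(plan, truth, n_listeners = 20, rng_seed = 19)
  pooled <- do.call(rbind, lapply(split(out, out$x), function(d)
    data.frame(x = d$x[1],
               pct = pooled_condition_score(d$n_keywords, d$n_correct))))
  fit <- fit_weibull(pooled$x, pooled$pct / 100)
  expect_equal(fit$params$alpha, truth$alpha, tolerance = 0.2)
  expect_equal(fit$params$beta, truth$beta, tolerance = 0.35)
  expect_gt(fit$r_squared, 0.95)
})

test_that("a synthetic corpus flows through the exp3 plan end to end", {
  # 16 sentences: exp3 has 8 conditions, so two sentences per condition
  corpus <- make_corpus(16, base_seed = 99,
                        spec = synthetic_sentence_spec(duration = 1.2))
  dir <- withr::local_tempdir()
  manifest <- make_stimuli(corpus, "exp3", rotation = 1, rng_seed = 99,
                           out_dir = dir)
  expect_equal(nrow(manifest), 16)
  expect_setequal(unique(manifest$condition), paste0("C", 1:8))
  expect_true(all(file.exists(file.path(dir, manifest$wav))))
  expect_true(file.exists(file.path(dir, "manifest.tsv")))

  # every synthesized stimulus is finite, in range, and non-trivial
  for (wav in manifest$wav[c(1, 8, 16)]) {
    stim <- read_wav(file.path(dir, wav))
    expect_true(all(abs(stim$left) <= 1) && all(abs(stim$right) <= 1))
    expect_gt(max(abs(stim$right)), 0)
  }

  # the separation constraint holds across the whole corpus
  audit <- competitor_separation_audit(corpus, base_seed = 99)
  expect_gte(min(audit$min_gap_hz), 80)
})
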